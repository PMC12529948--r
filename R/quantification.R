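#' Standard-addition quantification
#'
#' Ordinary least-squares fit of response = a + b * spike over all
#' replicates; the in-assay concentration is the magnitude of the x-axis
#' intercept, a/b. Its 95\% confidence half-width follows from first-order
#' (Fieller-type) propagation of the (a, b) covariance with the regression's
#' t quantile.
#'
#' @param spikes spike levels in ug/L, one per observation; must contain
#'   level 0 (the unspiked sample) and at least 3 distinct levels.
#' @param responses detector responses, positive, same length.
#' @return A [QuantResult-class] without dilution correction
#'   (\code{dilutionFactor} 1); LOD/LOQ are \code{NA} until derived via
#'   [lodLoqFromSn()].
#' @examples
#' sa <- simulateStandardAddition(500, noiseCv = 0, seed = 1)
#' fitStandardAddition(sa$spike, sa$response)
#' @export
fitStandardAddition <- function(spikes, responses) {
  if (length(spikes) != length(responses))
    stop("spikes and responses must have equal length")
  if (length(unique(spikes)) < 3)
    stop("at least 3 distinct spike levels are required")
  if (!any(spikes == 0))
    stop("the unspiked sample (spike level 0) must be included")
  if (any(responses <= 0)) stop("responses must be positive")
  fit <- stats::lm(responses ~ spikes)
  a <- stats::coef(fit)[[1]]
  b <- stats::coef(fit)[[2]]
  if (b <= 0) stop("non-positive sensitivity: regression slope must be > 0")
  vc <- suppressWarnings(stats::vcov(fit))  # noiseless data: perfect fit
  conc <- a / b
  # var(a/b) to first order in the estimates' covariance
  v <- vc[1, 1] / b^2 + a^2 * vc[2, 2] / b^4 - 2 * a * vc[1, 2] / b^3
  df <- stats::df.residual(fit)
  half <- stats::qt(0.975, df) * sqrt(max(v, 0))
  new("QuantResult",
      concAssay = .vwc(abs(conc), half),
      concSample = .vwc(abs(conc), half),
      dilutionFactor = 1, lod = NA_real_, loq = NA_real_,
      slope = b, intercept = a, vcov = unname(vc), df = df)
}

#' Correct a standard-addition result for sample dilution
#'
#' @param result a [QuantResult-class].
#' @param aliquot sample aliquot volume (uL), > 0.
#' @param total final assay volume (uL), >= aliquot.
#' @return The [QuantResult-class] with \code{dilutionFactor} total/aliquot
#'   and \code{concSample} (point estimate and CI) scaled linearly.
#' @examples
#' sa <- simulateStandardAddition(500, noiseCv = 0, seed = 1)
#' q <- fitStandardAddition(sa$spike, sa$response)
#' dilutionCorrect(q, aliquot = 20, total = 120)   # factor 6
#' @export
dilutionCorrect <- function(result, aliquot, total) {
  stopifnot(is(result, "QuantResult"))
  if (aliquot <= 0) stop("aliquot volume must be positive")
  if (total < aliquot) stop("total volume must be >= aliquot")
  f <- total / aliquot
  result@dilutionFactor <- f
  result@concSample <- .vwc(result@concAssay@value * f,
                            result@concAssay@ci95 * f)
  validObject(result)
  result
}

#' LOD and LOQ by signal-to-noise extrapolation
#'
#' Assuming the signal-to-noise ratio proportional to concentration, the
#' measured concentration is extrapolated to the concentrations at S/N 3
#' (limit of detection) and S/N 10 (limit of quantification):
#' lod = conc x 3 / sn, loq = conc x 10 / sn. Their ratio is exactly 10/3.
#'
#' @param measuredConc measured concentration (ug/L), > 0.
#' @param measuredSn signal-to-noise ratio of that measurement, > 0.
#' @return list(lod, loq) in ug/L.
#' @examples
#' lodLoqFromSn(0.233, 10)   # lod 0.07, loq 0.233
#' @export
lodLoqFromSn <- function(measuredConc, measuredSn) {
  if (measuredConc <= 0 || measuredSn <= 0)
    stop("measuredConc and measuredSn must be positive")
  list(lod = measuredConc * 3 / measuredSn,
       loq = measuredConc * 10 / measuredSn)
}
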