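#' Normalize a peak area to the internal standard
#'
#' @param rawArea raw chromatographic peak area (counts).
#' @param isArea internal-standard peak area (counts), > 0.
#' @return ratio rawArea / isArea (vectorized).
#' @export
normalizeToIS <- function(rawArea, isArea) {
  if (any(isArea <= 0)) stop("internal-standard area must be positive")
  rawArea / isArea
}

#' Reduced-species fraction of a redox couple over time
#'
#' Percentage of the reduced species' IS-normalized area on the sum of both
#' species, per timepoint.
#'
#' @param series a [SpeciesSeries-class].
#' @return numeric vector, percent (0-100), one value per timepoint.
#' @export
speciesFraction <- function(series) {
  stopifnot(is(series, "SpeciesSeries"))
  tot <- series@areaReduced + series@areaOxidized
  bad <- which(tot <= 0)
  if (length(bad))
    stop(sprintf("zero total area at timepoint t = %g h", series@times[bad[1]]))
  100 * series@areaReduced / tot
}

#' Mass-balance diagnostic of a speciation series
#'
#' Computes the per-timepoint sum of both species' normalized areas and its
#' relative deviation from the series mean sum. Constancy of the sum
#' indicates that the two species interconvert without losses to side
#' reactions.
#'
#' @param series a [SpeciesSeries-class] with >= 2 timepoints.
#' @param tolerance maximal allowed relative deviation, default 0.04.
#' @return list(pass, maxDeviation, deviations).
#' @export
massBalanceCheck <- function(series, tolerance = 0.04) {
  stopifnot(is(series, "SpeciesSeries"))
  if (length(series@times) < 2) stop("at least 2 timepoints are required")
  s <- series@areaReduced + series@areaOxidized
  dev <- abs(s - mean(s)) / mean(s)
  list(pass = max(dev) < tolerance, maxDeviation = max(dev),
       deviations = dev)
}

#' Fit a speciation-kinetics model
#'
#' Fits the reduced-species fraction versus time with either a linear
#' decline f(t) = f0 + slope t, an exponential approach to plateau
#' f(t) = plateau + (f0 - plateau) exp(-k t) (nonlinear least squares with
#' deterministic starts: f0 = first value, plateau = last value,
#' k = 3 / t_max), or automatic selection of the model with the higher R^2
#' (ties favour linear). Fractions are carried on the 0-1 scale; percent
#' input (values above 1) is converted.
#'
#' @param times hours, >= 4 timepoints.
#' @param fractions reduced-species fractions, 0-1 (or percent, 0-100).
#' @param model \code{"linear"}, \code{"exponential_plateau"} or
#'   \code{"auto"}; \code{"auto"} on fewer than 6 points issues a warning.
#' @return A [KineticFit-class]. A constant series is reported as a
#'   degenerate linear fit with slope 0 and R^2 NA.
#' @examples
#' t <- kineticsTimeGrid()
#' fitKinetics(t, 0.92 - 6.6e-4 * t, "linear")
#' @export
fitKinetics <- function(times, fractions,
                        model = c("linear", "exponential_plateau", "auto")) {
  model <- match.arg(model)
  if (length(times) != length(fractions))
    stop("times and fractions must have equal length")
  if (length(times) < 4) stop("at least 4 timepoints are required")
  if (max(fractions) > 1) fractions <- fractions / 100
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1] (or [0, 100] as percent)")

  if (diff(range(fractions)) == 0) {
    return(new("KineticFit", model = "linear",
               params = c(f0 = fractions[1], slope = 0),
               ci95 = c(f0 = 0, slope = 0), r2 = NA_real_,
               degenerate = TRUE))
  }
  if (model == "auto") {
    if (length(times) < 6)
      warning("'auto' model selection on fewer than 6 timepoints")
    lin <- fitKinetics(times, fractions, "linear")
    ex <- tryCatch(fitKinetics(times, fractions, "exponential_plateau"),
                   error = function(e) NULL)
    if (is.null(ex) || is.na(ex@r2) || ex@r2 <= lin@r2) return(lin)
    return(ex)
  }

  sst <- sum((fractions - mean(fractions))^2)
  if (model == "linear") {
    fit <- stats::lm(fractions ~ times)
    cf <- stats::coef(fit)
    # confint warns about 'essentially perfect fit' on noiseless data
    ci <- tryCatch(suppressWarnings(stats::confint(fit)),
                   error = function(e) matrix(NA_real_, 2, 2))
    half <- (ci[, 2] - ci[, 1]) / 2
    r2 <- 1 - sum(stats::residuals(fit)^2) / sst
    return(new("KineticFit", model = "linear",
               params = c(f0 = unname(cf[1]), slope = unname(cf[2])),
               ci95 = c(f0 = unname(half[1]), slope = unname(half[2])),
               r2 = r2, degenerate = FALSE))
  }

  d <- data.frame(t = times, f = fractions)
  start <- list(f0 = fractions[1], plateau = fractions[length(fractions)],
                k = 3 / max(times))
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ plateau + (f0 - plateau) * exp(-k * t), data = d,
                      start = start, lower = c(0, 0, 1e-9), upper = c(1, 1, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop(sprintf(
      "exponential-plateau fit did not converge: %s", conditionMessage(e))))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 3))
  tq <- stats::qt(0.975, max(length(times) - 3, 1))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sst
  new("KineticFit", model = "exponential_plateau",
      params = c(f0 = cf[["f0"]], plateau = cf[["plateau"]], k = cf[["k"]]),
      ci95 = c(f0 = tq * se[1], plateau = tq * se[2], k = tq * se[3]),
      r2 = r2, degenerate = FALSE)
}

#' Deprotonated fraction by Henderson-Hasselbalch
#'
#' Fraction of the anionic (deprotonated) form of a monoprotic acid at a
#' given pH: 1 / (1 + 10^(pKa - pH)). Strictly increasing in pH.
#'
#' @param pH solution pH (vectorized).
#' @param pKa acid dissociation constant of the phenol.
#' @return fraction in (0, 1).
#' @examples
#' deprotonatedFraction(7, 7)        # 0.5
#' deprotonatedFraction(9, 7)        # 0.990
#' @export
deprotonatedFraction <- function(pH, pKa) {
  1 / (1 + 10^(pKa - pH))
}
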