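.plateData <- function(plate) {
  if (is(plate, "PlateSeries"))
    return(data.frame(conc = plate@concentrations, response = plate@responses))
  if (is.list(plate) && all(vapply(plate, is, logical(1), "PlateSeries"))) {
    return(do.call(rbind, lapply(plate, .plateData)))
  }
  if (is.data.frame(plate)) {
    stopifnot(all(c("conc", "response") %in% names(plate)))
    return(plate[, c("conc", "response")])
  }
  stop("plate must be a PlateSeries, a list of PlateSeries, or a data.frame")
}

#' Fit a 4-parameter logistic concentration-response model
#'
#' Least-squares fit of
#' \deqn{r(c) = floor + \frac{ceiling - floor}{1 + (ec50/c)^{hill}}}
#' by Levenberg-Marquardt with a fixed, deterministic starting heuristic
#' (floor = min response, ceiling = max response, ec50 = geometric mid-dose,
#' hill = 1). The parameter covariance of the converged fit drives all
#' downstream delta-method confidence intervals.
#'
#' @param plate a [PlateSeries-class], a list of them (replicates are
#'   pooled), or a data.frame(conc, response).
#' @return A [DoseResponseFit-class].
#' @examples
#' ps <- simulateYesPlate(120, hill = 1.2, noiseCv = 0, seed = 1)
#' fit <- fit4PL(ps)
#' ec50(fit)
#' @export
fit4PL <- function(plate) {
  d <- .plateData(plate)
  if (length(unique(d$conc)) < 5)
    stop("at least 5 distinct concentrations are required")
  if (diff(range(d$response)) == 0)
    stop("no response: responses are constant")
  start <- list(floor = min(d$response), ceiling = max(d$response),
                ec50 = sqrt(min(d$conc) * max(d$conc)), hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ floor + (ceiling - floor) / (1 + (ec50 / conc)^hill),
      data = d, start = start,
      lower = c(-Inf, -Inf, 1e-12, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop(sprintf("4PL fit did not converge: %s",
                                     conditionMessage(e))))
  cf <- stats::coef(fit)
  if (cf[["ceiling"]] <= cf[["floor"]])
    stop("no response: fitted ceiling does not exceed floor")
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(0, 4, 4))
  if (any(!is.finite(vc))) vc <- matrix(0, 4, 4)
  dimnames(vc) <- list(names(cf), names(cf))
  new("DoseResponseFit", floor = cf[["floor"]], ceiling = cf[["ceiling"]],
      ec50 = cf[["ec50"]], hill = cf[["hill"]], vcov = vc,
      df = nrow(d) - 4, data = d)
}

#' Predict the 4PL response at given concentrations
#'
#' @param fit a [DoseResponseFit-class].
#' @param conc concentrations (same units as the fit).
#' @return predicted responses.
#' @export
predict4PL <- function(fit, conc) {
  fit@floor + (fit@ceiling - fit@floor) / (1 + (fit@ec50 / conc)^fit@hill)
}

#' Effect concentration at a given effect level
#'
#' Concentration at which the fitted response reaches
#' floor + (level/100) (ceiling - floor). The 4PL inverse is analytic:
#' \deqn{EC_{level} = ec50 \left(\frac{level}{100-level}\right)^{1/hill}}
#' The 95\% confidence half-width comes from the first-order delta method on
#' (ec50, hill) with the fit's t quantile.
#'
#' @param fit a [DoseResponseFit-class].
#' @param level effect level in percent, in (0, 100).
#' @return A [ValueWithCI-class] (concentration units of the fit).
#' @examples
#' ps <- simulateYesPlate(120, hill = 1.2, noiseCv = 0, seed = 1)
#' ecLevel(fit4PL(ps), 10)
#' @export
ecLevel <- function(fit, level) {
  stopifnot(is(fit, "DoseResponseFit"))
  if (level <= 0 || level >= 100) stop("level must lie strictly in (0, 100)")
  ratio <- level / (100 - level)
  ec <- fit@ec50 * ratio^(1 / fit@hill)
  # gradient wrt (floor, ceiling, ec50, hill); only ec50 and hill enter
  g <- c(0, 0,
         ratio^(1 / fit@hill),
         -fit@ec50 * ratio^(1 / fit@hill) * log(ratio) / fit@hill^2)
  v <- as.numeric(t(g) %*% fit@vcov %*% g)
  tq <- if (fit@df > 0) stats::qt(0.975, fit@df) else stats::qnorm(0.975)
  .vwc(ec, tq * sqrt(max(v, 0)))
}

#' Estradiol equivalents of a sample dilution series
#'
#' The sample's estrogenic potential expressed as the concentration of
#' 17beta-estradiol with equal effect:
#' E2-EQ = EC10(PC) x dilution factor at which the sample response reaches
#' the positive control's 10\% effect level. The sample's effect dilution is
#' interpolated from the sample's own 4PL fit; the confidence interval is
#' propagated from both fits by the delta method over their independent
#' parameter covariances.
#'
#' @param sampleCurve a [PlateSeries-class] (or list / data.frame) whose
#'   concentration axis is the \emph{relative concentration} of the sample,
#'   i.e. 1/dilution factor (1 = undiluted).
#' @param pcFit positive-control [DoseResponseFit-class] with concentrations
#'   in ng/L.
#' @param level effect level in percent, default 10.
#' @return A [ValueWithCI-class], ng/L.
#' @export
e2Equivalents <- function(sampleCurve, pcFit, level = 10) {
  stopifnot(is(pcFit, "DoseResponseFit"))
  sFit <- fit4PL(sampleCurve)
  val <- .e2eqFromParams(
    c(pcFit@floor, pcFit@ceiling, pcFit@ec50, pcFit@hill),
    c(sFit@floor, sFit@ceiling, sFit@ec50, sFit@hill), level)
  if (!is.finite(val))
    stop("below effect threshold: sample never reaches the PC effect level")
  theta <- c(pcFit@floor, pcFit@ceiling, pcFit@ec50, pcFit@hill,
             sFit@floor, sFit@ceiling, sFit@ec50, sFit@hill)
  fn <- function(p) .e2eqFromParams(p[1:4], p[5:8], level)
  g <- .numGrad(fn, theta)
  V <- matrix(0, 8, 8)
  V[1:4, 1:4] <- pcFit@vcov
  V[5:8, 5:8] <- sFit@vcov
  v <- as.numeric(t(g) %*% V %*% g)
  df <- min(pcFit@df, sFit@df)
  tq <- if (df > 0) stats::qt(0.975, df) else stats::qnorm(0.975)
  .vwc(val, tq * sqrt(max(v, 0)))
}

# E2-EQ from PC params (floor, ceiling, ec50, hill) and sample params:
# the PC's `level`% response inverted on the sample curve gives the relative
# concentration c*; E2-EQ = EC_level(PC) / c*.
.e2eqFromParams <- function(pc, s, level) {
  rLev <- pc[1] + level / 100 * (pc[2] - pc[1])
  if (rLev <= s[1] || rLev >= s[2]) return(NA_real_)
  cStar <- s[3] * ((rLev - s[1]) / (s[2] - rLev))^(1 / s[4])
  ecPc <- pc[3] * (level / (100 - level))^(1 / pc[4])
  ecPc / cStar
}

.numGrad <- function(fn, x, rel = 1e-6) {
  f0 <- fn(x)
  vapply(seq_along(x), function(i) {
    h <- rel * max(abs(x[i]), 1e-8)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(1))
}
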