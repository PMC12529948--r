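.asVwc <- function(x) {
  if (is(x, "ValueWithCI")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(.vwc(x, 0))
  if (is.numeric(x) && length(x) == 2L) return(.vwc(x[1], x[2]))
  stop("expected a ValueWithCI or a numeric (value) or numeric(2) (value, ci)")
}

.relErr <- function(x) if (x@value == 0) 0 else x@ci95 / abs(x@value)

# first-order Gaussian propagation for products/ratios: relative 95%
# half-widths add in quadrature
.propagateRatio <- function(value, ...) {
  rel <- sqrt(sum(vapply(list(...), .relErr, numeric(1))^2))
  .vwc(value, abs(value) * rel)
}

#' Relative potency of an analyte
#'
#' REP = EC10(E2) / EC10(analyte); the 95\% half-width follows first-order
#' Gaussian propagation (relative half-widths added in quadrature).
#'
#' @param ec10E2 EC10 of the estradiol positive control (ng/L), as a
#'   [ValueWithCI-class] or numeric(2) (value, half-width).
#' @param ec10Analyte EC10 of the analyte (ng/L), same forms.
#' @return A [ValueWithCI-class] (dimensionless).
#' @examples
#' relativePotency(ValueWithCI(19, 3), ValueWithCI(329000, 59000))
#' @export
relativePotency <- function(ec10E2, ec10Analyte) {
  a <- .asVwc(ec10E2); b <- .asVwc(ec10Analyte)
  if (a@value <= 0 || b@value <= 0)
    stop("both effect concentrations must be positive")
  .propagateRatio(a@value / b@value, a, b)
}

#' Estradiol equivalent of an analyte
#'
#' E2-EQ(analyte) = REP x C, with quadrature-propagated relative uncertainty.
#'
#' @param rep relative potency ([ValueWithCI-class] or numeric).
#' @param conc analyte concentration in the sample (ng/L), same forms.
#' @return A [ValueWithCI-class], ng/L.
#' @export
e2eqAnalyte <- function(rep, conc) {
  r <- .asVwc(rep); cc <- .asVwc(conc)
  if (r@value <= 0 || cc@value <= 0)
    stop("rep and conc must be positive")
  .propagateRatio(r@value * cc@value, r, cc)
}

#' Percent contribution of an analyte to the sample's total effect
#'
#' percentage = E2-EQ(analyte) / E2-EQ(sample) x 100, with first-order
#' Gaussian propagation. When called through the composed chain
#' ([effectBalance()]) the propagated half-width carries all four input
#' uncertainties.
#'
#' @param e2eqAnalyte analyte estradiol equivalent (ng/L).
#' @param e2eqSample sample estradiol equivalent (ng/L), > 0.
#' @return A [ValueWithCI-class], percent.
#' @export
percentContribution <- function(e2eqAnalyte, e2eqSample) {
  a <- .asVwc(e2eqAnalyte); s <- .asVwc(e2eqSample)
  if (s@value <= 0) stop("sample E2-EQ must be positive")
  .propagateRatio(a@value / s@value * 100, a, s)
}

#' Full effect-balance chain
#'
#' Chains relative potency, analyte estradiol equivalent and percent
#' contribution. Because relative half-widths add in quadrature at every
#' step, the chained result equals the single-formula evaluation
#' (EC10(E2) x C) / (EC10(analyte) x E2-EQ(sample)) x 100 with all four
#' relative errors propagated jointly; the four inputs are treated as
#' independent (they come from separate experiments).
#'
#' @param ec10E2 EC10 of the estradiol positive control (ng/L).
#' @param ec10Analyte EC10 of the analyte (ng/L).
#' @param analyteConc analyte concentration in the sample (ng/L).
#' @param e2eqSample total estradiol equivalent of the sample (ng/L).
#' @return An [EffectBalance-class].
#' @examples
#' # worked example: 19 +- 3 ng/L, 329000 +- 59000 ng/L,
#' # 3000 +- 170 ug/L (in ng/L), 140 +- 7 ng/L -> ~120 +- 30 %
#' effectBalance(ValueWithCI(19, 3), ValueWithCI(329000, 59000),
#'               ValueWithCI(3e6, 1.7e5), ValueWithCI(140, 7))
#' @export
effectBalance <- function(ec10E2, ec10Analyte, analyteConc, e2eqSample) {
  ec10E2 <- .asVwc(ec10E2); ec10Analyte <- .asVwc(ec10Analyte)
  analyteConc <- .asVwc(analyteConc); e2eqSample <- .asVwc(e2eqSample)
  rep <- relativePotency(ec10E2, ec10Analyte)
  eqA <- e2eqAnalyte(rep, analyteConc)
  pct <- percentContribution(eqA, e2eqSample)
  new("EffectBalance", rep = rep, analyteConc = analyteConc,
      e2eqAnalyte = eqA, e2eqSample = e2eqSample, percent = pct)
}
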