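#' @import methods
NULL

.FEATURE_ROLES <- c("extract", "fraction_upper", "fraction_lower", "blank")
.POLARITIES <- c("positive", "negative")

#' FeatureTable: detected LC-HRMS features of one sample
#'
#' Container for the features (m/z, retention time, intensity) detected in a
#' single LC-HRMS run, together with the sample's role in the effect-directed
#' analysis design and its relative enrichment factor (REF).
#'
#' @slot sampleId character(1), sample label.
#' @slot role character(1), one of \code{"extract"}, \code{"fraction_upper"},
#'   \code{"fraction_lower"}, \code{"blank"}.
#' @slot ref numeric(1), relative enrichment factor (> 0, dimensionless).
#' @slot polarity character(1), ionization mode, \code{"positive"} or
#'   \code{"negative"}; all features of a table share one polarity.
#' @slot features data.frame with numeric columns \code{mz} (Da, > 0),
#'   \code{rt} (min, >= 0) and \code{intensity} (counts, > 0).
#'
#' @seealso [FeatureTable()], [readFeatureTable()], [runCascade()]
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(
    sampleId = "character",
    role = "character",
    ref = "numeric",
    polarity = "character",
    features = "data.frame"
  )
)

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be length 1")
  if (length(object@role) != 1L || !object@role %in% .FEATURE_ROLES)
    msg <- c(msg, sprintf("role must be one of %s",
                          paste(.FEATURE_ROLES, collapse = ", ")))
  if (length(object@ref) != 1L || !is.finite(object@ref) || object@ref <= 0)
    msg <- c(msg, "ref must be a single positive number")
  if (length(object@polarity) != 1L || !object@polarity %in% .POLARITIES)
    msg <- c(msg, "polarity must be 'positive' or 'negative'")
  ft <- object@features
  need <- c("mz", "rt", "intensity")
  if (!all(need %in% names(ft))) {
    msg <- c(msg, sprintf("features must have columns %s",
                          paste(need, collapse = ", ")))
  } else if (nrow(ft) > 0L) {
    bad <- which(!is.finite(ft$mz) | ft$mz <= 0)
    if (length(bad)) msg <- c(msg, sprintf("non-positive mz in row %d", bad[1L]))
    bad <- which(!is.finite(ft$rt) | ft$rt < 0)
    if (length(bad)) msg <- c(msg, sprintf("negative rt in row %d", bad[1L]))
    bad <- which(!is.finite(ft$intensity) | ft$intensity <= 0)
    if (length(bad)) msg <- c(msg, sprintf("non-positive intensity in row %d", bad[1L]))
  }
  if (length(msg)) msg else TRUE
})

#' MatchTolerances: m/z and retention-time matching tolerances
#'
#' Absolute tolerances used throughout the nontarget-screening and
#' prioritization steps. Defaults follow the screening settings: MS1 tolerance
#' 10 mDa, MS2 tolerance 15 mDa, retention-time tolerance 1 min.
#'
#' @slot ms1 numeric(1), absolute MS1 m/z tolerance in Da.
#' @slot ms2 numeric(1), absolute MS2 m/z tolerance in Da.
#' @slot rt numeric(1), retention-time tolerance in minutes.
#' @exportClass MatchTolerances
setClass("MatchTolerances",
  representation(ms1 = "numeric", ms2 = "numeric", rt = "numeric")
)

setValidity("MatchTolerances", function(object) {
  ok <- vapply(list(object@ms1, object@ms2, object@rt),
               function(x) length(x) == 1L && is.finite(x) && x > 0, logical(1))
  if (all(ok)) TRUE else "ms1, ms2 and rt tolerances must all be single positive numbers"
})

#' PlateSeries: one dose-response dilution series
#'
#' Responses of a microtiter-plate bioassay (yeast estrogen screen) along a
#' dilution series. Concentrations are either absolute doses (ng/L) for a
#' defined analyte or relative concentrations (1/dilution factor) for a
#' sample of unknown composition.
#'
#' @slot concentrations numeric, strictly positive, sorted increasing.
#' @slot responses numeric, induction signal (arbitrary units), same length.
#' @slot replicate integer, replicate id per observation.
#' @exportClass PlateSeries
setClass("PlateSeries",
  representation(concentrations = "numeric", responses = "numeric",
                 replicate = "integer")
)

setValidity("PlateSeries", function(object) {
  msg <- character()
  n <- length(object@concentrations)
  if (length(object@responses) != n || length(object@replicate) != n)
    msg <- c(msg, "concentrations, responses and replicate must have equal length")
  if (n && (any(!is.finite(object@concentrations)) || any(object@concentrations <= 0)))
    msg <- c(msg, "concentrations must be strictly positive")
  if (n && is.unsorted(object@concentrations))
    msg <- c(msg, "concentrations must be sorted increasing")
  if (length(msg)) msg else TRUE
})

#' ValueWithCI: a value with its 95\% confidence half-width
#'
#' @slot value numeric(1).
#' @slot ci95 numeric(1), non-negative half-width of the 95\% confidence
#'   interval, in the same units as \code{value}.
#' @exportClass ValueWithCI
setClass("ValueWithCI", representation(value = "numeric", ci95 = "numeric"))

setValidity("ValueWithCI", function(object) {
  if (length(object@value) != 1L || length(object@ci95) != 1L)
    return("value and ci95 must be length 1")
  if (!is.finite(object@value)) return("value must be finite")
  if (!is.finite(object@ci95) || object@ci95 < 0)
    return("ci95 must be a non-negative finite number")
  TRUE
})

#' DoseResponseFit: fitted 4-parameter logistic concentration-response model
#'
#' Parameters of r(c) = floor + (ceiling - floor) / (1 + (ec50/c)^hill),
#' with the estimated parameter covariance used for delta-method confidence
#' intervals on derived effect concentrations.
#'
#' @slot floor,ceiling numeric(1), lower/upper response asymptotes.
#' @slot ec50 numeric(1), concentration of half-maximal response (> 0).
#' @slot hill numeric(1), slope parameter (> 0).
#' @slot vcov 4x4 covariance matrix of (floor, ceiling, ec50, hill).
#' @slot df residual degrees of freedom of the fit.
#' @slot data data.frame(conc, response) the model was fitted to.
#' @exportClass DoseResponseFit
setClass("DoseResponseFit",
  representation(floor = "numeric", ceiling = "numeric", ec50 = "numeric",
                 hill = "numeric", vcov = "matrix", df = "numeric",
                 data = "data.frame")
)

setValidity("DoseResponseFit", function(object) {
  msg <- character()
  if (object@ceiling <= object@floor) msg <- c(msg, "ceiling must exceed floor")
  if (object@ec50 <= 0) msg <- c(msg, "ec50 must be positive")
  if (object@hill <= 0) msg <- c(msg, "hill must be positive")
  if (!all(dim(object@vcov) == c(4L, 4L))) msg <- c(msg, "vcov must be 4x4")
  if (length(msg)) msg else TRUE
})

#' QuantResult: standard-addition quantification result
#'
#' @slot concAssay [ValueWithCI-class], in-assay concentration (ug/L).
#' @slot concSample [ValueWithCI-class], dilution-corrected sample
#'   concentration (ug/L).
#' @slot dilutionFactor numeric(1), >= 1.
#' @slot lod,loq numeric(1), limits of detection/quantification (ug/L); NA
#'   until derived from a measured S/N.
#' @slot slope,intercept numeric(1), regression parameters of response vs spike.
#' @slot vcov 2x2 covariance of (intercept, slope).
#' @slot df residual degrees of freedom.
#' @exportClass QuantResult
setClass("QuantResult",
  representation(concAssay = "ValueWithCI", concSample = "ValueWithCI",
                 dilutionFactor = "numeric", lod = "numeric", loq = "numeric",
                 slope = "numeric", intercept = "numeric", vcov = "matrix",
                 df = "numeric")
)

setValidity("QuantResult", function(object) {
  msg <- character()
  if (object@dilutionFactor < 1) msg <- c(msg, "dilutionFactor must be >= 1")
  if (!is.na(object@lod) && object@lod < 0) msg <- c(msg, "lod must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SpeciesSeries: time series of a two-member redox couple at one pH
#'
#' Internal-standard-normalized chromatographic peak areas of the reduced
#' (phenolic, 4HDPA-like) and oxidized (quinone-imine, QMI-like) members of a
#' redox couple, observed over time in a buffered solution.
#'
#' @slot pH numeric(1).
#' @slot times numeric, hours, non-negative increasing.
#' @slot areaReduced,areaOxidized numeric, IS-normalized areas (>= 0).
#' @slot replicateId character(1).
#' @exportClass SpeciesSeries
setClass("SpeciesSeries",
  representation(pH = "numeric", times = "numeric", areaReduced = "numeric",
                 areaOxidized = "numeric", replicateId = "character")
)

setValidity("SpeciesSeries", function(object) {
  msg <- character()
  n <- length(object@times)
  if (length(object@areaReduced) != n || length(object@areaOxidized) != n)
    msg <- c(msg, "times and areas must have equal length")
  if (n && (any(object@times < 0) || is.unsorted(object@times, strictly = TRUE)))
    msg <- c(msg, "times must be non-negative and strictly increasing")
  if (any(object@areaReduced < 0) || any(object@areaOxidized < 0))
    msg <- c(msg, "areas must be non-negative")
  if (length(msg)) msg else TRUE
})

#' KineticFit: fitted speciation kinetics model
#'
#' Either a linear decline f(t) = f0 + slope * t or an exponential approach to
#' plateau f(t) = plateau + (f0 - plateau) * exp(-k * t), fitted to the
#' reduced-species fraction (0-1 scale) versus time in hours.
#'
#' @slot model character(1), \code{"linear"} or \code{"exponential_plateau"}.
#' @slot params named numeric: (f0, slope) or (f0, plateau, k).
#' @slot ci95 named numeric, 95\% half-widths per parameter.
#' @slot r2 numeric(1), coefficient of determination (NA for degenerate data).
#' @slot degenerate logical(1), TRUE when the data carried no usable signal
#'   (e.g. constant series).
#' @exportClass KineticFit
setClass("KineticFit",
  representation(model = "character", params = "numeric", ci95 = "numeric",
                 r2 = "numeric", degenerate = "logical")
)

setValidity("KineticFit", function(object) {
  msg <- character()
  if (!object@model %in% c("linear", "exponential_plateau"))
    msg <- c(msg, "model must be 'linear' or 'exponential_plateau'")
  if (!is.na(object@r2) && object@r2 > 1 + 1e-12) msg <- c(msg, "r2 must be <= 1")
  if (object@model == "exponential_plateau" && !object@degenerate &&
      object@params[["k"]] <= 0)
    msg <- c(msg, "k must be positive for the exponential model")
  if (length(msg)) msg else TRUE
})

#' EffectBalance: contribution of one analyte to a sample's total effect
#'
#' Result of the relative-potency chain: REP = EC10(E2) / EC10(analyte),
#' E2-EQ(analyte) = REP x C, percent = E2-EQ(analyte) / E2-EQ(sample) x 100,
#' with first-order Gaussian propagation of the 95\% confidence half-widths.
#'
#' @slot rep [ValueWithCI-class], relative potency (dimensionless).
#' @slot analyteConc [ValueWithCI-class], analyte concentration (ng/L).
#' @slot e2eqAnalyte [ValueWithCI-class], analyte estradiol equivalent (ng/L).
#' @slot e2eqSample [ValueWithCI-class], sample estradiol equivalent (ng/L).
#' @slot percent [ValueWithCI-class], percent of the sample's effect explained.
#' @exportClass EffectBalance
setClass("EffectBalance",
  representation(rep = "ValueWithCI", analyteConc = "ValueWithCI",
                 e2eqAnalyte = "ValueWithCI", e2eqSample = "ValueWithCI",
                 percent = "ValueWithCI")
)

setValidity("EffectBalance", function(object) {
  msg <- character()
  if (object@rep@value <= 0) msg <- c(msg, "rep must be positive")
  if (object@percent@value < 0) msg <- c(msg, "percent must be non-negative")
  rel <- abs(object@e2eqAnalyte@value -
             object@rep@value * object@analyteConc@value)
  if (rel > 1e-8 * max(1, abs(object@e2eqAnalyte@value)))
    msg <- c(msg, "e2eqAnalyte must equal rep * analyteConc")
  if (length(msg)) msg else TRUE
})

#' CascadeReport: outcome of the feature-prioritization cascade
#'
#' @slot steps data.frame(step, label, count): surviving feature count after
#'   every cascade step, counts non-increasing.
#' @slot survivors data.frame of final candidate features (extract-5x view).
#' @slot polarity character(1).
#' @exportClass CascadeReport
setClass("CascadeReport",
  representation(steps = "data.frame", survivors = "data.frame",
                 polarity = "character")
)

setValidity("CascadeReport", function(object) {
  cnt <- object@steps$count
  if (length(cnt) > 1L && any(diff(cnt) > 0))
    return("per-step counts must be non-increasing")
  TRUE
})

#' ScenarioTruth: ground truth of a synthetic feature scenario
#'
#' @slot drivers data.frame of planted driver features (formula, mz, rt, base
#'   intensities per sample).
#' @slot background data.frame of background features with the cascade
#'   criterion each one violates.
#' @slot params list of generator parameters.
#' @exportClass ScenarioTruth
setClass("ScenarioTruth",
  representation(drivers = "data.frame", background = "data.frame",
                 params = "list")
)
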