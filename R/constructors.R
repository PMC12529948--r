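#' Construct a FeatureTable
#'
#' @param features data.frame with numeric columns \code{mz} (Da), \code{rt}
#'   (min) and \code{intensity} (counts).
#' @param sampleId sample label.
#' @param role one of \code{"extract"}, \code{"fraction_upper"},
#'   \code{"fraction_lower"}, \code{"blank"}.
#' @param ref relative enrichment factor (> 0).
#' @param polarity \code{"positive"} or \code{"negative"}.
#' @return A [FeatureTable-class] object. Row order of \code{features} is
#'   preserved.
#' @examples
#' ft <- FeatureTable(data.frame(mz = 186.0913, rt = 9.9, intensity = 1e5),
#'                    sampleId = "extract5", role = "extract", ref = 5)
#' nFeatures(ft)
#' @export
FeatureTable <- function(features, sampleId, role = "extract", ref = 1,
                         polarity = "positive") {
  features <- as.data.frame(features)[, c("mz", "rt", "intensity"),
                                      drop = FALSE]
  rownames(features) <- NULL
  new("FeatureTable", sampleId = as.character(sampleId), role = role,
      ref = as.numeric(ref), polarity = polarity, features = features)
}

#' Construct matching tolerances
#'
#' Defaults are the nontarget-screening settings: 10 mDa MS1, 15 mDa MS2,
#' 1 min retention time.
#'
#' @param ms1 absolute MS1 m/z tolerance (Da).
#' @param ms2 absolute MS2 m/z tolerance (Da).
#' @param rt retention-time tolerance (min).
#' @return A [MatchTolerances-class] object.
#' @examples
#' MatchTolerances()
#' @export
MatchTolerances <- function(ms1 = 0.010, ms2 = 0.015, rt = 1.0) {
  new("MatchTolerances", ms1 = ms1, ms2 = ms2, rt = rt)
}

#' Construct a PlateSeries
#'
#' @param concentrations dose values (ng/L) or relative concentrations
#'   (1/dilution factor); strictly positive.
#' @param responses induction signal, same length.
#' @param replicate replicate ids (recycled if length 1).
#' @return A [PlateSeries-class] object sorted by concentration.
#' @export
PlateSeries <- function(concentrations, responses, replicate = 1L) {
  replicate <- as.integer(rep_len(replicate, length(concentrations)))
  o <- order(concentrations)
  new("PlateSeries", concentrations = as.numeric(concentrations[o]),
      responses = as.numeric(responses[o]), replicate = replicate[o])
}

#' Construct a ValueWithCI
#'
#' @param value point estimate.
#' @param ci95 95\% confidence half-width (same units, >= 0).
#' @return A [ValueWithCI-class] object.
#' @examples
#' ValueWithCI(19, 3)
#' @export
ValueWithCI <- function(value, ci95 = 0) {
  new("ValueWithCI", value = as.numeric(value), ci95 = as.numeric(ci95))
}

#' Construct a SpeciesSeries
#'
#' @param times hours, strictly increasing.
#' @param areaReduced,areaOxidized IS-normalized areas of the reduced and
#'   oxidized species.
#' @param pH solution pH.
#' @param replicateId replicate label.
#' @return A [SpeciesSeries-class] object.
#' @export
SpeciesSeries <- function(times, areaReduced, areaOxidized, pH,
                          replicateId = "r1") {
  new("SpeciesSeries", pH = as.numeric(pH), times = as.numeric(times),
      areaReduced = as.numeric(areaReduced),
      areaOxidized = as.numeric(areaOxidized),
      replicateId = as.character(replicateId))
}

.vwc <- function(value, ci95) new("ValueWithCI", value = value,
                                  ci95 = abs(ci95))
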