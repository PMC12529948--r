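#' @name accessors
#' @title Accessors for estroEDA classes
#'
#' @description Slot accessors. \code{nFeatures} counts features in a table,
#' \code{featureData} returns the feature data.frame, \code{sampleRole} and
#' \code{enrichmentFactor} return the design metadata, \code{polarity} the
#' ionization mode. \code{ciValue} and \code{ciHalfWidth} extract the point
#' estimate and 95\% half-width of a [ValueWithCI-class].
#'
#' @param object an estroEDA S4 object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))
#' @rdname accessors
#' @export
setMethod("nFeatures", "FeatureTable", function(object) nrow(object@features))

#' @rdname accessors
#' @export
setGeneric("featureData", function(object) standardGeneric("featureData"))
#' @rdname accessors
#' @export
setMethod("featureData", "FeatureTable", function(object) object@features)

#' @rdname accessors
#' @export
setGeneric("sampleRole", function(object) standardGeneric("sampleRole"))
#' @rdname accessors
#' @export
setMethod("sampleRole", "FeatureTable", function(object) object@role)

#' @rdname accessors
#' @export
setGeneric("enrichmentFactor",
           function(object) standardGeneric("enrichmentFactor"))
#' @rdname accessors
#' @export
setMethod("enrichmentFactor", "FeatureTable", function(object) object@ref)

#' @rdname accessors
#' @export
setGeneric("polarity", function(object) standardGeneric("polarity"))
#' @rdname accessors
#' @export
setMethod("polarity", "FeatureTable", function(object) object@polarity)

#' @rdname accessors
#' @export
setGeneric("ciValue", function(object) standardGeneric("ciValue"))
#' @rdname accessors
#' @export
setMethod("ciValue", "ValueWithCI", function(object) object@value)

#' @rdname accessors
#' @export
setGeneric("ciHalfWidth", function(object) standardGeneric("ciHalfWidth"))
#' @rdname accessors
#' @export
setMethod("ciHalfWidth", "ValueWithCI", function(object) object@ci95)

#' @rdname accessors
#' @export
setGeneric("ec50", function(object) standardGeneric("ec50"))
#' @rdname accessors
#' @export
setMethod("ec50", "DoseResponseFit", function(object) object@ec50)

#' @rdname accessors
#' @export
setGeneric("hillSlope", function(object) standardGeneric("hillSlope"))
#' @rdname accessors
#' @export
setMethod("hillSlope", "DoseResponseFit", function(object) object@hill)

#' @rdname accessors
#' @export
setGeneric("cascadeSteps", function(object) standardGeneric("cascadeSteps"))
#' @rdname accessors
#' @export
setMethod("cascadeSteps", "CascadeReport", function(object) object@steps)

#' @rdname accessors
#' @export
setGeneric("cascadeSurvivors",
           function(object) standardGeneric("cascadeSurvivors"))
#' @rdname accessors
#' @export
setMethod("cascadeSurvivors", "CascadeReport",
          function(object) object@survivors)

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable '%s' (%s, REF %g, %s): %d features\n",
              object@sampleId, object@role, object@ref, object@polarity,
              nrow(object@features)))
  if (nrow(object@features)) {
    cat(sprintf("  m/z %.4f-%.4f Da, rt %.2f-%.2f min\n",
                min(object@features$mz), max(object@features$mz),
                min(object@features$rt), max(object@features$rt)))
  }
  invisible(NULL)
})

setMethod("show", "ValueWithCI", function(object) {
  cat(sprintf("%g ± %g (95%% CI)\n", object@value, object@ci95))
  invisible(NULL)
})

setMethod("show", "DoseResponseFit", function(object) {
  cat("4-parameter logistic fit\n")
  cat(sprintf("  floor %.4g  ceiling %.4g  ec50 %.6g  hill %.4g\n",
              object@floor, object@ceiling, object@ec50, object@hill))
  cat(sprintf("  n = %d observations, df = %g\n", nrow(object@data),
              object@df))
  invisible(NULL)
})

setMethod("show", "QuantResult", function(object) {
  cat("Standard-addition quantification\n")
  cat(sprintf("  in-assay: %.4g ± %.3g ug/L\n",
              object@concAssay@value, object@concAssay@ci95))
  cat(sprintf("  sample (x%g dilution): %.4g ± %.3g ug/L\n",
              object@dilutionFactor, object@concSample@value,
              object@concSample@ci95))
  if (!is.na(object@lod))
    cat(sprintf("  LOD %.3g ug/L, LOQ %.3g ug/L\n", object@lod, object@loq))
  invisible(NULL)
})

setMethod("show", "KineticFit", function(object) {
  cat(sprintf("Kinetic fit (%s)%s\n", object@model,
              if (object@degenerate) " [degenerate]" else ""))
  p <- object@params
  cat("  ", paste(sprintf("%s = %.6g", names(p), p), collapse = ", "), "\n")
  cat(sprintf("  R^2 = %s\n",
              if (is.na(object@r2)) "NA" else sprintf("%.4f", object@r2)))
  invisible(NULL)
})

setMethod("show", "EffectBalance", function(object) {
  cat("Effect balance\n")
  cat(sprintf("  REP          : %.3g ± %.2g\n",
              object@rep@value, object@rep@ci95))
  cat(sprintf("  E2-EQ analyte: %.3g ± %.2g ng/L\n",
              object@e2eqAnalyte@value, object@e2eqAnalyte@ci95))
  cat(sprintf("  E2-EQ sample : %.3g ± %.2g ng/L\n",
              object@e2eqSample@value, object@e2eqSample@ci95))
  cat(sprintf("  contribution : %.3g ± %.2g %%\n",
              object@percent@value, object@percent@ci95))
  invisible(NULL)
})

setMethod("show", "CascadeReport", function(object) {
  cat(sprintf("Prioritization cascade (%s)\n", object@polarity))
  for (i in seq_len(nrow(object@steps)))
    cat(sprintf("  %d. %-45s %d\n", object@steps$step[i],
                object@steps$label[i], object@steps$count[i]))
  invisible(NULL)
})

setMethod("show", "SpeciesSeries", function(object) {
  cat(sprintf("SpeciesSeries pH %g (%s): %d timepoints, %g-%g h\n",
              object@pH, object@replicateId, length(object@times),
              min(object@times), max(object@times)))
  invisible(NULL)
})
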