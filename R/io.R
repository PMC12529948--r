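.FT_COLUMNS <- c(sample_id = "sample_id", role = "role", ref = "ref",
                 polarity = "polarity", mz = "mz", rt_min = "rt_min",
                 intensity = "intensity")

#' Read a feature table from CSV
#'
#' Canonical columns are \code{sample_id, role, ref, polarity, mz, rt_min,
#' intensity}; a \code{schema} map can rename them for foreign files. One
#' file holds one sample's table; row order is preserved.
#'
#' @param path file path of a delimited text file (CSV).
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names.
#' @return A validated [FeatureTable-class].
#' @export
readFeatureTable <- function(path, schema = NULL) {
  cols <- .FT_COLUMNS
  if (!is.null(schema)) cols[names(schema)] <- schema
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(unname(cols), names(d))
  if (length(miss))
    stop(sprintf("schema error: missing column(s) %s in %s",
                 paste(miss, collapse = ", "), path))
  sid <- unique(d[[cols["sample_id"]]])
  role <- unique(d[[cols["role"]]])
  ref <- unique(d[[cols["ref"]]])
  pol <- unique(d[[cols["polarity"]]])
  if (length(sid) != 1L || length(role) != 1L || length(ref) != 1L ||
      length(pol) != 1L)
    stop("a feature-table file must describe exactly one sample (one sample_id, role, ref, polarity)")
  FeatureTable(data.frame(mz = d[[cols["mz"]]], rt = d[[cols["rt_min"]]],
                          intensity = d[[cols["intensity"]]]),
               sampleId = sid, role = role, ref = ref, polarity = pol)
}

#' Write a feature table to CSV
#'
#' @param x a [FeatureTable-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(x, path) {
  stopifnot(is(x, "FeatureTable"))
  d <- data.frame(sample_id = x@sampleId, role = x@role, ref = x@ref,
                  polarity = x@polarity, mz = x@features$mz,
                  rt_min = x@features$rt, intensity = x@features$intensity)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read bioassay plate series from a long-format CSV
#'
#' Expected columns: \code{sample_id}, \code{conc_ngL} (or
#' \code{dilution_factor}, converted to relative concentration
#' 1/dilution), \code{response}, \code{replicate}.
#'
#' @param path file path.
#' @return named list of [PlateSeries-class], one per sample_id.
#' @export
readPlateSeries <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"conc_ngL" %in% names(d)) {
    if (!"dilution_factor" %in% names(d))
      stop("schema error: need column conc_ngL or dilution_factor")
    d$conc_ngL <- 1 / d$dilution_factor
  }
  miss <- setdiff(c("sample_id", "response", "replicate"), names(d))
  if (length(miss))
    stop(sprintf("schema error: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  lapply(split(d, d$sample_id), function(s)
    PlateSeries(s$conc_ngL, s$response, s$replicate))
}

#' Write plate series to a long-format CSV
#'
#' @param plates named list of [PlateSeries-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePlateSeries <- function(plates, path) {
  rows <- lapply(names(plates), function(nm) {
    p <- plates[[nm]]
    data.frame(sample_id = nm, conc_ngL = p@concentrations,
               response = p@responses, replicate = p@replicate)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read speciation-kinetics series from CSV
#'
#' Expected columns: \code{pH, replicate, time_h, area_reduced,
#' area_oxidized, is_area}; areas are normalized to the internal standard on
#' reading.
#'
#' @param path file path.
#' @return list of [SpeciesSeries-class], one per pH x replicate.
#' @export
readKineticsSeries <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pH", "replicate", "time_h", "area_reduced", "area_oxidized",
            "is_area")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("schema error: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  out <- list()
  for (key in split(d, interaction(d$pH, d$replicate, drop = TRUE))) {
    key <- key[order(key$time_h), ]
    out[[length(out) + 1L]] <- SpeciesSeries(
      times = key$time_h,
      areaReduced = normalizeToIS(key$area_reduced, key$is_area),
      areaOxidized = normalizeToIS(key$area_oxidized, key$is_area),
      pH = key$pH[1], replicateId = as.character(key$replicate[1]))
  }
  out
}

#' Write speciation-kinetics series to CSV
#'
#' Areas are written as already-normalized ratios with \code{is_area} 1.
#'
#' @param series list of [SpeciesSeries-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeKineticsSeries <- function(series, path) {
  rows <- lapply(series, function(s)
    data.frame(pH = s@pH, replicate = s@replicateId, time_h = s@times,
               area_reduced = s@areaReduced, area_oxidized = s@areaOxidized,
               is_area = 1))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
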