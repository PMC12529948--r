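#' Read a spectral library CSV
#'
#' The library format is a CSV with columns \code{name}, \code{formula},
#' \code{polarity} ("positive"/"negative"), \code{rt_min}, optionally
#' \code{mz} (computed from the formula and polarity when absent), an MS2
#' spectrum encoded as \code{"mz:relint;mz:relint"} in column \code{ms2}, and
#' a logical \code{reference_standard} flag.
#'
#' @param path file path.
#' @return data.frame with one row per library entry; the \code{ms2} column
#'   is a list column of data.frames (\code{mz}, \code{relint}).
#' @export
readSpectralLibrary <- function(path) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "polarity", "rt_min")
  miss <- setdiff(need, names(lib))
  if (length(miss))
    stop(sprintf("library is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (is.null(lib$mz) || anyNA(lib$mz)) {
    add <- ifelse(lib$polarity == "positive", "[M+H]+", "[M-H]-")
    calc <- mapply(adductMz, lib$formula, add)
    lib$mz <- if (is.null(lib$mz)) calc else ifelse(is.na(lib$mz), calc, lib$mz)
  }
  if (is.null(lib$reference_standard)) lib$reference_standard <- FALSE
  lib$reference_standard <- as.logical(lib$reference_standard)
  lib$ms2 <- lapply(if (is.null(lib$ms2)) rep("", nrow(lib)) else lib$ms2,
                    .parseMs2)
  lib
}

.parseMs2 <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(mz = numeric(), relint = numeric()))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(mz = as.numeric(vapply(parts, `[`, "", 1L)),
             relint = as.numeric(vapply(parts, `[`, "", 2L)))
}

.encodeMs2 <- function(df) {
  if (!nrow(df)) return("")
  paste(sprintf("%.4f:%g", df$mz, df$relint), collapse = ";")
}

#' Match a feature against a spectral library
#'
#' A library entry is a candidate when the m/z difference is within the MS1
#' tolerance and the retention-time difference within the RT tolerance.
#' Candidates are assigned an identification confidence level:
#' \describe{
#'   \item{4}{m/z + RT match only (unequivocal formula evidence).}
#'   \item{3}{feature has an MS2 spectrum but the library entry carries none
#'     to compare against (tentative evidence).}
#'   \item{2}{MS2 library match: at least half of the entry's MS2 peaks are
#'     matched within the MS2 tolerance.}
#'   \item{1}{as level 2, with the entry flagged as a measured reference
#'     standard.}
#' }
#'
#' @param mz,rt feature m/z (Da) and retention time (min).
#' @param library data.frame as returned by [readSpectralLibrary()].
#' @param tol a [MatchTolerances-class] object.
#' @param ms2 optional feature MS2 spectrum, data.frame(mz, relint).
#' @param polarity optional; when given, only entries of this polarity are
#'   considered.
#' @return data.frame of candidates: \code{name}, \code{libMz}, \code{libRt},
#'   \code{deltaMz}, \code{deltaRt}, \code{ms2Score}, \code{confidenceLevel};
#'   zero rows when nothing matches (an empty library is not an error).
#' @export
matchLibrary <- function(mz, rt, library, tol = MatchTolerances(),
                         ms2 = NULL, polarity = NULL) {
  stopifnot(is(tol, "MatchTolerances"))
  empty <- data.frame(name = character(), libMz = numeric(),
                      libRt = numeric(), deltaMz = numeric(),
                      deltaRt = numeric(), ms2Score = numeric(),
                      confidenceLevel = integer())
  if (is.null(library) || !nrow(library)) return(empty)
  if (!is.null(polarity)) library <- library[library$polarity == polarity, ]
  if (!nrow(library)) return(empty)

  dmz <- abs(library$mz - mz)
  drt <- abs(library$rt_min - rt)
  cand <- which(dmz <= tol@ms1 & drt <= tol@rt)
  if (!length(cand)) return(empty)

  rows <- lapply(cand, function(i) {
    entry <- library[i, ]
    libSpec <- library$ms2[[i]]
    score <- NA_real_
    cl <- 4L
    if (!is.null(ms2) && nrow(ms2)) {
      if (nrow(libSpec)) {
        hit <- vapply(libSpec$mz,
                      function(m) any(abs(ms2$mz - m) <= tol@ms2), logical(1))
        score <- mean(hit)
        if (score >= 0.5)
          cl <- if (isTRUE(entry$reference_standard)) 1L else 2L
      } else {
        cl <- 3L
      }
    }
    data.frame(name = entry$name, libMz = entry$mz, libRt = entry$rt_min,
               deltaMz = mz - entry$mz, deltaRt = rt - entry$rt_min,
               ms2Score = score, confidenceLevel = cl)
  })
  res <- do.call(rbind, rows)
  res <- res[order(abs(res$deltaMz), abs(res$deltaRt)), ]
  rownames(res) <- NULL
  res
}
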