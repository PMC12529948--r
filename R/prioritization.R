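#' Align the features of two tables
#'
#' Pairs features across two tables of the same ionization polarity: a pair
#' is admissible when its m/z difference is within the MS1 tolerance and its
#' retention-time difference within the RT tolerance. Each feature is matched
#' to at most one partner; admissible pairs are assigned greedily in order of
#' increasing m/z distance, ties broken by RT distance, then by lower row
#' index.
#'
#' @param a,b [FeatureTable-class] objects of the same polarity.
#' @param tol a [MatchTolerances-class] object.
#' @return data.frame with columns \code{idxA}, \code{idxB} (row indices into
#'   the two feature tables), \code{deltaMz}, \code{deltaRt}.
#' @export
alignFeatures <- function(a, b, tol = MatchTolerances()) {
  stopifnot(is(a, "FeatureTable"), is(b, "FeatureTable"),
            is(tol, "MatchTolerances"))
  if (a@polarity != b@polarity)
    stop(sprintf("polarity mismatch: '%s' vs '%s'", a@polarity, b@polarity))
  fa <- a@features
  fb <- b@features
  empty <- data.frame(idxA = integer(), idxB = integer(),
                      deltaMz = numeric(), deltaRt = numeric())
  if (!nrow(fa) || !nrow(fb)) return(empty)

  # admissible pairs via interval overlap on sorted m/z
  ob <- order(fb$mz)
  mzb <- fb$mz[ob]
  lo <- findInterval(fa$mz - tol@ms1, mzb) + 1L
  hi <- findInterval(fa$mz + tol@ms1, mzb)
  pairs <- vector("list", nrow(fa))
  for (i in seq_len(nrow(fa))) {
    if (lo[i] > hi[i]) next
    j <- ob[lo[i]:hi[i]]
    drt <- abs(fb$rt[j] - fa$rt[i])
    keep <- drt <= tol@rt
    if (!any(keep)) next
    j <- j[keep]
    pairs[[i]] <- data.frame(idxA = i, idxB = j,
                             dmz = abs(fb$mz[j] - fa$mz[i]),
                             drt = drt[keep])
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || !nrow(pairs)) return(empty)

  o <- order(pairs$dmz, pairs$drt, pairs$idxA, pairs$idxB)
  pairs <- pairs[o, ]
  usedA <- logical(nrow(fa)); usedB <- logical(nrow(fb))
  sel <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$idxA[k]; j <- pairs$idxB[k]
    if (!usedA[i] && !usedB[j]) {
      sel[k] <- TRUE
      usedA[i] <- TRUE
      usedB[j] <- TRUE
    }
  }
  res <- pairs[sel, ]
  res <- data.frame(idxA = res$idxA, idxB = res$idxB,
                    deltaMz = res$dmz, deltaRt = res$drt)
  res <- res[order(res$idxA), ]
  rownames(res) <- NULL
  res
}

#' Subtract blank features from a sample table
#'
#' Removes every sample feature that aligns to any blank feature within the
#' tolerances, regardless of the intensity ratio. Order of the remaining
#' features is preserved.
#'
#' @param sample,blank [FeatureTable-class] objects of the same polarity.
#' @param tol a [MatchTolerances-class] object.
#' @return The sample [FeatureTable-class] without blank-matched features.
#' @export
subtractBlank <- function(sample, blank, tol = MatchTolerances()) {
  hits <- alignFeatures(sample, blank, tol)
  if (!nrow(hits)) return(sample)
  keep <- setdiff(seq_len(nFeatures(sample)), hits$idxA)
  FeatureTable(sample@features[keep, , drop = FALSE], sample@sampleId,
               sample@role, sample@ref, sample@polarity)
}

#' Run the feature-prioritization cascade
#'
#' Reduces the features of the enriched extract to candidate toxicity drivers
#' by applying, in order:
#' \enumerate{
#'   \item keep 5x-extract features that are also detected in the 1x extract;
#'   \item intersect with the upper and with the lower HPTLC fraction,
#'     separately;
#'   \item drop features whose 1x intensity exceeds their 5x intensity
#'     (enrichment must not invert);
#'   \item subtract features detected in the HPTLC process blank;
#'   \item keep features present in \emph{both} fraction-restricted sets;
#'   \item keep features whose 5x-extract intensity exceeds
#'     \code{intensityFraction} of the summed intensity of all 5x-extract
#'     features.
#' }
#' Feature counts are recorded after every step and are non-increasing.
#'
#' @param extract5,extract1 [FeatureTable-class]s of the 5x and 1x enriched
#'   extract.
#' @param upper,lower [FeatureTable-class]s of the two HPTLC fractions.
#' @param processBlank [FeatureTable-class] of the HPTLC process blank; may
#'   contain zero features but must be supplied.
#' @param tol a [MatchTolerances-class] object.
#' @param intensityFraction relative intensity threshold of step 6,
#'   default 0.01 (i.e. >1\% of total).
#' @return A [CascadeReport-class]; survivors are reported in the 5x-extract
#'   coordinate system.
#' @export
runCascade <- function(extract5, extract1, upper, lower, processBlank,
                       tol = MatchTolerances(), intensityFraction = 0.01) {
  tabs <- list(extract5 = extract5, extract1 = extract1, upper = upper,
               lower = lower)
  for (nm in names(tabs)) {
    if (!is(tabs[[nm]], "FeatureTable"))
      stop(sprintf("'%s' must be a FeatureTable", nm))
    if (nFeatures(tabs[[nm]]) == 0L)
      stop(sprintf("required table '%s' is empty", nm))
  }
  if (!is(processBlank, "FeatureTable"))
    stop("'processBlank' must be a FeatureTable")
  pols <- vapply(c(tabs, list(processBlank = processBlank)), polarity, "")
  if (length(unique(pols)) != 1L)
    stop("all cascade tables must share one polarity")

  f5 <- extract5@features
  total5 <- sum(f5$intensity)
  steps <- data.frame(step = integer(), label = character(),
                      count = integer())
  note <- function(lbl, idx) {
    steps <<- rbind(steps, data.frame(step = nrow(steps) + 1L, label = lbl,
                                      count = length(idx)))
    idx
  }
  sub5 <- function(idx) {
    FeatureTable(f5[idx, , drop = FALSE], extract5@sampleId, "extract",
                 extract5@ref, extract5@polarity)
  }

  # step 1: detected in both enrichment levels
  al1 <- alignFeatures(extract5, extract1, tol)
  idx <- note("detected in 5x and 1x extract", al1$idxA)
  int1 <- stats::setNames(extract1@features$intensity[al1$idxB], al1$idxA)

  # step 2: present in the upper / in the lower fraction (kept separately)
  alU <- alignFeatures(sub5(idx), upper, tol)
  inUpper <- idx[alU$idxA]
  alL <- alignFeatures(sub5(idx), lower, tol)
  inLower <- idx[alL$idxA]
  idx <- note("present in upper or lower fraction", union(inUpper, inLower))

  # step 3: 1x intensity must not exceed 5x intensity
  mono <- idx[int1[as.character(idx)] <= f5$intensity[idx]]
  inUpper <- intersect(inUpper, mono)
  inLower <- intersect(inLower, mono)
  idx <- note("1x intensity <= 5x intensity", mono)

  # step 4: process-blank subtraction
  alB <- alignFeatures(sub5(idx), processBlank, tol)
  idx <- note("not in process blank",
              if (nrow(alB)) idx[-alB$idxA] else idx)
  inUpper <- intersect(inUpper, idx)
  inLower <- intersect(inLower, idx)

  # step 5: present in both fractions
  idx <- note("present in both fractions", intersect(inUpper, inLower))

  # step 6: relative intensity above the 1% threshold
  idx <- note(sprintf("intensity > %g%% of 5x total", 100 * intensityFraction),
              idx[f5$intensity[idx] > intensityFraction * total5])

  surv <- f5[sort(idx), , drop = FALSE]
  surv$idx5 <- sort(idx)
  rownames(surv) <- NULL
  new("CascadeReport", steps = steps, survivors = surv,
      polarity = extract5@polarity)
}
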