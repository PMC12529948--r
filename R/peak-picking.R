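#' Pick chromatographic peaks from an intensity trace
#'
#' Detects peaks in a single extracted-ion or total-ion trace using the
#' screening thresholds: minimum apex intensity, minimum signal-to-noise
#' ratio, and a full-width-at-half-maximum window. The noise level is the
#' MAD-based sigma of the detrended baseline after masking candidate peak
#' regions; the baseline is a running median wider than the largest allowed
#' peak.
#'
#' @param times numeric, acquisition times in seconds, strictly increasing.
#' @param intensities numeric, non-negative counts, same length.
#' @param minIntensity minimum apex intensity (counts), default 10.
#' @param sn minimum apex signal-to-noise ratio, default 3.
#' @param widthBounds numeric(2), allowed FWHM range in seconds,
#'   default c(5, 60).
#' @return data.frame with one row per detected peak: \code{rt} (apex time,
#'   minutes), \code{intensity} (apex counts), \code{fwhm} (seconds) and
#'   \code{snr}. Zero rows when nothing passes the thresholds (a flat trace
#'   is not an error).
#' @examples
#' t <- seq(0, 600, by = 1)
#' y <- 100 * exp(-(t - 300)^2 / (2 * 8^2))
#' pickPeaks(t, y)
#' @export
pickPeaks <- function(times, intensities, minIntensity = 10, sn = 3,
                      widthBounds = c(5, 60)) {
  if (length(times) != length(intensities))
    stop("times and intensities must have equal length")
  if (length(times) < 3L)
    return(.emptyPeaks())
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(intensities < 0)) stop("intensities must be non-negative")

  dt <- stats::median(diff(times))
  # baseline window much wider than the widest allowed peak, so that broad
  # out-of-spec humps are not absorbed into the baseline
  win <- max(3L, as.integer(6 * widthBounds[2] / dt))
  if (win %% 2L == 0L) win <- win + 1L
  win <- min(win, length(times) - (1 - length(times) %% 2L))
  baseline <- stats::runmed(intensities, k = win, endrule = "median")
  det <- intensities - baseline

  # two-pass robust noise: mask obvious signal, then MAD of the remainder
  sigma0 <- stats::mad(det)
  keep <- if (sigma0 > 0) det <= 3 * sigma0 else rep(TRUE, length(det))
  sigma <- stats::mad(det[keep])
  if (!is.finite(sigma)) sigma <- 0

  n <- length(det)
  apex <- which(det[-c(1L, n)] > det[-c(n - 1L, n)] &
                det[-c(1L, n)] >= det[-c(1L, 2L)]) + 1L
  if (!length(apex)) return(.emptyPeaks())

  out <- lapply(apex, function(i) {
    h <- det[i]
    if (intensities[i] < minIntensity) return(NULL)
    snr <- if (sigma > 0) h / sigma else Inf
    if (snr < sn) return(NULL)
    half <- h / 2
    # walk outwards to the half-height crossings, linear interpolation
    l <- i
    while (l > 1L && det[l] > half) l <- l - 1L
    if (det[l] > half) return(NULL)  # ran off the trace edge
    tl <- times[l] + (half - det[l]) / (det[l + 1L] - det[l]) *
      (times[l + 1L] - times[l])
    r <- i
    while (r < n && det[r] > half) r <- r + 1L
    if (det[r] > half) return(NULL)
    tr <- times[r - 1L] + (half - det[r - 1L]) / (det[r] - det[r - 1L]) *
      (times[r] - times[r - 1L])
    fwhm <- tr - tl
    if (fwhm < widthBounds[1] || fwhm > widthBounds[2]) return(NULL)
    data.frame(rt = times[i] / 60, intensity = intensities[i],
               fwhm = fwhm, snr = snr, left = tl, right = tr)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.emptyPeaks())
  res <- do.call(rbind, out)
  # noise riding on a peak top can produce several maxima inside one
  # half-height region; keep only the highest apex per region
  res <- res[order(-res$intensity), ]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    inside <- res$rt * 60 >= res$left[i] & res$rt * 60 <= res$right[i]
    inside[i] <- FALSE
    keep[keep & inside] <- FALSE
  }
  res <- res[keep, c("rt", "intensity", "fwhm", "snr")]
  res <- res[order(res$rt), ]
  rownames(res) <- NULL
  res
}

.emptyPeaks <- function() {
  data.frame(rt = numeric(), intensity = numeric(), fwhm = numeric(),
             snr = numeric())
}
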