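# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# naive all-pairs one-to-one alignment: enumerate every admissible pair,
# sort by (|dmz|, |drt|, idxA, idxB), assign greedily
oracleAlign <- function(fa, fb, ms1 = 0.010, rtTol = 1.0) {
  grid <- expand.grid(i = seq_len(nrow(fa)), j = seq_len(nrow(fb)))
  pairs <- data.frame(grid,
                      dmz = abs(fa$mz[grid$i] - fb$mz[grid$j]),
                      drt = abs(fa$rt[grid$i] - fb$rt[grid$j]))
  pairs <- pairs[pairs$dmz <= ms1 & pairs$drt <= rtTol, ]
  if (!nrow(pairs)) return(data.frame(i = integer(), j = integer()))
  pairs <- pairs[order(pairs$dmz, pairs$drt, pairs$i, pairs$j), ]
  usedI <- usedJ <- integer()
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if (!(pairs$i[k] %in% usedI) && !(pairs$j[k] %in% usedJ)) {
      keep[k] <- TRUE
      usedI <- c(usedI, pairs$i[k])
      usedJ <- c(usedJ, pairs$j[k])
    }
  }
  out <- pairs[keep, c("i", "j")]
  out[order(out$i), ]
}

# explicit set-operation cascade on plain data.frames; returns per-step
# counts and the surviving extract-5x row indices
oracleCascade <- function(f5, f1, up, lo, bl, ms1 = 0.010, rtTol = 1.0,
                          frac = 0.01) {
  counts <- integer()
  al1 <- oracleAlign(f5, f1, ms1, rtTol)
  idx <- al1$i
  int1 <- setNames(f1$intensity[al1$j], al1$i)
  counts <- c(counts, length(idx))

  alU <- oracleAlign(f5[idx, , drop = FALSE], up, ms1, rtTol)
  inUp <- idx[alU$i]
  alL <- oracleAlign(f5[idx, , drop = FALSE], lo, ms1, rtTol)
  inLo <- idx[alL$i]
  idx <- union(inUp, inLo)
  counts <- c(counts, length(idx))

  mono <- idx[int1[as.character(idx)] <= f5$intensity[idx]]
  inUp <- intersect(inUp, mono); inLo <- intersect(inLo, mono)
  idx <- mono
  counts <- c(counts, length(idx))

  alB <- oracleAlign(f5[idx, , drop = FALSE], bl, ms1, rtTol)
  if (nrow(alB)) idx <- idx[-alB$i]
  inUp <- intersect(inUp, idx); inLo <- intersect(inLo, idx)
  counts <- c(counts, length(idx))

  idx <- intersect(inUp, inLo)
  counts <- c(counts, length(idx))

  idx <- idx[f5$intensity[idx] > frac * sum(f5$intensity)]
  counts <- c(counts, length(idx))

  list(counts = counts, survivors = sort(idx))
}

# Monte-Carlo half-width of the percent-contribution chain: inputs drawn as
# independent Gaussians with sd = half/1.96, interval from the 2.5/97.5%
# quantiles
mcPercentHalf <- function(values, halves, n = 1e5, seed = 1) {
  set.seed(seed)
  draws <- mapply(function(v, h) rnorm(n, v, h / 1.96), values, halves)
  p <- draws[, 1] * draws[, 3] / (draws[, 2] * draws[, 4]) * 100
  unname(diff(quantile(p, c(0.025, 0.975))) / 2)
}

# brute-force local-maximum count above a threshold (peak-picking oracle)
oracleLocalMaxima <- function(y, thresh) {
  n <- length(y)
  sum(vapply(2:(n - 1), function(i)
    y[i] > y[i - 1] && y[i] >= y[i + 1] && y[i] >= thresh, logical(1)))
}

gaussPeak <- function(t, center, height, sigma) {
  height * exp(-(t - center)^2 / (2 * sigma^2))
}
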