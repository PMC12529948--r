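#' @name simulate
#' @title Synthetic-data generators
#' @description
#' Generators for every input the pipeline consumes, each deterministic given
#' its seed and each returning its ground truth (or taking it as arguments).
#' Intensities and assay responses carry multiplicative log-normal noise of a
#' stated coefficient of variation; kinetics fractions carry additive
#' Gaussian noise. Defaults emulate the study conditions of the
#' elastomer-leachate investigation this package models.
NULL

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate an effect-directed feature scenario with planted drivers
#'
#' Generates the five feature tables the prioritization cascade consumes
#' (5x and 1x enriched extracts, upper and lower HPTLC fractions, process
#' blank) with \code{nDrivers} planted driver features and
#' \code{nBackground} background features. Drivers appear in both extracts
#' with 5x intensity proportional to the enrichment factor, in both
#' fractions, are absent from the blank, and exceed 1\% of the summed
#' 5x-extract intensity. Each background feature is constructed to violate at
#' least one cascade criterion; which one is recorded in the ground truth.
#' Observed m/z and retention times carry small per-table jitter (sd 2 mDa
#' and 0.05 min), intensities multiplicative log-normal noise of CV
#' \code{noiseCv}.
#'
#' @param nBackground number of background features (>= \code{nDrivers}).
#' @param nDrivers number of planted drivers (>= 1).
#' @param noiseCv intensity coefficient of variation, in [0, 0.5].
#' @param seed integer seed; identical seeds give identical tables.
#' @return list with elements \code{tables} (named list of
#'   [FeatureTable-class]: \code{extract5}, \code{extract1}, \code{upper},
#'   \code{lower}, \code{blank}) and \code{truth}
#'   (a [ScenarioTruth-class]).
#' @examples
#' sc <- simulateFeatureScenario(20, 2, 0.05, seed = 1)
#' nFeatures(sc$tables$extract5)
#' @export
simulateFeatureScenario <- function(nBackground = 100, nDrivers = 2,
                                    noiseCv = 0.05, seed = 1) {
  if (nDrivers < 1) stop("nDrivers must be >= 1")
  if (nBackground > 0 && nBackground < nDrivers)
    stop("nBackground must be 0 (no distractors) or at least nDrivers")
  if (noiseCv < 0 || noiseCv > 0.5) stop("noiseCv must lie in [0, 0.5]")
  .withSeed(seed, {
    nTot <- nBackground + nDrivers
    grid <- seq(100.03, 1199.93, by = 0.1)
    # the first planted drivers take the redox couple's adduct masses
    driverPool <- c("C12H11NO", "C12H9NO")
    dmz <- numeric(nDrivers)
    dform <- character(nDrivers)
    nPool <- min(nDrivers, length(driverPool))
    dform[seq_len(nPool)] <- driverPool[seq_len(nPool)]
    dmz[seq_len(nPool)] <- vapply(driverPool[seq_len(nPool)], adductMz,
                                  numeric(1), adduct = "[M+H]+")
    extra <- nDrivers - nPool
    gridIdx <- sample.int(length(grid), nBackground + extra)
    if (extra > 0) {
      dmz[(nPool + 1):nDrivers] <- grid[gridIdx[seq_len(extra)]]
      dform[(nPool + 1):nDrivers] <- NA_character_
      gridIdx <- gridIdx[-seq_len(extra)]
    }
    bmz <- grid[gridIdx]
    rt <- stats::runif(nTot, 1, 20)
    drt <- rt[seq_len(nDrivers)]
    brt <- rt[nDrivers + seq_len(nBackground)]

    # driver intensities: 1x base, 5x exactly proportional before noise
    dInt1 <- stats::runif(nDrivers, 15000, 30000)
    dInt5 <- 5 * dInt1
    dIntFrac <- dInt5 * stats::runif(nDrivers, 0.2, 0.6)

    violations <- c("absent_1x", "absent_upper", "absent_lower",
                    "higher_in_1x", "in_blank")
    bViol <- if (nBackground)
      violations[(seq_len(nBackground) - 1L) %% length(violations) + 1L]
      else character()
    bInt5 <- stats::runif(nBackground, 50, 800)
    bInt1 <- ifelse(bViol == "higher_in_1x", 2 * bInt5, bInt5 / 5)

    obs <- function(mzs, rts, ints) {
      n <- length(mzs)
      data.frame(
        mz = mzs + stats::rnorm(n, 0, 0.002),
        rt = pmax(0, rts + stats::rnorm(n, 0, 0.05)),
        intensity = ints * .lognoise(n, noiseCv))
    }
    mk <- function(df, id, role, ref) {
      FeatureTable(df, sampleId = id, role = role, ref = ref,
                   polarity = "positive")
    }
    inTab <- function(tab) {
      keepB <- switch(tab,
        extract5 = rep(TRUE, nBackground),
        extract1 = bViol != "absent_1x",
        upper = bViol != "absent_upper",
        lower = bViol != "absent_lower",
        blank = bViol == "in_blank")
      keepB
    }
    bInt <- function(tab) switch(tab,
      extract5 = bInt5, extract1 = bInt1, upper = 0.4 * bInt5,
      lower = 0.4 * bInt5, blank = 0.4 * bInt5)
    dI <- list(extract5 = dInt5, extract1 = dInt1, upper = dIntFrac,
               lower = dIntFrac)

    tabs <- list()
    for (tab in c("extract5", "extract1", "upper", "lower", "blank")) {
      kb <- inTab(tab)
      drivers <- tab != "blank"
      mzs <- c(if (drivers) dmz, bmz[kb])
      rts <- c(if (drivers) drt, brt[kb])
      ints <- c(if (drivers) dI[[tab]], bInt(tab)[kb])
      df <- if (length(mzs)) obs(mzs, rts, ints) else
        data.frame(mz = numeric(), rt = numeric(), intensity = numeric())
      role <- switch(tab, extract5 = "extract", extract1 = "extract",
                     upper = "fraction_upper", lower = "fraction_lower",
                     blank = "blank")
      ref <- if (tab == "extract5") 5 else 1
      tabs[[tab]] <- mk(df, tab, role, ref)
    }

    truth <- new("ScenarioTruth",
      drivers = data.frame(formula = dform, mz = dmz, rt = drt,
                           int5 = dInt5, int1 = dInt1,
                           intFraction = dIntFrac),
      background = data.frame(mz = bmz, rt = brt, int5 = bInt5,
                              int1 = bInt1, violates = bViol),
      params = list(nBackground = nBackground, nDrivers = nDrivers,
                    noiseCv = noiseCv, seed = seed))
    list(tables = tabs, truth = truth)
  })
}

#' Positive-control concentration grid
#'
#' Ten nominally 1:2 serial-dilution levels of the 17beta-estradiol on-plate
#' positive control spanning 0.66 to 500 ng/L (geometric spacing, step
#' ratio about 2.09).
#'
#' @return numeric(10), ng/L, increasing.
#' @export
pcConcentrationGrid <- function() {
  exp(seq(log(0.66), log(500), length.out = 10))
}

#' Simulate a yeast-estrogen-screen dilution series
#'
#' Responses follow a 4-parameter logistic in concentration with
#' multiplicative log-normal noise. The default dose grid is a 1:2 serial
#' dilution of \code{nDilutions} levels topped at eight times the true EC50;
#' pass [pcConcentrationGrid()] to emulate the estradiol positive control.
#'
#' @param trueEc50 true EC50 (ng/L, > 0).
#' @param hill Hill slope (> 0), default 1.2.
#' @param floor,ceiling response asymptotes, defaults 1 and 10 (induction
#'   ratio scale).
#' @param concentrations optional explicit dose grid (ng/L); overrides
#'   \code{nDilutions}.
#' @param nDilutions number of 1:2 dilution levels (>= 5), default 7.
#' @param noiseCv response coefficient of variation.
#' @param nReplicates replicates per level, default 3.
#' @param seed integer seed.
#' @return A [PlateSeries-class] with all replicates.
#' @examples
#' ps <- simulateYesPlate(820000, hill = 2.4, noiseCv = 0, seed = 1)
#' @export
simulateYesPlate <- function(trueEc50, hill = 1.2, floor = 1, ceiling = 10,
                             concentrations = NULL, nDilutions = 7,
                             noiseCv = 0.1, nReplicates = 3, seed = 1) {
  if (hill <= 0) stop("hill must be positive")
  if (trueEc50 <= 0) stop("trueEc50 must be positive")
  if (is.null(concentrations)) {
    if (nDilutions < 5) stop("nDilutions must be >= 5")
    concentrations <- 8 * trueEc50 / 2^(seq_len(nDilutions) - 1)
  }
  concentrations <- sort(concentrations)
  .withSeed(seed, {
    conc <- rep(concentrations, each = nReplicates)
    mu <- floor + (ceiling - floor) / (1 + (trueEc50 / conc)^hill)
    resp <- mu * .lognoise(length(mu), noiseCv)
    PlateSeries(conc, resp, replicate = rep(seq_len(nReplicates),
                                            times = length(concentrations)))
  })
}

#' Simulate a sample dilution curve with known estradiol-equivalent truth
#'
#' Emulates a leachate whose estrogenicity is fully carried by an
#' estradiol-equivalent dose: at relative concentration c (1/dilution
#' factor) the assay sees an E2 dose of \code{e2eq * c} ng/L, read out on
#' the positive-control 4PL curve with multiplicative log-normal noise.
#'
#' @param e2eq true estradiol equivalent of the undiluted sample (ng/L).
#' @param pcEc50,pcHill,pcFloor,pcCeiling positive-control curve parameters.
#' @param nDilutions number of 1:2 dilution levels starting at the undiluted
#'   sample, default 7.
#' @param noiseCv response coefficient of variation.
#' @param nReplicates replicates per level, default 3.
#' @param seed integer seed.
#' @return A [PlateSeries-class] whose concentration axis is the relative
#'   concentration (1 = undiluted), as [e2Equivalents()] expects.
#' @export
simulateSampleCurve <- function(e2eq, pcEc50 = 120, pcHill = 1.2,
                                pcFloor = 1, pcCeiling = 10, nDilutions = 7,
                                noiseCv = 0.1, nReplicates = 3, seed = 1) {
  if (e2eq <= 0) stop("e2eq must be positive")
  cRel <- 1 / 2^(seq_len(nDilutions) - 1)
  .withSeed(seed, {
    conc <- rep(cRel, each = nReplicates)
    mu <- pcFloor + (pcCeiling - pcFloor) /
      (1 + (pcEc50 / (e2eq * conc))^pcHill)
    PlateSeries(conc, mu * .lognoise(length(mu), noiseCv),
                replicate = rep(seq_len(nReplicates), times = length(cRel)))
  })
}

#' Simulate a standard-addition spike series
#'
#' Linear detector response to the summed (native + spiked) analyte
#' concentration with multiplicative log-normal noise. The unspiked sample is
#' included as spike level 0. Default spike levels are 210, 420, 630 and
#' 840 ug/L.
#'
#' @param trueConc true in-assay concentration (ug/L).
#' @param spikes strictly increasing spike levels (ug/L), >= 3 levels
#'   (level 0 is added automatically).
#' @param slope detector sensitivity (> 0).
#' @param noiseCv response coefficient of variation, default 0.05.
#' @param nReplicates replicates per level, default 3.
#' @param seed integer seed.
#' @return data.frame(spike, replicate, response).
#' @export
simulateStandardAddition <- function(trueConc = 500,
                                     spikes = c(210, 420, 630, 840),
                                     slope = 1, noiseCv = 0.05,
                                     nReplicates = 3, seed = 1) {
  if (slope <= 0) stop("slope must be positive")
  if (length(spikes) < 3 || any(diff(spikes) <= 0) || any(spikes <= 0))
    stop("spikes must be >= 3 strictly increasing positive levels")
  if (trueConc <= 0) stop("trueConc must be positive")
  .withSeed(seed, {
    lev <- c(0, spikes)
    spike <- rep(lev, each = nReplicates)
    mu <- slope * (trueConc + spike)
    data.frame(spike = spike,
               replicate = rep(seq_len(nReplicates), times = length(lev)),
               response = mu * .lognoise(length(mu), noiseCv))
  })
}

#' Default speciation-kinetics parameters per pH
#'
#' First-order approach-to-plateau parameters of the reduced-species fraction
#' calibrated to the study's buffered-pH behaviour: near-linear slow decline
#' at pH 5-7 (far plateau, small rate) and plateaus of 0.58 / 0.53 reached
#' within about 100 h at pH 8 / 9.
#'
#' @return data.frame(pH, f0, plateau, k).
#' @export
defaultKineticsParams <- function() {
  data.frame(pH = 5:9,
             f0 = c(0.92, 0.93, 0.95, 0.95, 0.95),
             plateau = c(0.30, 0.30, 0.40, 0.58, 0.53),
             k = c(1.13e-3, 1.11e-3, 4.1e-3, 0.030, 0.030))
}

#' Timepoint grid of the pH-stability experiment
#'
#' @return numeric(14), hours.
#' @export
kineticsTimeGrid <- function() {
  c(0, 3, 5, 7, 9, 12, 14, 17, 48, 73, 100, 123, 146, 173)
}

#' Simulate redox-couple speciation time series
#'
#' The reduced-species fraction follows
#' f(t) = plateau + (f0 - plateau) * exp(-k t); the two species'
#' IS-normalized areas sum to \code{totalArea} perturbed by additive Gaussian
#' noise (sd \code{noiseSd} per species, truncated so that the relative
#' deviation of the per-timepoint sum stays below 4\% by construction at the
#' default noise level).
#'
#' @param params data.frame(pH, f0, plateau, k) as in
#'   [defaultKineticsParams()]; fractions must lie in (0, 1] with
#'   plateau < f0 for a decay scenario.
#' @param times timepoint grid in hours, default [kineticsTimeGrid()].
#' @param noiseSd additive noise sd on fractions, default 0.01.
#' @param nReplicates replicates per pH, default 3.
#' @param totalArea constant total normalized area, default 1.
#' @param seed integer seed.
#' @return list of [SpeciesSeries-class], one per pH x replicate.
#' @export
simulateKinetics <- function(params = defaultKineticsParams(),
                             times = kineticsTimeGrid(), noiseSd = 0.01,
                             nReplicates = 3, totalArea = 1, seed = 1) {
  stopifnot(all(c("pH", "f0", "plateau", "k") %in% names(params)))
  if (any(params$f0 <= 0 | params$f0 > 1 |
          params$plateau <= 0 | params$plateau > 1))
    stop("f0 and plateau must lie in (0, 1]")
  if (any(params$plateau > params$f0))
    stop("plateau must not exceed f0 for a decay scenario")
  if (any(params$k < 0)) stop("k must be non-negative")
  .withSeed(seed, {
    out <- list()
    for (i in seq_len(nrow(params))) {
      f <- params$plateau[i] +
        (params$f0[i] - params$plateau[i]) * exp(-params$k[i] * times)
      for (r in seq_len(nReplicates)) {
        n <- length(times)
        e1 <- stats::rnorm(n, 0, noiseSd)
        e2 <- stats::rnorm(n, 0, noiseSd)
        # keep the summed-area deviation inside the 4% mass-balance band
        bad <- which(abs(e1 + e2) > 0.038 * totalArea)
        while (length(bad)) {
          e1[bad] <- stats::rnorm(length(bad), 0, noiseSd)
          e2[bad] <- stats::rnorm(length(bad), 0, noiseSd)
          bad <- which(abs(e1 + e2) > 0.038 * totalArea)
        }
        out[[length(out) + 1L]] <- SpeciesSeries(
          times = times,
          areaReduced = pmax(0, totalArea * (f + e1)),
          areaOxidized = pmax(0, totalArea * (1 - f + e2)),
          pH = params$pH[i], replicateId = sprintf("r%d", r))
      }
    }
    out
  })
}
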