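#' Default pipeline configuration
#'
#' A flat list of every tunable the pipeline uses, pre-filled with the
#' screening defaults (MS1 tolerance 0.010 Da, MS2 tolerance 0.015 Da, RT
#' tolerance 1 min, minimum peak intensity 10 counts, S/N 3, peak width
#' 5-60 s, relative intensity threshold 1\%) and the synthetic study
#' conditions (positive-control EC10 near 19 ng/L, analyte EC50 820 ug/L
#' with Hill slope 2.4, sample E2-EQ 140 ng/L, in-assay analyte
#' concentration 500 ug/L at dilution factor 6, speciation kinetics of
#' [defaultKineticsParams()]).
#'
#' @param seed master integer seed; every stage forks its own stream from
#'   it.
#' @return named list.
#' @export
defaultConfig <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    ms1_tol = 0.010, ms2_tol = 0.015, rt_tol = 1.0,
    min_intensity = 10, sn = 3, peak_width = c(5, 60),
    intensity_fraction = 0.01,
    scenario = list(synthetic = TRUE, nBackground = 100, nDrivers = 2,
                    noiseCv = 0.05),
    pc = list(ec50 = 120, hill = 1.2, floor = 1, ceiling = 10,
              noiseCv = 0.1, nReplicates = 3),
    analyte = list(ec50 = 820000, hill = 2.4, floor = 1, ceiling = 10,
                   noiseCv = 0.1, nReplicates = 3),
    sample = list(e2eq = 140, nDilutions = 7, noiseCv = 0.1,
                  nReplicates = 3),
    standard_addition = list(trueConc = 500, spikes = c(210, 420, 630, 840),
                             slope = 1, noiseCv = 0.05, nReplicates = 3,
                             aliquot = 20, total = 120),
    kinetics = list(params = defaultKineticsParams(), noiseSd = 0.01,
                    nReplicates = 3),
    paths = list()
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full effect-directed-analysis pipeline
#'
#' Executes prioritization, dose-response modelling, standard-addition
#' quantification, the effect-balance calculation and speciation-kinetics
#' fitting, on either the synthetic scenario (default) or on user-supplied
#' CSV inputs named in \code{config$paths} (\code{extract5, extract1, upper,
#' lower, blank} feature tables, \code{plates}, \code{spikes},
#' \code{kinetics}). All randomness of the synthetic scenario forks from
#' \code{config$seed}, so two runs with the same configuration are
#' identical. Per-stage feature counts are collected in the returned
#' \code{log}.
#'
#' @param config configuration list, see [defaultConfig()].
#' @param outDir optional directory; when given, per-stage CSV outputs are
#'   written there.
#' @return list with elements \code{cascade} ([CascadeReport-class]),
#'   \code{truth} (when synthetic), \code{pcFit}, \code{analyteFit}
#'   ([DoseResponseFit-class]), \code{ec10Pc}, \code{ec10Analyte},
#'   \code{e2eqSample} ([ValueWithCI-class]), \code{quant}
#'   ([QuantResult-class]), \code{balance} ([EffectBalance-class]),
#'   \code{kinetics} (list of [KineticFit-class] per pH),
#'   \code{massBalance}, and \code{log} (data.frame of stage messages and
#'   counts).
#' @examples
#' \donttest{
#' res <- runPipeline(defaultConfig(seed = 1))
#' res$balance
#' }
#' @export
runPipeline <- function(config = defaultConfig(), outDir = NULL) {
  seed <- config$seed
  tol <- MatchTolerances(config$ms1_tol, config$ms2_tol, config$rt_tol)
  log <- data.frame(stage = character(), key = character(),
                    count = numeric())
  note <- function(stage, key, count) {
    log <<- rbind(log, data.frame(stage = stage, key = key,
                                  count = as.numeric(count)))
  }

  ## inputs ----------------------------------------------------------------
  truth <- NULL
  if (isTRUE(config$scenario$synthetic)) {
    sc <- .stage("simulate", simulateFeatureScenario(
      config$scenario$nBackground, config$scenario$nDrivers,
      config$scenario$noiseCv, seed = seed + 1L))
    tabs <- sc$tables
    truth <- sc$truth
  } else {
    p <- config$paths
    need <- c("extract5", "extract1", "upper", "lower", "blank")
    miss <- setdiff(need, names(p))
    if (length(miss))
      stop(sprintf("pipeline stage 'prioritization' failed: missing input table(s) %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    tabs <- .stage("read", lapply(p[need], readFeatureTable))
  }
  for (nm in names(tabs)) note("input", nm, nFeatures(tabs[[nm]]))

  ## prioritization --------------------------------------------------------
  cascade <- .stage("prioritization", runCascade(
    tabs$extract5, tabs$extract1, tabs$upper, tabs$lower, tabs$blank,
    tol = tol, intensityFraction = config$intensity_fraction))
  for (i in seq_len(nrow(cascade@steps)))
    note("prioritization", cascade@steps$label[i], cascade@steps$count[i])

  ## dose-response ---------------------------------------------------------
  if (isTRUE(config$scenario$synthetic)) {
    pc <- config$pc
    pcPlate <- simulateYesPlate(pc$ec50, pc$hill, pc$floor, pc$ceiling,
                                concentrations = pcConcentrationGrid(),
                                noiseCv = pc$noiseCv,
                                nReplicates = pc$nReplicates,
                                seed = seed + 2L)
    an <- config$analyte
    anPlate <- simulateYesPlate(an$ec50, an$hill, an$floor, an$ceiling,
                                noiseCv = an$noiseCv,
                                nReplicates = an$nReplicates,
                                seed = seed + 3L)
    sm <- config$sample
    smPlate <- simulateSampleCurve(sm$e2eq, pc$ec50, pc$hill, pc$floor,
                                   pc$ceiling, sm$nDilutions, sm$noiseCv,
                                   sm$nReplicates, seed = seed + 4L)
  } else {
    plates <- .stage("read", readPlateSeries(config$paths$plates))
    need <- c("pc", "analyte", "sample")
    miss <- setdiff(need, names(plates))
    if (length(miss))
      stop(sprintf("pipeline stage 'dose_response' failed: plate file lacks sample_id(s) %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    pcPlate <- plates$pc; anPlate <- plates$analyte; smPlate <- plates$sample
  }
  pcFit <- .stage("dose_response", fit4PL(pcPlate))
  anFit <- .stage("dose_response", fit4PL(anPlate))
  ec10Pc <- ecLevel(pcFit, 10)
  ec10An <- ecLevel(anFit, 10)
  e2eqSm <- .stage("dose_response", e2Equivalents(smPlate, pcFit))
  note("dose_response", "pc_ec10_ngL", ec10Pc@value)
  note("dose_response", "analyte_ec10_ngL", ec10An@value)
  note("dose_response", "sample_e2eq_ngL", e2eqSm@value)

  ## quantification --------------------------------------------------------
  sa <- config$standard_addition
  saData <- if (isTRUE(config$scenario$synthetic)) {
    simulateStandardAddition(sa$trueConc, sa$spikes, sa$slope, sa$noiseCv,
                             sa$nReplicates, seed = seed + 5L)
  } else {
    d <- .stage("read", utils::read.csv(config$paths$spikes))
    data.frame(spike = d$level_ugL, replicate = d$replicate,
               response = d$response)
  }
  quant <- .stage("quantification",
                  dilutionCorrect(fitStandardAddition(saData$spike,
                                                      saData$response),
                                  sa$aliquot, sa$total))
  note("quantification", "conc_sample_ugL", quant@concSample@value)

  ## effect balance --------------------------------------------------------
  balance <- .stage("effect_balance", effectBalance(
    ec10Pc, ec10An,
    .vwc(quant@concSample@value * 1000, quant@concSample@ci95 * 1000),
    e2eqSm))
  note("effect_balance", "percent_contribution", balance@percent@value)

  ## kinetics --------------------------------------------------------------
  kin <- config$kinetics
  kinSeries <- if (isTRUE(config$scenario$synthetic)) {
    simulateKinetics(kin$params, noiseSd = kin$noiseSd,
                     nReplicates = kin$nReplicates, seed = seed + 6L)
  } else {
    .stage("read", readKineticsSeries(config$paths$kinetics))
  }
  kinFits <- .stage("kinetics", {
    byPh <- split(kinSeries, vapply(kinSeries, function(s) s@pH, numeric(1)))
    lapply(byPh, function(group) {
      tAll <- unlist(lapply(group, function(s) s@times))
      fAll <- unlist(lapply(group, function(s) speciesFraction(s) / 100))
      o <- order(tAll)
      model <- if (group[[1]]@pH <= 7) "linear" else "exponential_plateau"
      fitKinetics(tAll[o], fAll[o], model)
    })
  })
  mb <- lapply(kinSeries, massBalanceCheck)
  for (nm in names(kinFits))
    note("kinetics", sprintf("pH%s_r2", nm), kinFits[[nm]]@r2)

  res <- list(cascade = cascade, truth = truth, pcFit = pcFit,
              analyteFit = anFit, ec10Pc = ec10Pc, ec10Analyte = ec10An,
              e2eqSample = e2eqSm, quant = quant, balance = balance,
              kinetics = kinFits, massBalance = mb, log = log)
  if (!is.null(outDir)) .writePipelineOutputs(res, tabs, outDir)
  res
}

.writePipelineOutputs <- function(res, tabs, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$log, file.path(outDir, "stage_log.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cbind(polarity = res$cascade@polarity,
                         res$cascade@steps),
                   file.path(outDir, "cascade_steps.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(res$cascade@survivors,
                   file.path(outDir, "cascade_candidates.csv"),
                   row.names = FALSE, quote = FALSE)
  fits <- data.frame(
    curve = c("pc", "analyte"),
    floor = c(res$pcFit@floor, res$analyteFit@floor),
    ceiling = c(res$pcFit@ceiling, res$analyteFit@ceiling),
    ec50 = c(res$pcFit@ec50, res$analyteFit@ec50),
    hill = c(res$pcFit@hill, res$analyteFit@hill),
    ec10 = c(res$ec10Pc@value, res$ec10Analyte@value),
    ec10_ci95 = c(res$ec10Pc@ci95, res$ec10Analyte@ci95))
  utils::write.csv(fits, file.path(outDir, "dose_response.csv"),
                   row.names = FALSE, quote = FALSE)
  bal <- res$balance
  utils::write.csv(data.frame(
    rep = bal@rep@value, rep_ci95 = bal@rep@ci95,
    e2eq_analyte_ngL = bal@e2eqAnalyte@value,
    e2eq_analyte_ci95 = bal@e2eqAnalyte@ci95,
    e2eq_sample_ngL = bal@e2eqSample@value,
    e2eq_sample_ci95 = bal@e2eqSample@ci95,
    percent = bal@percent@value, percent_ci95 = bal@percent@ci95),
    file.path(outDir, "effect_balance.csv"), row.names = FALSE,
    quote = FALSE)
  kin <- do.call(rbind, lapply(names(res$kinetics), function(nm) {
    k <- res$kinetics[[nm]]
    data.frame(pH = nm, model = k@model,
               f0 = k@params[["f0"]],
               slope = if (k@model == "linear") k@params[["slope"]] else NA,
               plateau = if (k@model == "exponential_plateau")
                 k@params[["plateau"]] else NA,
               k = if (k@model == "exponential_plateau")
                 k@params[["k"]] else NA,
               r2 = k@r2)
  }))
  utils::write.csv(kin, file.path(outDir, "kinetics.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(outDir)
}
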