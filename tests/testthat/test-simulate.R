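test_that("feature scenarios are deterministic and honour their contract", {
  a <- simulateFeatureScenario(100, 2, 0.05, seed = 1)
  b <- simulateFeatureScenario(100, 2, 0.05, seed = 1)
  for (nm in names(a$tables))
    expect_identical(featureData(a$tables[[nm]]), featureData(b$tables[[nm]]))
  expect_identical(a$truth@drivers, b$truth@drivers)

  tb <- a$tables
  drivers <- a$truth@drivers
  background <- a$truth@background
  # drivers present in both extracts and both fractions, absent from blank
  for (m in drivers$mz) {
    for (nm in c("extract5", "extract1", "upper", "lower"))
      expect_true(any(abs(featureData(tb[[nm]])$mz - m) < 0.011),
                  label = sprintf("driver %f in %s", m, nm))
    expect_false(any(abs(featureData(tb$blank)$mz - m) < 0.011))
  }
  # 5x intensity ~ 5-fold the 1x intensity (exact before noise)
  expect_equal(drivers$int5, 5 * drivers$int1)
  # drivers exceed 1% of the summed 5x intensity
  tot5 <- sum(featureData(tb$extract5)$intensity)
  expect_true(all(drivers$int5 > 0.01 * tot5))
  # every background feature records a violated criterion
  expect_true(all(background$violates %in%
                  c("absent_1x", "absent_upper", "absent_lower",
                    "higher_in_1x", "in_blank")))
})

test_that("a scenario without distractors keeps its single driver", {
  sc <- simulateFeatureScenario(0, 1, 0, seed = 5)
  tb <- sc$tables
  expect_equal(nFeatures(tb$extract5), 1L)
  expect_equal(nFeatures(tb$blank), 0L)
  rep <- runCascade(tb$extract5, tb$extract1, tb$upper, tb$lower, tb$blank)
  expect_equal(nrow(cascadeSurvivors(rep)), 1L)
})

test_that("scenario parameter violations are rejected", {
  expect_error(simulateFeatureScenario(1, 2, 0.05, 1), "at least nDrivers")
  expect_error(simulateFeatureScenario(10, 0, 0.05, 1), "nDrivers")
  expect_error(simulateFeatureScenario(10, 2, 0.7, 1), "noiseCv")
})

test_that("the positive-control grid spans 0.66-500 ng/L in ~1:2 steps", {
  g <- pcConcentrationGrid()
  expect_length(g, 10L)
  expect_equal(g[1], 0.66)
  expect_equal(g[10], 500)
  ratios <- g[-1] / g[-10]
  expect_true(all(abs(ratios - 2.09) < 0.01))
})

test_that("noiseless plates are exactly identifiable", {
  ps <- simulateYesPlate(820000, hill = 2.4, noiseCv = 0, seed = 1)
  f <- fit4PL(ps)
  expect_equal(ec50(f), 820000, tolerance = 1e-6)
  expect_equal(hillSlope(f), 2.4, tolerance = 1e-6)
  expect_error(simulateYesPlate(100, hill = -1), "hill")
  expect_error(simulateYesPlate(100, nDilutions = 4), "nDilutions")
})

test_that("yes-plate EC50 recovery is unbiased at assay-like noise", {
  rel <- vapply(1:50, function(s) {
    ps <- simulateYesPlate(820000, hill = 2.4, noiseCv = 0.1, seed = s)
    abs(ec50(fit4PL(ps)) - 820000) / 820000
  }, numeric(1))
  expect_lt(median(rel), 0.2)
})

test_that("standard-addition series behave and recover exactly without noise", {
  a <- simulateStandardAddition(500, noiseCv = 0.05, seed = 3)
  b <- simulateStandardAddition(500, noiseCv = 0.05, seed = 3)
  expect_identical(a, b)
  expect_true(all(c(0, 210, 420, 630, 840) %in% a$spike))

  clean <- simulateStandardAddition(500, noiseCv = 0, seed = 1)
  q <- fitStandardAddition(clean$spike, clean$response)
  expect_equal(ciValue(q@concAssay), 500, tolerance = 1e-9)
  expect_error(simulateStandardAddition(500, slope = 0), "slope")
  expect_error(simulateStandardAddition(500, spikes = c(3, 2, 1)), "spikes")
})

test_that("standard addition recovers the undiluted concentration within 10%", {
  recovered <- vapply(1:50, function(s) {
    d <- simulateStandardAddition(500, noiseCv = 0.05, seed = s)
    q <- dilutionCorrect(fitStandardAddition(d$spike, d$response), 20, 120)
    ciValue(q@concSample)
  }, numeric(1))
  expect_lt(abs(median(recovered) - 3000) / 3000, 0.1)
})

test_that("kinetics generator obeys its asymptotics and noise contract", {
  # no decay, no noise: constant at f0
  p <- data.frame(pH = 7, f0 = 0.9, plateau = 0.5, k = 0)
  s <- simulateKinetics(p, noiseSd = 0, nReplicates = 1, seed = 1)[[1]]
  expect_equal(speciesFraction(s), rep(90, 14), tolerance = 1e-10)
  # large k*t: late timepoints at the plateau
  p2 <- data.frame(pH = 8, f0 = 0.9, plateau = 0.53, k = 0.5)
  s2 <- simulateKinetics(p2, noiseSd = 0, nReplicates = 1, seed = 1)[[1]]
  late <- speciesFraction(s2)[s2@times > 40]
  expect_equal(late, rep(53, length(late)), tolerance = 1e-6)
  # default noisy series keep the mass balance within 4% by construction
  kin <- simulateKinetics(seed = 9)
  for (s in kin) expect_true(massBalanceCheck(s, 0.04)$pass)
  # determinism
  expect_identical(simulateKinetics(seed = 2)[[5]]@areaReduced,
                   simulateKinetics(seed = 2)[[5]]@areaReduced)
  expect_error(
    simulateKinetics(data.frame(pH = 7, f0 = 0.5, plateau = 0.9, k = 1)),
    "plateau")
})

test_that("sample dilution curves carry the intended estradiol equivalent", {
  sm <- simulateSampleCurve(140, noiseCv = 0, seed = 1)
  pc <- fit4PL(simulateYesPlate(120, hill = 1.2,
                                concentrations = pcConcentrationGrid(),
                                noiseCv = 0, seed = 2))
  expect_equal(ciValue(e2Equivalents(sm, pc)), 140, tolerance = 1e-6)
})
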