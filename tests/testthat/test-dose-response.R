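test_that("noiseless 4PL fits recover the generating parameters", {
  ps <- simulateYesPlate(120, hill = 1.2, floor = 1, ceiling = 10,
                         concentrations = pcConcentrationGrid(),
                         noiseCv = 0, seed = 1)
  f <- fit4PL(ps)
  expect_equal(ec50(f), 120, tolerance = 1e-6)
  expect_equal(hillSlope(f), 1.2, tolerance = 1e-6)
  expect_equal(f@floor, 1, tolerance = 1e-6)
  expect_equal(f@ceiling, 10, tolerance = 1e-6)
})

test_that("degenerate plate inputs are rejected", {
  expect_error(fit4PL(data.frame(conc = c(1, 2), response = c(1, 5))),
               "at least 5 distinct concentrations")
  expect_error(fit4PL(data.frame(conc = 2^(0:6), response = rep(3, 7))),
               "no response")
})

test_that("effect concentrations follow the analytic 4PL inverse", {
  ps <- simulateYesPlate(100, hill = 1, noiseCv = 0, seed = 1)
  f <- fit4PL(ps)
  expect_equal(ciValue(ecLevel(f, 50)), ec50(f), tolerance = 1e-8)
  expect_equal(ciValue(ecLevel(f, 10)), 100 * (10 / 90), tolerance = 1e-6)
  expect_error(ecLevel(f, 0), "level")
  expect_error(ecLevel(f, 100), "level")
  # strictly increasing in level
  levs <- c(5, 10, 25, 50, 75, 90)
  ecs <- vapply(levs, function(l) ciValue(ecLevel(f, l)), numeric(1))
  expect_true(all(diff(ecs) > 0))
})

test_that("fitting is equivariant under concentration rescaling", {
  ps <- simulateYesPlate(820000, hill = 2.4, noiseCv = 0.1, seed = 6)
  f1 <- fit4PL(ps)
  scaled <- PlateSeries(ps@concentrations / 1000, ps@responses,
                        ps@replicate)
  f2 <- fit4PL(scaled)
  expect_equal(ec50(f2), ec50(f1) / 1000, tolerance = 1e-5)
  expect_equal(hillSlope(f2), hillSlope(f1), tolerance = 1e-5)
  expect_equal(f2@floor, f1@floor, tolerance = 1e-5)
})

test_that("delta-method EC10 interval agrees with a parametric bootstrap", {
  ps <- simulateYesPlate(820000, hill = 2.4, noiseCv = 0.1, seed = 7)
  f <- fit4PL(ps)
  ec <- ecLevel(f, 10)
  # draw parameters from the fitted covariance, invert analytically
  set.seed(11)
  L <- chol(f@vcov)
  th <- c(f@floor, f@ceiling, ec50(f), hillSlope(f))
  draws <- sweep(matrix(rnorm(2000 * 4), 2000) %*% L, 2, th, "+")
  ecs <- draws[, 3] * (10 / 90)^(1 / draws[, 4])
  bootHalf <- unname(diff(quantile(ecs, c(0.025, 0.975))) / 2)
  # compare on the same (normal-quantile) scale as the draws
  deltaHalf <- ciHalfWidth(ec) / qt(0.975, f@df) * qnorm(0.975)
  expect_lt(abs(deltaHalf - bootHalf) / bootHalf, 0.1)
})

test_that("a literal estradiol dilution reads back its own concentration", {
  pc <- fit4PL(simulateYesPlate(120, hill = 1.2,
                                concentrations = pcConcentrationGrid(),
                                noiseCv = 0, seed = 2))
  # 'sample' = E2 at 100x the positive-control concentration when undiluted
  e2conc <- 250
  sm <- simulateSampleCurve(100 * e2conc, pcEc50 = 120, pcHill = 1.2,
                            noiseCv = 0, seed = 3)
  expect_equal(ciValue(e2Equivalents(sm, pc)), 100 * e2conc,
               tolerance = 1e-6)
})

test_that("samples that never reach the effect threshold are reported", {
  pc <- fit4PL(simulateYesPlate(120, hill = 1.2,
                                concentrations = pcConcentrationGrid(),
                                noiseCv = 0, seed = 2))
  # a genuine but weak sigmoid topping out below the PC's 10% level
  weak <- simulateSampleCurve(140, pcEc50 = 120, pcHill = 1.2, pcFloor = 1,
                              pcCeiling = 1.5, noiseCv = 0, seed = 4)
  expect_error(e2Equivalents(weak, pc), "below effect threshold")
  # a flat series fails earlier, at the sample fit itself
  flat <- PlateSeries(1 / 2^(0:6), rep(1.2, 7), 1L)
  expect_error(e2Equivalents(flat, pc), "no response")
})

test_that("E2-EQ intervals cover the truth at assay-like noise", {
  hits <- 0
  n <- 50
  for (s in 1:n) {
    pc <- tryCatch(fit4PL(simulateYesPlate(
      120, hill = 1.2, concentrations = pcConcentrationGrid(),
      noiseCv = 0.1, seed = 1000 + s)), error = function(e) NULL)
    if (is.null(pc)) next
    sm <- simulateSampleCurve(140, noiseCv = 0.1, seed = 2000 + s)
    e <- tryCatch(e2Equivalents(sm, pc), error = function(e) NULL)
    if (is.null(e)) next
    if (abs(ciValue(e) - 140) <= ciHalfWidth(e)) hits <- hits + 1
  }
  expect_gte(hits / n, 0.9)
})
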