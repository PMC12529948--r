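test_that("IS normalization is a plain ratio with guarded input", {
  expect_equal(normalizeToIS(100, 100), 1)
  expect_equal(normalizeToIS(0, 50), 0)
  expect_equal(normalizeToIS(7 * 3, 7 * 6), normalizeToIS(3, 6))
  expect_error(normalizeToIS(10, 0), "positive")
})

test_that("species fractions sum to 100% and flag empty timepoints", {
  s <- SpeciesSeries(c(0, 1, 2), c(1, 2, 0), c(1, 2, 3), pH = 7)
  expect_equal(speciesFraction(s), c(50, 50, 0))
  flip <- SpeciesSeries(c(0, 1, 2), c(1, 2, 3), c(1, 2, 0), pH = 7)
  expect_equal(speciesFraction(s) + speciesFraction(flip),
               rep(100, 3))
  zero <- SpeciesSeries(c(0, 5), c(1, 0), c(1, 0), pH = 7)
  expect_error(speciesFraction(zero), "t = 5")
})

test_that("mass balance detects an inflated timepoint", {
  t <- c(0, 3, 5, 7, 9)
  good <- SpeciesSeries(t, rep(0.6, 5), rep(0.4, 5), pH = 6)
  mb <- massBalanceCheck(good)
  expect_true(mb$pass)
  expect_equal(mb$maxDeviation, 0)
  bad <- SpeciesSeries(t, c(0.6, 0.6, 0.66, 0.6, 0.6),
                       c(0.4, 0.4, 0.44, 0.4, 0.4), pH = 6)
  expect_false(massBalanceCheck(bad, 0.04)$pass)
  expect_gt(massBalanceCheck(bad, 0.04)$maxDeviation, 0.04)
})

test_that("a linear decline sampled at the experiment grid is recovered", {
  t <- kineticsTimeGrid()
  f <- 0.92 - 6.6e-4 * t
  fit <- fitKinetics(t, f, "linear")
  expect_equal(fit@params[["slope"]], -6.6e-4, tolerance = 1e-10)
  expect_equal(fit@params[["f0"]], 0.92, tolerance = 1e-10)
  expect_equal(fit@r2, 1, tolerance = 1e-12)
  # endpoint consistent with ~81% reduced species after 173 h
  expect_equal(f[length(f)], 0.80582)
  # percent-scale input gives the slope in fraction units
  fitPct <- fitKinetics(t, 100 * f, "linear")
  expect_equal(fitPct@params[["slope"]], -6.6e-4, tolerance = 1e-10)
})

test_that("a noiseless exponential plateau is exactly identifiable", {
  t <- kineticsTimeGrid()
  f <- 0.53 + (0.95 - 0.53) * exp(-0.03 * t)
  fit <- fitKinetics(t, f, "exponential_plateau")
  expect_equal(fit@params[["plateau"]], 0.53, tolerance = 1e-6)
  expect_equal(fit@params[["f0"]], 0.95, tolerance = 1e-6)
  expect_equal(fit@params[["k"]], 0.03, tolerance = 1e-6)
  expect_equal(fit@r2, 1, tolerance = 1e-10)
})

test_that("constant series degrade gracefully, short series warn on auto", {
  fit <- fitKinetics(c(0, 3, 5, 7), rep(0.9, 4), "linear")
  expect_true(fit@degenerate)
  expect_equal(fit@params[["slope"]], 0)
  expect_true(is.na(fit@r2))
  expect_warning(fitKinetics(c(0, 3, 5, 7, 9),
                             0.9 - 1e-3 * c(0, 3, 5, 7, 9), "auto"),
                 "fewer than 6")
  expect_error(fitKinetics(c(0, 1, 2), c(0.9, 0.8, 0.7)), "4 timepoints")
})

test_that("auto selection prefers the better-fitting model", {
  t <- kineticsTimeGrid()
  lin <- 0.92 - 6.6e-4 * t
  expect_equal(fitKinetics(t, lin, "auto")@model, "linear")
  ex <- 0.58 + (0.95 - 0.58) * exp(-0.03 * t)
  expect_equal(fitKinetics(t, ex, "auto")@model, "exponential_plateau")
})

test_that("plateau recovery succeeds on noisy synthetics", {
  t <- kineticsTimeGrid()
  ok <- sum(vapply(1:50, function(s) {
    set.seed(s)
    f <- pmin(pmax(0.53 + (0.95 - 0.53) * exp(-0.03 * t) +
                   rnorm(length(t), 0, 0.01), 0), 1)
    fit <- fitKinetics(t, f, "exponential_plateau")
    abs(fit@params[["plateau"]] - 0.53) <= 0.02
  }, logical(1)))
  expect_gte(ok / 50, 0.9)
})

test_that("Henderson-Hasselbalch speciation behaves", {
  expect_equal(deprotonatedFraction(7, 7), 0.5)
  expect_equal(deprotonatedFraction(9, 7), 1 / (1 + 1e-2))
  expect_equal(round(deprotonatedFraction(9, 7), 3), 0.990)
  ph <- seq(3, 11, by = 0.5)
  expect_true(all(diff(deprotonatedFraction(ph, 7)) > 0))
})
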