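mkTab <- function(df, role = "extract", ref = 1, id = "t") {
  FeatureTable(df, sampleId = id, role = role, ref = ref)
}

test_that("identical tables self-match feature by feature", {
  set.seed(11)
  df <- data.frame(mz = sort(runif(15, 100, 1200)), rt = runif(15, 1, 20),
                   intensity = runif(15, 100, 1e5))
  al <- alignFeatures(mkTab(df), mkTab(df))
  expect_equal(al$idxA, 1:15)
  expect_equal(al$idxB, 1:15)
  expect_equal(al$deltaMz, rep(0, 15))
})

test_that("the 10 mDa MS1 tolerance separates matched from unmatched", {
  a <- mkTab(data.frame(mz = 200, rt = 10, intensity = 100))
  b9 <- mkTab(data.frame(mz = 200.009, rt = 10, intensity = 100))
  b11 <- mkTab(data.frame(mz = 200.011, rt = 10, intensity = 100))
  expect_equal(nrow(alignFeatures(a, b9)), 1L)
  expect_equal(nrow(alignFeatures(a, b11)), 0L)
  # polarity mismatch is an error
  bneg <- FeatureTable(data.frame(mz = 200, rt = 10, intensity = 100),
                       "b", "extract", 1, polarity = "negative")
  expect_error(alignFeatures(a, bneg), "polarity mismatch")
})

test_that("alignment equals the brute-force nearest-pair assignment", {
  for (s in 1:5) {
    set.seed(s)
    fa <- data.frame(mz = runif(30, 100, 110), rt = runif(30, 1, 5),
                     intensity = runif(30, 10, 100))
    fb <- data.frame(mz = fa$mz + rnorm(30, 0, 0.008),
                     rt = fa$rt + rnorm(30, 0, 0.3),
                     intensity = runif(30, 10, 100))
    got <- alignFeatures(mkTab(fa), mkTab(fb))
    want <- oracleAlign(fa, fb)
    expect_equal(got$idxA, want$i)
    expect_equal(got$idxB, want$j)
  }
})

test_that("blank subtraction removes exactly the blank-matched features", {
  set.seed(21)
  df <- data.frame(mz = seq(100, 145, by = 5) + runif(10, 0, 0.001),
                   rt = runif(10, 1, 20), intensity = runif(10, 100, 1000))
  sample <- mkTab(df)
  # empty blank: unchanged
  emptyBlank <- mkTab(df[0, ], role = "blank")
  expect_equal(featureData(subtractBlank(sample, emptyBlank)),
               featureData(sample))
  # blank == sample: everything removed
  expect_equal(nFeatures(subtractBlank(sample, mkTab(df, role = "blank"))),
               0L)
  # 3 of 10 planted in the blank: 7 survive, order preserved
  blank <- mkTab(df[c(2, 5, 9), ], role = "blank")
  left <- subtractBlank(sample, blank)
  expect_equal(nFeatures(left), 7L)
  expect_equal(featureData(left)$mz, df$mz[-c(2, 5, 9)])
})

test_that("cascade on the synthetic scenario matches the set-operation oracle", {
  sc <- simulateFeatureScenario(100, 2, 0.05, seed = 1)
  tb <- sc$tables
  rep <- runCascade(tb$extract5, tb$extract1, tb$upper, tb$lower, tb$blank)
  orc <- oracleCascade(featureData(tb$extract5), featureData(tb$extract1),
                       featureData(tb$upper), featureData(tb$lower),
                       featureData(tb$blank))
  expect_equal(cascadeSteps(rep)$count, orc$counts)
  expect_equal(cascadeSurvivors(rep)$idx5, orc$survivors)
  # final candidates are the two planted drivers
  sv <- cascadeSurvivors(rep)
  expect_equal(nrow(sv), 2L)
  for (m in sc$truth@drivers$mz)
    expect_true(any(abs(sv$mz - m) < 0.011))
})

test_that("cascade counts never increase and scale with intensity uniformly", {
  sc <- simulateFeatureScenario(60, 3, 0.1, seed = 4)
  tb <- sc$tables
  rep <- runCascade(tb$extract5, tb$extract1, tb$upper, tb$lower, tb$blank)
  expect_true(all(diff(cascadeSteps(rep)$count) <= 0))
  # uniform intensity scaling leaves every ratio-based step unchanged
  scale <- function(ft, s) FeatureTable(
    transform(featureData(ft), intensity = intensity * s),
    ft@sampleId, sampleRole(ft), enrichmentFactor(ft), polarity(ft))
  rep2 <- runCascade(scale(tb$extract5, 13), scale(tb$extract1, 13),
                     scale(tb$upper, 13), scale(tb$lower, 13),
                     scale(tb$blank, 13))
  expect_equal(cascadeSteps(rep2)$count, cascadeSteps(rep)$count)
  expect_equal(cascadeSurvivors(rep2)$idx5, cascadeSurvivors(rep)$idx5)
})

test_that("identical tables without blank overlap reduce only via the 1% filter", {
  set.seed(31)
  df <- data.frame(mz = seq(100, 600, length.out = 20) + runif(20, 0, 0.001),
                   rt = runif(20, 1, 20),
                   intensity = c(rep(10, 18), 5000, 5000))
  t5 <- mkTab(df, ref = 5)
  blank <- mkTab(data.frame(mz = 900.5, rt = 2, intensity = 10),
                 role = "blank")
  rep <- runCascade(t5, mkTab(df), mkTab(df, "fraction_upper"),
                    mkTab(df, "fraction_lower"), blank)
  cnt <- cascadeSteps(rep)$count
  expect_equal(cnt[1:5], rep(20L, 5))
  # only the two 5000-count features exceed 1% of the summed intensity
  expect_equal(cnt[6], 2L)
})

test_that("a driver at 0.9% of total intensity dies at the intensity filter", {
  set.seed(41)
  # one candidate feature plus one dominant feature setting the total
  df <- data.frame(mz = c(200.0005, 400.0005), rt = c(5, 10),
                   intensity = c(0.9, 99.1))
  t5 <- mkTab(df, ref = 5)
  t1 <- mkTab(transform(df, intensity = intensity / 5))
  rep <- runCascade(t5, t1, mkTab(df, "fraction_upper"),
                    mkTab(df, "fraction_lower"),
                    mkTab(df[0, ], role = "blank"))
  sv <- cascadeSurvivors(rep)
  expect_false(any(abs(sv$mz - 200.0005) < 0.01))   # 0.9% < 1%: eliminated
  expect_true(any(abs(sv$mz - 400.0005) < 0.01))
})

test_that("empty required tables are rejected by name", {
  sc <- simulateFeatureScenario(5, 1, 0, seed = 2)
  tb <- sc$tables
  empty <- FeatureTable(featureData(tb$upper)[0, ], "u", "fraction_upper", 1)
  expect_error(runCascade(tb$extract5, tb$extract1, empty, tb$lower,
                          tb$blank), "'upper' is empty")
})
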