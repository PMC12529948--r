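makeLib <- function(df) {
  df$ms2 <- lapply(df$ms2txt, estroEDA:::.parseMs2)
  df$ms2txt <- NULL
  df
}

test_that("matching respects the MS1 and RT tolerances", {
  lib <- makeLib(data.frame(
    name = "phenolic-amine", formula = "C12H11NO", polarity = "positive",
    rt_min = 10.06, mz = 186.0913, reference_standard = FALSE,
    ms2txt = "", stringsAsFactors = FALSE))
  # measured feature vs library entry: 0.1 mDa and 0.16 min apart
  hit <- matchLibrary(186.0914, 9.90, lib)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$confidenceLevel, 4L)
  # 12 mDa offset: outside the 10 mDa tolerance
  expect_equal(nrow(matchLibrary(186.0913 + 0.012, 10.06, lib)), 0L)
  # 1.2 min RT offset: outside the 1 min tolerance
  expect_equal(nrow(matchLibrary(186.0913, 11.3, lib)), 0L)
  # empty library: empty result, not an error
  expect_equal(nrow(matchLibrary(186.0913, 10, lib[0, ])), 0L)
})

test_that("confidence levels follow the evidence hierarchy", {
  lib <- makeLib(data.frame(
    name = c("withSpec", "noSpec", "standard"),
    formula = "C12H11NO", polarity = "positive",
    rt_min = 10.0, mz = 186.0913,
    reference_standard = c(FALSE, FALSE, TRUE),
    ms2txt = c("93.07:100;120.08:40", "", "93.07:100;120.08:40"),
    stringsAsFactors = FALSE))
  ms2 <- data.frame(mz = c(93.071, 120.081, 65.04), relint = c(100, 35, 10))
  hits <- matchLibrary(186.0913, 10.0, lib, ms2 = ms2)
  expect_equal(sort(hits$confidenceLevel), c(1L, 2L, 3L))
  expect_equal(hits$confidenceLevel[hits$name == "standard"], 1L)
  expect_equal(hits$confidenceLevel[hits$name == "withSpec"], 2L)
  expect_equal(hits$confidenceLevel[hits$name == "noSpec"], 3L)
  # exactly half the library peaks matched still clears the >= 0.5 bar
  ms2half <- data.frame(mz = 93.071, relint = 100)
  one <- matchLibrary(186.0913, 10.0, lib[1, ], ms2 = ms2half)
  expect_equal(one$confidenceLevel, 2L)
  expect_equal(one$ms2Score, 0.5)
  # below half: back to formula-level evidence
  lib3 <- makeLib(data.frame(
    name = "threePeak", formula = "C12H11NO", polarity = "positive",
    rt_min = 10.0, mz = 186.0913, reference_standard = FALSE,
    ms2txt = "93.07:100;120.08:40;77.04:25", stringsAsFactors = FALSE))
  low <- matchLibrary(186.0913, 10.0, lib3, ms2 = ms2half)
  expect_equal(low$confidenceLevel, 4L)
  expect_equal(low$ms2Score, 1 / 3, tolerance = 1e-12)
})

test_that("candidate set equals a brute-force all-pairs filter", {
  set.seed(7)
  n <- 50
  lib <- makeLib(data.frame(
    name = sprintf("cmp%02d", 1:n), formula = "C10H10O2",
    polarity = "positive", rt_min = runif(n, 1, 20),
    mz = runif(n, 100, 400), reference_standard = FALSE, ms2txt = "",
    stringsAsFactors = FALSE))
  tol <- MatchTolerances()
  for (k in 1:10) {
    mz <- runif(1, 100, 400)
    rt <- runif(1, 1, 20)
    got <- sort(matchLibrary(mz, rt, lib)$name)
    want <- sort(lib$name[abs(lib$mz - mz) <= tol@ms1 &
                          abs(lib$rt_min - rt) <= tol@rt])
    expect_equal(got, want)
  }
})

test_that("widening a tolerance never removes a match", {
  set.seed(8)
  lib <- makeLib(data.frame(
    name = sprintf("c%d", 1:30), formula = "C10H10O2",
    polarity = "positive", rt_min = runif(30, 1, 20),
    mz = 186.09 + rnorm(30, 0, 0.02), reference_standard = FALSE,
    ms2txt = "", stringsAsFactors = FALSE))
  narrow <- matchLibrary(186.0913, 10, lib, MatchTolerances(0.005, 0.015, 0.5))
  wide <- matchLibrary(186.0913, 10, lib, MatchTolerances(0.02, 0.03, 2))
  expect_true(all(narrow$name %in% wide$name))
})

test_that("a library round-trips through its CSV encoding", {
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(name = c("a", "b"), formula = c("C12H11NO", "C12H9NO"),
                   polarity = "positive", rt_min = c(9.9, 9.92),
                   ms2 = c("93.0699:100;120.0808:45", ""),
                   reference_standard = c(TRUE, FALSE))
  write.csv(df, tmp, row.names = FALSE)
  lib <- readSpectralLibrary(tmp)
  expect_equal(lib$mz, c(adductMz("C12H11NO", "[M+H]+"),
                         adductMz("C12H9NO", "[M+H]+")))
  expect_equal(lib$ms2[[1]]$mz, c(93.0699, 120.0808))
  expect_equal(nrow(lib$ms2[[2]]), 0L)
  expect_true(lib$reference_standard[1])
  unlink(tmp)
})
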