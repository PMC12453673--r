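test_that("perfect clustering scores (1, 1, 1) up to relabeling", {
  v <- vMeasure(c(0, 0, 1, 1), c(5, 5, 2, 2))
  expect_identical(unlist(v), c(homogeneity = 1, completeness = 1,
                                vMeasure = 1))
})

test_that("collapsing distinct classes zeroes homogeneity", {
  v <- vMeasure(c(0, 0, 1, 1), c(1, 1, 1, 1))
  expect_identical(v$homogeneity, 0)
  expect_identical(v$completeness, 1)
  expect_identical(v$vMeasure, 0)
})

test_that("shattering classes keeps homogeneity 1 and costs completeness", {
  # frozen from the entropy definitions: H(P)=log 4, H(P|T)=log 2
  v <- vMeasure(c(0, 0, 1, 1), c(0, 1, 2, 3))
  expect_identical(v$homogeneity, 1)
  expect_equal(v$completeness, 0.5, tolerance = 1e-12)
  expect_equal(v$vMeasure, 2 / 3, tolerance = 1e-12)
})

test_that("label identities do not matter", {
  set.seed(51)
  truth <- sample(1:5, 100, replace = TRUE)
  pred <- sample(1:4, 100, replace = TRUE)
  v1 <- vMeasure(truth, pred)
  v2 <- vMeasure(match(truth, sample(1:5)), paste0("c", pred))
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("degenerate label vectors are rejected", {
  expect_error(vMeasure(1:3, 1:4), "equal length")
  expect_error(vMeasure(integer(), integer()), "non-empty")
})

test_that("vMeasure agrees with the contingency-entropy oracle", {
  set.seed(52)
  for (i in 1:200) {
    n <- sample(5:200, 1)
    truth <- sample(seq_len(sample(2:10, 1)), n, replace = TRUE)
    pred <- sample(seq_len(sample(2:10, 1)), n, replace = TRUE)
    got <- vMeasure(truth, pred)
    want <- oracleVMeasure(truth, pred)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("splitting lowers completeness only; merging lowers homogeneity only", {
  truth <- rep(1:2, each = 10)
  ident <- truth
  split <- c(rep(1, 5), rep(3, 5), rep(2, 10))   # class 1 split in two
  merged <- rep(1, 20)                           # classes merged
  v0 <- vMeasure(truth, ident)
  vs <- vMeasure(truth, split)
  vm <- vMeasure(truth, merged)
  expect_identical(vs$homogeneity, 1)
  expect_lt(vs$completeness, v0$completeness)
  expect_identical(vm$completeness, 1)
  expect_lt(vm$homogeneity, v0$homogeneity)
})

test_that("case weights reproduce expanded label vectors", {
  truth <- c(1, 1, 2)
  pred <- c(1, 2, 2)
  w <- c(3, 2, 4)
  a <- vMeasure(truth, pred, weights = w)
  b <- vMeasure(rep(truth, w), rep(pred, w))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("pctRecovered follows the reporting convention", {
  expect_identical(pctRecovered(1000, 1045), 104.5)
  expect_identical(pctRecovered(1000, 1000), 100)
  expect_identical(pctRecovered(10000, 9944), 99.44)
})

test_that("evaluateRun scores error-free runs perfectly", {
  sim <- simulateUmiData(SimulationConfig(15, 120, 0), seed = 14)
  cl <- deduplicate(sim$observations, ErrorModel(1e-6))
  m <- evaluateRun(sim$truth, cl, filtered = FALSE)
  expect_identical(m$homogeneity, 1)
  expect_identical(m$completeness, 1)
  expect_identical(m$vMeasure, 1)
  expect_identical(m$pctRecovered, 100)
})

test_that("merging two true founders costs homogeneity, not completeness", {
  # two founders one substitution apart; an aggressive threshold merges them
  obs <- UmiSet(c("AAAAAAAAAAAA", "AAAAAAAAAAAT"), c(2L, 2L))
  truth <- new("SimulationTruth",
    founders = c("AAAAAAAAAAAA", "AAAAAAAAAAAT"), depths = c(2L, 2L),
    observedUmi = rep(c("AAAAAAAAAAAA", "AAAAAAAAAAAT"), each = 2),
    founderIndex = rep(1:2, each = 2L))
  cl <- deduplicate(obs, ErrorModel(0.005), maxDist = 2)
  expect_identical(nClusters(cl), 1L)
  m <- evaluateRun(truth, cl, filtered = FALSE)
  expect_identical(m$completeness, 1)
  expect_lt(m$homogeneity, 1)
})

test_that("filtered evaluation counts only kept clusters", {
  sim <- simulateUmiData(SimulationConfig(15, 50, 0), seed = 15)
  cl <- deduplicate(sim$observations, ErrorModel(1e-6))
  dec <- umidedup:::ThresholdDecision(
    min(clusterTotals(cl)) + 1, "knee", kneeScore = 1)
  clf <- applyFilter(cl, dec)
  dropped <- sum(!keptClusters(clf))
  expect_gt(dropped, 0L)
  m <- evaluateRun(sim$truth, clf, filtered = TRUE)
  expect_identical(m$nRecovered, 50L - dropped)
})

test_that("UMIs missing from the truth are an error", {
  sim <- simulateUmiData(SimulationConfig(15, 30, 0), seed = 16)
  cl <- deduplicate(sim$observations, ErrorModel(1e-6))
  truth <- sim$truth
  truth@observedUmi[1] <- strrep("G", 15)  # not among clustered UMIs
  expect_error(evaluateRun(truth, cl), "missing from the clustering")
})

test_that("per-UMI scoring weighs each distinct UMI once", {
  sim <- simulateUmiData(SimulationConfig(15, 40, 0), seed = 18)
  cl <- deduplicate(sim$observations, ErrorModel(1e-6))
  m <- evaluateRun(sim$truth, cl, perUmi = TRUE)
  expect_identical(m$vMeasure, 1)
})
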