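test_that("rankCurve sorts totals and assigns 1-based ranks", {
  expect_identical(rankCurve(c(3, 100, 1)),
                   data.frame(rank = 1:3, total = c(100L, 3L, 1L)))
  expect_identical(rankCurve(c(5, 5, 5))$rank, 1:3)
  expect_identical(rankCurve(7)$total, 7L)
  expect_error(rankCurve(integer()), "nothing to rank")
})

test_that("collinear log-log curves have zero knee score", {
  curve <- data.frame(rank = c(1L, 10L, 100L), total = c(100L, 10L, 1L))
  k <- detectKnee(curve)
  expect_identical(k$kneeScore, 0)
})

test_that("short curves yield a no-knee result", {
  expect_identical(detectKnee(data.frame(rank = 1:2, total = c(10L, 1L))),
                   list(cutoff = 0L, kneeScore = 0, kneeRank = NA_integer_,
                        gapRank = NA_integer_))
})

test_that("a two-plateau curve puts the cutoff at the plateau transition", {
  curve <- rankCurve(c(rep(100L, 100), rep(1L, 1000)))
  k <- detectKnee(curve)
  expect_true(k$cutoff >= 1L && k$cutoff <= 100L)
  expect_identical(k$cutoff, 100L)  # last supported cluster before the cliff
  # chord location and score agree with an exhaustive projection oracle
  orc <- oracleChordKnee(curve)
  expect_identical(k$kneeRank, curve$rank[orc$idx])
  expect_equal(k$kneeScore, orc$score, tolerance = 1e-12)
  expect_gt(k$kneeScore, 0.05)
})

test_that("chord score matches the exhaustive oracle on random curves", {
  set.seed(31)
  for (i in 1:20) {
    totals <- sort(rnbinom(300, size = 2, mu = 50) + 1L, decreasing = TRUE)
    curve <- rankCurve(totals)
    k <- detectKnee(curve)
    orc <- oracleChordKnee(curve)
    expect_equal(k$kneeScore, orc$score, tolerance = 1e-12)
    expect_identical(k$kneeRank, curve$rank[orc$idx])
  }
})

test_that("NB fit recovers parameters from clean draws", {
  set.seed(32)
  totals <- rnbinom(10000, size = 10, mu = 100)
  totals[totals < 1] <- 1
  fit <- fitNegativeBinomial(totals)
  expect_lt(abs(fit$mu - 100) / 100, 0.05)
  expect_gt(fit$cutoff, 0L)
  expect_lt(fit$cutoff, 100L)
})

test_that("NB fit guards degenerate and tiny inputs", {
  expect_error(fitNegativeBinomial(rep(50, 9)), "at least 10")
  fit <- fitNegativeBinomial(rep(50, 100))
  expect_identical(fit$size, Inf)
  expect_lte(fit$cutoff, 50L)
  fit1 <- fitNegativeBinomial(rep(1, 100))
  expect_lte(fit1$cutoff, 1L)
})

test_that("decision selects the knee when it is sharp", {
  totals <- c(rep(100L, 200), rep(1L, 400))
  dec <- decideThreshold(totals)
  expect_identical(dec@method, "knee")
  expect_identical(dec@cutoff, 100)
})

test_that("decision falls back to the NB fit without a clear knee", {
  # log-linear (power-law) rank curve: no knee, but enough clusters to fit
  totals <- as.integer(round(500 * (1:200)^-1)) + 1L
  dec <- decideThreshold(totals)
  expect_lt(dec@kneeScore, 0.05)
  expect_identical(dec@method, "negative_binomial")
  expect_false(is.na(dec@nbMu))
})

test_that("a handful of clusters filters nothing", {
  dec <- decideThreshold(c(100, 3, 1))
  expect_identical(dec@method, "none")
  expect_identical(dec@cutoff, 0)
})

test_that("filtering flags clusters but never reassigns or drops reads", {
  set.seed(33)
  sim <- simulateUmiData(
    SimulationConfig(18, 300, 0.005, subWeight = 40), seed = 13)
  cl <- deduplicate(sim$observations, ErrorModel(0.005, subWeight = 40))
  clf <- applyFilter(cl)
  expect_lte(sum(keptClusters(clf)), nClusters(cl))
  expect_identical(clusterMap(clf)$umi, clusterMap(cl)$umi)
  expect_identical(sum(clusterTotals(clf)), sum(readCounts(sim$observations)))
  # boundary convention: keep iff total >= cutoff
  dec <- thresholdDecision(clf)
  expect_identical(unname(keptClusters(clf)),
                   unname(clusterTotals(clf) >= dec@cutoff))
})

test_that("an explicit none decision leaves the cluster set unchanged", {
  obs <- UmiSet(c("AAAAAAAAAAAA", "TTTTTTTTTTTT"), c(100L, 1L))
  cl <- deduplicate(obs, ErrorModel(0.001))
  clf <- applyFilter(cl)  # 2 clusters -> method none
  expect_identical(thresholdDecision(clf)@method, "none")
  expect_true(all(keptClusters(clf)))
})

test_that("adaptive filtering improves founder counts by about an order of magnitude", {
  sim <- simulateUmiData(
    SimulationConfig(18, 1000, 0.005, subWeight = 40), seed = 17)
  cl <- deduplicate(sim$observations, ErrorModel(0.005, subWeight = 40))
  pre <- evaluateRun(sim$truth, cl, filtered = FALSE)
  post <- evaluateRun(sim$truth, applyFilter(cl), filtered = TRUE)
  devPre <- abs(pre$pctRecovered - 100)
  devPost <- abs(post$pctRecovered - 100)
  expect_gt(devPre, 0.5)           # uncorrected error clusters inflate counts
  expect_lte(devPost, devPre / 5)  # filter removes nearly all of them
})
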