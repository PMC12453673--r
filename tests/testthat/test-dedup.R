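test_that("a single-substitution low-count UMI is absorbed by its founder", {
  obs <- UmiSet(c("AAAAAAAAAAAA", "AAAAAAAAAAAT"), c(100L, 2L))
  cl <- deduplicate(obs, ErrorModel(0.005))
  expect_identical(nClusters(cl), 1L)
  expect_identical(founders(cl), "AAAAAAAAAAAA")
  expect_identical(unname(clusterTotals(cl)), 102L)
})

test_that("distant UMIs found separate clusters", {
  obs <- UmiSet(c("AAAAAAAAAAAA", "TTTTTTTTTTTT"), c(100L, 90L))
  cl <- deduplicate(obs, ErrorModel(0.005))
  expect_identical(nClusters(cl), 2L)
  # distance 12 exceeds any threshold up to 11
  cl <- deduplicate(obs, ErrorModel(0.005), maxDist = 11)
  expect_identical(nClusters(cl), 2L)
})

test_that("ties go to the founder earlier in the sorted list", {
  f1 <- "AAAAAAAAAAAA"       # lexicographically first, equal counts
  f2 <- "AAAAAAAAAATT"       # distance 2 from f1
  p <- "AAAAAAAAAAAT"        # distance 1 from both
  obs <- UmiSet(c(f2, f1, p), c(50L, 50L, 1L))
  cl <- deduplicate(obs, ErrorModel(0.005), maxDist = 1)
  df <- clusterMap(cl)
  expect_identical(df$founder_umi[df$umi == p], f1)
})

test_that("progeny attach to the closest founder, not the first within threshold", {
  f1 <- "AAAAAAAAAAAA"       # processed first (highest count)
  f2 <- "AAAAAAATTTTT"       # distance 5 from f1: a separate founder
  p <- "AAAAAAAATTTT"        # distance 4 from f1, 1 from f2
  obs <- UmiSet(c(f1, f2, p), c(90L, 50L, 1L))
  cl <- deduplicate(obs, ErrorModel(0.005), maxDist = 4)
  df <- clusterMap(cl)
  expect_identical(nClusters(cl), 2L)
  expect_identical(df$founder_umi[df$umi == p], f2)
})

test_that("empty input gives an empty clustering", {
  cl <- deduplicate(UmiSet(character()), ErrorModel(0.01))
  expect_identical(nClusters(cl), 0L)
  expect_identical(length(umis(cl)), 0L)
})

test_that("zero-error simulations are recovered exactly", {
  sim <- simulateUmiData(SimulationConfig(18, 300, 0), seed = 5)
  cl <- deduplicate(sim$observations, ErrorModel(1e-6))
  expect_identical(nClusters(cl), 300L)
  expect_identical(sort(unname(clusterTotals(cl))),
                   sort(as.integer(sim$truth@depths)))
})

test_that("the kernel reproduces a naive adist-driven greedy oracle", {
  set.seed(21)
  for (rep in 1:5) {
    umi <- unique(randomSeqs(300, c(8L, 14L)))
    count <- sample(1:100, length(umi), replace = TRUE)
    model <- ErrorModel(0.01)
    cl <- deduplicate(UmiSet(umi, count), model)
    orc <- oracleGreedy(umi, count, model)
    expect_identical(umis(cl), orc$umi)
    expect_identical(unname(readCounts(cl)), orc$count)
    expect_identical(cl@founderRow, orc$founderRow)
  }
})

test_that("batching and worker counts never change the output", {
  set.seed(22)
  umi <- unique(randomSeqs(250, c(8L, 14L)))
  count <- sample(1:80, length(umi), replace = TRUE)
  obs <- UmiSet(umi, count)
  model <- ErrorModel(0.02)
  ref <- clusterMap(deduplicate(obs, model))
  for (bs in c(1L, 16L, 1024L)) {
    for (w in c(1L, 2L, 8L)) {
      got <- clusterMap(deduplicateBatched(obs, model, batchSize = bs,
                                           workers = w))
      expect_identical(got, ref)
    }
  }
})

test_that("output clusters form a partition conserving reads", {
  set.seed(23)
  umi <- unique(randomSeqs(400, c(10L, 12L)))
  count <- sample(1:60, length(umi), replace = TRUE)
  cl <- deduplicate(UmiSet(umi, count), ErrorModel(0.01))
  df <- clusterMap(cl)
  expect_setequal(df$umi, umi)
  expect_identical(anyDuplicated(df$umi), 0L)
  expect_identical(sum(df$umi_read_count), sum(count))
  totals <- clusterTotals(cl)
  expect_identical(sum(totals), sum(count))
  # every member is within its pair threshold of its founder
  prog <- df[df$umi != df$founder_umi, ]
  if (nrow(prog)) {
    t <- pairThreshold(nchar(prog$umi), nchar(prog$founder_umi),
                       ErrorModel(0.01))
    expect_true(all(levenshteinDist(prog$umi, prog$founder_umi) <= t))
  }
})

test_that("founders dominate their progeny in count or sort order", {
  set.seed(24)
  umi <- unique(randomSeqs(300, c(8L, 12L)))
  count <- sample(1:40, length(umi), replace = TRUE)
  cl <- deduplicate(UmiSet(umi, count), ErrorModel(0.02))
  expect_true(all(cl@founderRow <= seq_along(cl@umi)))
  fCount <- cl@readCount[cl@founderRow]
  expect_true(all(fCount >= cl@readCount |
                  cl@founderRow < seq_along(cl@umi)))
})

test_that("every founder pair is separated by more than its threshold", {
  set.seed(25)
  sim <- simulateUmiData(
    SimulationConfig(18, 200, 0.005, subWeight = 40), seed = 9)
  model <- ErrorModel(0.005, subWeight = 40)
  cl <- deduplicate(sim$observations, model)
  f <- founders(cl)
  kt <- umidedup:::thresholdTable(2L * max(nchar(f)), model)
  expect_identical(umidedup:::cppCountFounderViolations(f, kt), 0L)
})
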