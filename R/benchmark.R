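#' Standard simulation regimes
#'
#' The benchmark grids: Illumina-like short-read UMIs (12 and 18 bp at
#' per-base error rates 0.001 and 0.005, ins:del:sub 1:1:40) and long-read
#' PacBio/Nanopore-like UMIs (25 and 50 bp at 0.01 and 0.03, 1:1:1), with
#' negative binomial progeny depth of mean 100 per founder.
#'
#' @param nFounders Founders per dataset (default 1000).
#' @param depthMean,depthSize Reads-per-founder negative binomial
#'   parameters.
#'
#' @return A list of [SimulationConfig-class] objects (one per UMI length x
#'   error rate combination).
#' @export
shortReadRegimes <- function(nFounders = 1000, depthMean = 100,
                             depthSize = 10) {
  grid <- expand.grid(len = c(12L, 18L), rate = c(0.001, 0.005))
  lapply(seq_len(nrow(grid)), function(i) {
    SimulationConfig(grid$len[i], nFounders, grid$rate[i],
                     insWeight = 1, delWeight = 1, subWeight = 40,
                     depthMean = depthMean, depthSize = depthSize)
  })
}

#' @rdname shortReadRegimes
#' @export
longReadRegimes <- function(nFounders = 1000, depthMean = 100,
                            depthSize = 10) {
  grid <- expand.grid(len = c(25L, 50L), rate = c(0.01, 0.03))
  lapply(seq_len(nrow(grid)), function(i) {
    SimulationConfig(grid$len[i], nFounders, grid$rate[i],
                     insWeight = 1, delWeight = 1, subWeight = 1,
                     depthMean = depthMean, depthSize = depthSize)
  })
}

#' Simulate, deduplicate, filter and score a grid of regimes
#'
#' For every regime and replicate seed (`baseSeed`, `baseSeed + 1`, ...,
#' one per replicate), simulates a ground-truth dataset, deduplicates it,
#' applies the adaptive filter, and scores the result against the truth.
#' The summary aggregates the mean and standard error (sample standard
#' deviation over sqrt of the number of runs) of the pre- and post-filter
#' founder-recovery percentages and of the V-measure across all runs of the
#' grid.
#'
#' @param regimes List of [SimulationConfig-class] objects, e.g. from
#'   [shortReadRegimes()].
#' @param replicates Replicate simulations per regime (>= 2 for a standard
#'   error; default 3).
#' @param baseSeed Integer base seed; replicate `j` of every regime uses
#'   `baseSeed + j - 1`.
#' @param confidenceLevel Confidence level of the distance threshold.
#' @param filter Apply the adaptive filter (default `TRUE`).
#' @param workers Threads for candidate precomputation.
#'
#' @return A list with `runs` (one row per regime x replicate: regime
#'   parameters, seed, dataset sizes, pre/post-filter recovery, metrics,
#'   filter decision) and `summary` (one-row data frame of means and
#'   standard errors).
#' @export
runBenchmark <- function(regimes, replicates = 3L, baseSeed = 1L,
                         confidenceLevel = 0.99, filter = TRUE,
                         workers = 1L) {
  stopifnot(length(regimes) >= 1L, replicates >= 1L)
  rows <- vector("list", length(regimes) * replicates)
  k <- 0L
  for (cfg in regimes) {
    for (j in seq_len(replicates)) {
      seed <- as.integer(baseSeed) + j - 1L
      sim <- simulateUmiData(cfg, seed = seed)
      model <- ErrorModel(
        errorRate = max(cfg@errorRate, 1e-12),
        insWeight = cfg@insWeight, delWeight = cfg@delWeight,
        subWeight = cfg@subWeight, confidenceLevel = confidenceLevel)
      cl <- deduplicate(sim$observations, model, workers = workers)
      pre <- evaluateRun(sim$truth, cl, filtered = FALSE)
      if (filter) cl <- applyFilter(cl)
      post <- evaluateRun(sim$truth, cl, filtered = TRUE)
      dec <- thresholdDecision(cl)
      k <- k + 1L
      rows[[k]] <- data.frame(
        umiLength = cfg@umiLength, errorRate = cfg@errorRate,
        nFounders = cfg@nFounders, replicate = j, seed = seed,
        nReads = sum(sim$truth@depths), nUmis = length(sim$observations),
        nClustersPre = pre$nRecovered, pctPre = pre$pctRecovered,
        nClustersPost = post$nRecovered, pctPost = post$pctRecovered,
        homogeneity = pre$homogeneity, completeness = pre$completeness,
        vMeasure = pre$vMeasure,
        filterMethod = if (is.null(dec)) "unfiltered" else dec@method,
        cutoff = if (is.null(dec)) 0 else dec@cutoff
      )
    }
  }
  runs <- do.call(rbind, rows)
  se <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0
  summary <- data.frame(
    nRuns = nrow(runs),
    pctPreMean = mean(runs$pctPre), pctPreSE = se(runs$pctPre),
    pctPostMean = mean(runs$pctPost), pctPostSE = se(runs$pctPost),
    vMeasureMean = mean(runs$vMeasure), vMeasureSE = se(runs$vMeasure)
  )
  list(runs = runs, summary = summary)
}

#' Write a reproducibility manifest for a run
#'
#' One-line JSON with the package version, the full parameter set, the
#' input/output paths, seeds, a timestamp and the headline counts --
#' sufficient to re-run the command bit-identically given the same inputs.
#'
#' @param path Output path of the manifest JSON.
#' @param params Named list of parameters (flags, seeds, paths).
#' @param counts Named list of result counts (reads, UMIs, founders, kept).
#'
#' @return Invisibly, the manifest list.
#' @export
writeRunManifest <- function(path, params, counts = list()) {
  manifest <- list(
    tool = "umidedup",
    version = as.character(utils::packageVersion("umidedup")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    counts = counts
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
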