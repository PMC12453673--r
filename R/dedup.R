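#' Greedy founder discovery and progeny assignment
#'
#' Implements abundance-greedy clustering of UMIs: observations are processed
#' in sort order (read count descending, then sequence ascending in the C
#' locale), the first UMI seeds the founder list, and each subsequent UMI
#' either joins the closest founder within the pair threshold (ties broken in
#' favour of the founder appearing earlier in the sorted list) or, if its
#' distance to every existing founder exceeds the threshold, founds a new
#' cluster. The pair threshold is [pairThreshold()] of the two sequence
#' lengths under `model`; all comparisons use the capped Levenshtein kernel,
#' so only the predicate "within threshold" and the argmin among qualifying
#' founders are ever computed.
#'
#' The output is a deterministic function of the observation multiset: it is
#' identical for every `workers` and, for [deduplicateBatched()], every
#' `batchSize`. Worker threads only precompute candidate founders for a
#' batch; final decisions are committed strictly in sort order by a single
#' sequential pass, and a UMI's founder always precedes it (or is the UMI
#' itself).
#'
#' @param observations A [UmiSet-class] of aggregated observations.
#' @param model An [ErrorModel-class] supplying the error rate and the
#'   confidence level of the threshold.
#' @param workers Number of threads used to precompute candidate founders
#'   (default 1). Has no effect on the result.
#' @param maxDist Optional fixed distance threshold overriding the binomial
#'   calibration for every pair.
#'
#' @return A [UmiClustering-class].
#' @examples
#' obs <- UmiSet(c("AAAAAAAAAAAA", "AAAAAAAAAAAT"), c(100L, 2L))
#' deduplicate(obs, ErrorModel(0.005))
#' @export
deduplicate <- function(observations, model, workers = 1L, maxDist = NULL) {
  dedupImpl(observations, model, batchSize = NULL, workers = workers,
            maxDist = maxDist)
}

#' @rdname deduplicate
#' @param batchSize Number of UMIs per batch handed to the candidate
#'   precomputation phase.
#' @export
deduplicateBatched <- function(observations, model, batchSize,
                               workers = 1L, maxDist = NULL) {
  batchSize <- as.integer(batchSize)
  if (is.na(batchSize) || batchSize < 1L)
    stop("batchSize must be a positive integer")
  dedupImpl(observations, model, batchSize = batchSize, workers = workers,
            maxDist = maxDist)
}

dedupImpl <- function(observations, model, batchSize, workers, maxDist) {
  stopifnot(is(observations, "UmiSet"), is(model, "ErrorModel"))
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L)
    stop("workers must be a positive integer")
  n <- length(observations)
  if (n == 0L) {
    return(new("UmiClustering",
      umi = character(), readCount = integer(), founderRow = integer(),
      kept = logical(), model = model, decision = NULL))
  }
  umi <- observations@umi
  count <- observations@readCount
  o <- order(-count, umi, method = "radix")
  umi <- umi[o]
  count <- count[o]
  if (is.null(batchSize)) batchSize <- n
  kt <- thresholdTable(2L * max(nchar(umi)), model, maxDist = maxDist)
  founderRow <- cppAssignFounders(umi, kt, batchSize, workers)
  new("UmiClustering",
    umi = umi, readCount = count, founderRow = founderRow,
    kept = rep(TRUE, sum(founderRow == seq_len(n))),
    model = model, decision = NULL)
}
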