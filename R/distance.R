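#' Levenshtein distance between nucleotide strings
#'
#' Exact unit-cost edit distance (substitutions, insertions, deletions all
#' cost 1), computed with a banded dynamic program that stops as soon as the
#' distance is proven to exceed `cap`. The comparison is case-sensitive
#' (the input readers uppercase sequences on read); the uppercase ambiguity
#' code N matches nothing, including another N, so it always contributes a
#' unit mismatch.
#'
#' @param a,b Character vectors of non-empty sequences; recycled to a common
#'   length and compared element-wise.
#' @param cap Non-negative integer cap (recycled). The exact distance is
#'   returned whenever it is `<= cap`; otherwise `cap + 1` is returned,
#'   meaning "exceeds cap". The default `Inf` always returns the exact
#'   distance.
#'
#' @return Integer vector of distances (values `> cap` reported as
#'   `cap + 1`).
#' @examples
#' levenshteinDist("ACGT", "AGT")           # 1
#' levenshteinDist("kitten", "sitting")     # 3
#' levenshteinDist("AAAA", "TTTT", cap = 2) # 3 == cap + 1: exceeds cap
#' @export
levenshteinDist <- function(a, b, cap = Inf) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  if (length(a) == 0L || length(b) == 0L)
    return(integer())
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(is.na(a)) || any(is.na(b)) || any(!nzchar(a)) || any(!nzchar(b)))
    stop("sequences must be non-empty and non-NA")
  cap <- rep_len(cap, n)
  if (any(is.na(cap)) || any(cap < 0))
    stop("cap must be non-negative")
  # a cap at the longer length never truncates: distance <= max(|a|, |b|)
  capInt <- as.integer(pmin(cap, pmax(nchar(a), nchar(b))))
  cppLevDistance(a, b, capInt)
}

#' Error-count threshold from a one-sided binomial interval
#'
#' Number of sequencing/PCR errors tolerated before two UMIs are considered
#' to come from different molecules: the smallest integer `k` such that a
#' `Binomial(n, p)` error count exceeds `k` with probability at most
#' `1 - confidenceLevel` (the upper limit of the exact one-sided binomial
#' interval on the error count). Monotone non-decreasing in `n`, `p` and the
#' confidence level.
#'
#' @param nBases Number of bases over which errors can occur. For a pair of
#'   observed sequences this is their combined length (see
#'   [pairThreshold()]).
#' @param model An [ErrorModel-class].
#'
#' @return Non-negative integer threshold (vectorized over `nBases`).
#' @examples
#' m <- ErrorModel(0.005, confidenceLevel = 0.99)
#' errorCountThreshold(36, m)
#' @export
errorCountThreshold <- function(nBases, model) {
  stopifnot(is(model, "ErrorModel"))
  nBases <- as.integer(nBases)
  if (any(is.na(nBases)) || any(nBases < 1L))
    stop("nBases must be a positive integer")
  as.integer(qbinom(model@confidenceLevel, nBases, model@perBaseErrorRate))
}

#' Distance threshold for one pair of observed UMIs
#'
#' Both compared sequences are observed reads, so the edit distance between
#' them accumulates the errors of both: the tolerated error count is the
#' binomial threshold over their combined length,
#' `errorCountThreshold(lenA + lenB, model)`. A pair of UMIs whose distance
#' exceeds this value is classified as coming from different founders.
#'
#' @param lenA,lenB Positive integer lengths of the two sequences
#'   (vectorized).
#' @inheritParams errorCountThreshold
#'
#' @return Non-negative integer threshold.
#' @examples
#' m <- ErrorModel(0.005, confidenceLevel = 0.99)
#' pairThreshold(18, 18, m)
#' @export
pairThreshold <- function(lenA, lenB, model) {
  lenA <- as.integer(lenA)
  lenB <- as.integer(lenB)
  if (any(is.na(lenA)) || any(is.na(lenB)) || any(lenA < 1L) || any(lenB < 1L))
    stop("sequence lengths must be positive integers")
  errorCountThreshold(lenA + lenB, model)
}

# internal: lookup table kt[n + 1] = threshold for combined length n,
# n = 0..maxSum. Positions 0 and 1 are unused placeholders.
thresholdTable <- function(maxSum, model, maxDist = NULL) {
  if (!is.null(maxDist)) {
    return(rep(as.integer(maxDist), maxSum + 1L))
  }
  c(0L, 0L, errorCountThreshold(seq(2L, max(2L, maxSum)), model))[
    seq_len(maxSum + 1L)]
}
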