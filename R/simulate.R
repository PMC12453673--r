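#' Draw distinct founder UMI sequences
#'
#' Uniform random sequences over A, C, G, T of the configured length;
#' collisions are rejection-resampled so the founders are pairwise distinct.
#'
#' @param config A [SimulationConfig-class].
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#'
#' @return Character vector of `nFounders` distinct UMIs.
#' @export
drawFounders <- function(config, seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  L <- config@umiLength
  n <- config@nFounders
  if (log(n) > L * log(4))
    stop("cannot draw ", n, " distinct founders of length ", L,
         " (only 4^", L, " sequences exist)")
  bases <- c("A", "C", "G", "T")
  draw <- function(k) {
    m <- matrix(sample(bases, k * L, replace = TRUE), nrow = k)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  out <- draw(n)
  repeat {
    dup <- duplicated(out)
    if (!any(dup)) break
    out[dup] <- draw(sum(dup))
  }
  out
}

#' Draw reads-per-founder depths
#'
#' Negative binomial draws with mean `depthMean` and dispersion `depthSize`
#' (`size = Inf` gives the Poisson limit), raised to a minimum of one read:
#' a founder with zero reads would be unobservable and silently change the
#' ground-truth founder count.
#'
#' @inheritParams drawFounders
#' @return Integer vector of `nFounders` depths, all `>= 1`.
#' @export
drawDepths <- function(config, seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  n <- config@nFounders
  d <- if (is.infinite(config@depthSize)) {
    rpois(n, lambda = config@depthMean)
  } else {
    rnbinom(n, size = config@depthSize, mu = config@depthMean)
  }
  d <- as.integer(d)
  d[d < 1L] <- 1L
  d
}

#' Apply the per-base error process to UMI sequences
#'
#' Each position independently suffers an error with probability
#' `errorRate`; the error type is drawn from the normalized
#' (ins, del, sub) weights. A substitution replaces the base with a
#' different uniform base, a deletion removes it, and an insertion places a
#' uniform base immediately before it, so the output length is the input
#' length minus deletions plus insertions.
#'
#' @param umi Character vector, one (founder) UMI per read to mutate.
#' @param errorRate Per-base error probability in `[0, 1)`.
#' @param weights Numeric length-3 vector of (ins, del, sub) weights.
#'
#' @return Character vector of observed UMIs, parallel to `umi`.
#' @export
mutateUmis <- function(umi, errorRate, weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3L, all(weights >= 0), sum(weights) > 0,
            errorRate >= 0, errorRate < 1)
  umi <- as.character(umi)
  if (!length(umi) || errorRate == 0) return(umi)
  w <- weights / sum(weights)
  L <- nchar(umi)
  nerr <- rbinom(length(umi), L, errorRate)
  idx <- which(nerr > 0L)
  if (!length(idx)) return(umi)
  bases <- c("A", "C", "G", "T")
  pieces <- strsplit(umi[idx], "", fixed = TRUE)
  for (k in seq_along(idx)) {
    chars <- pieces[[k]]
    ne <- nerr[idx[k]]
    pos <- sort(sample.int(length(chars), ne), decreasing = TRUE)
    type <- sample.int(3L, ne, replace = TRUE, prob = w)
    for (e in seq_len(ne)) {
      p <- pos[e]
      if (type[e] == 3L) {            # substitution: a different base
        chars[p] <- sample(bases[bases != chars[p]], 1L)
      } else if (type[e] == 2L) {     # deletion
        chars <- chars[-p]
      } else {                        # insertion before the position
        chars <- append(chars, sample(bases, 1L), after = p - 1L)
      }
    }
    pieces[[k]] <- chars
  }
  umi[idx] <- vapply(pieces, paste, character(1L), collapse = "")
  umi
}

#' Simulate a ground-truth UMI dataset
#'
#' Draws distinct founders, negative binomial per-founder depths, and one
#' observed UMI per read by applying the error process to the founder
#' sequence. The returned truth maps every read to its founder; the
#' observations are the aggregated (UMI, count) table a deduplication run
#' consumes. Identical config and seed give byte-identical datasets.
#'
#' @inheritParams drawFounders
#' @param seed Integer seed for the whole dataset.
#'
#' @return A list with elements `truth` (a [SimulationTruth-class]) and
#'   `observations` (a [UmiSet-class]). Total observation counts equal the
#'   sum of depths.
#' @examples
#' sim <- simulateUmiData(SimulationConfig(12, 50, 0.001, subWeight = 40),
#'                        seed = 1)
#' sim$observations
#' @export
simulateUmiData <- function(config, seed) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(seed)
  founders <- drawFounders(config)
  depths <- drawDepths(config)
  founderIndex <- rep(seq_along(founders), depths)
  observed <- mutateUmis(
    founders[founderIndex], config@errorRate,
    c(config@insWeight, config@delWeight, config@subWeight))
  truth <- new("SimulationTruth",
    founders = founders, depths = depths,
    observedUmi = observed, founderIndex = founderIndex)
  list(truth = truth, observations = UmiSet(observed, dropN = FALSE))
}
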