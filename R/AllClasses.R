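#' Error model for UMI comparison thresholds and simulation
#'
#' Bundles the per-base error probability, the relative weights of insertion,
#' deletion and substitution errors, and the confidence level used for the
#' binomial error-count threshold. The weights are interpreted after
#' normalization to sum 1; they parameterize the simulator only -- the
#' Levenshtein comparison itself uses unit costs.
#'
#' @slot perBaseErrorRate Per-base error probability, in (0, 1).
#' @slot insWeight,delWeight,subWeight Non-negative relative weights of
#'   insertion, deletion and substitution errors (e.g. 1:1:40 for an
#'   Illumina-like profile, 1:1:1 for a long-read profile).
#' @slot confidenceLevel Confidence level of the one-sided binomial interval
#'   behind [errorCountThreshold()], in (0, 1).
#'
#' @seealso [ErrorModel()], [errorCountThreshold()], [pairThreshold()]
#' @export
setClass("ErrorModel",
  representation(
    perBaseErrorRate = "numeric",
    insWeight = "numeric",
    delWeight = "numeric",
    subWeight = "numeric",
    confidenceLevel = "numeric"
  )
)

setValidity("ErrorModel", function(object) {
  msg <- character()
  p <- object@perBaseErrorRate
  if (length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    msg <- c(msg, "perBaseErrorRate must be a single value in (0, 1)")
  w <- c(object@insWeight, object@delWeight, object@subWeight)
  if (length(w) != 3L || any(is.na(w)) || any(w < 0))
    msg <- c(msg, "ins/del/sub weights must be single non-negative values")
  else if (sum(w) == 0)
    msg <- c(msg, "ins/del/sub weights must not all be zero")
  cl <- object@confidenceLevel
  if (length(cl) != 1L || is.na(cl) || cl <= 0 || cl >= 1)
    msg <- c(msg, "confidenceLevel must be a single value in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct an ErrorModel
#'
#' @param errorRate Per-base error probability, in (0, 1).
#' @param insWeight,delWeight,subWeight Non-negative relative weights of
#'   insertion, deletion and substitution errors; normalized internally.
#' @param confidenceLevel Confidence level for the binomial error-count
#'   threshold (default 0.99).
#'
#' @return An [ErrorModel-class] object.
#' @examples
#' ErrorModel(0.005, insWeight = 1, delWeight = 1, subWeight = 40)
#' @export
ErrorModel <- function(errorRate, insWeight = 1, delWeight = 1, subWeight = 1,
                       confidenceLevel = 0.99) {
  new("ErrorModel",
    perBaseErrorRate = as.numeric(errorRate),
    insWeight = as.numeric(insWeight),
    delWeight = as.numeric(delWeight),
    subWeight = as.numeric(subWeight),
    confidenceLevel = as.numeric(confidenceLevel)
  )
}

#' A set of aggregated UMI observations
#'
#' One row per distinct UMI sequence, with the number of reads bearing that
#' exact sequence. This is the atomic input of the founder-assignment
#' algorithm. UMIs are stored uppercased and lexicographically sorted
#' (C locale), so the container is independent of input order.
#'
#' @slot umi Character vector of distinct UMI sequences over A, C, G, T, N.
#' @slot readCount Integer vector of read counts, all >= 1.
#'
#' @seealso [UmiSet()], [readUmiTsv()], [readFastqUmis()]
#' @export
setClass("UmiSet",
  representation(umi = "character", readCount = "integer")
)

setValidity("UmiSet", function(object) {
  msg <- character()
  if (length(object@umi) != length(object@readCount))
    msg <- c(msg, "umi and readCount must have the same length")
  if (length(object@umi)) {
    if (anyDuplicated(object@umi))
      msg <- c(msg, "umi values must be unique after aggregation")
    if (any(is.na(object@umi)) || any(!grepl("^[ACGTN]+$", object@umi)))
      msg <- c(msg, "umi values must be non-empty strings over A,C,G,T,N")
    if (any(is.na(object@readCount)) || any(object@readCount < 1L))
      msg <- c(msg, "readCount values must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Aggregate UMI observations into a UmiSet
#'
#' Uppercases the input, optionally drops UMIs containing the ambiguous base
#' N, and aggregates duplicate sequences by summing their read counts.
#' Aggregation is order-independent.
#'
#' @param umi Character vector of UMI sequences, one per read (or one per
#'   distinct UMI when `readCount` is given).
#' @param readCount Optional integer vector of read counts parallel to `umi`;
#'   defaults to one read per entry.
#' @param dropN If `TRUE` (default), UMIs containing N are removed (a message
#'   reports how many reads were dropped). If `FALSE` they are kept; N
#'   mismatches every base (including N) at unit cost in distance
#'   computations.
#'
#' @return A [UmiSet-class].
#' @examples
#' UmiSet(c("AAAA", "aaaa", "AAAT"))
#' @export
UmiSet <- function(umi, readCount = NULL, dropN = TRUE) {
  umi <- toupper(as.character(umi))
  if (is.null(readCount)) readCount <- rep(1L, length(umi))
  readCount <- as.integer(readCount)
  if (length(readCount) != length(umi))
    stop("readCount must be parallel to umi")
  if (length(umi)) {
    bad <- is.na(umi) | !grepl("^[ACGTN]+$", umi)
    if (any(bad))
      stop("invalid UMI sequence(s), e.g. ", umi[which(bad)[1L]])
    if (any(is.na(readCount) | readCount < 1L))
      stop("read counts must be positive integers")
    if (dropN) {
      hasN <- grepl("N", umi, fixed = TRUE)
      if (any(hasN)) {
        message("dropping ", sum(readCount[hasN]), " read(s) across ",
                sum(hasN), " UMI(s) containing N")
        umi <- umi[!hasN]
        readCount <- readCount[!hasN]
      }
    }
  }
  if (!length(umi)) {
    return(new("UmiSet", umi = character(), readCount = integer()))
  }
  o <- order(umi, method = "radix")
  umi <- umi[o]
  readCount <- readCount[o]
  grp <- cumsum(!duplicated(umi))
  agg <- rowsum(readCount, grp, reorder = FALSE)
  new("UmiSet",
    umi = umi[!duplicated(umi)],
    readCount = as.integer(agg[, 1L])
  )
}

#' Founder-progeny clustering of a UmiSet
#'
#' Result of [deduplicate()]. UMIs are stored in processing order (read count
#' descending, then sequence ascending); `founderRow[i]` is the row of the
#' founder that UMI `i` was assigned to, with `founderRow[i] == i` for
#' founders themselves. A founder always precedes its progeny. The `kept`
#' flag, one per founder, is set by [applyFilter()].
#'
#' @slot umi Character vector of distinct UMIs in processing order.
#' @slot readCount Integer read counts parallel to `umi`.
#' @slot founderRow Integer row index of each UMI's founder.
#' @slot kept Logical, one per founder cluster.
#' @slot model The [ErrorModel-class] used for the thresholds.
#' @slot decision A [ThresholdDecision-class], or `NULL` before filtering.
#'
#' @seealso [founders()], [clusterTotals()], [clusterMap()], [keptClusters()]
#' @export
setClass("UmiClustering",
  representation(
    umi = "character",
    readCount = "integer",
    founderRow = "integer",
    kept = "logical",
    model = "ErrorModel",
    decision = "ANY"
  )
)

setValidity("UmiClustering", function(object) {
  n <- length(object@umi)
  msg <- character()
  if (length(object@readCount) != n || length(object@founderRow) != n)
    msg <- c(msg, "umi, readCount and founderRow must be parallel")
  if (n) {
    fr <- object@founderRow
    if (any(fr < 1L | fr > n))
      msg <- c(msg, "founderRow out of range")
    else {
      if (any(fr > seq_len(n)))
        msg <- c(msg, "a founder must precede its progeny in sort order")
      isF <- fr == seq_len(n)
      if (any(fr[fr] != fr))
        msg <- c(msg, "founderRow must point at a founder row")
      if (length(object@kept) != sum(isF))
        msg <- c(msg, "kept must have one flag per founder")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Adaptive filter decision
#'
#' Records the minimum cluster read support chosen by [decideThreshold()],
#' which of the two methods produced it, and its diagnostics. Clusters with
#' `total_reads >= cutoff` are kept.
#'
#' @slot cutoff Non-negative minimum total read support to keep a cluster.
#' @slot method One of `"knee"`, `"negative_binomial"`, `"none"`.
#' @slot kneeScore Clarity of the rank-plot knee: maximum perpendicular
#'   distance to the log-log chord, normalized by the chord length.
#' @slot nbMu,nbSize Negative binomial mean and dispersion (size) when the
#'   fallback fit was used, `NA` otherwise.
#'
#' @seealso [decideThreshold()], [applyFilter()]
#' @export
setClass("ThresholdDecision",
  representation(
    cutoff = "numeric",
    method = "character",
    kneeScore = "numeric",
    nbMu = "numeric",
    nbSize = "numeric"
  )
)

setValidity("ThresholdDecision", function(object) {
  msg <- character()
  if (!object@method %in% c("knee", "negative_binomial", "none"))
    msg <- c(msg, "method must be knee, negative_binomial or none")
  if (is.na(object@cutoff) || object@cutoff < 0)
    msg <- c(msg, "cutoff must be >= 0")
  if (object@method == "none" && object@cutoff != 0)
    msg <- c(msg, "method 'none' implies cutoff 0")
  if (!is.finite(object@kneeScore))
    msg <- c(msg, "kneeScore must be finite")
  if (length(msg)) msg else TRUE
})

ThresholdDecision <- function(cutoff, method, kneeScore = 0,
                              nbMu = NA_real_, nbSize = NA_real_) {
  new("ThresholdDecision",
    cutoff = as.numeric(cutoff), method = method,
    kneeScore = as.numeric(kneeScore),
    nbMu = as.numeric(nbMu), nbSize = as.numeric(nbSize)
  )
}

#' Simulation configuration
#'
#' Parameters of one ground-truth UMI simulation: UMI length, number of
#' founder molecules, the per-base error process (rate plus ins:del:sub
#' weights) applied independently to every read, and the negative binomial
#' progeny-depth distribution (mean reads per founder and dispersion `size`).
#'
#' @slot umiLength Positive integer UMI length in bases.
#' @slot nFounders Positive integer number of founder molecules.
#' @slot errorRate Per-base, per-read error probability in `[0, 1)`; 0 gives
#'   an error-free dataset.
#' @slot insWeight,delWeight,subWeight Relative error-type weights.
#' @slot depthMean Mean of the negative binomial reads-per-founder
#'   distribution (default 100).
#' @slot depthSize Negative binomial dispersion parameter (`size`); `Inf`
#'   gives the Poisson limit. Default 10 (moderate overdispersion).
#'
#' @seealso [SimulationConfig()], [simulateUmiData()]
#' @export
setClass("SimulationConfig",
  representation(
    umiLength = "integer",
    nFounders = "integer",
    errorRate = "numeric",
    insWeight = "numeric",
    delWeight = "numeric",
    subWeight = "numeric",
    depthMean = "numeric",
    depthSize = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@umiLength < 1L) msg <- c(msg, "umiLength must be >= 1")
  if (object@nFounders < 1L) msg <- c(msg, "nFounders must be >= 1")
  if (is.na(object@errorRate) || object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "errorRate must be in [0, 1)")
  w <- c(object@insWeight, object@delWeight, object@subWeight)
  if (any(w < 0) || sum(w) == 0)
    msg <- c(msg, "error-type weights must be non-negative, not all zero")
  if (object@depthMean <= 0) msg <- c(msg, "depthMean must be > 0")
  if (object@depthSize <= 0) msg <- c(msg, "depthSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param umiLength UMI length in bases.
#' @param nFounders Number of founder molecules.
#' @param errorRate Per-base error probability in `[0, 1)`.
#' @param insWeight,delWeight,subWeight Relative weights of insertion,
#'   deletion and substitution errors (normalized internally).
#' @param depthMean Mean reads per founder (default 100).
#' @param depthSize Negative binomial dispersion (default 10; `Inf` for the
#'   Poisson limit).
#'
#' @return A [SimulationConfig-class].
#' @examples
#' SimulationConfig(12, 1000, 0.001, subWeight = 40)
#' @export
SimulationConfig <- function(umiLength, nFounders, errorRate,
                             insWeight = 1, delWeight = 1, subWeight = 1,
                             depthMean = 100, depthSize = 10) {
  new("SimulationConfig",
    umiLength = as.integer(umiLength), nFounders = as.integer(nFounders),
    errorRate = as.numeric(errorRate),
    insWeight = as.numeric(insWeight), delWeight = as.numeric(delWeight),
    subWeight = as.numeric(subWeight),
    depthMean = as.numeric(depthMean), depthSize = as.numeric(depthSize)
  )
}

#' Ground truth of a simulated UMI dataset
#'
#' Maps every emitted read to its originating founder molecule, so a
#' clustering of the observed UMIs can be scored against the truth.
#'
#' @slot founders Character vector of distinct founder UMI sequences.
#' @slot depths Integer reads per founder (all >= 1).
#' @slot observedUmi Character vector, one observed (possibly mutated) UMI
#'   per read.
#' @slot founderIndex Integer founder index per read, parallel to
#'   `observedUmi`.
#'
#' @seealso [simulateUmiData()], [evaluateRun()]
#' @export
setClass("SimulationTruth",
  representation(
    founders = "character",
    depths = "integer",
    observedUmi = "character",
    founderIndex = "integer"
  )
)

setValidity("SimulationTruth", function(object) {
  msg <- character()
  if (anyDuplicated(object@founders))
    msg <- c(msg, "founders must be pairwise distinct")
  if (length(object@depths) != length(object@founders))
    msg <- c(msg, "depths must be parallel to founders")
  if (length(object@depths) && any(object@depths < 1L))
    msg <- c(msg, "every founder must emit at least one read")
  if (length(object@observedUmi) != length(object@founderIndex))
    msg <- c(msg, "observedUmi and founderIndex must be parallel")
  if (length(object@founderIndex) &&
      (min(object@founderIndex) < 1L ||
       max(object@founderIndex) > length(object@founders)))
    msg <- c(msg, "founderIndex out of range")
  if (length(msg)) msg else TRUE
})
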