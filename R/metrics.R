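#' Homogeneity, completeness and V-measure of a clustering
#'
#' Entropy-based external clustering scores:
#' `homogeneity = 1 - H(true | pred) / H(true)` (each predicted cluster
#' contains members of a single true class),
#' `completeness = 1 - H(pred | true) / H(pred)` (each true class lands in a
#' single predicted cluster), both defined as 1 when the corresponding
#' unconditional entropy is 0, and the V-measure is their harmonic mean
#' (0 when both are 0). Natural logarithms are used; the scores are
#' invariant to relabeling of either side.
#'
#' @param trueLabels,predLabels Equal-length vectors of class/cluster labels
#'   (any atomic type; coerced to factors).
#' @param weights Optional non-negative case weights (e.g. read counts when
#'   labels are per distinct UMI).
#'
#' @return Named list with `homogeneity`, `completeness`, `vMeasure`.
#' @examples
#' vMeasure(c(0, 0, 1, 1), c(1, 1, 0, 0))  # perfect up to relabeling
#' @export
vMeasure <- function(trueLabels, predLabels, weights = NULL) {
  if (length(trueLabels) != length(predLabels))
    stop("label vectors must have equal length")
  if (!length(trueLabels)) stop("label vectors must be non-empty")
  w <- if (is.null(weights)) rep(1, length(trueLabels)) else as.numeric(weights)
  if (length(w) != length(trueLabels) || any(w < 0))
    stop("weights must be non-negative and parallel to the labels")
  ft <- as.integer(factor(trueLabels))
  fp <- as.integer(factor(predLabels))
  entropy <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log(p))
  }
  hT <- entropy(rowsum(w, ft)[, 1L])
  hP <- entropy(rowsum(w, fp)[, 1L])
  # joint entropy from the (sparse) contingency of observed label pairs
  key <- (ft - 1) * (max(fp) + 1) + fp
  hTP <- entropy(rowsum(w, key)[, 1L])
  homogeneity <- if (hT == 0) 1 else 1 - (hTP - hP) / hT
  completeness <- if (hP == 0) 1 else 1 - (hTP - hT) / hP
  v <- if (homogeneity + completeness == 0) 0 else
    2 * homogeneity * completeness / (homogeneity + completeness)
  list(homogeneity = homogeneity, completeness = completeness, vMeasure = v)
}

#' Percentage of recovered founders relative to ground truth
#'
#' @param nTrue True number of founder molecules (>= 1).
#' @param nRecovered Number of clusters recovered by deduplication
#'   (optionally after filtering).
#'
#' @return `100 * nRecovered / nTrue`. Values above 100 indicate
#'   under-clustering (inflated molecule counts), below 100 over-clustering.
#' @examples
#' pctRecovered(1000, 1045)  # 104.5
#' @export
pctRecovered <- function(nTrue, nRecovered) {
  stopifnot(nTrue >= 1)
  100 * nRecovered / nTrue
}

#' Score a clustering against simulation truth
#'
#' Builds per-read label vectors -- the true founder index of each read and
#' the cluster its observed UMI was assigned to -- and computes
#' [vMeasure()] plus the founder-recovery percentage. Reads are the unit of
#' account, so abundant UMIs weigh proportionally; set `perUmi = TRUE` to
#' score distinct UMIs with equal weight instead (each unique UMI labelled
#' by its majority true founder, ties to the smaller founder index).
#'
#' @param truth A [SimulationTruth-class].
#' @param clustering A [UmiClustering-class] built from the truth's
#'   observations.
#' @param filtered When `TRUE` (default), `nRecovered` counts only clusters
#'   kept by the adaptive filter; metrics themselves always use all reads.
#' @param perUmi Score per distinct UMI instead of per read.
#'
#' @return One-row data frame with columns `homogeneity`, `completeness`,
#'   `vMeasure`, `nTrue`, `nRecovered`, `pctRecovered`.
#' @export
evaluateRun <- function(truth, clustering, filtered = TRUE, perUmi = FALSE) {
  stopifnot(is(truth, "SimulationTruth"), is(clustering, "UmiClustering"))
  m <- match(truth@observedUmi, clustering@umi)
  if (anyNA(m))
    stop("observed UMI '", truth@observedUmi[which(is.na(m))[1L]],
         "' is missing from the clustering")
  trueLab <- truth@founderIndex
  predLab <- clustering@founderRow[m]
  if (perUmi) {
    split <- rowsum(rep(1L, length(m)),
                    (m - 1) * (length(truth@founders) + 1L) + trueLab)
    keys <- as.numeric(rownames(split))
    umiRow <- (keys - 1) %/% (length(truth@founders) + 1L) + 1
    fIdx <- keys - (umiRow - 1) * (length(truth@founders) + 1L)
    o <- order(umiRow, -split[, 1L], fIdx)
    first <- !duplicated(umiRow[o])
    trueLab <- fIdx[o][first]
    predLab <- clustering@founderRow[umiRow[o][first]]
  }
  v <- vMeasure(trueLab, predLab)
  nTrue <- length(truth@founders)
  nRecovered <- if (filtered) sum(clustering@kept) else nClusters(clustering)
  data.frame(
    homogeneity = v$homogeneity, completeness = v$completeness,
    vMeasure = v$vMeasure, nTrue = nTrue, nRecovered = nRecovered,
    pctRecovered = pctRecovered(nTrue, nRecovered)
  )
}
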