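#' Barcode rank curve of cluster read support
#'
#' Sorts cluster totals in decreasing order and attaches 1-based ranks, the
#' curve conventionally drawn log-log to locate the knee separating
#' well-supported molecules from the low-support error tail.
#'
#' @param x A [UmiClustering-class] or a numeric vector of positive cluster
#'   totals.
#'
#' @return A data frame with columns `rank` and `total`, one row per
#'   cluster.
#' @export
rankCurve <- function(x) {
  totals <- clusterTotalVector(x)
  if (!length(totals)) stop("no clusters: nothing to rank or filter")
  totals <- sort(totals, decreasing = TRUE, method = "radix")
  data.frame(rank = seq_along(totals), total = as.integer(totals))
}

#' Detect the knee of a barcode rank curve
#'
#' Works in log10(rank) vs log10(total) space. The knee is the point with
#' maximum perpendicular distance to the chord joining the first and last
#' points of the curve (ties go to the smaller rank); the clarity score is
#' that maximum distance divided by the chord length, and is 0 for curves
#' that are collinear in log-log space or shorter than 3 points. Because
#' dispersed per-molecule depths tilt the high-support plateau, the reported
#' cutoff is then refined to the largest consecutive log10 drop in totals at
#' or after the chord knee -- the cliff between the supported plateau and the
#' error tail -- and equals the total read count of the last cluster before
#' that drop. Keeping clusters with `total >= cutoff` keeps exactly the
#' curve up to the detected drop.
#'
#' @param curve A data frame from [rankCurve()] (columns `rank`, `total`).
#'
#' @return A list with elements `cutoff` (non-negative integer; 0 when no
#'   knee), `kneeScore`, `kneeRank` (chord knee position) and `gapRank`
#'   (rank of the last cluster kept).
#' @export
detectKnee <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("rank", "total") %in% names(curve)))
  n <- nrow(curve)
  if (n < 3L)
    return(list(cutoff = 0L, kneeScore = 0, kneeRank = NA_integer_,
                gapRank = NA_integer_))
  x <- log10(curve$rank)
  y <- log10(curve$total)
  dx <- x[n] - x[1L]
  dy <- y[n] - y[1L]
  chord <- sqrt(dx^2 + dy^2)
  if (chord == 0)
    return(list(cutoff = 0L, kneeScore = 0, kneeRank = NA_integer_,
                gapRank = NA_integer_))
  perp <- abs(dy * (x - x[1L]) - dx * (y - y[1L])) / chord
  kneeIdx <- which.max(perp)
  score <- perp[kneeIdx] / chord
  # refine: largest log-drop between consecutive clusters at/after the knee
  drops <- y[-n] - y[-1L]
  cand <- seq(kneeIdx, n - 1L)
  if (!length(cand) || max(drops[cand]) <= 0) {
    gapIdx <- kneeIdx
  } else {
    gapIdx <- cand[which.max(drops[cand])]
  }
  list(cutoff = as.integer(curve$total[gapIdx]), kneeScore = score,
       kneeRank = as.integer(curve$rank[kneeIdx]),
       gapRank = as.integer(curve$rank[gapIdx]))
}

#' Fit a negative binomial to cluster read support
#'
#' Maximum-likelihood fit (method-of-moments start) of reads-per-molecule,
#' used as the fallback support filter when the rank curve shows no clear
#' knee. The cutoff is the largest integer `c` with
#' `P(X < c) <= alpha` under the fitted distribution, so that a true
#' molecule survives the filter with probability at least `1 - alpha`. When
#' the sample shows no overdispersion (variance <= mean, including the
#' degenerate all-equal case) the Poisson limit (`size = Inf`) is used.
#'
#' @param totals Integer vector of cluster totals; at least 10 clusters are
#'   required for a usable fit.
#' @param alpha Lower-tail probability of losing a true molecule (default
#'   0.01).
#'
#' @return A list with elements `mu`, `size` and `cutoff`.
#' @export
fitNegativeBinomial <- function(totals, alpha = 0.01) {
  totals <- as.numeric(totals)
  if (length(totals) < 10L)
    stop("negative binomial fit needs at least 10 clusters")
  if (any(totals < 1)) stop("cluster totals must be positive")
  stopifnot(alpha > 0, alpha < 1)
  m <- mean(totals)
  v <- var(totals)
  if (v <= m) {
    # Poisson limit: dispersion unbounded
    return(list(mu = m, size = Inf, cutoff = as.integer(qpois(alpha, m))))
  }
  fit <- fitdistrplus::fitdist(totals, "nbinom", method = "mle")
  mu <- unname(fit$estimate["mu"])
  size <- unname(fit$estimate["size"])
  list(mu = mu, size = size,
       cutoff = as.integer(qnbinom(alpha, size = size, mu = mu)))
}

#' Choose the low-support cutoff for a clustering
#'
#' Applies the knee detector to the barcode rank curve and accepts its
#' cutoff if the knee is clear enough (`kneeScore >= kneeClarityMin`);
#' otherwise falls back to the negative binomial fit of cluster totals; if
#' that is unavailable too no filtering is performed. Fewer than 10 clusters
#' make both statistics unreliable, so the decision is then always
#' `"none"`. Clusters are kept iff `total_reads >= cutoff` for every
#' method.
#'
#' @param x A [UmiClustering-class] or numeric vector of cluster totals.
#' @param kneeClarityMin Minimum knee clarity score to trust the knee
#'   (default 0.05).
#' @param nbAlpha Lower-tail probability for the negative binomial cutoff
#'   (default 0.01).
#'
#' @return A [ThresholdDecision-class].
#' @export
decideThreshold <- function(x, kneeClarityMin = 0.05, nbAlpha = 0.01) {
  totals <- clusterTotalVector(x)
  if (!length(totals)) stop("no clusters: nothing to filter")
  knee <- if (length(totals) >= 3L) detectKnee(rankCurve(totals)) else
    list(cutoff = 0L, kneeScore = 0)
  # either statistic is degenerate on a handful of clusters; below 10 the
  # decision falls through to "none" and nothing is filtered
  if (length(totals) >= 10L && knee$kneeScore >= kneeClarityMin) {
    return(ThresholdDecision(knee$cutoff, "knee", kneeScore = knee$kneeScore))
  }
  nb <- tryCatch(fitNegativeBinomial(totals, alpha = nbAlpha),
                 error = function(e) NULL)
  if (!is.null(nb)) {
    return(ThresholdDecision(nb$cutoff, "negative_binomial",
                             kneeScore = knee$kneeScore,
                             nbMu = nb$mu, nbSize = nb$size))
  }
  ThresholdDecision(0L, "none", kneeScore = knee$kneeScore)
}

#' Flag low-support clusters of a clustering
#'
#' Marks every founder cluster as kept iff its total read support is at
#' least the decided cutoff, and stores the decision in the object. With
#' `method = "none"` the clustering is unchanged. Filtering never reassigns
#' reads; it only flags clusters, so total read counts are conserved.
#'
#' @param x A [UmiClustering-class].
#' @param decision A [ThresholdDecision-class]; computed with
#'   [decideThreshold()] when omitted.
#' @param ... Passed on to [decideThreshold()].
#'
#' @return The clustering with updated `kept` flags and decision.
#' @export
applyFilter <- function(x, decision = NULL, ...) {
  stopifnot(is(x, "UmiClustering"))
  if (is.null(decision)) decision <- decideThreshold(x, ...)
  stopifnot(is(decision, "ThresholdDecision"))
  x@kept <- unname(clusterTotals(x) >= decision@cutoff)
  x@decision <- decision
  x
}

# internal: cluster totals from either representation
clusterTotalVector <- function(x) {
  if (is(x, "UmiClustering")) unname(clusterTotals(x)) else as.numeric(x)
}
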