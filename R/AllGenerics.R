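#' @rdname UmiSet-class
#' @param x,object A package object.
#' @export
setGeneric("umis", function(x) standardGeneric("umis"))

#' @rdname UmiSet-class
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))

#' @rdname UmiClustering-class
#' @export
setGeneric("founders", function(x) standardGeneric("founders"))

#' @rdname UmiClustering-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname UmiClustering-class
#' @export
setGeneric("clusterTotals", function(x) standardGeneric("clusterTotals"))

#' @rdname UmiClustering-class
#' @export
setGeneric("keptClusters", function(x) standardGeneric("keptClusters"))

#' @rdname UmiClustering-class
#' @export
setGeneric("clusterMap", function(x) standardGeneric("clusterMap"))

#' @rdname UmiClustering-class
#' @export
setGeneric("thresholdDecision", function(x) standardGeneric("thresholdDecision"))

#' @rdname ErrorModel-class
#' @export
setGeneric("errorWeights", function(x) standardGeneric("errorWeights"))

## ---- UmiSet methods ----

#' @rdname UmiSet-class
#' @export
setMethod("umis", "UmiSet", function(x) x@umi)

#' @rdname UmiSet-class
#' @export
setMethod("readCounts", "UmiSet", function(x) {
  structure(x@readCount, names = x@umi)
})

#' @rdname UmiSet-class
#' @export
setMethod("length", "UmiSet", function(x) length(x@umi))

#' @rdname UmiSet-class
#' @export
setMethod("show", "UmiSet", function(object) {
  cat("UmiSet with", length(object@umi), "distinct UMI(s),",
      sum(object@readCount), "read(s)\n")
  if (length(object@umi)) {
    k <- min(5L, length(object@umi))
    cat("  e.g.", paste0(object@umi[seq_len(k)], " (",
        object@readCount[seq_len(k)], ")", collapse = ", "), "\n")
  }
  invisible(NULL)
})

## ---- ErrorModel methods ----

#' @rdname ErrorModel-class
#' @export
setMethod("errorWeights", "ErrorModel", function(x) {
  w <- c(ins = x@insWeight, del = x@delWeight, sub = x@subWeight)
  w / sum(w)
})

#' @rdname ErrorModel-class
#' @export
setMethod("show", "ErrorModel", function(object) {
  w <- errorWeights(object)
  cat(sprintf(
    "ErrorModel: per-base error rate %g, ins:del:sub = %.3g:%.3g:%.3g, confidence %g\n",
    object@perBaseErrorRate, w[1L], w[2L], w[3L], object@confidenceLevel))
  invisible(NULL)
})

## ---- UmiClustering methods ----

#' @rdname UmiClustering-class
#' @export
setMethod("umis", "UmiClustering", function(x) x@umi)

#' @rdname UmiClustering-class
#' @export
setMethod("readCounts", "UmiClustering", function(x) {
  structure(x@readCount, names = x@umi)
})

#' @rdname UmiClustering-class
#' @export
setMethod("founders", "UmiClustering", function(x) {
  x@umi[founderRows(x)]
})

#' @rdname UmiClustering-class
#' @export
setMethod("nClusters", "UmiClustering", function(x) {
  sum(x@founderRow == seq_along(x@founderRow))
})

#' @rdname UmiClustering-class
#' @export
setMethod("clusterTotals", "UmiClustering", function(x) {
  fr <- founderRows(x)
  if (!length(fr)) return(structure(integer(), names = character()))
  tot <- rowsum(x@readCount, match(x@founderRow, fr), reorder = TRUE)
  structure(as.integer(tot[, 1L]), names = x@umi[fr])
})

#' @rdname UmiClustering-class
#' @export
setMethod("keptClusters", "UmiClustering", function(x) {
  structure(x@kept, names = x@umi[founderRows(x)])
})

#' @rdname UmiClustering-class
#' @export
setMethod("thresholdDecision", "UmiClustering", function(x) x@decision)

#' @rdname UmiClustering-class
#' @export
setMethod("clusterMap", "UmiClustering", function(x) {
  fr <- founderRows(x)
  totals <- clusterTotals(x)
  clusterOf <- match(x@founderRow, fr)
  data.frame(
    umi = x@umi,
    founder_umi = x@umi[x@founderRow],
    umi_read_count = x@readCount,
    cluster_total_reads = as.integer(totals[clusterOf]),
    kept_after_filter = x@kept[clusterOf],
    stringsAsFactors = FALSE
  )
})

#' @rdname UmiClustering-class
#' @export
setMethod("show", "UmiClustering", function(object) {
  nf <- nClusters(object)
  cat("UmiClustering:", length(object@umi), "UMI(s),",
      sum(object@readCount), "read(s),", nf, "founder cluster(s)")
  if (!is.null(object@decision)) {
    cat(";", sum(object@kept), "kept by", object@decision@method,
        "filter (cutoff", object@decision@cutoff, "reads)")
  }
  cat("\n")
  invisible(NULL)
})

#' @rdname ThresholdDecision-class
#' @export
setMethod("show", "ThresholdDecision", function(object) {
  cat(sprintf("ThresholdDecision: method=%s, cutoff=%g, kneeScore=%.4f",
              object@method, object@cutoff, object@kneeScore))
  if (!is.na(object@nbMu))
    cat(sprintf(", NB(mu=%.2f, size=%.2f)", object@nbMu, object@nbSize))
  cat("\n")
  invisible(NULL)
})

#' @rdname SimulationTruth-class
#' @param object A SimulationTruth.
#' @export
setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", length(object@founders), "founder(s),",
      length(object@observedUmi), "read(s)\n")
  invisible(NULL)
})

# internal: rows of x@umi that founded a cluster, in processing order
founderRows <- function(x) which(x@founderRow == seq_along(x@founderRow))
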