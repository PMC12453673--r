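# shared fixtures and independent oracles, built in code at test time

randomSeq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

randomSeqs <- function(n, lenRange = c(8L, 14L)) {
  vapply(sample(seq(lenRange[1L], lenRange[2L]), n, replace = TRUE),
         randomSeq, character(1L))
}

# independent Levenshtein oracle (utils::adist, full DP, no banding)
oracleDist <- function(a, b) {
  mapply(function(x, y) drop(adist(x, y)), a, b, USE.NAMES = FALSE)
}

# plain serial greedy founder assignment, driven by the adist oracle;
# mirrors the published sort order and tie rule but shares no code with the
# package kernel
oracleGreedy <- function(umi, count, model = NULL, maxDist = NULL) {
  o <- order(-count, umi, method = "radix")
  umi <- umi[o]
  count <- count[o]
  founder <- integer(0)
  res <- integer(length(umi))
  for (i in seq_along(umi)) {
    best <- 0L
    bestd <- Inf
    for (f in founder) {
      t <- if (is.null(maxDist)) {
        pairThreshold(nchar(umi[i]), nchar(umi[f]), model)
      } else {
        maxDist
      }
      d <- drop(adist(umi[i], umi[f]))
      if (d <= t && d < bestd) {
        best <- f
        bestd <- d
      }
    }
    res[i] <- if (best == 0L) i else best
    if (best == 0L) founder <- c(founder, i)
  }
  list(umi = umi, count = count, founderRow = res)
}

# independent homogeneity/completeness from the explicit contingency table,
# conditional entropies written as double sums
oracleVMeasure <- function(truth, pred) {
  ct <- unclass(table(truth, pred))
  N <- sum(ct)
  rowS <- rowSums(ct)
  colS <- colSums(ct)
  hTrue <- -sum(ifelse(rowS > 0, rowS / N * log(rowS / N), 0))
  hPred <- -sum(ifelse(colS > 0, colS / N * log(colS / N), 0))
  hTgivenP <- 0
  hPgivenT <- 0
  for (i in seq_len(nrow(ct))) {
    for (j in seq_len(ncol(ct))) {
      n <- ct[i, j]
      if (n > 0) {
        hTgivenP <- hTgivenP - n / N * log(n / colS[j])
        hPgivenT <- hPgivenT - n / N * log(n / rowS[i])
      }
    }
  }
  h <- if (hTrue == 0) 1 else 1 - hTgivenP / hTrue
  c <- if (hPred == 0) 1 else 1 - hPgivenT / hPred
  v <- if (h + c == 0) 0 else 2 * h * c / (h + c)
  list(homogeneity = unname(h), completeness = unname(c), vMeasure = unname(v))
}

# exhaustive chord-distance computation over every point of a rank curve,
# in log10-log10 space (point-to-line projection formula)
oracleChordKnee <- function(curve) {
  x <- log10(curve$rank)
  y <- log10(curve$total)
  n <- length(x)
  p1 <- c(x[1L], y[1L])
  p2 <- c(x[n], y[n])
  v <- p2 - p1
  len <- sqrt(sum(v^2))
  d <- vapply(seq_len(n), function(i) {
    w <- c(x[i], y[i]) - p1
    proj <- sum(w * v) / len
    sqrt(max(sum(w^2) - proj^2, 0))
  }, numeric(1L))
  list(idx = which.max(d), maxDist = max(d), score = max(d) / len)
}

# direct binomial tail summation: smallest k with P(X > k) <= 1 - conf
oracleErrorThreshold <- function(n, p, conf) {
  k <- 0L
  repeat {
    tail <- 1 - sum(dbinom(0:k, n, p))
    if (tail <= 1 - conf) return(k)
    k <- k + 1L
  }
}

writeTempLines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

fastqRecord <- function(name, seq = "ACGTACGT") {
  c(paste0("@", name), seq, "+", strrep("I", nchar(seq)))
}
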