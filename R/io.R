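#' Read UMI observations from a tab-separated file
#'
#' Two dialects are supported: per-read files with columns
#' `(read_id, umi)`, one line per read, and pre-aggregated files with
#' columns `(umi, count)`. With `format = "auto"` (default) the dialect is
#' detected by whether every value in column 2 parses as a positive integer.
#' Lines starting with `#` are treated as comments/headers and skipped. An
#' empty file yields an empty [UmiSet-class].
#'
#' @param path Path to the TSV file (plain text or gzip).
#' @param format `"auto"`, `"perRead"` or `"aggregated"`.
#' @param dropN Drop UMIs containing N (default `TRUE`); see [UmiSet()].
#'
#' @return A [UmiSet-class] aggregated by identical UMI sequence; the counts
#'   sum to the number of reads in the file.
#' @export
readUmiTsv <- function(path, format = c("auto", "perRead", "aggregated"),
                       dropN = TRUE) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(UmiSet(character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L]
    stop("parse error at line ", lineNo[bad], ": expected 2 tab-separated ",
         "fields, found ", nf[bad])
  }
  col1 <- vapply(parts, `[[`, character(1L), 1L)
  col2 <- vapply(parts, `[[`, character(1L), 2L)
  if (format == "auto") {
    format <- if (all(grepl("^[0-9]+$", col2)) && !any(col2 == "0"))
      "aggregated" else "perRead"
  }
  if (format == "perRead") {
    UmiSet(col2, dropN = dropN)
  } else {
    counts <- suppressWarnings(as.integer(col2))
    if (any(is.na(counts) | counts < 1L)) {
      bad <- which(is.na(counts) | counts < 1L)[1L]
      stop("parse error at line ", lineNo[bad],
           ": count must be a positive integer, found '", col2[bad], "'")
    }
    UmiSet(col1, counts, dropN = dropN)
  }
}

#' Extract UMI observations from FASTQ read names
#'
#' Reads a FASTQ file (optionally gzip-compressed) and takes as UMI the token
#' after the last occurrence of `delimiter` in each read name (the part of
#' the header line before the first whitespace), the common
#' `readid_UMI` convention.
#'
#' @param path Path to the FASTQ file.
#' @param delimiter Single string separating the UMI from the read id
#'   (default `"_"`), matched literally.
#' @inheritParams readUmiTsv
#'
#' @return A [UmiSet-class] aggregated by UMI sequence.
#' @export
readFastqUmis <- function(path, delimiter = "_", dropN = TRUE) {
  stopifnot(is.character(delimiter), length(delimiter) == 1L,
            nzchar(delimiter))
  reads <- Biostrings::readDNAStringSet(path, format = "fastq")
  nm <- sub("\\s.*$", "", names(reads))
  if (!length(nm)) return(UmiSet(character()))
  tok <- strsplit(nm, delimiter, fixed = TRUE)
  noDelim <- !vapply(nm, function(s) grepl(delimiter, s, fixed = TRUE),
                     logical(1L), USE.NAMES = FALSE)
  if (any(noDelim)) {
    stop("read name '", nm[which(noDelim)[1L]], "' (record ",
         which(noDelim)[1L], ") lacks the UMI delimiter '", delimiter, "'")
  }
  umi <- vapply(tok, function(p) p[[length(p)]], character(1L))
  bad <- !grepl("^[ACGTNacgtn]+$", umi)
  if (any(bad)) {
    stop("read name '", nm[which(bad)[1L]], "' (record ", which(bad)[1L],
         ") carries a non-ACGTN UMI token '", umi[which(bad)[1L]], "'")
  }
  UmiSet(umi, dropN = dropN)
}

#' Write a founder-progeny cluster map
#'
#' Writes one row per UMI with its founder, read count, cluster total and the
#' adaptive-filter flag, as UTF-8 tab-separated text with a `#`-prefixed
#' header. Rows are ordered by descending cluster total, then founder
#' sequence, with the founder first within each cluster followed by progeny
#' in processing order.
#'
#' @param x A [UmiClustering-class].
#' @param path Output file path.
#'
#' @return Invisibly, the written data frame.
#' @seealso [readClusterMap()]
#' @export
writeClusterMap <- function(x, path) {
  stopifnot(is(x, "UmiClustering"))
  df <- clusterMap(x)
  if (nrow(df)) {
    isFounder <- df$umi == df$founder_umi
    o <- order(-df$cluster_total_reads, df$founder_umi, !isFounder,
               method = "radix")
    df <- df[o, , drop = FALSE]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con, sep = "\n")
  if (nrow(df)) {
    df$kept_after_filter <- as.integer(df$kept_after_filter)
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con,
               sep = "\n")
  }
  invisible(df)
}

#' Read a cluster map written by [writeClusterMap()]
#'
#' @param path Path to the cluster-map TSV.
#' @return A data frame with columns `umi`, `founder_umi`, `umi_read_count`,
#'   `cluster_total_reads`, `kept_after_filter`.
#' @export
readClusterMap <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- sub("^#", "", lines[1L])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  lines <- lines[-1L][nzchar(lines[-1L])]
  if (!length(lines)) {
    df <- as.data.frame(matrix(character(), 0L, length(cols)),
                        stringsAsFactors = FALSE)
    names(df) <- cols
    return(df)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- cols
  df$umi_read_count <- as.integer(df$umi_read_count)
  df$cluster_total_reads <- as.integer(df$cluster_total_reads)
  df$kept_after_filter <- as.logical(as.integer(df$kept_after_filter))
  df
}
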