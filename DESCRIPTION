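Package: umidedup
Title: Reference-Free UMI Deduplication via Edit-Distance Founder Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Groups error-bearing unique molecular identifiers (UMIs) to
    founder molecules using a capped Levenshtein distance with a
    binomial error-count threshold derived from UMI length and the
    per-base error rate. Spurious low-support clusters are removed by an
    adaptive filter that detects the knee of the barcode rank plot and
    falls back to a negative binomial fit of reads per molecule. Ships a
    ground-truth simulator for substitution/indel UMI error processes and
    entropy-based clustering metrics (homogeneity, completeness,
    V-measure) so deduplication accuracy can be benchmarked end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    fitdistrplus,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
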