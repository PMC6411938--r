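Package: pitrimseq
Title: Small RNA-Seq Diagnostics for piRNA 3' Trimming Defects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting defective piRNA 3' end trimming
    from small RNA sequencing libraries. Implements hierarchical read
    annotation against ordered reference sequence sets, miRNA-normalized
    length distributions, first-nucleotide (1U) composition, and 5'-5' /
    3'-3' end-distance frequency profiles of a query library against
    top-ranked uniquely mapped wild-type reference piRNAs. Includes an
    ungapped short-read aligner with a configurable mismatch allowance and
    a synthetic library simulator that emits matched wild-type and
    trimming-deficient libraries with a ground-truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    BiocGenerics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
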