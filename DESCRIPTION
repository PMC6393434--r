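Package: fraglenqc
Title: Fragment-Length-Stratified Quality Profiling of Paired-End Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality profiling of Illumina paired-end sequencing data with an
    emphasis on the dependence of second-read (R2) error rates on DNA fragment
    length. Reads coordinate-level alignments from SAM/BAM, applies a
    primary-and-properly-paired filtering contract, extracts per-read
    substitution positions in sequencing-cycle coordinates from CIGAR and MD
    tags, classifies reads as low quality by aligned-base mismatch rate or
    mean Phred score, stratifies read pairs by alignment-derived fragment
    length, and tests the association between a library's long-fragment
    content and its excess of low-quality R2 reads with Spearman rank
    correlation. Ships a seedable multi-sample paired-end alignment simulator
    with a cycle- and fragment-length-dependent substitution error model for
    validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
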