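Package: mprakit
Title: Design, Simulation and Analysis of Barcoded in Vivo MPRA Enhancer Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for systemic massively parallel reporter assay (MPRA)
    screens of candidate enhancers delivered across tissues. Covers in-silico
    library design (motif-shuffle and SNP-allele variants, GC-stratified
    random negative controls, barcode assignment, oligo assembly), a full
    synthetic-experiment generator (cloning dropout, per-tissue transduction,
    overdispersed DNA/RNA barcode counts, amplicon reads with substitution
    errors), anchor-filtered barcode extraction and counting from FASTQ,
    library complexity and transduction metrics, RNA:DNA enhancer-activity
    estimation with robust MAD scoring against negative controls, and
    downstream statistics for motif disruption, allelic effects, tissue
    specificity and cross-tissue correlation structure. All results are tidy
    tibbles that compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
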