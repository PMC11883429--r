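Package: rdnaedit
Title: Amplicon Indel Classification and Bisulfite Window Statistics for
    rDNA Editing Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies CRISPR editing outcomes at a multi-guide ribosomal
    DNA amplicon from paired-end deep-sequencing reads: quality trimming,
    anchored gapped alignment to the amplicon reference, detection of
    localized indels at guide cut-site windows and of large inter-site
    deletions, precedence-based per-read-pair variant categories, and
    per-sample summaries (reference conformity, binomial margin of error,
    Shannon-entropy mutation-spectrum diversity, QC gates). A second arm
    quantifies amplification of a target genomic window from bisulfite
    (PBAT-style) reads via three-letter mapping, CpG methylation calling,
    fixed-width genome tiling and the target-window CpG-call proportion,
    with conversion-efficiency and duplicate QC gates and an
    amplified-versus-baseline call. Synthetic-data generators for both read
    types, with ground-truth tables, support end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    jsonlite,
    Rcpp,
    rlang,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
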