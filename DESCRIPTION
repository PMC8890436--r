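Package: latsplice
Title: Annotation and Activation Analysis of Latent 5' Splice Sites from RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates latent and alternative 5' splice donor sites in coding
    introns and detects their activation from RNA-seq split-read evidence in
    knockdown-versus-control designs. Provides a maximum-entropy donor-site
    sequence model with generalized-iterative-scaling fitting (plus a PWM
    baseline), GT-candidate enumeration and classification by
    premature-termination-codon consequence (LSS, adSS_3n, adSS_fs), split-read
    junction quantification from SAM alignments or junction tables, an
    activation caller with replicate criteria, coverage-profile verification,
    label-switch negative controls and Fisher's-method ranking, contingency and
    gene-set enrichment statistics, and a deterministic synthetic-data
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    stringr,
    ggplot2,
    readr,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
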