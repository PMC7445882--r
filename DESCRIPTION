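Package: nanoverify
Title: Multiplexed Nanopore Amplicon Sequencing for Construct Verification
Version: 0.1.0
Authors@R:
    person("SynBio", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for verifying synthetic DNA constructs by
    highly multiplexed nanopore amplicon sequencing. Provides dual-barcoded
    primer design with plate/well allocation, a seeded long-read simulator
    with strand-biased systematic error sites, error-tolerant dual-barcode
    demultiplexing, a banded semi-global aligner with strand-separated
    pileups, and a Bayesian strand-concordance SNV caller that separates
    genuine mutations from strand-biased systematic sequencing errors.
    Emits per-sample VCF and identity/coverage summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    BiocGenerics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
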