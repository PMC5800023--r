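Package: covote
Title: Consensus Variant Calling by Multi-Caller Genotype Voting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable engine for consensus germline variant calling from the
    VCF output of several independent variant callers run on one sample.
    Per-caller call-sets are harmonized (multiallelic decomposition, allele
    trimming, indel left-alignment) so that every spelling of the same edit
    receives one canonical match key, then voted with a two-stage scheme: a
    site-detection threshold followed by a genotype-concordance threshold
    (default: simple majority, 2 of 3 callers). Variants are emitted as
    consensus, low-confidence, or discordant call-sets annotated with the
    number of supporting methods (NM). Includes genotype-exact benchmarking
    against a truth set with evaluable-region restriction and depth
    stratification, a prioritization filter engine over annotated variant
    tables, and a synthetic truth-set and caller simulator with controlled
    per-caller error structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    optparse,
    GenomicRanges,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
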