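Package: autozyg
Title: Autozygosity Mapping and Private-Variant Triage for Recessive
    Disease-Gene Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping autosomal recessive disease genes in small
    pedigrees: detection of runs of homozygosity and case-shared
    autozygous (identity-by-descent) candidate regions from SNP-array
    genotypes, pairwise identity-by-state, a triple-step private-variant
    filter of whole-genome variant calls against control cohorts and a
    population variant database under recessive and de-novo-dominant
    hypotheses, HGVS-style frameshift consequence prediction with
    protein-truncation and domain-loss statistics, and segregation and
    carrier-frequency reporting. Includes a pedigree genotype and
    variant-cohort simulator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
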