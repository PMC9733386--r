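Package: asqtl
Title: Allele-Specific and Traditional Molecular QTL Mapping with
    Variant-Centred Motif Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for nominating putative causal
    regulatory variants from paired expression and chromatin
    immunoprecipitation sequencing data. Implements two-stage
    allele-specific expression/binding QTL tests on phased parental
    allele counts (a binomial first-stage gate and a phased log-ratio
    regression), G-tests of within-feature allelic heterogeneity,
    traditional peak-height and exon-expression QTL mapping with an
    EMMA-style leave-one-chromosome-out mixed linear model, four-way
    intersection of the result sets (overlap odds ratios, direction
    concordance, enrichment under peaks, chi-squared p-value
    combination), and variant-centred motif discovery (flank
    extraction, Levenshtein clustering, position frequency matrices,
    IUPAC consensus enrichment, multinomial allele-skew tests and PFM
    database matching). A fully parameterised synthetic-data generator
    with known ground truth makes every stage testable without access
    to controlled animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
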