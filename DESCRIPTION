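Package: rareburden
Title: Rare-Variant Enrichment Testing for Extreme-Phenotype Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A case-control pipeline for rare protein-altering variants in
    small extreme-phenotype cohorts sequenced genome-wide. Annotates variants
    against gene models into protein-altering consequence categories, applies
    a rare-variant filtering cascade (platform no-call rate, known-variant
    exclusion, reference-panel and empirical minor allele frequency) with a
    per-variant audit trail, and tests enrichment at the variant level
    (Fisher exact against a reference panel with Bonferroni correction), at
    the gene level (RVT1 collapsing burden test with an analytic
    likelihood-ratio statistic under quasi-separation, and a recessive
    two-or-more-variants scan), with closed-form power calculators for both.
    Also screens genomes for reportable incidental findings in ACMG-listed
    genes via a pathogenic-variant catalogue plus a loss-of-function rule,
    and ships a deterministic synthetic-cohort generator (reference genome,
    gene models, frequency panel, genotypes with no-calls and sequencing
    errors) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    vcfR,
    Biostrings,
    rtracklayer,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
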