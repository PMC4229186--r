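#' Candidate-gene follow-up table (TSHZ3 resequencing)
#'
#' Protein-altering variants found by resequencing the top burden-scan
#' candidate gene in an independent cohort of 99 long-lived individuals
#' (centenarians and nonagenarians), with per-stratum carrier counts and
#' the reference-panel MAF (`NA` = novel, counted as frequency 0). Ships
#' as a plain TSV under `inst/extdata`.
#'
#' @return Tibble: `chrom`, `pos`, `ref`, `alt`, `aa_pos`, `aa_ref`,
#'   `aa_alt`, `supercent_carriers`, `cent_carriers`, `nona_carriers`,
#'   `panel_maf`, `novel`.
#' @export
tshz3_followup <- function() {
  path <- system.file("extdata", "tshz3_followup.tsv",
                      package = "rareburden")
  tab <- read_prefixed_tsv(path)
  maf <- suppressWarnings(as.numeric(tab$panel_maf))
  tab$novel <- is.na(maf)
  tab$panel_maf <- ifelse(is.na(maf), 0, maf)
  tab
}

#' Allele-frequency follow-up test for a resequenced candidate gene
#'
#' Applies the panel-MAF rarity filter to a follow-up variant table, sums
#' the carrier alleles over the retained rows, and compares the resulting
#' allele frequency in the follow-up cohort against a reference cohort
#' with a two-sided Fisher exact test ([allele_burden_test()]).
#'
#' @param variants Tibble with a per-variant carrier-allele count column
#'   `carriers` and a `panel_maf` column (novel variants as 0).
#' @param n_individuals Diploid individuals sequenced in the follow-up
#'   cohort.
#' @param ref_carrier_alleles,ref_total_alleles Carrier and total alleles
#'   in the reference cohort.
#' @param panel_maf_cutoff Retain rows with `panel_maf` strictly below
#'   this (default 0.015).
#' @return One-row tibble: `n_variants_retained`, `carrier_alleles`,
#'   `total_alleles`, `cohort_frequency`, `ref_frequency`, `p_value`.
#' @export
followup_allele_test <- function(variants, n_individuals,
                                 ref_carrier_alleles, ref_total_alleles,
                                 panel_maf_cutoff = 0.015) {
  keep <- variants$panel_maf < panel_maf_cutoff
  carriers <- sum(variants$carriers[keep])
  total <- 2L * n_individuals
  tibble::tibble(
    n_variants_retained = sum(keep),
    carrier_alleles = carriers,
    total_alleles = total,
    cohort_frequency = carriers / total,
    ref_frequency = ref_carrier_alleles / ref_total_alleles,
    p_value = allele_burden_test(carriers, total, ref_carrier_alleles,
                                 ref_total_alleles))
}
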