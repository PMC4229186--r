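#' Read an ACMG-style reportable-gene list
#'
#' TSV with columns `gene` and `lof_actionable` (logical or 0/1): the genes
#' screened for incidental findings, and the subset in which a novel clear
#' loss-of-function variant is itself reportable. The shipped reference
#' fixture (`system.file("extdata", "acmg56_genes.tsv", package =
#' "rareburden")`) lists 56 genes with 45 flagged LoF-actionable.
#'
#' @param path TSV path.
#' @return Tibble `gene`, `lof_actionable`.
#' @export
read_acmg_genes <- function(path) {
  tab <- read_prefixed_tsv(path)
  names(tab) <- tolower(names(tab))
  tibble::tibble(gene = as.character(tab$gene),
                 lof_actionable = as.logical(tab$lof_actionable))
}

#' Read a pathogenic-variant catalogue
#'
#' TSV with columns `chrom`, `pos`, `ref`, `alt`, `classification`
#' (`pathogenic` / `benign` / `uncertain`), `source`, `identifier`. One
#' classification per (variant, source); different sources may disagree.
#'
#' @param path TSV path.
#' @return Tibble with a normalised `variant_id` column added.
#' @export
read_catalogue <- function(path) {
  tab <- read_prefixed_tsv(path)
  names(tab) <- tolower(names(tab))
  stopifnot(all(tab$classification %in%
                  c("pathogenic", "benign", "uncertain")))
  keys <- normalize_variant(tab$chrom, tab$pos, tab$ref, tab$alt)
  dplyr::bind_cols(keys,
                   tab[, c("classification", "source", "identifier")])
}

#' Screen a cohort for reportable incidental findings
#'
#' Reports every (sample, variant) pair where the sample carries at least
#' one alternate allele of a variant in a screened gene and either (a) the
#' variant is classified pathogenic by at least one catalogue source, or
#' (b) its consequence is a clear loss-of-function category (frameshift,
#' stop-gain, stop-loss, splice-site) in a LoF-actionable gene. A benign
#' classification in any source vetoes reporting regardless of other
#' evidence; `uncertain` entries neither trigger nor veto. No rarity filter
#' is applied: common catalogued-pathogenic variants are still reported.
#'
#' @param cohort A `cohort`.
#' @param annotations Output of [annotate_cohort()] covering the cohort's
#'   variants (unfiltered).
#' @param acmg Tibble from [read_acmg_genes()].
#' @param catalogue Tibble from [read_catalogue()].
#' @param labels Sample labels screened (default cases and controls).
#' @return Tibble: `sample`, `variant_id`, `gene`, `basis`
#'   (`catalogue_pathogenic` / `novel_lof`), `category`, `allele_count`,
#'   `evidence` (collapsed `source:classification:identifier` string).
#' @export
screen_incidental <- function(cohort, annotations, acmg, catalogue,
                              labels = c("case", "control")) {
  ann <- annotations[annotations$gene %in% acmg$gene, , drop = FALSE]
  # catalogue entries for variants not annotated to any screened gene
  seen <- catalogue$variant_id %in% cohort$variants$variant_id
  outside <- seen & !(catalogue$variant_id %in% ann$variant_id)
  if (any(outside)) {
    warning(sum(outside), " catalogue entr(ies) for variants outside the ",
            "screened genes ignored")
  }
  empty <- tibble::tibble(sample = character(), variant_id = character(),
                          gene = character(), basis = character(),
                          category = character(), allele_count = integer(),
                          evidence = character())
  if (nrow(ann) == 0) return(empty)

  benign <- unique(catalogue$variant_id[
    catalogue$classification == "benign"])
  pathogenic <- unique(catalogue$variant_id[
    catalogue$classification == "pathogenic"])

  lof_genes <- acmg$gene[acmg$lof_actionable]
  per_variant <- ann |>
    dplyr::group_by(.data$variant_id, .data$gene) |>
    dplyr::summarise(
      lof = any(.data$category %in% LOF_CATEGORIES),
      category = .data$category[order(match(.data$category,
                                            c(PROTEIN_ALTERING,
                                              "non_protein_altering")))][1],
      .groups = "drop")
  per_variant <- per_variant |>
    dplyr::mutate(
      vetoed = .data$variant_id %in% benign,
      cat_path = .data$variant_id %in% pathogenic & !.data$vetoed,
      novel_lof = .data$lof & .data$gene %in% lof_genes &
        !.data$vetoed & !(.data$variant_id %in% pathogenic)) |>
    dplyr::filter(.data$cat_path | .data$novel_lof) |>
    dplyr::mutate(basis = ifelse(.data$cat_path, "catalogue_pathogenic",
                                 "novel_lof"))
  if (nrow(per_variant) == 0) return(empty)

  ev <- catalogue |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(evidence = paste(.data$source, .data$classification,
                                      .data$identifier, sep = ":",
                                      collapse = "; "), .groups = "drop")
  per_variant <- dplyr::left_join(per_variant, ev, by = "variant_id")

  samp <- cohort_samples(cohort, labels)
  rows <- purrr::pmap(per_variant, function(variant_id, gene, basis,
                                            category, evidence, ...) {
    g <- cohort$geno[samp, variant_id, drop = FALSE][, 1]
    names(g) <- samp
    carriers <- samp[!is.na(g) & g >= 1L]
    if (length(carriers) == 0) return(NULL)
    tibble::tibble(sample = carriers, variant_id = variant_id, gene = gene,
                   basis = basis, category = category,
                   allele_count = as.integer(g[carriers]),
                   evidence = evidence %||% NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$sample, .data$variant_id)
}

#' Human-readable text block for incidental findings
#'
#' @param findings Tibble from [screen_incidental()].
#' @return Character vector, one block per finding.
#' @export
format_findings <- function(findings) {
  if (nrow(findings) == 0) return("No reportable incidental findings.")
  vapply(seq_len(nrow(findings)), function(i) {
    f <- findings[i, ]
    paste0("Sample ", f$sample, ": ", f$variant_id, " in ", f$gene,
           " [", f$category, ", ",
           if (f$allele_count == 2) "homozygous" else "heterozygous",
           "]\n  basis: ", f$basis,
           if (!is.na(f$evidence)) paste0("\n  evidence: ", f$evidence)
           else "")
  }, character(1))
}
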