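PROTEIN_ALTERING <- c("missense", "frameshift", "nonframeshift_indel",
                      "stopgain", "stoploss", "splice_site")
LOF_CATEGORIES <- c("frameshift", "stopgain", "stoploss", "splice_site")

#' Classify one variant against one transcript model
#'
#' Assigns exactly one consequence category per (variant, transcript):
#' `splice_site` when the variant alters either of the two intronic bases
#' flanking a coding exon (the canonical GT donor / AG acceptor on the
#' coding strand); coding SNVs are classified by codon translation under the
#' standard genetic code (`missense`, `stopgain`, `stoploss`, or
#' `non_protein_altering` for synonymous changes); coding indels by the net
#' length change modulo three (`frameshift` / `nonframeshift_indel`), taking
#' precedence over `splice_site` when an indel touches both; everything
#' outside the CDS and the splice dinucleotides is `non_protein_altering`.
#' Start-codon SNVs that do not create a stop are treated as missense.
#'
#' @param chrom,pos,ref,alt A normalised variant key.
#' @param model One-row `gene_models` tibble.
#' @param reference A named [Biostrings::DNAStringSet] of chromosomes.
#' @return One-row tibble: `variant_id`, `gene`, `transcript_id`,
#'   `category`, `aa_pos`, `aa_ref`, `aa_alt` (amino-acid fields only for
#'   missense/stopgain/stoploss).
#' @export
classify_variant <- function(chrom, pos, ref, alt, model, reference) {
  stopifnot(nrow(model) == 1)
  pos <- as.integer(pos)
  span_lo <- min(model$exon_start[[1]]) - 2L
  span_hi <- max(model$exon_end[[1]]) + 2L
  v_end <- pos + nchar(ref) - 1L
  if (v_end < span_lo || pos > span_hi) {
    stop("variant ", variant_id(chrom, pos, ref, alt),
         " outside transcript span of ", model$transcript_id)
  }
  obs <- as.character(Biostrings::subseq(reference[[chrom]], pos, v_end))
  if (obs != ref) {
    stop("reference mismatch at ", chrom, ":", pos, " (expected ", ref,
         ", reference has ", obs, ")")
  }

  civ <- coding_intervals(model)
  spl <- splice_windows(model)
  in_iv <- function(p, iv) any(p >= iv$start & p <= iv$end)

  is_snv <- nchar(ref) == 1 && nchar(alt) == 1
  category <- "non_protein_altering"
  aa_pos <- NA_integer_
  aa_ref <- NA_character_
  aa_alt <- NA_character_

  if (is_snv) {
    if (in_iv(pos, civ)) {
      cds_pos <- genomic_to_cds(model, pos)
      cds <- cds_sequence(model, reference)
      codon_idx <- (cds_pos - 1L) %/% 3L + 1L
      codon <- substr(cds, 3L * codon_idx - 2L, 3L * codon_idx)
      within <- (cds_pos - 1L) %% 3L + 1L
      alt_coding <- if (model$strand == "+") alt else complement_base(alt)
      mutated <- codon
      substr(mutated, within, within) <- alt_coding
      a_ref <- translate_codon(codon)
      a_alt <- translate_codon(mutated)
      if (a_ref == a_alt) {
        category <- "non_protein_altering"
      } else if (a_alt == "*") {
        category <- "stopgain"
      } else if (a_ref == "*") {
        category <- "stoploss"
      } else {
        category <- "missense"
      }
      if (category %in% c("missense", "stopgain", "stoploss")) {
        aa_pos <- codon_idx
        aa_ref <- a_ref
        aa_alt <- a_alt
      }
    } else if (in_iv(pos, spl)) {
      category <- "splice_site"
    }
  } else {
    # indel: affected genomic range (anchored VCF representation)
    if (nchar(ref) > 1) {
      aff_lo <- pos + 1L
      aff_hi <- v_end
      hits_cds <- any(aff_lo <= civ$end & aff_hi >= civ$start)
      hits_spl <- nrow(spl) > 0 &&
        any(aff_lo <= spl$end & aff_hi >= spl$start)
    } else {
      # pure insertion between pos and pos+1: interior containment
      hits_cds <- any(pos >= civ$start & pos + 1L <= civ$end)
      hits_spl <- nrow(spl) > 0 && any(pos >= spl$start & pos + 1L <= spl$end)
    }
    if (hits_cds) {
      net <- abs(nchar(ref) - nchar(alt)) %% 3L
      category <- if (net == 0L) "nonframeshift_indel" else "frameshift"
    } else if (hits_spl) {
      category <- "splice_site"
    }
  }
  tibble::tibble(variant_id = variant_id(chrom, pos, ref, alt),
                 gene = model$gene, transcript_id = model$transcript_id,
                 category = category, aa_pos = aa_pos,
                 aa_ref = aa_ref, aa_alt = aa_alt)
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[[b]]
}

translate_codon <- function(codon) {
  if (grepl("[^ACGT]", codon) || nchar(codon) != 3) return("X")
  unname(Biostrings::GENETIC_CODE[codon])
}

# brute-force oracle used in tests: translate the full mutated CDS and
# compare protein sequences (SNVs only)
translate_cds <- function(model, reference, pos = NULL, alt = NULL) {
  cds <- cds_sequence(model, reference)
  if (!is.null(pos)) {
    cds_pos <- genomic_to_cds(model, pos)
    alt_coding <- if (model$strand == "+") alt else complement_base(alt)
    substr(cds, cds_pos, cds_pos) <- alt_coding
  }
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

#' Annotate a cohort's variants against a set of gene models
#'
#' Applies [classify_variant()] to every (variant, transcript) pair whose
#' footprints overlap (transcript span padded by 2 bp to cover splice
#' windows). A variant is protein-altering for a gene if any of that gene's
#' transcripts yields one of the six protein-altering categories.
#'
#' @param cohort A `cohort` object (or a variant tibble with `chrom`, `pos`,
#'   `ref`, `alt`).
#' @param models A `gene_models` tibble.
#' @param reference A named [Biostrings::DNAStringSet].
#' @return Tibble with one row per (variant, transcript) call, plus a
#'   logical `gene_protein_altering` column (the any-transcript OR within
#'   the gene).
#' @export
annotate_cohort <- function(cohort, models, reference) {
  variants <- if (inherits(cohort, "cohort")) cohort$variants else
    tibble::as_tibble(cohort)
  if (!"variant_id" %in% names(variants)) {
    variants$variant_id <- variant_id(variants$chrom, variants$pos,
                                      variants$ref, variants$alt)
  }
  calls <- list()
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    lo <- min(m$exon_start[[1]]) - 2L
    hi <- max(m$exon_end[[1]]) + 2L
    v_end <- variants$pos + nchar(variants$ref) - 1L
    hit <- which(variants$chrom == m$chrom & variants$pos <= hi & v_end >= lo)
    for (j in hit) {
      calls[[length(calls) + 1L]] <- classify_variant(
        variants$chrom[j], variants$pos[j], variants$ref[j],
        variants$alt[j], m, reference)
    }
  }
  if (length(calls) == 0) {
    return(tibble::tibble(variant_id = character(), gene = character(),
                          transcript_id = character(), category = character(),
                          aa_pos = integer(), aa_ref = character(),
                          aa_alt = character(),
                          gene_protein_altering = logical()))
  }
  ann <- dplyr::bind_rows(calls)
  ann |>
    dplyr::group_by(.data$variant_id, .data$gene) |>
    dplyr::mutate(
      gene_protein_altering = any(.data$category %in% PROTEIN_ALTERING)) |>
    dplyr::ungroup()
}

#' Variant keys with a protein-altering call in any gene
#'
#' @param annotations Output of [annotate_cohort()].
#' @return Character vector of variant keys.
#' @export
protein_altering_variants <- function(annotations) {
  unique(annotations$variant_id[annotations$category %in% PROTEIN_ALTERING])
}
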