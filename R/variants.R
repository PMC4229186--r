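#' Normalise a variant allele pair
#'
#' Trims the shared suffix, then the shared prefix, of the ref/alt allele
#' strings (keeping at least one base of each) and shifts the position
#' accordingly, so that membership tests against a known-variant set or a
#' frequency panel are representation-invariant. Alleles are upper-cased.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position (VCF convention).
#' @param ref,alt Reference and alternate allele strings (A/C/G/T only).
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `variant_id`.
#' @examples
#' normalize_variant("chr1", 100, "CAT", "CGT")  # -> pos 101, A>G
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  stopifnot(length(chrom) == length(pos), length(pos) == length(ref),
            length(ref) == length(alt))
  bad <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
  if (any(bad)) {
    stop("non-ACGT allele in variant(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  pos <- as.integer(pos)
  for (i in seq_along(ref)) {
    r <- strsplit(ref[i], "")[[1]]
    a <- strsplit(alt[i], "")[[1]]
    # shared suffix
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # shared prefix
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]
      a <- a[-1]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  tibble::tibble(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
                 variant_id = variant_id(chrom, pos, ref, alt))
}

#' Canonical variant identifier
#'
#' @inheritParams normalize_variant
#' @return Character vector `"chrom:pos:ref:alt"`.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, toupper(ref), toupper(alt), sep = ":")
}

#' Build a cohort genotype container
#'
#' The central in-memory representation: a variant table, a sample table with
#' case/control/platform-control labels, and a samples-by-variants matrix of
#' alternate-allele counts where `NA` encodes a no-call. An optional logical
#' matrix of the same shape flags low-quality genotype calls.
#'
#' @param variants Tibble with columns `chrom`, `pos`, `ref`, `alt` (a
#'   `variant_id` column is added if absent). One row per biallelic variant.
#' @param samples Tibble with columns `sample` and `label`; labels must be
#'   one of `"case"`, `"control"`, `"platform_control"`.
#' @param geno Integer matrix (samples x variants) of alt-allele counts in
#'   \{0,1,2\}, `NA` = no-call.
#' @param lowq Optional logical matrix, `TRUE` where the genotype call is
#'   low-quality. Defaults to all-`FALSE` (the high tier).
#' @return An object of class `cohort`.
#' @export
new_cohort <- function(variants, samples, geno, lowq = NULL) {
  variants <- tibble::as_tibble(variants)
  samples <- tibble::as_tibble(samples)
  if (!"variant_id" %in% names(variants)) {
    variants$variant_id <- variant_id(variants$chrom, variants$pos,
                                      variants$ref, variants$alt)
  }
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicate variant keys in cohort")
  }
  if (anyDuplicated(samples$sample)) stop("duplicate sample identifiers")
  if (!all(samples$label %in% c("case", "control", "platform_control"))) {
    stop("labels must be case, control or platform_control")
  }
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(samples) || ncol(geno) != nrow(variants)) {
    stop("genotype matrix dimensions do not match sample/variant tables")
  }
  if (any(geno[!is.na(geno)] < 0L | geno[!is.na(geno)] > 2L)) {
    stop("allele counts must be 0, 1 or 2")
  }
  if (is.null(lowq)) {
    lowq <- matrix(FALSE, nrow(geno), ncol(geno))
  }
  dimnames(geno) <- list(samples$sample, variants$variant_id)
  dimnames(lowq) <- dimnames(geno)
  structure(list(variants = variants, samples = samples,
                 geno = geno, lowq = lowq),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$samples$label)
  cat("<cohort> ", nrow(x$variants), " variants x ", nrow(x$samples),
      " samples (", paste(names(tab), tab, sep = ": ", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort <- function(x) c(nrow(x$samples), nrow(x$variants))

#' Samples carrying a given label
#' @param cohort A [new_cohort()] object.
#' @param labels Character vector of labels to keep.
#' @return Character vector of sample names.
#' @export
cohort_samples <- function(cohort, labels = c("case", "control")) {
  cohort$samples$sample[cohort$samples$label %in% labels]
}

#' Long-format view of cohort genotypes
#'
#' @param x A `cohort` object.
#' @param ... Unused.
#' @return A tibble with one row per sample x variant: `sample`, `label`,
#'   `variant_id`, `allele_count` (`NA` = no-call), `called`, `quality_tier`.
#' @export
tidy.cohort <- function(x, ...) {
  g <- x$geno
  long <- tibble::tibble(
    sample = rep(rownames(g), times = ncol(g)),
    variant_id = rep(colnames(g), each = nrow(g)),
    allele_count = as.integer(g),
    quality_tier = ifelse(as.logical(x$lowq), "low", "high")
  )
  long$called <- !is.na(long$allele_count)
  dplyr::left_join(long, x$samples, by = "sample")[
    , c("sample", "label", "variant_id", "allele_count", "called",
        "quality_tier")]
}

#' Restrict a cohort to a subset of variants and/or samples
#'
#' @param cohort A `cohort` object.
#' @param variant_ids Variant keys to keep (default all).
#' @param samples Sample names to keep (default all).
#' @return A `cohort`.
#' @export
cohort_subset <- function(cohort, variant_ids = NULL, samples = NULL) {
  vi <- if (is.null(variant_ids)) seq_len(nrow(cohort$variants)) else {
    match(variant_ids, cohort$variants$variant_id)
  }
  if (anyNA(vi)) stop("unknown variant key(s) in subset")
  si <- if (is.null(samples)) seq_len(nrow(cohort$samples)) else {
    match(samples, cohort$samples$sample)
  }
  if (anyNA(si)) stop("unknown sample(s) in subset")
  new_cohort(cohort$variants[vi, , drop = FALSE],
             cohort$samples[si, , drop = FALSE],
             cohort$geno[si, vi, drop = FALSE],
             cohort$lowq[si, vi, drop = FALSE])
}

#' Per-variant summary statistics over a set of samples
#'
#' Computes, for each variant, the carrier count, alt-allele count, called
#' allele total, no-call fraction and empirical minor allele frequency over
#' the samples selected by `labels`.
#'
#' @param cohort A `cohort` object.
#' @param labels Labels of the samples entering the summary.
#' @return A tibble keyed by `variant_id` with columns `carriers`,
#'   `alt_alleles`, `called_alleles`, `n_samples`, `nocall_fraction`,
#'   `empirical_maf`.
#' @export
variant_stats <- function(cohort, labels = c("case", "control")) {
  keep <- cohort$samples$label %in% labels
  g <- cohort$geno[keep, , drop = FALSE]
  called <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  af <- ifelse(called > 0, alt / (2 * called), 0)
  tibble::tibble(
    variant_id = cohort$variants$variant_id,
    carriers = unname(colSums(g >= 1L, na.rm = TRUE)),
    alt_alleles = unname(alt),
    called_alleles = unname(2L * called),
    n_samples = sum(keep),
    nocall_fraction = unname(1 - called / sum(keep)),
    alt_frequency = unname(af),
    empirical_maf = unname(pmin(af, 1 - af))
  )
}

#' Mask low-quality genotype calls as no-calls
#'
#' Used by the filtering cascade when low-quality calls are excluded from the
#' analysis (the default); re-running with `use_low_quality = TRUE` in
#' [filter_config()] skips this step, which is how reduced-stringency
#' sensitivity analyses are expressed.
#'
#' @param cohort A `cohort` object.
#' @return A `cohort` in which every low-tier genotype is a no-call.
#' @export
mask_low_quality <- function(cohort) {
  g <- cohort$geno
  g[cohort$lowq] <- NA_integer_
  new_cohort(cohort$variants, cohort$samples, g,
             matrix(FALSE, nrow(g), ncol(g)))
}
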