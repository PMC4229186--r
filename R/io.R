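#' Read a multi-sample VCF into a cohort
#'
#' Parses GT fields for all samples, decomposes multi-allelic records into
#' biallelic variant keys (recomputing per-allele counts), normalises
#' indel representation, and encodes missing genotypes. `"./."` and
#' half-calls such as `"0/."` become no-calls for that sample. Records with
#' symbolic or non-ACGT alleles are skipped with a warning.
#'
#' @param path Path to a VCF 4.x file (plain text or bgzipped).
#' @param label_map Named character vector mapping sample name to one of
#'   `"case"`, `"control"`, `"platform_control"`. Every name must be present
#'   in the VCF header; VCF samples not in the map are dropped.
#' @param quality_key Optional FORMAT key (e.g. `"GQ"`) used to assign the
#'   low quality tier.
#' @param quality_threshold Calls with `quality_key` strictly below this
#'   value are flagged low-quality.
#' @return A [new_cohort()] object.
#' @export
read_cohort_vcf <- function(path, label_map, quality_key = NULL,
                            quality_threshold = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as_row_matrix(vcfR::getFIX(v), nrow(v@fix))
  if (nrow(v@gt) == 0) stop("VCF has no genotype records")
  vcf_samples <- colnames(v@gt)[-1]
  missing <- setdiff(names(label_map), vcf_samples)
  if (length(missing) > 0) {
    stop("samples in label_map absent from VCF header: ",
         paste(missing, collapse = ", "))
  }
  keep_samples <- names(label_map)
  gt <- as_row_matrix(vcfR::extract.gt(v, element = "GT"), nrow(v@fix))
  gt <- gt[, keep_samples, drop = FALSE]
  qm <- NULL
  if (!is.null(quality_key)) {
    qm <- suppressWarnings(
      vcfR::extract.gt(v, element = quality_key, as.numeric = TRUE))
    qm <- as_row_matrix(qm, nrow(v@fix))[, keep_samples, drop = FALSE]
  }

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix[i, "REF"])
    alts <- strsplit(toupper(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
    if (!grepl("^[ACGT]+$", ref) || !all(grepl("^[ACGT*]+$", alts))) {
      warning("skipping record with symbolic/invalid alleles at ",
              fix[i, "CHROM"], ":", fix[i, "POS"], call. = FALSE)
      next
    }
    gtr <- gt[i, ]
    alleles <- parse_gt(gtr)
    for (k in seq_along(alts)) {
      if (alts[k] == "*" || !grepl("^[ACGT]+$", alts[k])) next
      ac <- vapply(alleles, function(a) {
        if (anyNA(a)) NA_integer_ else sum(a == k)
      }, integer(1))
      lq <- if (is.null(qm)) rep(FALSE, length(ac)) else {
        q <- qm[i, ]
        !is.na(q) & q < quality_threshold
      }
      key <- normalize_variant(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                               ref, alts[k])
      rows[[length(rows) + 1L]] <- list(key = key, ac = ac, lq = lq)
    }
  }
  if (length(rows) == 0) stop("no usable variant records in ", path)
  variants <- dplyr::bind_rows(lapply(rows, `[[`, "key"))
  geno <- do.call(cbind, lapply(rows, `[[`, "ac"))
  lowq <- do.call(cbind, lapply(rows, `[[`, "lq"))
  # collapse duplicates arising from normalisation (keep first occurrence)
  dup <- duplicated(variants$variant_id)
  if (any(dup)) {
    warning(sum(dup), " duplicate variant key(s) after normalisation dropped")
    variants <- variants[!dup, , drop = FALSE]
    geno <- geno[, !dup, drop = FALSE]
    lowq <- lowq[, !dup, drop = FALSE]
  }
  samples <- tibble::tibble(sample = keep_samples,
                            label = unname(label_map[keep_samples]))
  new_cohort(variants, samples, geno, lowq)
}

# Parse GT strings into lists of allele indices; NA element = no-call.
# Half-calls (any missing allele) are treated as a full no-call.
parse_gt <- function(gt_strings) {
  lapply(gt_strings, function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
    parts <- strsplit(gsub("|", "/", s, fixed = TRUE), "/", fixed = TRUE)[[1]]
    if (any(parts == ".") || length(parts) == 0) return(NA_integer_)
    a <- suppressWarnings(as.integer(parts))
    if (anyNA(a)) stop("malformed GT field: ", s)
    a
  })
}

#' Write a cohort as a multi-sample VCF
#'
#' One biallelic record per variant; no-calls are written as `./.`.
#' Low-quality calls carry `GQ=5`, high-quality `GQ=99` (so the file
#' round-trips through [read_cohort_vcf()] with `quality_key = "GQ"`).
#'
#' @param cohort A `cohort` object.
#' @param path Output path.
#' @export
write_cohort_vcf <- function(cohort, path) {
  v <- cohort$variants[order(cohort$variants$chrom, cohort$variants$pos), ]
  idx <- match(v$variant_id, cohort$variants$variant_id)
  gt_codes <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples$sample), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(j) {
    g <- cohort$geno[, idx[j]]
    lq <- cohort$lowq[, idx[j]]
    cell <- ifelse(is.na(g), "./.:.",
                   paste0(gt_codes[g + 1L], ":", ifelse(lq, 5L, 99L)))
    paste(c(v$chrom[j], v$pos[j], ".", v$ref[j], v$alt[j], ".", "PASS", ".",
            "GT:GQ", cell), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a reference-panel allele-frequency table
#'
#' Accepts a sites-only VCF with `AC`/`AN` INFO fields, or a 5-column TSV
#' (`chrom`, `pos`, `ref`, `alt`, `maf`) whose frequencies are converted to
#' counts over `2 * n_individuals` alleles.
#'
#' @param path Path to the panel file.
#' @param n_individuals Number of diploid individuals in the panel.
#' @return A `frequency_panel`: list with `entries` (tibble `variant_id`,
#'   `ac`, `an`) and `n_individuals`.
#' @export
read_frequency_panel <- function(path, n_individuals) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  if (is_vcf_file(path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as_row_matrix(vcfR::getFIX(v), nrow(v@fix))
    ac <- as.integer(vcfR::extract.info(v, "AC"))
    an <- as.integer(vcfR::extract.info(v, "AN"))
    keys <- normalize_variant(fix[, "CHROM"], as.integer(fix[, "POS"]),
                              fix[, "REF"], fix[, "ALT"])
    entries <- tibble::tibble(variant_id = keys$variant_id, ac = ac, an = an)
  } else {
    tab <- read_prefixed_tsv(path)
    names(tab) <- tolower(names(tab))
    keys <- normalize_variant(tab$chrom, tab$pos, tab$ref, tab$alt)
    an <- 2L * n_individuals
    entries <- tibble::tibble(variant_id = keys$variant_id,
                              ac = as.integer(round(tab$maf * an)), an = an)
  }
  if (any(is.na(entries$ac)) || any(entries$ac < 0)) {
    stop("negative or missing AC in panel")
  }
  if (any(entries$ac > entries$an)) stop("AC exceeds AN in panel")
  if (any(entries$an > 2L * n_individuals)) {
    stop("AN exceeds 2 * n_individuals in panel")
  }
  entries <- entries[!duplicated(entries$variant_id), ]
  structure(list(entries = entries, n_individuals = n_individuals),
            class = "frequency_panel")
}

#' @export
print.frequency_panel <- function(x, ...) {
  cat("<frequency_panel> ", nrow(x$entries), " sites over ",
      x$n_individuals, " individuals\n", sep = "")
  invisible(x)
}

#' Look up panel frequencies for a set of variant keys
#'
#' A variant absent from the panel is "novel": frequency 0 over the panel's
#' full allele count.
#'
#' @param panel A `frequency_panel`.
#' @param variant_ids Character vector of variant keys.
#' @return Tibble `variant_id`, `ac`, `an`, `maf`.
#' @export
panel_lookup <- function(panel, variant_ids) {
  i <- match(variant_ids, panel$entries$variant_id)
  ac <- ifelse(is.na(i), 0L, panel$entries$ac[i])
  an <- ifelse(is.na(i), 2L * panel$n_individuals, panel$entries$an[i])
  tibble::tibble(variant_id = variant_ids, ac = as.integer(ac),
                 an = as.integer(an), maf = ifelse(an > 0, ac / an, 0))
}

#' Write a frequency panel as a sites-only VCF
#' @param panel A `frequency_panel`.
#' @param path Output path.
#' @export
write_frequency_panel <- function(panel, path) {
  k <- id_to_key(panel$entries$variant_id)
  ord <- order(k$chrom, k$pos)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alt allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Called alleles\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    paste(k$chrom[ord], k$pos[ord], ".", k$ref[ord], k$alt[ord], ".", "PASS",
          paste0("AC=", panel$entries$ac[ord], ";AN=", panel$entries$an[ord]),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

# split "chrom:pos:ref:alt" keys back into columns
id_to_key <- function(variant_ids) {
  parts <- stringr::str_split_fixed(variant_ids, ":", 4)
  tibble::tibble(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                 ref = parts[, 3], alt = parts[, 4],
                 variant_id = variant_ids)
}

#' Read a known-variant set
#'
#' Membership is by chromosome, position and alleles (never by identifier),
#' after the same normalisation applied to cohort variants. Duplicate keys
#' collapse to one member.
#'
#' @param path Sites-only VCF, or TSV with columns `chrom`, `pos`, `ref`,
#'   `alt`.
#' @return Character vector of normalised variant keys (the membership set).
#' @export
read_known_variants <- function(path) {
  if (!file.exists(path)) stop("known-variant file not found: ", path)
  if (is_vcf_file(path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as_row_matrix(vcfR::getFIX(v), nrow(v@fix))
    keys <- normalize_variant(fix[, "CHROM"], as.integer(fix[, "POS"]),
                              fix[, "REF"], fix[, "ALT"])
  } else {
    tab <- read_prefixed_tsv(path)
    names(tab) <- tolower(names(tab))
    keys <- normalize_variant(tab$chrom, tab$pos, tab$ref, tab$alt)
  }
  unique(keys$variant_id)
}

#' Write a known-variant set as a TSV
#' @param variant_ids Character vector of variant keys.
#' @param path Output path.
#' @export
write_known_variants <- function(variant_ids, path) {
  write_prefixed_tsv(id_to_key(unique(variant_ids))[
    , c("chrom", "pos", "ref", "alt")], path)
}

# vcfR drops matrix dimensions for single-record files
as_row_matrix <- function(x, n_records) {
  if (is.null(dim(x)) && n_records == 1L) {
    t(as.matrix(x))
  } else {
    x
  }
}

is_vcf_file <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) return(TRUE)
  con <- file(path, "r")
  on.exit(close(con))
  grepl("^##fileformat=VCF", readLines(con, n = 1))
}

#' Write/read a '#'-header TSV
#'
#' All tabular artifacts of the pipeline use tab separation with a
#' `#`-prefixed header line.
#'
#' @param x A data frame.
#' @param path File path.
#' @return `read_prefixed_tsv` returns a tibble.
#' @export
write_prefixed_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(x), collapse = "\t")), con)
  if (nrow(x) > 0) {
    utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' @rdname write_prefixed_tsv
#' @export
read_prefixed_tsv <- function(path) {
  header <- readLines(path, n = 1)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  tab <- suppressWarnings(readr::read_tsv(
    path, skip = 1, col_names = cols, show_col_types = FALSE,
    progress = FALSE, na = "NA"))
  tibble::as_tibble(tab)
}

#' Write the annotated/filtered variant report table
#'
#' One row per variant x consequence call, with the variant key, gene,
#' category, per-sample genotypes, panel MAF and the filter-trace outcome.
#'
#' @param cohort A `cohort` object.
#' @param annotations Consequence tibble from [annotate_cohort()].
#' @param panel A `frequency_panel` (optional).
#' @param traces Filter-trace tibble from [run_cascade()] (optional).
#' @param path Output path.
#' @return The written tibble, invisibly.
#' @export
write_variant_table <- function(cohort, annotations, path, panel = NULL,
                                traces = NULL) {
  ann <- annotations
  if (nrow(ann) == 0) {
    out <- tibble::tibble(variant_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), gene = character(),
                          category = character())
    write_prefixed_tsv(out, path)
    return(invisible(out))
  }
  out <- dplyr::left_join(ann, cohort$variants, by = "variant_id")
  if (!is.null(panel)) {
    out$panel_maf <- panel_lookup(panel, out$variant_id)$maf
  }
  if (!is.null(traces)) {
    out <- dplyr::left_join(
      out, traces[, c("variant_id", "removed_by")], by = "variant_id")
  }
  gt <- cohort$geno[cohort$samples$label != "platform_control", , drop = FALSE]
  gmat <- t(gt)[out$variant_id, , drop = FALSE]
  colnames(gmat) <- paste0("gt_", rownames(gt))
  out <- dplyr::bind_cols(out, tibble::as_tibble(gmat))
  write_prefixed_tsv(out, path)
  invisible(out)
}
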