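#' Construct a transcript gene-model table
#'
#' Gene models are stored as a tibble with one row per transcript and exon
#' coordinates in list columns. Coordinates are 1-based inclusive (genomic);
#' `cds_start`/`cds_end` bound the coding region in genomic coordinates
#' regardless of strand.
#'
#' @param gene Gene symbol(s).
#' @param transcript_id Transcript identifier(s).
#' @param chrom Chromosome name(s).
#' @param strand `"+"` or `"-"`.
#' @param exon_start,exon_end Lists of integer vectors (one vector per
#'   transcript), sorted, non-overlapping.
#' @param cds_start,cds_end Genomic CDS bounds.
#' @return A tibble of class `gene_models`.
#' @export
gene_models <- function(gene, transcript_id, chrom, strand,
                        exon_start, exon_end, cds_start, cds_end) {
  m <- tibble::tibble(gene = gene, transcript_id = transcript_id,
                      chrom = chrom, strand = strand,
                      exon_start = exon_start, exon_end = exon_end,
                      cds_start = as.integer(cds_start),
                      cds_end = as.integer(cds_end))
  class(m) <- c("gene_models", class(m))
  validate_gene_models(m)
  m
}

#' Validate gene-model invariants
#'
#' Checks that exons are sorted and non-overlapping, that the CDS lies
#' inside the exon span, and that the coding length is divisible by three.
#'
#' @param models A `gene_models` tibble.
#' @return The input, invisibly; errors on violation.
#' @export
validate_gene_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    s <- models$exon_start[[i]]
    e <- models$exon_end[[i]]
    if (length(s) != length(e) || any(e < s)) {
      stop("malformed exons in ", models$transcript_id[i])
    }
    if (length(s) > 1 && any(s[-1] <= e[-length(e)])) {
      stop("exons overlap or are unsorted in ", models$transcript_id[i])
    }
    if (models$cds_start[i] < min(s) || models$cds_end[i] > max(e)) {
      stop("CDS outside exon span in ", models$transcript_id[i])
    }
    civ <- coding_intervals(models[i, ])
    if (sum(civ$end - civ$start + 1L) %% 3L != 0L) {
      stop("CDS length not divisible by 3 in ", models$transcript_id[i])
    }
  }
  invisible(models)
}

# genomic intervals of the coding part of each exon (sorted by position)
coding_intervals <- function(model) {
  s <- pmax(model$exon_start[[1]], model$cds_start)
  e <- pmin(model$exon_end[[1]], model$cds_end)
  keep <- s <= e
  tibble::tibble(start = s[keep], end = e[keep])
}

# 2-bp intronic splice windows flanking coding exons:
# donor = first two intron bases, acceptor = last two (genomic order).
# A window is kept if the adjacent exon overlaps the CDS.
splice_windows <- function(model) {
  s <- model$exon_start[[1]]
  e <- model$exon_end[[1]]
  if (length(s) < 2) {
    return(tibble::tibble(start = integer(), end = integer(),
                          side = character()))
  }
  coding <- s <= model$cds_end & e >= model$cds_start
  out <- list()
  for (k in seq_len(length(s) - 1)) {
    # window after exon k (genomic): kept if exon k is coding
    if (coding[k]) {
      out[[length(out) + 1L]] <- tibble::tibble(
        start = e[k] + 1L, end = e[k] + 2L,
        side = if (model$strand == "+") "donor" else "acceptor")
    }
    # window before exon k+1
    if (coding[k + 1]) {
      out[[length(out) + 1L]] <- tibble::tibble(
        start = s[k + 1] - 2L, end = s[k + 1] - 1L,
        side = if (model$strand == "+") "acceptor" else "donor")
    }
  }
  dplyr::distinct(dplyr::bind_rows(out))
}

# map a genomic position inside the CDS to the 1-based coding-strand CDS
# coordinate; NA if outside the coding intervals
genomic_to_cds <- function(model, pos) {
  civ <- coding_intervals(model)
  lens <- civ$end - civ$start + 1L
  hit <- which(pos >= civ$start & pos <= civ$end)
  if (length(hit) == 0) return(NA_integer_)
  plus_offset <- sum(lens[seq_len(hit - 1)]) + (pos - civ$start[hit]) + 1L
  if (model$strand == "+") plus_offset else sum(lens) - plus_offset + 1L
}

# inverse mapping: coding-strand CDS coordinate -> genomic position
cds_to_genomic <- function(model, cds_pos) {
  civ <- coding_intervals(model)
  lens <- civ$end - civ$start + 1L
  total <- sum(lens)
  plus_offset <- if (model$strand == "+") cds_pos else total - cds_pos + 1L
  cum <- cumsum(lens)
  hit <- which(plus_offset <= cum)[1]
  prev <- if (hit > 1) cum[hit - 1] else 0L
  civ$start[hit] + (plus_offset - prev) - 1L
}

# coding-strand CDS sequence as a character string
cds_sequence <- function(model, reference) {
  civ <- coding_intervals(model)
  chrseq <- reference[[model$chrom]]
  pieces <- vapply(seq_len(nrow(civ)), function(i) {
    as.character(Biostrings::subseq(chrseq, civ$start[i], civ$end[i]))
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

#' Write gene models to GFF3
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` features with `ID`/`Parent`
#' attributes, readable back with [read_gene_models()].
#'
#' @param models A `gene_models` tibble.
#' @param path Output path.
#' @export
write_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    s <- m$exon_start[[1]]
    e <- m$exon_end[[1]]
    gid <- paste0("gene:", m$gene)
    tid <- paste0("tx:", m$transcript_id)
    feat <- function(type, start, end, attrs) {
      paste(m$chrom, "rareburden", type, start, end, ".", m$strand, ".",
            attrs, sep = "\t")
    }
    lines <- c(
      lines,
      feat("gene", min(s), max(e),
           paste0("ID=", gid, ";Name=", m$gene)),
      feat("mRNA", min(s), max(e),
           paste0("ID=", tid, ";Parent=", gid, ";Name=", m$transcript_id))
    )
    for (k in seq_along(s)) {
      lines <- c(lines, feat("exon", s[k], e[k], paste0("Parent=", tid)))
    }
    civ <- coding_intervals(m)
    for (k in seq_len(nrow(civ))) {
      lines <- c(lines, feat("CDS", civ$start[k], civ$end[k],
                             paste0("Parent=", tid)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reconstructs one transcript model per `mRNA` feature from its `exon` and
#' `CDS` children.
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_models` tibble.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))
  mrna <- df[df$type %in% c("mRNA", "transcript"), ]
  genes <- df[df$type == "gene", ]
  gene_name <- function(gid) {
    row <- genes[genes$ID == gid, ]
    if (nrow(row) == 0) return(sub("^gene:", "", gid))
    if (!is.null(row$Name) && !is.na(row$Name[1])) row$Name[1] else
      sub("^gene:", "", row$ID[1])
  }
  out <- lapply(seq_len(nrow(mrna)), function(i) {
    tid <- mrna$ID[i]
    ex <- df[df$type == "exon" & df$Parent == tid, ]
    cds <- df[df$type == "CDS" & df$Parent == tid, ]
    ex <- ex[order(ex$start), ]
    name <- if (!is.null(mrna$Name) && !is.na(mrna$Name[i])) mrna$Name[i] else
      sub("^tx:", "", tid)
    tibble::tibble(
      gene = gene_name(mrna$Parent[i]),
      transcript_id = name,
      chrom = as.character(mrna$seqnames[i]),
      strand = as.character(mrna$strand[i]),
      exon_start = list(as.integer(ex$start)),
      exon_end = list(as.integer(ex$end)),
      cds_start = as.integer(min(cds$start)),
      cds_end = as.integer(max(cds$end)))
  })
  m <- dplyr::bind_rows(out)
  class(m) <- c("gene_models", class(m))
  validate_gene_models(m)
  m
}
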