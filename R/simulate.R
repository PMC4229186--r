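#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a small
#' extreme-phenotype case series against genotype-level controls plus a
#' larger reference frequency panel, a rare-shifted site-frequency
#' spectrum, genes spiked with case-only carriers, platform-specific
#' no-call patterns at bad sites, and a sequencing-error process in which a
#' fraction of apparent rare coding calls are false singletons.
#'
#' @param seed Master seed; every operation derives a named substream from
#'   it, so outputs are reproducible and stable under config extension.
#' @param n_cases,n_controls,n_platform_controls Cohort sizes (defaults 13,
#'   34, 54).
#' @param panel_individuals Diploid individuals in the frequency panel
#'   (default 379).
#' @param n_genes Number of genes in the synthetic genome.
#' @param sites_per_gene Poisson mean of polymorphic coding sites per gene.
#' @param sfs_shape1,sfs_shape2 Beta parameters of the rare-variant
#'   site-frequency spectrum (defaults 0.3, 40: median well below 1%).
#' @param spike List of spikes, each `list(gene =, n_case_carriers =,
#'   n_control_carriers =)`. Spiked genes carry only their spike sites.
#' @param nocall_site_fraction Fraction of sites with elevated no-call
#'   ("bad" sites).
#' @param nocall_rate_at_bad_sites Per-platform-control no-call probability
#'   at bad sites (default 0.55, so bad sites usually exceed a 50% no-call
#'   filter).
#' @param false_rare_call_rate Expected fraction of candidate rare coding
#'   calls that are injected sequencing errors (default 0.30).
#' @param common_known_fraction Fraction of panel sites drawn common
#'   (MAF >= 1.5%) and entered into the known-variant set.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_cases = 13L, n_controls = 34L,
                       n_platform_controls = 54L, panel_individuals = 379L,
                       n_genes = 200L, sites_per_gene = 3,
                       sfs_shape1 = 0.3, sfs_shape2 = 40,
                       spike = list(), nocall_site_fraction = 0.10,
                       nocall_rate_at_bad_sites = 0.55,
                       false_rare_call_rate = 0.30,
                       common_known_fraction = 0.25) {
  cfg <- list(seed = as.integer(seed), n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_platform_controls = as.integer(n_platform_controls),
              panel_individuals = as.integer(panel_individuals),
              n_genes = as.integer(n_genes),
              sites_per_gene = sites_per_gene,
              sfs_shape1 = sfs_shape1, sfs_shape2 = sfs_shape2,
              spike = spike,
              nocall_site_fraction = nocall_site_fraction,
              nocall_rate_at_bad_sites = nocall_rate_at_bad_sites,
              false_rare_call_rate = false_rare_call_rate,
              common_known_fraction = common_known_fraction)
  fr <- c(cfg$nocall_site_fraction, cfg$nocall_rate_at_bad_sites,
          cfg$false_rare_call_rate, cfg$common_known_fraction)
  stopifnot(all(fr >= 0 & fr <= 1), cfg$n_cases > 0, cfg$n_controls > 0,
            cfg$n_genes > 0)
  structure(cfg, class = "sim_config")
}

# deterministic named substream: same (seed, name) -> same stream, and
# streams for different operations are decoupled
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  as.integer((as.numeric(seed) * 10007 + sum(codes * seq_along(codes)) * 131)
             %% 2147483629)
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# gene template (coding-strand, block-relative 1-based coordinates)
GENE_TPL <- list(
  utr5 = 9L, cds1 = 60L, intron1 = 40L, cds2 = 57L, intron2 = 40L,
  cds3 = 48L, utr3 = 9L)

gene_block_coords <- function() {
  t <- GENE_TPL
  e1 <- c(1L, t$utr5 + t$cds1)                          # exon 1
  i1 <- c(e1[2] + 1L, e1[2] + t$intron1)                # intron 1
  e2 <- c(i1[2] + 1L, i1[2] + t$cds2)                   # exon 2
  i2 <- c(e2[2] + 1L, e2[2] + t$intron2)                # intron 2
  e3 <- c(i2[2] + 1L, i2[2] + t$cds3 + t$utr3)          # exon 3
  list(exons = rbind(e1, e2, e3), introns = rbind(i1, i2),
       cds = c(t$utr5 + 1L, e3[1] + t$cds3 - 1L),
       length = e3[2])
}

random_coding_codons <- function(n) {
  ok <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  sample(ok, n, replace = TRUE)
}

# assemble one gene block on the coding strand
build_gene_block <- function() {
  t <- GENE_TPL
  n_codons <- (t$cds1 + t$cds2 + t$cds3) / 3L  # 55, incl. start and stop
  cds <- paste0("ATG", paste(random_coding_codons(n_codons - 2L),
                             collapse = ""),
                sample(STOP_CODONS, 1))
  intron <- function(len) {
    paste0("GT", paste(sample(BASES, len - 4L, replace = TRUE),
                       collapse = ""), "AG")
  }
  rnd <- function(len) paste(sample(BASES, len, replace = TRUE),
                             collapse = "")
  paste0(rnd(t$utr5), substr(cds, 1L, t$cds1), intron(t$intron1),
         substr(cds, t$cds1 + 1L, t$cds1 + t$cds2), intron(t$intron2),
         substr(cds, t$cds1 + t$cds2 + 1L, nchar(cds)), rnd(t$utr3))
}

#' Generate a synthetic reference genome with valid gene models
#'
#' Builds a small multi-chromosome reference in which every gene has an
#' ATG...stop coding sequence split over three exons with canonical GT/AG
#' introns, on alternating strands, and plants a truth set of variants
#' spanning all six protein-altering categories plus non-altering controls
#' (synonymous, intronic, UTR) in the first genes.
#'
#' @param config A [sim_config()].
#' @param n_truth_genes Number of genes receiving planted truth variants.
#' @return List of class `sim_genome`: `reference` (a named
#'   [Biostrings::DNAStringSet]), `models` (a `gene_models` tibble), and
#'   `truth` (tibble `variant_id`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `true_category`).
#' @export
generate_genome <- function(config, n_truth_genes = min(6L, config$n_genes)) {
  set.seed(substream_seed(config$seed, "genome"))
  bc <- gene_block_coords()
  spacer <- 60L
  n_chrom <- 2L
  per_chrom <- ceiling(config$n_genes / n_chrom)

  chrom_seq <- stats::setNames(vector("list", n_chrom),
                               paste0("chrS", seq_len(n_chrom)))
  models <- list()
  gi <- 0L
  for (ci in seq_len(n_chrom)) {
    parts <- character(0)
    offset <- 0L
    for (k in seq_len(per_chrom)) {
      gi <- gi + 1L
      if (gi > config$n_genes) break
      gene <- sprintf("GENE%04d", gi)
      strand <- if (gi %% 2L == 1L) "+" else "-"
      sp <- paste(sample(BASES, spacer, replace = TRUE), collapse = "")
      block <- build_gene_block()
      L <- bc$length
      if (strand == "-") {
        block <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(block)))
        mirror <- function(iv) cbind(L - iv[, 2] + 1L, L - iv[, 1] + 1L)
        exons <- mirror(bc$exons)
        cds <- c(L - bc$cds[2] + 1L, L - bc$cds[1] + 1L)
      } else {
        exons <- bc$exons
        cds <- bc$cds
      }
      gstart <- offset + spacer
      exons <- exons[order(exons[, 1]), , drop = FALSE]
      models[[gi]] <- tibble::tibble(
        gene = gene, transcript_id = paste0(gene, ".t1"),
        chrom = names(chrom_seq)[ci], strand = strand,
        exon_start = list(as.integer(gstart + exons[, 1])),
        exon_end = list(as.integer(gstart + exons[, 2])),
        cds_start = as.integer(gstart + cds[1]),
        cds_end = as.integer(gstart + cds[2]))
      parts <- c(parts, sp, block)
      offset <- offset + spacer + L
    }
    parts <- c(parts, paste(sample(BASES, spacer, replace = TRUE),
                            collapse = ""))
    chrom_seq[[ci]] <- paste(parts, collapse = "")
  }
  models <- dplyr::bind_rows(models)
  class(models) <- c("gene_models", class(models))
  reference <- Biostrings::DNAStringSet(unlist(chrom_seq))
  validate_gene_models(models)

  truth <- plant_truth_variants(models[seq_len(n_truth_genes), ], reference)
  structure(list(reference = reference, models = models, truth = truth,
                 config = config), class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome> ", length(x$reference), " chromosomes (",
      sum(Biostrings::width(x$reference)), " bp), ", nrow(x$models),
      " genes, ", nrow(x$truth), " truth variants\n", sep = "")
  invisible(x)
}

# ---- truth-variant planting ------------------------------------------------

ref_base <- function(reference, chrom, pos, len = 1L) {
  as.character(Biostrings::subseq(reference[[chrom]], pos, pos + len - 1L))
}

# genomic SNV (ref/alt on the genome's plus strand) for a coding-strand
# substitution at CDS position cds_pos
cds_snv <- function(model, reference, cds_pos, alt_coding) {
  g <- cds_to_genomic(model, cds_pos)
  ref <- ref_base(reference, model$chrom, g)
  alt <- if (model$strand == "+") alt_coding else complement_base(alt_coding)
  tibble::tibble(chrom = model$chrom, pos = g, ref = ref, alt = alt,
                 variant_id = variant_id(model$chrom, g, ref, alt))
}

# find a coding SNV of the requested kind; NULL if no codon qualifies
find_coding_snv <- function(model, reference,
                            kind = c("missense", "synonymous", "stopgain"),
                            codon_range = NULL) {
  kind <- match.arg(kind)
  cds <- cds_sequence(model, reference)
  n_codons <- nchar(cds) / 3L
  idxs <- codon_range %||% 2:(n_codons - 1L)
  for (ci in sample(idxs)) {
    codon <- substr(cds, 3L * ci - 2L, 3L * ci)
    for (within in sample(1:3)) {
      for (b in sample(setdiff(BASES, substr(codon, within, within)))) {
        mutated <- codon
        substr(mutated, within, within) <- b
        a_ref <- translate_codon(codon)
        a_alt <- translate_codon(mutated)
        hit <- switch(kind,
          missense = a_ref != a_alt && a_alt != "*" && a_ref != "*",
          synonymous = a_ref == a_alt,
          stopgain = a_ref != "*" && a_alt == "*")
        if (hit) {
          return(cds_snv(model, reference, 3L * (ci - 1L) + within, b))
        }
      }
    }
  }
  NULL
}

# anchored deletion of n_del coding-strand CDS bases starting at cds_pos
# (must lie inside one exon, with the anchor base inside the gene)
cds_deletion <- function(model, reference, cds_pos, n_del) {
  g <- vapply(cds_pos:(cds_pos + n_del - 1L), function(p) {
    cds_to_genomic(model, p)
  }, integer(1))
  gstart <- min(g)
  gend <- max(g)
  pos <- gstart - 1L
  ref <- ref_base(reference, model$chrom, pos, gend - pos + 1L)
  alt <- substr(ref, 1L, 1L)
  normalize_variant(model$chrom, pos, ref, alt)
}

# splice-acceptor SNV: mutate the -2 (A of AG) base of the first intron's
# acceptor on the coding strand
splice_acceptor_snv <- function(model, reference) {
  spl <- splice_windows(model)
  acc <- spl[spl$side == "acceptor", ][1, ]
  # the A of the AG dinucleotide: first base in genomic order on "+",
  # second on "-"
  g <- if (model$strand == "+") acc$start else acc$end
  ref <- ref_base(reference, model$chrom, g)
  alt_coding <- "G"
  alt <- if (model$strand == "+") alt_coding else complement_base(alt_coding)
  if (alt == ref) alt <- setdiff(BASES, c(ref, "G"))[1]
  tibble::tibble(chrom = model$chrom, pos = g, ref = ref, alt = alt,
                 variant_id = variant_id(model$chrom, g, ref, alt))
}

plant_truth_variants <- function(models, reference) {
  rows <- list()
  add <- function(v, gene, category) {
    rows[[length(rows) + 1L]] <<- dplyr::mutate(
      v[, c("variant_id", "chrom", "pos", "ref", "alt")],
      gene = gene, true_category = category)
  }
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    add(find_coding_snv(m, reference, "missense"), m$gene, "missense")
    add(find_coding_snv(m, reference, "synonymous"), m$gene,
        "non_protein_altering")
    sg <- find_coding_snv(m, reference, "stopgain")
    if (!is.null(sg)) add(sg, m$gene, "stopgain")
    # stop-loss: mutate the first base of the stop codon (T -> C)
    cds <- cds_sequence(m, reference)
    add(cds_snv(m, reference, nchar(cds) - 2L, "C"), m$gene, "stoploss")
    add(splice_acceptor_snv(m, reference), m$gene, "splice_site")
    # indels in the interior of the middle coding exon
    mid <- GENE_TPL$cds1 + 10L
    add(cds_deletion(m, reference, mid, 2L), m$gene, "frameshift")
    add(cds_deletion(m, reference, mid + 12L, 3L), m$gene,
        "nonframeshift_indel")
    # deep-intronic and UTR controls
    intron_mid <- intronic_snv(m, reference)
    add(intron_mid, m$gene, "non_protein_altering")
    add(utr_snv(m, reference), m$gene, "non_protein_altering")
  }
  out <- dplyr::bind_rows(rows)
  out[!duplicated(out$variant_id), ]
}

intronic_snv <- function(model, reference) {
  s <- model$exon_start[[1]]
  e <- model$exon_end[[1]]
  g <- e[1] + 10L  # 10 bp into the first intron, clear of splice windows
  ref <- ref_base(reference, model$chrom, g)
  tibble::tibble(chrom = model$chrom, pos = g, ref = ref,
                 alt = setdiff(BASES, ref)[1],
                 variant_id = variant_id(model$chrom, g, ref,
                                         setdiff(BASES, ref)[1]))
}

utr_snv <- function(model, reference) {
  # 3rd base of the transcript: UTR on the coding strand's first exon
  g <- if (model$strand == "+") min(model$exon_start[[1]]) + 2L else
    max(model$exon_end[[1]]) - 2L
  ref <- ref_base(reference, model$chrom, g)
  tibble::tibble(chrom = model$chrom, pos = g, ref = ref,
                 alt = setdiff(BASES, ref)[1],
                 variant_id = variant_id(model$chrom, g, ref,
                                         setdiff(BASES, ref)[1]))
}

#' Simulate a reference frequency panel
#'
#' Draws polymorphic coding sites per gene (Poisson), assigns each a true
#' population frequency from either the rare Beta spectrum or, with
#' probability `common_known_fraction`, a common stratum (MAF >= 1.5%)
#' whose members also enter the known-variant set, then draws the panel's
#' observed alt-allele count binomially over `2 * panel_individuals`
#' alleles. Spiked genes receive no background sites.
#'
#' @param config A [sim_config()].
#' @param genome A [generate_genome()] result.
#' @return List of class `sim_panel`: `panel` (a `frequency_panel`),
#'   `sites` (tibble with true frequencies and known flags), `known`
#'   (character vector of known keys).
#' @export
simulate_panel <- function(config, genome) {
  set.seed(substream_seed(config$seed, "panel"))
  spiked <- vapply(config$spike, `[[`, character(1), "gene")
  models <- genome$models[!genome$models$gene %in% spiked, ]
  an <- 2L * config$panel_individuals
  rows <- list()
  used <- character(0)
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    n_sites <- stats::rpois(1, config$sites_per_gene)
    if (n_sites == 0) next
    for (k in seq_len(n_sites)) {
      # background coding polymorphism: missense or synonymous (standing
      # loss-of-function polymorphism is rare; LoF sites are planted
      # explicitly where a simulation calls for them)
      kind <- if (stats::runif(1) < 0.75) "missense" else "synonymous"
      v <- find_coding_snv(m, genome$reference, kind)
      if (is.null(v) || v$variant_id %in% used) next
      used <- c(used, v$variant_id)
      common <- stats::runif(1) < config$common_known_fraction
      f <- if (common) stats::runif(1, 0.02, 0.25) else
        stats::rbeta(1, config$sfs_shape1, config$sfs_shape2)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
        ref = v$ref, alt = v$alt,
        gene = m$gene, f_true = f, known = common,
        ac = stats::rbinom(1, an, f))
    }
  }
  sites <- dplyr::bind_rows(rows)
  panel <- structure(list(entries = tibble::tibble(
    variant_id = sites$variant_id, ac = as.integer(sites$ac),
    an = an), n_individuals = config$panel_individuals),
    class = "frequency_panel")
  structure(list(panel = panel, sites = sites,
                 known = sites$variant_id[sites$known]),
            class = "sim_panel")
}

#' Simulate cohort genotypes with truth labels
#'
#' Genotypes at panel sites are drawn per sample as Binomial(2, panel
#' frequency), independently for cases, controls and platform controls.
#' Spiked genes override: the configured number of distinct case (and
#' control) samples each receive one heterozygous alt at a distinct novel
#' missense site of the gene. A fraction of sites is marked "bad" and given
#' elevated platform-control no-call rates, and false rare calls are
#' injected as novel case singletons so that the expected fraction of
#' candidate rare coding calls that are errors equals
#' `false_rare_call_rate`. Sites with no alternate allele in any sample are
#' dropped (they would not appear in a cohort VCF).
#'
#' @param config A [sim_config()].
#' @param panel_sim A [simulate_panel()] result.
#' @param genome A [generate_genome()] result.
#' @return List of class `sim_cohort`: `cohort` (a `cohort` object),
#'   `truth` (per-variant tibble: `gene`, `f_true`, `known`, `spike`,
#'   `error`, `bad_site`), `spike_carriers` (tibble `gene`, `sample`,
#'   `variant_id`).
#' @export
simulate_cohort <- function(config, panel_sim, genome) {
  set.seed(substream_seed(config$seed, "cohort"))
  samples <- tibble::tibble(
    sample = c(sprintf("case%02d", seq_len(config$n_cases)),
               sprintf("ctrl%02d", seq_len(config$n_controls)),
               sprintf("plat%02d", seq_len(config$n_platform_controls))),
    label = c(rep("case", config$n_cases),
              rep("control", config$n_controls),
              rep("platform_control", config$n_platform_controls)))
  n_samp <- nrow(samples)
  sites <- panel_sim$sites
  an <- panel_sim$panel$entries$an[1]
  f_panel <- panel_sim$panel$entries$ac / an

  geno <- matrix(stats::rbinom(n_samp * nrow(sites), 2L,
                               rep(f_panel, each = n_samp)),
                 nrow = n_samp)
  variants <- sites[, c("chrom", "pos", "ref", "alt", "variant_id")]
  truth <- tibble::tibble(variant_id = sites$variant_id, gene = sites$gene,
                          f_true = sites$f_true, known = sites$known,
                          spike = FALSE, error = FALSE, bad_site = FALSE)

  used <- sites$variant_id
  add_site <- function(v, gene, carriers, flags) {
    variants <<- dplyr::bind_rows(
      variants, v[, c("chrom", "pos", "ref", "alt", "variant_id")])
    col <- integer(n_samp)
    col[match(carriers, samples$sample)] <- 1L
    geno <<- cbind(geno, col)
    truth <<- dplyr::bind_rows(truth, tibble::tibble(
      variant_id = v$variant_id, gene = gene, f_true = 0,
      known = FALSE, spike = isTRUE(flags$spike),
      error = isTRUE(flags$error), bad_site = FALSE))
    used <<- c(used, v$variant_id)
  }

  # spikes: distinct carriers at distinct novel sites
  spike_rows <- list()
  for (sp in config$spike) {
    m <- genome$models[genome$models$gene == sp$gene, ]
    if (nrow(m) == 0) stop("spiked gene not in genome: ", sp$gene)
    ncc <- sp$n_case_carriers
    nctl <- sp$n_control_carriers %||% 0L
    if (ncc > config$n_cases || nctl > config$n_controls) {
      stop("spike carrier count exceeds cohort size for ", sp$gene)
    }
    carriers <- c(sample(samples$sample[samples$label == "case"], ncc),
                  sample(samples$sample[samples$label == "control"], nctl))
    for (s in carriers) {
      v <- plant_novel_missense(m, genome$reference, used)
      add_site(v, sp$gene, s, list(spike = TRUE))
      spike_rows[[length(spike_rows) + 1L]] <- tibble::tibble(
        gene = sp$gene, sample = s, variant_id = v$variant_id)
    }
  }

  # bad sites: elevated platform-control no-call (never at spike sites)
  plat <- samples$label == "platform_control"
  eligible <- which(!truth$spike & !truth$error)
  n_bad <- round(config$nocall_site_fraction * length(eligible))
  bad <- sample(eligible, n_bad)
  truth$bad_site[bad] <- TRUE
  for (j in bad) {
    miss <- plat & stats::runif(n_samp) < config$nocall_rate_at_bad_sites
    geno[miss, j] <- NA_integer_
  }

  # sequencing errors: novel case singletons at new coding sites, scaled so
  # the expected error share of candidate rare coding calls matches config
  cc <- samples$label %in% c("case", "control")
  rare <- f_panel < 0.015
  carried <- colSums(geno[cc, seq_len(nrow(sites)), drop = FALSE] >= 1L,
                     na.rm = TRUE) > 0
  n_real <- sum(rare & carried) + length(spike_rows)
  fr <- config$false_rare_call_rate
  n_err <- if (fr >= 1) 0L else round(fr / (1 - fr) * n_real)
  spiked_genes <- vapply(config$spike, `[[`, character(1), "gene")
  host_models <- genome$models[!genome$models$gene %in% spiked_genes, ]
  cases <- samples$sample[samples$label == "case"]
  for (k in seq_len(n_err)) {
    m <- host_models[sample(nrow(host_models), 1), ]
    v <- plant_novel_missense(m, genome$reference, used)
    add_site(v, m$gene, sample(cases, 1), list(error = TRUE))
  }

  # drop sites with no alt allele anywhere
  keep <- colSums(geno >= 1L, na.rm = TRUE) > 0
  cohort <- new_cohort(variants[keep, ], samples,
                       geno[, keep, drop = FALSE])
  structure(list(cohort = cohort, truth = truth[keep, ],
                 spike_carriers = dplyr::bind_rows(spike_rows)),
            class = "sim_cohort")
}

# novel missense SNV in a gene, avoiding already-used keys
plant_novel_missense <- function(model, reference, used) {
  for (attempt in 1:50) {
    v <- find_coding_snv(model, reference, "missense")
    if (!is.null(v) && !v$variant_id %in% used) return(v)
  }
  stop("could not place a novel missense variant in ", model$gene)
}

#' Simulate an ACMG-style gene list and pathogenic-variant catalogue
#'
#' Flags 56 of the genome's genes for incidental-finding screening (the
#' first 45 LoF-actionable) and plants, with carriers added to the cohort:
#' a catalogued-pathogenic missense, a benign-vetoed loss-of-function
#' variant (conflicting pathogenic + benign entries), a novel frameshift in
#' a LoF-actionable gene, a novel frameshift in a non-actionable gene
#' (not reportable), and an `uncertain`-classified missense (not
#' reportable). The expected screen output is returned as truth.
#'
#' @param config A [sim_config()].
#' @param genome A [generate_genome()] result with at least 56 genes.
#' @param sim_cohort A [simulate_cohort()] result (its cohort gains the
#'   planted carriers).
#' @return List of class `sim_catalogue`: `acmg`, `catalogue`, `cohort`
#'   (updated), `truth_findings` (tibble `sample`, `variant_id`, `gene`,
#'   `basis`).
#' @export
simulate_catalogue <- function(config, genome, sim_cohort) {
  stopifnot(nrow(genome$models) >= 56)
  set.seed(substream_seed(config$seed, "catalogue"))
  spiked <- vapply(config$spike, `[[`, character(1), "gene")
  pool <- genome$models$gene[!genome$models$gene %in% spiked]
  acmg <- tibble::tibble(gene = pool[1:56],
                         lof_actionable = c(rep(TRUE, 45), rep(FALSE, 11)))
  cohort <- sim_cohort$cohort
  cases <- cohort_samples(cohort, "case")
  used <- cohort$variants$variant_id
  mdl <- function(g) genome$models[genome$models$gene == g, ]

  plants <- list()
  plant <- function(v, gene, carrier, reportable, basis = NA) {
    col <- integer(nrow(cohort$samples))
    col[match(carrier, cohort$samples$sample)] <- 1L
    cohort <<- new_cohort(
      dplyr::bind_rows(cohort$variants,
                       v[, c("chrom", "pos", "ref", "alt", "variant_id")]),
      cohort$samples, cbind(cohort$geno, col))
    used <<- c(used, v$variant_id)
    if (reportable) {
      plants[[length(plants) + 1L]] <<- tibble::tibble(
        sample = carrier, variant_id = v$variant_id, gene = gene,
        basis = basis)
    }
    v
  }
  entry <- function(v, classification, source, identifier) {
    tibble::tibble(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                   classification = classification, source = source,
                   identifier = identifier)
  }

  g_path <- acmg$gene[1]
  g_veto <- acmg$gene[2]
  g_lof <- acmg$gene[3]
  g_nonact <- acmg$gene[46]
  g_unc <- acmg$gene[4]

  v1 <- plant(plant_novel_missense(mdl(g_path), genome$reference, used),
              g_path, sample(cases, 1), TRUE, "catalogue_pathogenic")
  v2 <- plant(cds_deletion(mdl(g_veto), genome$reference,
                           GENE_TPL$cds1 + 20L, 2L),
              g_veto, sample(cases, 1), FALSE)
  v3 <- plant(cds_deletion(mdl(g_lof), genome$reference,
                           GENE_TPL$cds1 + 20L, 2L),
              g_lof, sample(cases, 1), TRUE, "novel_lof")
  v4 <- plant(cds_deletion(mdl(g_nonact), genome$reference,
                           GENE_TPL$cds1 + 20L, 2L),
              g_nonact, sample(cases, 1), FALSE)
  v5 <- plant(plant_novel_missense(mdl(g_unc), genome$reference, used),
              g_unc, sample(cases, 1), FALSE)

  catalogue <- dplyr::bind_rows(
    entry(v1, "pathogenic", "ClinVar", "rsSIM0001"),
    entry(v2, "pathogenic", "HGMD", "CMSIM0002"),
    entry(v2, "benign", "LSDB", "lsdbSIM0002"),
    entry(v5, "uncertain", "ClinVar", "rsSIM0005"))
  catalogue <- dplyr::bind_cols(
    normalize_variant(catalogue$chrom, catalogue$pos, catalogue$ref,
                      catalogue$alt),
    catalogue[, c("classification", "source", "identifier")])

  structure(list(acmg = acmg, catalogue = catalogue, cohort = cohort,
                 truth_findings = dplyr::bind_rows(plants)),
            class = "sim_catalogue")
}

#' Write the synthetic genome to disk
#'
#' @param genome A `sim_genome`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "reference.fa")
  gff <- file.path(dir, "genes.gff3")
  truth <- file.path(dir, "consequence_truth.tsv")
  Biostrings::writeXStringSet(genome$reference, fasta)
  write_gene_models(genome$models, gff)
  write_prefixed_tsv(genome$truth, truth)
  list(fasta = fasta, gff = gff, truth = truth)
}
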