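#' Assemble a pipeline run configuration
#'
#' @param cohort_vcf Multi-sample VCF of cases, controls and platform
#'   controls.
#' @param labels_tsv TSV (`sample`, `label`) assigning each VCF sample to
#'   case / control / platform_control.
#' @param panel Sites-only VCF (AC/AN) or TSV of panel frequencies.
#' @param known TSV or sites-only VCF of known variants.
#' @param gene_models GFF3 of transcript models.
#' @param reference FASTA of the reference genome.
#' @param acmg,catalogue TSVs for the incidental screen (optional; screen
#'   is skipped when absent).
#' @param out_dir Output directory.
#' @param panel_individuals Number of diploid individuals behind the panel.
#' @param filter Named list of [filter_config()] overrides.
#' @param alpha Family-wise error rate for all scans.
#' @param variant_scan,burden,recessive,incidental Stage toggles.
#' @param quality_key,quality_threshold Optional FORMAT key/threshold for
#'   the low-quality genotype tier.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort_vcf, labels_tsv, panel, known = NULL,
                       gene_models, reference, acmg = NULL,
                       catalogue = NULL, out_dir,
                       panel_individuals = 379L, filter = list(),
                       alpha = 0.05, variant_scan = TRUE, burden = TRUE,
                       recessive = TRUE, incidental = TRUE,
                       quality_key = NULL, quality_threshold = NULL) {
  cfg <- list(cohort_vcf = cohort_vcf, labels_tsv = labels_tsv,
              panel = panel, known = known, gene_models = gene_models,
              reference = reference, acmg = acmg, catalogue = catalogue,
              out_dir = out_dir,
              panel_individuals = as.integer(panel_individuals),
              filter = filter, alpha = alpha, variant_scan = variant_scan,
              burden = burden, recessive = recessive,
              incidental = incidental, quality_key = quality_key,
              quality_threshold = quality_threshold)
  required <- c("cohort_vcf", "labels_tsv", "panel", "gene_models",
                "reference")
  for (f in required) {
    if (!file.exists(cfg[[f]])) stop("input not found: ", f, " = ",
                                     cfg[[f]])
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full case-control pipeline
#'
#' Annotates the cohort's variants, applies the per-path filter cascades
#' (single-variant path: platform no-call + known-variant exclusion;
#' gene path: platform no-call + panel/empirical MAF), runs the enabled
#' scans, screens for incidental findings, and writes every table plus a
#' YAML run report into `out_dir`. Re-running with an identical
#' configuration and inputs reproduces identical result tables.
#'
#' @param config A [run_config()].
#' @return The run report (list of class `run_report`), invisibly writable
#'   via its `report.yaml`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  labels <- read_prefixed_tsv(config$labels_tsv)
  label_map <- stats::setNames(labels$label, labels$sample)
  cohort <- read_cohort_vcf(config$cohort_vcf, label_map,
                            quality_key = config$quality_key,
                            quality_threshold = config$quality_threshold)
  panel <- read_frequency_panel(config$panel, config$panel_individuals)
  known <- if (!is.null(config$known)) read_known_variants(config$known)
  models <- read_gene_models(config$gene_models)
  reference <- Biostrings::readDNAStringSet(config$reference)
  names(reference) <- sub("\\s.*$", "", names(reference))

  report <- list(package_version = as.character(
    utils::packageVersion("rareburden")),
    config_hash = rlang::hash(unclass(config)),
    alpha = config$alpha)

  annotations <- annotate_cohort(cohort, models, reference)
  write_variant_table(cohort, annotations, out("annotations.tsv"),
                      panel = panel)
  pa <- protein_altering_variants(annotations)
  report$n_variants <- nrow(cohort$variants)
  report$n_protein_altering <- length(pa)

  base_filter <- config$filter
  mk_filter <- function(...) {
    do.call(filter_config, utils::modifyList(base_filter, list(...)))
  }

  results <- list()
  if (isTRUE(config$variant_scan)) {
    if (is.null(known)) stop("variant scan requires a known-variant set")
    casc <- run_cascade(cohort, panel = panel, known = known,
                        config = mk_filter(known_set_enabled = TRUE,
                                           maf_enabled = FALSE),
                        variant_ids = pa)
    write_prefixed_tsv(casc$traces, out("filter_trace_variant_path.tsv"))
    scan <- variant_enrichment_scan(casc$cohort, panel, casc$retained,
                                    alpha = config$alpha)
    write_prefixed_tsv(scan, out("variant_scan.tsv"))
    results$variant_scan <- scan
    report$variant_path <- list(
      n_input = length(pa), n_retained = length(casc$retained),
      n_tests = if (nrow(scan)) scan$n_tests[1] else 0L,
      threshold = if (nrow(scan)) scan$threshold[1] else NA,
      n_significant = sum(scan$significant))
    stopifnot(sum(casc$traces$removed_by != "none") +
                length(casc$retained) == length(pa))
  }
  if (isTRUE(config$burden) || isTRUE(config$recessive)) {
    casc <- run_cascade(cohort, panel = panel, known = known,
                        config = mk_filter(known_set_enabled = FALSE,
                                           maf_enabled = TRUE),
                        variant_ids = pa)
    write_prefixed_tsv(casc$traces, out("filter_trace_gene_path.tsv"))
    if (isTRUE(config$burden)) {
      bs <- burden_scan(casc$cohort, annotations, casc$retained,
                        alpha = config$alpha)
      write_prefixed_tsv(bs, out("gene_burden.tsv"))
      results$burden <- bs
      report$burden <- list(
        n_genes_tested = nrow(bs),
        threshold = if (nrow(bs)) bs$threshold[1] else NA,
        n_significant = sum(bs$significant),
        top = utils::head(bs$gene, 5))
    }
    if (isTRUE(config$recessive)) {
      rs <- recessive_scan(casc$cohort, annotations, casc$retained,
                           alpha = config$alpha)
      write_prefixed_tsv(rs, out("recessive_scan.tsv"))
      results$recessive <- rs
      report$recessive <- list(
        n_genes_tested = nrow(rs),
        threshold = if (nrow(rs)) rs$threshold[1] else NA,
        n_significant = sum(rs$significant))
    }
  }
  if (isTRUE(config$incidental) && !is.null(config$acmg) &&
      !is.null(config$catalogue)) {
    acmg <- read_acmg_genes(config$acmg)
    catalogue <- read_catalogue(config$catalogue)
    findings <- screen_incidental(cohort, annotations, acmg, catalogue)
    write_prefixed_tsv(findings, out("incidental_findings.tsv"))
    writeLines(format_findings(findings), out("incidental_findings.txt"))
    results$incidental <- findings
    report$incidental <- list(n_findings = nrow(findings),
                              n_samples = length(unique(findings$sample)))
  }
  yaml::write_yaml(report, out("report.yaml"))
  structure(c(report, list(results = results)), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> rareburden", x$package_version, "\n")
  cat("  variants:", x$n_variants, "| protein-altering:",
      x$n_protein_altering, "\n")
  if (!is.null(x$variant_path)) {
    cat("  variant scan:", x$variant_path$n_retained, "tested,",
        x$variant_path$n_significant, "significant at",
        format(x$variant_path$threshold, digits = 3), "\n")
  }
  if (!is.null(x$burden)) {
    cat("  burden scan:", x$burden$n_genes_tested, "genes,",
        x$burden$n_significant, "significant; top:",
        paste(x$burden$top, collapse = ", "), "\n")
  }
  if (!is.null(x$recessive)) {
    cat("  recessive scan:", x$recessive$n_genes_tested, "genes,",
        x$recessive$n_significant, "significant\n")
  }
  if (!is.null(x$incidental)) {
    cat("  incidental findings:", x$incidental$n_findings, "\n")
  }
  invisible(x)
}

#' Write a complete synthetic input set for the pipeline
#'
#' Runs the generator end to end (genome, panel, cohort, catalogue) and
#' writes every pipeline input in its standard format, so a full analysis
#' is reproducible from files alone.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return A [run_config()] pointing at the written files (outputs under
#'   `dir/results`), with the simulation truth attached as attribute
#'   `"truth"`.
#' @export
pipeline_simulate <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- generate_genome(config)
  paths <- write_genome(genome, dir)
  ps <- simulate_panel(config, genome)
  sc <- simulate_cohort(config, ps, genome)
  cat_sim <- if (nrow(genome$models) >= 56) {
    simulate_catalogue(config, genome, sc)
  }
  cohort <- if (!is.null(cat_sim)) cat_sim$cohort else sc$cohort
  p <- list(cohort_vcf = file.path(dir, "cohort.vcf"),
            labels_tsv = file.path(dir, "labels.tsv"),
            panel = file.path(dir, "panel.vcf"),
            known = file.path(dir, "known.tsv"))
  write_cohort_vcf(cohort, p$cohort_vcf)
  write_prefixed_tsv(cohort$samples, p$labels_tsv)
  write_frequency_panel(ps$panel, p$panel)
  write_known_variants(ps$known, p$known)
  write_prefixed_tsv(sc$truth, file.path(dir, "cohort_truth.tsv"))
  acmg_path <- catalogue_path <- NULL
  if (!is.null(cat_sim)) {
    acmg_path <- file.path(dir, "acmg_genes.tsv")
    catalogue_path <- file.path(dir, "catalogue.tsv")
    write_prefixed_tsv(cat_sim$acmg, acmg_path)
    write_prefixed_tsv(cat_sim$catalogue[
      , c("chrom", "pos", "ref", "alt", "classification", "source",
          "identifier")], catalogue_path)
  }
  rc <- run_config(cohort_vcf = p$cohort_vcf, labels_tsv = p$labels_tsv,
                   panel = p$panel, known = p$known,
                   gene_models = paths$gff, reference = paths$fasta,
                   acmg = acmg_path, catalogue = catalogue_path,
                   out_dir = file.path(dir, "results"),
                   panel_individuals = config$panel_individuals,
                   quality_key = "GQ", quality_threshold = 20)
  attr(rc, "truth") <- list(
    genome = genome, panel = ps, cohort = sc,
    catalogue = cat_sim)
  rc
}
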