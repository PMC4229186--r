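#' Rare-variant filter configuration
#'
#' Thresholds of the three-stage cascade. Defaults reproduce the standard
#' analysis: variants with a platform-control no-call fraction above 50%
#' are dropped; the single-variant test path additionally removes variants
#' present in a known-variant catalogue, while the gene-burden path instead
#' requires a reference-panel MAF below 1.5% and an empirical MAF below 10%.
#' Sensitivity re-runs (e.g. a 5% panel cutoff, or keeping low-quality
#' calls) are expressed purely through this object.
#'
#' @param nocall_rate_threshold Variants whose no-call fraction among
#'   platform controls strictly exceeds this are removed. Default 0.5.
#' @param panel_maf_cutoff Retain only variants with panel MAF strictly
#'   below this. Default 0.015.
#' @param empirical_maf_cutoff Retain only variants with empirical alt
#'   frequency (alt alleles / called alleles in cases + controls) strictly
#'   below this. Default 0.10.
#' @param use_low_quality Keep low-tier genotype calls? Default `FALSE`
#'   (low-quality calls are masked to no-calls before filtering).
#' @param known_set_enabled Apply the known-variant exclusion stage?
#' @param maf_enabled Apply the MAF stage?
#' @param empirical_over `"combined"` (cases + controls; default) or
#'   `"cases"` for the empirical-MAF denominator.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(nocall_rate_threshold = 0.5,
                          panel_maf_cutoff = 0.015,
                          empirical_maf_cutoff = 0.10,
                          use_low_quality = FALSE,
                          known_set_enabled = TRUE,
                          maf_enabled = TRUE,
                          empirical_over = c("combined", "cases")) {
  empirical_over <- match.arg(empirical_over)
  stopifnot(nocall_rate_threshold >= 0, nocall_rate_threshold <= 1,
            panel_maf_cutoff >= 0, panel_maf_cutoff <= 1,
            empirical_maf_cutoff >= 0, empirical_maf_cutoff <= 1)
  structure(list(nocall_rate_threshold = nocall_rate_threshold,
                 panel_maf_cutoff = panel_maf_cutoff,
                 empirical_maf_cutoff = empirical_maf_cutoff,
                 use_low_quality = use_low_quality,
                 known_set_enabled = known_set_enabled,
                 maf_enabled = maf_enabled,
                 empirical_over = empirical_over),
            class = "filter_config")
}

filter_result <- function(variant_ids, removed, stage, observed = NA_real_) {
  tibble::tibble(variant_id = variant_ids,
                 removed_by = ifelse(removed, stage, "none"),
                 observed_value = observed)
}

#' Platform no-call filter
#'
#' Removes variants whose genotype no-call fraction among platform-control
#' samples strictly exceeds the threshold. A fraction exactly at the
#' threshold is retained.
#'
#' @param cohort A `cohort` containing platform-control samples.
#' @param variant_ids Candidate variant keys (default: all in cohort).
#' @param config A [filter_config()].
#' @return List with `retained` (keys) and `traces` (tibble `variant_id`,
#'   `removed_by`, `observed_value`).
#' @export
platform_nocall_filter <- function(cohort, variant_ids = NULL,
                                   config = filter_config()) {
  if (is.null(variant_ids)) variant_ids <- cohort$variants$variant_id
  if (!any(cohort$samples$label == "platform_control")) {
    stop("no platform-control samples in cohort")
  }
  st <- variant_stats(cohort, labels = "platform_control")
  frac <- st$nocall_fraction[match(variant_ids, st$variant_id)]
  removed <- frac > config$nocall_rate_threshold
  list(retained = variant_ids[!removed],
       traces = filter_result(variant_ids, removed, "platform_nocall", frac))
}

#' Known-variant exclusion filter
#'
#' Removes variants whose normalised key is a member of the known set;
#' membership is allele-aware (same position, different alt stays).
#'
#' @param variant_ids Candidate variant keys.
#' @param known Character vector of known variant keys
#'   (see [read_known_variants()]).
#' @return List with `retained` and `traces`.
#' @export
known_variant_filter <- function(variant_ids, known) {
  removed <- variant_ids %in% known
  list(retained = variant_ids[!removed],
       traces = filter_result(variant_ids, removed, "known_variant",
                              as.numeric(removed)))
}

#' Panel + empirical minor-allele-frequency filter
#'
#' Retains a variant iff its reference-panel frequency is strictly below
#' `panel_maf_cutoff` AND its empirical alt-allele frequency across the
#' analysed samples is strictly below `empirical_maf_cutoff`. A variant
#' absent from the panel counts as frequency 0 (novel). A variant with zero
#' called alleles in the cohort is judged by the panel rule alone (with a
#' message).
#'
#' @param cohort A `cohort`.
#' @param panel A `frequency_panel`.
#' @param variant_ids Candidate variant keys (default: all).
#' @param config A [filter_config()].
#' @return List with `retained` and `traces`.
#' @export
maf_filter <- function(cohort, panel, variant_ids = NULL,
                       config = filter_config()) {
  if (is.null(variant_ids)) variant_ids <- cohort$variants$variant_id
  pf <- panel_lookup(panel, variant_ids)
  labs <- if (config$empirical_over == "cases") "case" else
    c("case", "control")
  st <- variant_stats(cohort, labels = labs)
  st <- st[match(variant_ids, st$variant_id), ]
  uncalled <- st$called_alleles == 0
  if (any(uncalled, na.rm = TRUE)) {
    message(sum(uncalled), " variant(s) with zero called alleles: ",
            "retained by panel rule alone")
  }
  fail_panel <- pf$maf >= config$panel_maf_cutoff
  fail_emp <- !uncalled & st$alt_frequency >= config$empirical_maf_cutoff
  removed <- fail_panel | fail_emp
  stage <- ifelse(fail_panel, "panel_maf",
                  ifelse(fail_emp, "empirical_maf", "none"))
  obs <- ifelse(fail_panel, pf$maf,
                ifelse(fail_emp, st$alt_frequency, pf$maf))
  list(retained = variant_ids[!removed],
       traces = tibble::tibble(variant_id = variant_ids,
                               removed_by = stage, observed_value = obs))
}

#' Run the rare-variant filtering cascade
#'
#' Applies, in order: low-quality masking (unless `use_low_quality`),
#' platform no-call filter, known-variant exclusion (if
#' `known_set_enabled`), panel + empirical MAF filter (if `maf_enabled`).
#' A variant failing several stages is attributed to the first failing
#' stage. The single-variant test path enables the known-variant stage and
#' disables the MAF stage; the gene-burden path does the reverse.
#'
#' @param cohort A `cohort` (cases, controls and platform controls).
#' @param panel A `frequency_panel` (required when `maf_enabled`).
#' @param known Character vector of known variant keys (required when
#'   `known_set_enabled`).
#' @param config A [filter_config()].
#' @param variant_ids Candidate variant keys (default: all in cohort).
#' @return List of class `filter_cascade`: `retained` (keys), `traces`
#'   (tibble with one row per input variant), `cohort` (the cohort after any
#'   quality masking, used by downstream tests), and `counts` (tibble of
#'   per-stage input/removed counts).
#' @export
run_cascade <- function(cohort, panel = NULL, known = NULL,
                        config = filter_config(), variant_ids = NULL) {
  if (is.null(variant_ids)) variant_ids <- cohort$variants$variant_id
  work <- if (config$use_low_quality) cohort else mask_low_quality(cohort)
  traces <- tibble::tibble(variant_id = variant_ids,
                           removed_by = "none",
                           observed_value = NA_real_)
  counts <- list()
  current <- variant_ids

  apply_stage <- function(stage_name, res) {
    tr <- res$traces
    hit <- match(tr$variant_id, traces$variant_id)
    newly <- tr$removed_by != "none" & traces$removed_by[hit] == "none"
    traces$removed_by[hit[newly]] <<- tr$removed_by[newly]
    traces$observed_value[hit[newly]] <<- tr$observed_value[newly]
    counts[[length(counts) + 1L]] <<- tibble::tibble(
      stage = stage_name, n_in = length(current),
      n_removed = length(current) - length(res$retained))
    current <<- res$retained
  }

  if (!config$use_low_quality) {
    # a variant whose alt carriers were all low-quality loses its support
    # once those calls are masked; attribute its removal to this stage
    before <- variant_stats(cohort, labels = c("case", "control"))
    after <- variant_stats(work, labels = c("case", "control"))
    cb <- before$carriers[match(current, before$variant_id)]
    ca <- after$carriers[match(current, after$variant_id)]
    removed <- cb > 0 & ca == 0
    apply_stage("low_quality", list(
      retained = current[!removed],
      traces = filter_result(current, removed, "low_quality")))
  }
  if (any(cohort$samples$label == "platform_control")) {
    apply_stage("platform_nocall",
                platform_nocall_filter(work, current, config))
  }
  if (config$known_set_enabled) {
    if (is.null(known)) stop("known set enabled but no known set given")
    apply_stage("known_variant", known_variant_filter(current, known))
  }
  if (config$maf_enabled) {
    if (is.null(panel)) stop("MAF stage enabled but no panel given")
    apply_stage("maf", maf_filter(work, panel, current, config))
  }
  structure(list(retained = current, traces = traces, cohort = work,
                 counts = dplyr::bind_rows(counts)),
            class = "filter_cascade")
}

#' @export
print.filter_cascade <- function(x, ...) {
  cat("<filter_cascade> ", length(x$retained), " of ", nrow(x$traces),
      " variants retained\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Bar chart of variants removed per cascade stage
#'
#' @param traces Trace tibble from [run_cascade()].
#' @return A ggplot object.
#' @export
plot_filter_cascade <- function(traces) {
  counts <- dplyr::count(traces, .data$removed_by)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = stats::reorder(.data$removed_by, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "outcome", y = "variants",
                  title = "Filter cascade attribution") +
    ggplot2::theme_minimal()
}
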