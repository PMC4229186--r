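#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric p-value computed from tail / point-probability sums
#' at fixed margins. The table is
#' \preformatted{          carrier  non-carrier
#'   group 1     a          b
#'   group 2     c          d}
#' `one_greater` sums the probability of `a` or more group-1 carriers; the
#' two-sided p sums the probabilities of all tables whose point probability
#' does not exceed that of the observed table (the convention of
#' [stats::fisher.test()]). An empty margin yields p = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param sided `"one_greater"` or `"two"`.
#' @return A probability in (0, 1].
#' @export
fisher_exact <- function(a, b, c, d, sided = c("one_greater", "two")) {
  sided <- match.arg(sided)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  K <- a + c            # total carriers
  n1 <- a + b           # group-1 size
  n2 <- c + d
  N <- n1 + n2
  if (K == 0 || K == N || n1 == 0 || n2 == 0) return(1)
  support <- max(0L, K - n2):min(K, n1)
  probs <- stats::dhyper(support, K, N - K, n1)
  if (sided == "one_greater") {
    p <- sum(probs[support >= a])
  } else {
    p_obs <- probs[support == a]
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  min(1, p)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests performed.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 13892)  # 3.6e-06
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(alpha > 0, alpha <= 1, n_tests >= 1)
  alpha / n_tests
}

#' Variant-level enrichment scan against a reference panel
#'
#' For every retained variant, compares carrier counts per genome: cases
#' carrying at least one alt allele among `n_cases`, versus carrier
#' individuals in the panel among its `n_individuals` (approximated from
#' the alt-allele count, capped at the panel size; exact for the rare
#' variants this scan is applied to). One-sided (enrichment in cases)
#' Fisher exact p-values are compared against the Bonferroni threshold over
#' the number of variants actually tested.
#'
#' @param cohort A `cohort` (after any quality masking).
#' @param panel A `frequency_panel`.
#' @param variant_ids Retained variant keys; default all in cohort.
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests for the Bonferroni threshold; defaults to
#'   `length(variant_ids)`.
#' @return Tibble sorted by p-value then key: `variant_id`,
#'   `case_carriers`, `n_cases`, `panel_carriers`, `n_panel`, `p_value`,
#'   `n_tests`, `threshold`, `significant`.
#' @export
variant_enrichment_scan <- function(cohort, panel, variant_ids = NULL,
                                    alpha = 0.05, n_tests = NULL) {
  if (is.null(variant_ids)) variant_ids <- cohort$variants$variant_id
  if (length(variant_ids) == 0) {
    return(tibble::tibble(variant_id = character(), case_carriers = integer(),
                          n_cases = integer(), panel_carriers = integer(),
                          n_panel = integer(), p_value = double(),
                          n_tests = integer(), threshold = double(),
                          significant = logical()))
  }
  if (is.null(n_tests)) n_tests <- length(variant_ids)
  thr <- bonferroni_threshold(alpha, n_tests)
  st <- variant_stats(cohort, labels = "case")
  st <- st[match(variant_ids, st$variant_id), ]
  pf <- panel_lookup(panel, variant_ids)
  n_panel <- panel$n_individuals
  panel_carriers <- pmin(pf$ac, n_panel)
  p <- vapply(seq_along(variant_ids), function(i) {
    fisher_exact(st$carriers[i], st$n_samples[i] - st$carriers[i],
                 panel_carriers[i], n_panel - panel_carriers[i],
                 sided = "one_greater")
  }, double(1))
  out <- tibble::tibble(variant_id = variant_ids,
                        case_carriers = st$carriers,
                        n_cases = st$n_samples,
                        panel_carriers = as.integer(panel_carriers),
                        n_panel = n_panel, p_value = p,
                        n_tests = as.integer(n_tests), threshold = thr,
                        significant = p < thr)
  dplyr::arrange(out, .data$p_value, .data$variant_id)
}

#' RVT1 collapsing burden test for one gene
#'
#' Logistic regression of case/control status on the per-sample proportion
#' of the gene's rare sites at which the sample carries an alternate
#' allele: x_i = r_i / n_i with r_i the carried sites and n_i the called
#' sites. Significance is a likelihood-ratio test against the
#' intercept-only model, referred to a chi-square distribution with one
#' degree of freedom. Under complete or quasi-separation (the carrier
#' proportion perfectly splits cases from controls, driving the slope to
#' infinity) the likelihood is evaluated analytically at its boundary
#' supremum: perfectly predicted samples contribute zero and any samples
#' tied at the separating proportion contribute a binomial log-likelihood
#' at their own case fraction. The statistic stays finite and the
#' `separation` flag is set.
#'
#' @param geno Samples-by-sites matrix of alt-allele counts over the gene's
#'   rare sites (`NA` = no-call), or a `cohort` restricted to those sites.
#' @param labels Character vector (`"case"`/`"control"`) aligned with the
#'   matrix rows; taken from the cohort if `geno` is a `cohort`.
#' @return An object of class `rvt1`: list with `lrt_statistic`, `p_value`,
#'   `separation`, `proportions` (tibble `sample`, `label`, `r`, `n`, `x`),
#'   `carriers_cases`, `carriers_controls`, `n_rare_sites`.
#' @export
rvt1_test <- function(geno, labels = NULL) {
  if (inherits(geno, "cohort")) {
    keep <- geno$samples$label %in% c("case", "control")
    labels <- geno$samples$label[keep]
    geno <- geno$geno[keep, , drop = FALSE]
  }
  geno <- as.matrix(geno)
  stopifnot(length(labels) == nrow(geno),
            all(labels %in% c("case", "control")))
  if (!all(c("case", "control") %in% labels)) {
    stop("both cases and controls are required")
  }
  if (ncol(geno) < 1) stop("at least one rare site is required")
  y <- as.integer(labels == "case")
  r <- rowSums(geno >= 1L, na.rm = TRUE)
  n <- rowSums(!is.na(geno))
  x <- ifelse(n > 0, r / n, 0)
  props <- tibble::tibble(sample = rownames(geno) %||%
                            paste0("s", seq_along(y)),
                          label = labels, r = r, n = n, x = x)
  carriers <- tapply(r > 0, labels, sum)
  base <- list(proportions = props, n_rare_sites = ncol(geno),
               carriers_cases = unname(carriers["case"]),
               carriers_controls = unname(carriers["control"]))

  if (length(unique(x)) == 1L) {
    return(structure(c(base, list(lrt_statistic = 0, p_value = 1,
                                  separation = FALSE)), class = "rvt1"))
  }
  ll_null <- binom_ll(sum(y), length(y))
  sep <- separation_direction(x, y)
  if (!is.na(sep)) {
    # boundary supremum: only the group tied at the separating value
    # contributes; perfectly predicted samples contribute zero
    cut <- if (sep > 0) max(x[y == 0]) else min(x[y == 0])
    tied <- x == cut
    mixed_tied <- any(tied & y == 1) && any(tied & y == 0)
    ll_alt <- if (mixed_tied) binom_ll(sum(y[tied]), sum(tied)) else 0
    lrt <- 2 * (ll_alt - ll_null)
    return(structure(c(base, list(
      lrt_statistic = lrt,
      p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
      separation = TRUE)), class = "rvt1"))
  }
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(),
                                     control = list(maxit = 100)))
  lrt <- max(0, fit$null.deviance - fit$deviance)
  separation <- !fit$converged || abs(stats::coef(fit)[2]) > 30
  structure(c(base, list(
    lrt_statistic = lrt,
    p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
    separation = separation)), class = "rvt1")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

binom_ll <- function(k, n) {
  if (n == 0 || k == 0 || k == n) return(0)
  k * log(k / n) + (n - k) * log(1 - k / n)
}

# +1 if cases sit at or above all controls (and strictly above the tie on
# at least one sample), -1 for the mirror, NA if the groups overlap
separation_direction <- function(x, y) {
  x1 <- x[y == 1]
  x0 <- x[y == 0]
  if (min(x1) >= max(x0)) return(1)
  if (max(x1) <= min(x0)) return(-1)
  NA
}

#' @export
print.rvt1 <- function(x, ...) {
  cat("RVT1 burden test: LRT = ", format(x$lrt_statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 3),
      if (x$separation) " (separation; boundary likelihood)" else "",
      "\n", sep = "")
  cat("  rare sites: ", x$n_rare_sites, "; carriers ",
      x$carriers_cases, " cases / ", x$carriers_controls, " controls\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.rvt1 <- function(x, ...) {
  tibble::tibble(term = "rare_site_proportion",
                 statistic = x$lrt_statistic,
                 p.value = x$p_value,
                 separation = x$separation)
}

#' @export
glance.rvt1 <- function(x, ...) {
  tibble::tibble(n_rare_sites = x$n_rare_sites,
                 carriers_cases = x$carriers_cases,
                 carriers_controls = x$carriers_controls,
                 statistic = x$lrt_statistic,
                 p.value = x$p_value,
                 separation = x$separation)
}

#' @export
autoplot.rvt1 <- function(object, ...) {
  ggplot2::ggplot(object$proportions,
                  ggplot2::aes(x = .data$label, y = .data$x)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "proportion of rare sites carried",
                  title = "RVT1 carrier proportions") +
    ggplot2::theme_minimal()
}

#' Gene-level burden scan
#'
#' Runs [rvt1_test()] on every gene with at least one retained rare
#' protein-altering variant and corrects over the number of genes actually
#' tested.
#'
#' @param cohort A `cohort` (after quality masking).
#' @param annotations Output of [annotate_cohort()].
#' @param retained Variant keys surviving the gene-path filter cascade.
#' @param alpha Family-wise error rate.
#' @param n_tests Override for the Bonferroni denominator (defaults to the
#'   number of genes tested).
#' @return Tibble sorted by ascending p then gene symbol: `gene`,
#'   `n_rare_sites`, `carriers_cases`, `carriers_controls`,
#'   `lrt_statistic`, `p_value`, `separation`, `n_tests`, `threshold`,
#'   `significant`.
#' @export
burden_scan <- function(cohort, annotations, retained = NULL, alpha = 0.05,
                        n_tests = NULL) {
  sets <- gene_variant_sets(cohort, annotations, retained)
  if (length(sets) == 0) {
    return(tibble::tibble(gene = character(), n_rare_sites = integer(),
                          carriers_cases = integer(),
                          carriers_controls = integer(),
                          lrt_statistic = double(), p_value = double(),
                          separation = logical(), n_tests = integer(),
                          threshold = double(), significant = logical()))
  }
  keep <- cohort$samples$label %in% c("case", "control")
  labels <- cohort$samples$label[keep]
  rows <- purrr::imap(sets, function(ids, g) {
    fit <- rvt1_test(cohort$geno[keep, ids, drop = FALSE], labels)
    tibble::tibble(gene = g, n_rare_sites = fit$n_rare_sites,
                   carriers_cases = fit$carriers_cases,
                   carriers_controls = fit$carriers_controls,
                   lrt_statistic = fit$lrt_statistic,
                   p_value = fit$p_value, separation = fit$separation)
  })
  out <- dplyr::bind_rows(rows)
  if (is.null(n_tests)) n_tests <- nrow(out)
  thr <- bonferroni_threshold(alpha, n_tests)
  out$n_tests <- as.integer(n_tests)
  out$threshold <- thr
  out$significant <- out$p_value < thr
  dplyr::arrange(out, .data$p_value, .data$gene)
}

# named list gene -> retained rare protein-altering variant ids with at
# least one carrier among cases+controls
gene_variant_sets <- function(cohort, annotations, retained = NULL) {
  ann <- annotations[annotations$category %in% PROTEIN_ALTERING, ]
  if (!is.null(retained)) ann <- ann[ann$variant_id %in% retained, ]
  ann <- ann[ann$variant_id %in% cohort$variants$variant_id, ]
  if (nrow(ann) == 0) return(list())
  st <- variant_stats(cohort, labels = c("case", "control"))
  carried <- st$variant_id[st$carriers > 0]
  ann <- ann[ann$variant_id %in% carried, ]
  if (nrow(ann) == 0) return(list())
  split(ann$variant_id, ann$gene) |> lapply(unique)
}

#' Recessive-model gene scan
#'
#' For each gene, counts the samples whose summed alt-allele count over the
#' gene's rare protein-altering sites is at least two (two heterozygous
#' sites, or one homozygous site; phase is not inferred) and compares
#' cases against controls with Fisher's exact test.
#'
#' @inheritParams burden_scan
#' @param sided Sidedness of the Fisher test (default one-sided enrichment
#'   in cases; `"two"` also available).
#' @return Tibble sorted by p then gene: `gene`, `cases_with_two_plus`,
#'   `controls_with_two_plus`, `p_value`, `n_tests`, `threshold`,
#'   `significant`.
#' @export
recessive_scan <- function(cohort, annotations, retained = NULL,
                           alpha = 0.05, n_tests = NULL,
                           sided = c("one_greater", "two")) {
  sided <- match.arg(sided)
  sets <- gene_variant_sets(cohort, annotations, retained)
  if (length(sets) == 0) {
    return(tibble::tibble(gene = character(),
                          cases_with_two_plus = integer(),
                          controls_with_two_plus = integer(),
                          p_value = double(), n_tests = integer(),
                          threshold = double(), significant = logical()))
  }
  keep_case <- cohort$samples$label == "case"
  keep_ctrl <- cohort$samples$label == "control"
  n_cases <- sum(keep_case)
  n_ctrl <- sum(keep_ctrl)
  rows <- purrr::imap(sets, function(ids, g) {
    tot_case <- rowSums(cohort$geno[keep_case, ids, drop = FALSE],
                        na.rm = TRUE)
    tot_ctrl <- rowSums(cohort$geno[keep_ctrl, ids, drop = FALSE],
                        na.rm = TRUE)
    a <- sum(tot_case >= 2L)
    c_ <- sum(tot_ctrl >= 2L)
    tibble::tibble(gene = g, cases_with_two_plus = a,
                   controls_with_two_plus = c_,
                   p_value = fisher_exact(a, n_cases - a, c_, n_ctrl - c_,
                                          sided = sided))
  })
  out <- dplyr::bind_rows(rows)
  if (is.null(n_tests)) n_tests <- nrow(out)
  thr <- bonferroni_threshold(alpha, n_tests)
  out$n_tests <- as.integer(n_tests)
  out$threshold <- thr
  out$significant <- out$p_value < thr
  dplyr::arrange(out, .data$p_value, .data$gene)
}

#' Allele-level burden follow-up test
#'
#' Two-sided Fisher exact test on the allele-level 2x2 table comparing the
#' frequency of protein-altering alleles in a follow-up cohort against a
#' reference cohort (carrier alleles vs non-carrier alleles).
#'
#' @param carrier_alleles_cohort,total_alleles_cohort Carrier alleles and
#'   total sequenced alleles in the follow-up cohort.
#' @param carrier_alleles_ref,total_alleles_ref Same for the reference.
#' @return A probability.
#' @export
allele_burden_test <- function(carrier_alleles_cohort, total_alleles_cohort,
                               carrier_alleles_ref, total_alleles_ref) {
  stopifnot(total_alleles_cohort > 0, total_alleles_ref > 0,
            carrier_alleles_cohort <= total_alleles_cohort,
            carrier_alleles_ref <= total_alleles_ref)
  fisher_exact(carrier_alleles_cohort,
               total_alleles_cohort - carrier_alleles_cohort,
               carrier_alleles_ref,
               total_alleles_ref - carrier_alleles_ref,
               sided = "two")
}

#' Minimum detectable case carriers at the variant level
#'
#' Smallest number of case carriers k such that a variant carried by k of
#' `n_cases` cases and absent from the panel reaches significance under the
#' one-sided Fisher test.
#'
#' @param n_cases Number of cases.
#' @param n_panel Number of panel individuals.
#' @param threshold Significance threshold.
#' @return Integer k, or `NA` (with a warning) if unattainable.
#' @examples
#' min_detectable_carriers_variant(13, 379, 3.6e-6)  # 4
#' @export
min_detectable_carriers_variant <- function(n_cases, n_panel, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  for (k in seq_len(n_cases)) {
    if (fisher_exact(k, n_cases - k, 0, n_panel, "one_greater") < threshold)
      return(k)
  }
  warning("no carrier count up to ", n_cases, " reaches the threshold")
  NA_integer_
}

#' Minimum detectable case carriers at the gene level
#'
#' Smallest k such that the RVT1 test on a gene altered in k cases (one
#' distinct site each) and in no control reaches significance.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param threshold Significance threshold.
#' @return Integer k, or `NA` (with a warning) if unattainable.
#' @examples
#' min_detectable_carriers_gene(13, 34, 4.758e-6)  # 7
#' @export
min_detectable_carriers_gene <- function(n_cases, n_controls, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  labels <- c(rep("case", n_cases), rep("control", n_controls))
  for (k in seq_len(n_cases)) {
    geno <- matrix(0L, n_cases + n_controls, k)
    for (j in seq_len(k)) geno[j, j] <- 1L
    if (rvt1_test(geno, labels)$p_value < threshold) return(k)
  }
  warning("no carrier count up to ", n_cases, " reaches the threshold")
  NA_integer_
}

#' Manhattan-style plot of a gene burden scan
#'
#' @param scan Tibble from [burden_scan()] (or [recessive_scan()]).
#' @param label_top Number of top genes to label.
#' @return A ggplot object.
#' @export
plot_burden <- function(scan, label_top = 3) {
  scan <- dplyr::mutate(scan, rank = dplyr::row_number())
  top <- utils::head(scan, label_top)
  p <- ggplot2::ggplot(scan, ggplot2::aes(x = .data$rank,
                                          y = -log10(.data$p_value))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(scan$threshold[1]),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "gene rank", y = expression(-log[10](p)),
                  title = "Gene burden scan") +
    ggplot2::theme_minimal()
  if (nrow(top) > 0) {
    p <- p + ggplot2::geom_text(data = top,
                                ggplot2::aes(label = .data$gene),
                                vjust = -0.6, size = 3)
  }
  p
}
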