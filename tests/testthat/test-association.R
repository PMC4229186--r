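test_that("fisher_exact reproduces tail probabilities exactly", {
  # 4 of 13 case carriers vs 0 of 379 panel individuals
  expect_equal(fisher_exact(4, 9, 0, 379, "one_greater"),
               choose(13, 4) / choose(392, 4), tolerance = 1e-12)
  # 3 of 13 vs 0 of 379: C(13,3)/C(392,3)
  expect_equal(fisher_exact(3, 10, 0, 379, "one_greater"),
               choose(13, 3) / choose(392, 3), tolerance = 1e-12)
  expect_equal(fisher_exact(3, 10, 0, 379, "one_greater"), 2.87e-5,
               tolerance = 2e-3)
  # empty margins
  expect_equal(fisher_exact(0, 13, 0, 379, "one_greater"), 1)
  expect_equal(fisher_exact(0, 13, 0, 379, "two"), 1)
  # two-sided enumeration example
  expect_equal(fisher_exact(2, 18, 0, 20, "two"),
               enum_fisher(2, 18, 0, 20, "two"), tolerance = 1e-12)
  expect_equal(fisher_exact(2, 18, 0, 20, "two"), 0.487, tolerance = 1e-3)
})

test_that("fisher_exact matches stats::fisher.test on random tables", {
  set.seed(7)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(c(2, 10, 60), 1)), 2, 2)
    ft2 <- stats::fisher.test(tab)$p.value
    ft1 <- stats::fisher.test(tab, alternative = "greater")$p.value
    expect_equal(fisher_exact(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                              "two"), ft2, tolerance = 1e-9)
    expect_equal(fisher_exact(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                              "one_greater"), ft1, tolerance = 1e-9)
  }
})

test_that("one-sided p decreases as case carriers grow at fixed margins", {
  p <- vapply(0:13, function(a) {
    fisher_exact(a, 13 - a, 2, 377, "one_greater")
  }, double(1))
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("Bonferroni thresholds divide alpha by the tests performed", {
  expect_equal(bonferroni_threshold(0.05, 13892), 0.05 / 13892)
  expect_equal(signif(bonferroni_threshold(0.05, 13892), 2), 3.6e-6)
  expect_equal(signif(bonferroni_threshold(0.05, 10508), 2), 4.8e-6)
  expect_equal(bonferroni_threshold(0.05, 10508), 4.758e-6,
               tolerance = 1e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
})

test_that("RVT1 handles the degenerate and separated regimes", {
  labels <- c(rep("case", 13), rep("control", 34))
  # no predictor variation
  flat <- rvt1_test(matrix(0L, 47, 3), labels)
  expect_equal(flat$p_value, 1)
  expect_equal(flat$lrt_statistic, 0)
  # seven case carriers, one distinct site each, no control carriers:
  # quasi-separation, boundary deviance equals the closed form
  g7 <- matrix(0L, 47, 7)
  for (j in 1:7) g7[j, j] <- 1L
  fit7 <- rvt1_test(g7, labels)
  expect_true(fit7$separation)
  expect_equal(fit7$lrt_statistic, boundary_lrt(7, 13, 34),
               tolerance = 1e-10)
  expect_equal(fit7$lrt_statistic, 21.62, tolerance = 1e-3)
  expect_equal(fit7$p_value, 3.3e-6, tolerance = 0.01)
  # six carriers: above the genome-wide threshold
  g6 <- matrix(0L, 47, 6)
  for (j in 1:6) g6[j, j] <- 1L
  fit6 <- rvt1_test(g6, labels)
  expect_equal(fit6$lrt_statistic, boundary_lrt(6, 13, 34),
               tolerance = 1e-10)
  expect_equal(fit6$lrt_statistic, 17.96, tolerance = 1e-3)
  expect_equal(fit6$p_value, 2.3e-5, tolerance = 0.01)
  # the boundary value is the supremum: a capped iterative fit approaches
  # but never exceeds it
  x <- rowSums(g7 >= 1) / 7
  y <- as.integer(labels == "case")
  ll <- function(beta) {
    p <- stats::plogis(beta[1] + beta[2] * x)
    sum(stats::dbinom(y, 1, p, log = TRUE))
  }
  ll_null <- sum(y) * log(mean(y)) + sum(1 - y) * log(1 - mean(y))
  # iterative stand-in for the diverging fit: a very large pinned slope
  # (logit scale per unit x), intercept profiled out
  prof <- stats::optimize(function(b0) -ll(c(b0, 500)), c(-40, 10))
  lrt_capped <- 2 * (-prof$objective - ll_null)
  expect_lte(lrt_capped, fit7$lrt_statistic + 1e-6)
  expect_equal(lrt_capped, fit7$lrt_statistic, tolerance = 1e-3)
})

test_that("RVT1 matches glm in the non-separated regime", {
  set.seed(12)
  labels <- c(rep("case", 13), rep("control", 34))
  geno <- matrix(rbinom(47 * 5, 2, 0.15), 47, 5)
  geno[40, ] <- 1L  # make sure controls carry too
  fit <- rvt1_test(geno, labels)
  x <- rowSums(geno >= 1) / 5
  y <- as.integer(labels == "case")
  ref <- stats::glm(y ~ x, family = stats::binomial())
  expect_false(fit$separation)
  expect_equal(fit$lrt_statistic, ref$null.deviance - ref$deviance,
               tolerance = 1e-8)
})

test_that("RVT1 is invariant to rescaling the carrier proportions", {
  labels <- c(rep("case", 6), rep("control", 10))
  geno <- cbind(c(1L, 1L, 0L, rep(0L, 13)), c(0L, 1L, 1L, rep(0L, 13)))
  geno[10, 1] <- 1L
  a <- rvt1_test(geno, labels)
  # doubling the number of called sites per sample halves every x_i
  b <- rvt1_test(cbind(geno, matrix(0L, 16, 2)), labels)
  expect_equal(a$lrt_statistic, b$lrt_statistic, tolerance = 1e-8)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-8)
})

test_that("RVT1 type-I error is at or below nominal on null genes", {
  set.seed(2024)
  labels <- c(rep("case", 13), rep("control", 34))
  n_genes <- 500
  p <- vapply(seq_len(n_genes), function(i) {
    # rare sites (1% allele frequency), the sparse regime the scan runs in
    geno <- matrix(rbinom(47 * 3, 2, 0.01), 47, 3)
    rvt1_test(geno, labels)$p_value
  }, double(1))
  frac <- mean(p < 0.05)
  upper <- 0.05 + stats::qnorm(0.995) * sqrt(0.05 * 0.95 / n_genes)
  expect_lte(frac, upper)
})

test_that("tidy and glance summarise an RVT1 fit", {
  labels <- c(rep("case", 5), rep("control", 5))
  geno <- cbind(c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L))
  fit <- rvt1_test(geno, labels)
  td <- tidy(fit)
  expect_equal(td$term, "rare_site_proportion")
  gl <- glance(fit)
  expect_equal(gl$carriers_cases, 2L)
  expect_equal(gl$carriers_controls, 1L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("variant scan counts carriers per genome and ranks by p", {
  geno <- matrix(0L, 47, 3)
  geno[1:4, 1] <- 1L             # 4 case carriers
  geno[c(1, 20), 2] <- c(2L, 1L) # 1 case (hom) + 1 control carrier
  geno[15, 3] <- 1L              # control only
  co <- make_cohort(geno, c(rep("case", 13), rep("control", 34)))
  panel <- structure(list(entries = tibble::tibble(
    variant_id = co$variants$variant_id[3], ac = 5L, an = 758L),
    n_individuals = 379L), class = "frequency_panel")
  scan <- variant_enrichment_scan(co, panel, n_tests = 13892)
  expect_equal(scan$case_carriers[1], 4L)
  expect_equal(scan$p_value[1], choose(13, 4) / choose(392, 4),
               tolerance = 1e-12)
  expect_true(scan$significant[1])  # 7.4e-7 < 0.05/13892
  expect_false(any(scan$significant[-1]))
  expect_equal(scan$panel_carriers[scan$variant_id ==
                                     co$variants$variant_id[3]], 5L)
  # empty input
  empty <- variant_enrichment_scan(co, panel, variant_ids = character(0))
  expect_equal(nrow(empty), 0L)
})

test_that("burden scan ranks a spiked gene first among nulls", {
  cfg <- sim_config(seed = 5, n_genes = 40, false_rare_call_rate = 0,
                    nocall_site_fraction = 0,
                    spike = list(list(gene = "GENE0010",
                                      n_case_carriers = 8,
                                      n_control_carriers = 0)))
  g <- generate_genome(cfg)
  ps <- simulate_panel(cfg, g)
  sc <- simulate_cohort(cfg, ps, g)
  ann <- annotate_cohort(sc$cohort, g$models, g$reference)
  casc <- run_cascade(sc$cohort, ps$panel, NULL,
                      filter_config(known_set_enabled = FALSE))
  bs <- burden_scan(casc$cohort, ann, casc$retained)
  expect_equal(bs$gene[1], "GENE0010")
  expect_equal(bs$carriers_cases[1], 8L)
  expect_equal(bs$lrt_statistic[1], boundary_lrt(8, 13, 34),
               tolerance = 1e-8)
  # results are sorted by p then symbol, and thresholds use genes tested
  expect_true(!is.unsorted(bs$p_value))
  expect_equal(bs$threshold[1], 0.05 / nrow(bs))
})

test_that("recessive scan counts two-plus-variant samples, phase-free", {
  labels <- c(rep("case", 13), rep("control", 34))
  geno <- matrix(0L, 47, 2)
  geno[1, 1] <- 1L
  geno[1, 2] <- 1L   # compound het
  geno[2, 1] <- 2L   # homozygous: counts as two
  geno[3, 2] <- 1L   # single het: does not count
  co <- make_cohort(geno, labels)
  ann <- tibble::tibble(variant_id = co$variants$variant_id,
                        gene = "G1", transcript_id = "G1.t1",
                        category = "missense", aa_pos = 1L,
                        aa_ref = "A", aa_alt = "V",
                        gene_protein_altering = TRUE)
  rs <- recessive_scan(co, ann)
  expect_equal(rs$cases_with_two_plus, 2L)
  expect_equal(rs$controls_with_two_plus, 0L)
  expect_equal(rs$p_value, choose(13, 2) / choose(47, 2), tolerance = 1e-12)
  # 3 of 13 vs 0 of 34 worked example: C(13,3)/C(47,3) = 286/16215
  expect_equal(fisher_exact(3, 10, 0, 34, "one_greater"), 286 / 16215,
               tolerance = 1e-12)
})

test_that("allele-level follow-up test is two-sided and symmetric", {
  # identical proportions: p = 1
  expect_equal(allele_burden_test(5, 100, 50, 1000), 1)
  expect_equal(allele_burden_test(2, 22, 0, 20),
               enum_fisher(2, 20, 0, 20, "two"), tolerance = 1e-12)
})

test_that("power calculators reproduce the detectability boundaries", {
  thr_variant <- 0.05 / 13892
  expect_equal(min_detectable_carriers_variant(13, 379, thr_variant), 4L)
  expect_equal(min_detectable_carriers_variant(13, 379, 1.0), 1L)
  # k = 3 sits at p = 2.87e-5: thresholds either side flip the answer
  p3 <- choose(13, 3) / choose(392, 3)
  expect_equal(min_detectable_carriers_variant(13, 379, p3 * 1.01), 3L)
  expect_equal(min_detectable_carriers_variant(13, 379, p3 * 0.99), 4L)

  thr_gene <- 0.05 / 10508
  expect_equal(min_detectable_carriers_gene(13, 34, thr_gene), 7L)
  expect_equal(min_detectable_carriers_gene(13, 34, 1.0), 1L)
  # k = 6 boundary p = 2.26e-5
  p6 <- stats::pchisq(boundary_lrt(6, 13, 34), 1, lower.tail = FALSE)
  expect_equal(min_detectable_carriers_gene(13, 34, p6 * 0.99), 7L)
  expect_equal(min_detectable_carriers_gene(13, 34, p6 * 1.01), 6L)
  expect_warning(out <- min_detectable_carriers_variant(2, 10, 1e-9),
                 "threshold")
  expect_true(is.na(out))
})

test_that("spiked-gene detection matches the power prediction", {
  # at the predicted detectability boundary the test statistic depends only
  # on the carrier count, so detection is all-or-none across random
  # carrier/site assignments
  labels <- c(rep("case", 13), rep("control", 34))
  thr <- 0.05 / 10508
  for (seed in 1:20) {
    set.seed(seed)
    for (k in c(6L, 7L)) {
      carriers <- sample(1:13, k)
      geno <- matrix(0L, 47, k)
      for (j in seq_len(k)) geno[carriers[j], j] <- 1L
      detected <- rvt1_test(geno, labels)$p_value < thr
      expect_equal(detected, k >= 7L)
    }
  }
})
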