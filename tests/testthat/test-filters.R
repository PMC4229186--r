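# cohort fixture: cases + controls + 54 platform controls, with planted
# no-call patterns per variant
nocall_fixture <- function(nocalls_per_variant) {
  n_cc <- 10L
  n_plat <- 54L
  n_var <- length(nocalls_per_variant)
  geno <- matrix(0L, n_cc + n_plat, n_var)
  geno[1, ] <- 1L  # one case carrier everywhere
  for (j in seq_len(n_var)) {
    k <- nocalls_per_variant[j]
    if (k > 0) geno[n_cc + seq_len(k), j] <- NA_integer_
  }
  make_cohort(geno, c(rep("case", 5), rep("control", 5),
                      rep("platform_control", n_plat)))
}

test_that("platform no-call filter removes strictly above the threshold", {
  co <- nocall_fixture(c(28L, 27L, 0L))
  res <- platform_nocall_filter(co)
  # 28/54 = 0.519 > 0.5 removed; exactly 27/54 = 0.5 retained; 0/54 retained
  expect_equal(res$traces$removed_by,
               c("platform_nocall", "none", "none"))
  expect_equal(res$traces$observed_value, c(28, 27, 0) / 54)
  expect_length(res$retained, 2L)
  no_plat <- make_cohort(matrix(0L, 2, 1), c("case", "control"))
  expect_error(platform_nocall_filter(no_plat), "platform-control")
})

test_that("known-variant filter is allele-aware", {
  ids <- c("chr1:100:A:G", "chr1:100:A:T", "chr2:5:C:T")
  res <- known_variant_filter(ids, known = "chr1:100:A:G")
  expect_equal(res$retained, c("chr1:100:A:T", "chr2:5:C:T"))
  expect_equal(res$traces$removed_by[1], "known_variant")
  # empty known set retains everything
  expect_equal(known_variant_filter(ids, character(0))$retained, ids)
})

test_that("MAF filter applies panel and empirical rules with strict cutoffs", {
  # 47 samples (13 cases, 34 controls), fully called: 94 alleles
  geno <- matrix(0L, 47, 4)
  geno[1, 1] <- 1L          # singleton: 1/94 = 0.0106
  geno[1:20, 4] <- 1L       # 20/94 = 0.213 fails the empirical rule
  co <- make_cohort(geno, c(rep("case", 13), rep("control", 34)))
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"x\">",
               "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"x\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO"), collapse = "\t"),
               "T1\t110\t.\tA\tG\t.\tPASS\tAC=10;AN=1000",   # 0.010 passes
               "T1\t120\t.\tA\tG\t.\tPASS\tAC=15;AN=1000"),  # 0.015 removed
             vcf)
  panel <- read_frequency_panel(vcf, n_individuals = 500)
  res <- maf_filter(co, panel)
  expect_equal(res$traces$removed_by,
               c("none", "none", "panel_maf", "empirical_maf"))
  # novel singleton retained with no removing rule
  expect_true("T1:100:A:G" %in% res$retained)
  expect_true("T1:110:A:G" %in% res$retained)
})

test_that("variants with zero called alleles fall back to the panel rule", {
  geno <- matrix(NA_integer_, 4, 1)
  co <- make_cohort(geno, c("case", "case", "control", "control"))
  panel <- structure(list(entries = tibble::tibble(
    variant_id = character(), ac = integer(), an = integer()),
    n_individuals = 379L), class = "frequency_panel")
  expect_message(res <- maf_filter(co, panel), "zero called")
  expect_length(res$retained, 1L)
})

test_that("cascade attributes removal to the first failing stage", {
  co <- nocall_fixture(c(30L, 0L, 0L, 0L))
  known <- c(co$variants$variant_id[1], co$variants$variant_id[2])
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tpos\tref\talt\tmaf",
               paste0("T1\t", co$variants$pos[3], "\tA\tG\t0.5")), tsv)
  panel <- read_frequency_panel(tsv, n_individuals = 379)
  res <- run_cascade(co, panel = panel, known = known,
                     config = filter_config())
  expect_equal(res$traces$removed_by,
               c("platform_nocall",  # fails no-call AND known: first wins
                 "known_variant", "panel_maf", "none"))
  # conservation: traces partition the input
  expect_equal(sum(res$traces$removed_by == "none"), length(res$retained))
  expect_setequal(c(res$retained,
                    res$traces$variant_id[res$traces$removed_by != "none"]),
                  co$variants$variant_id)
})

test_that("cascade with all stages disabled is the identity", {
  co <- make_cohort(matrix(1L, 3, 2), c("case", "control", "control"))
  res <- run_cascade(co, config = filter_config(known_set_enabled = FALSE,
                                                maf_enabled = FALSE,
                                                use_low_quality = TRUE))
  expect_equal(res$retained, co$variants$variant_id)
  expect_true(all(res$traces$removed_by == "none"))
})

test_that("cascade is monotone and order-independent on the retained set", {
  set.seed(99)
  n_var <- 40L
  geno <- matrix(rbinom(20 * n_var, 2, 0.08), 20, n_var)
  geno[1, ] <- 1L
  plat <- matrix(rbinom(54 * n_var, 2, 0.08), 54, n_var)
  plat[, 1:5] <- NA_integer_
  co <- make_cohort(rbind(geno, plat),
                    c(rep("case", 8), rep("control", 12),
                      rep("platform_control", 54)))
  known <- sample(co$variants$variant_id, 10)
  tsv <- tempfile(fileext = ".tsv")
  maf <- round(runif(n_var, 0, 0.05), 4)
  writeLines(c("#chrom\tpos\tref\talt\tmaf",
               paste("T1", co$variants$pos, "A", "G", maf, sep = "\t")),
             tsv)
  panel <- read_frequency_panel(tsv, n_individuals = 379)

  full <- run_cascade(co, panel, known, filter_config())
  no_known <- run_cascade(co, panel, known,
                          filter_config(known_set_enabled = FALSE))
  no_maf <- run_cascade(co, panel, known,
                        filter_config(maf_enabled = FALSE))
  # enabling an extra stage never enlarges the retained set
  expect_true(all(full$retained %in% no_known$retained))
  expect_true(all(full$retained %in% no_maf$retained))
  # final retained set equals the intersection of independent stage runs
  indep <- Reduce(intersect, list(
    platform_nocall_filter(co, config = filter_config())$retained,
    known_variant_filter(co$variants$variant_id, known)$retained,
    maf_filter(co, panel, config = filter_config())$retained))
  expect_setequal(full$retained, indep)
})

test_that("low-quality calls are masked unless explicitly kept", {
  geno <- matrix(0L, 4, 2)
  geno[1, 1] <- 1L
  geno[2, 2] <- 1L
  lowq <- matrix(FALSE, 4, 2)
  lowq[1, 1] <- TRUE  # the only carrier of variant 1 is low quality
  co <- make_cohort(geno, c("case", "case", "control", "control"),
                    lowq = lowq)
  strict <- run_cascade(co, config = filter_config(
    known_set_enabled = FALSE, maf_enabled = FALSE))
  expect_equal(strict$traces$removed_by, c("low_quality", "none"))
  lenient <- run_cascade(co, config = filter_config(
    known_set_enabled = FALSE, maf_enabled = FALSE,
    use_low_quality = TRUE))
  expect_true(all(lenient$traces$removed_by == "none"))
})
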