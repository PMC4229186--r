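test_that("GT fields encode allele counts and missing-data conventions", {
  path <- write_vcf_fixture(c(
    vcf_row("chr1", 100, "A", "G", "0/0", "0/1"),
    vcf_row("chr1", 200, "C", "T", "1/1", "1|0"),
    vcf_row("chr1", 300, "G", "A", "./.", "0/."),
    vcf_row("chr1", 400, "T", "C", "1/1", "0/0")))
  co <- read_cohort_vcf(path, c(S1 = "case", S2 = "control"))
  expect_equal(dim(co), c(2L, 4L))
  expect_equal(unname(co$geno["S1", ]), c(0L, 2L, NA, 2L))
  # half-call "0/." is a no-call for that sample
  expect_equal(unname(co$geno["S2", ]), c(1L, 1L, NA, 0L))
})

test_that("multi-allelic records decompose into per-allele biallelic keys", {
  path <- write_vcf_fixture(c(
    vcf_row("chr1", 100, "A", "G", "0/0", "0/1"),
    vcf_row("chr1", 200, "C", "A,T", "1/2", "0/2"),
    vcf_row("chr1", 300, "G", "A", "1/1", "0/1"),
    vcf_row("chr1", 400, "T", "C", "0/1", "0/0"),
    vcf_row("chr1", 500, "CT", "C,CTT", "1/1", "0/2")))
  co <- read_cohort_vcf(path, c(S1 = "case", S2 = "control"))
  # manual decomposition of the two multi-allelic records:
  # 200 C>A: S1 one allele-1 copy, S2 none; 200 C>T: S1 one, S2 one
  expect_equal(co$geno["S1", "chr1:200:C:A"], 1L, ignore_attr = TRUE)
  expect_equal(co$geno["S2", "chr1:200:C:A"], 0L, ignore_attr = TRUE)
  expect_equal(co$geno["S1", "chr1:200:C:T"], 1L, ignore_attr = TRUE)
  expect_equal(co$geno["S2", "chr1:200:C:T"], 1L, ignore_attr = TRUE)
  # 500 CT>C stays anchored; CT>CTT trims the shared suffix to C>CT
  expect_true(all(c("chr1:500:CT:C", "chr1:500:C:CT") %in%
                    co$variants$variant_id))
  expect_equal(co$geno["S1", "chr1:500:CT:C"], 2L, ignore_attr = TRUE)
  expect_equal(co$geno["S2", "chr1:500:C:CT"], 1L, ignore_attr = TRUE)
  # decomposition preserves total non-reference allele counts per sample
  total_alt <- rowSums(co$geno[, c("chr1:200:C:A", "chr1:200:C:T")])
  expect_equal(unname(total_alt), c(2L, 1L))
})

test_that("symbolic alleles are skipped with a warning", {
  path <- write_vcf_fixture(c(
    vcf_row("chr1", 100, "A", "G", "0/1", "0/0"),
    vcf_row("chr1", 200, "C", "<DEL>", "0/1", "0/0")))
  expect_warning(co <- read_cohort_vcf(path, c(S1 = "case", S2 = "control")),
                 "symbolic")
  expect_equal(nrow(co$variants), 1L)
})

test_that("samples missing from the VCF header are an error", {
  path <- write_vcf_fixture(vcf_row("chr1", 100, "A", "G", "0/1", "0/0"))
  expect_error(read_cohort_vcf(path, c(S9 = "case")), "absent")
})

test_that("quality FORMAT threshold assigns the low tier", {
  path <- write_vcf_fixture(c(
    vcf_row("chr1", 100, "A", "G", "0/1:10", "0/1:99", format = "GT:GQ"),
    vcf_row("chr1", 200, "C", "T", "1/1:50", "0/0:3", format = "GT:GQ")))
  co <- read_cohort_vcf(path, c(S1 = "case", S2 = "control"),
                        quality_key = "GQ", quality_threshold = 20)
  expect_equal(unname(co$lowq["S1", ]), c(TRUE, FALSE))
  expect_equal(unname(co$lowq["S2", ]), c(FALSE, TRUE))
  masked <- mask_low_quality(co)
  expect_true(is.na(masked$geno["S1", 1]))
  expect_equal(masked$geno["S2", 1], 1L, ignore_attr = TRUE)
})

test_that("allele normalisation is representation-invariant", {
  v <- normalize_variant("chr1", 100, "CAT", "CGT")
  expect_equal(v$pos, 101L)
  expect_equal(v$ref, "A")
  expect_equal(v$alt, "G")
  # anchored deletion representations converge to the same key
  a <- normalize_variant("chr1", 100, "CTT", "C")
  b <- normalize_variant("chr1", 100, "CTTT", "CT")
  expect_equal(a$variant_id, b$variant_id)
  expect_error(normalize_variant("chr1", 1, "A", "N"), "non-ACGT")
})

test_that("cohort VCF writing round-trips genotypes and quality tiers", {
  set.seed(42)
  geno <- matrix(sample(c(0:2, NA), 60, replace = TRUE), nrow = 6)
  lowq <- matrix(stats::runif(60) < 0.2, nrow = 6) & !is.na(geno)
  co <- make_cohort(geno, c(rep("case", 2), rep("control", 2),
                            rep("platform_control", 2)), lowq = lowq)
  path <- tempfile(fileext = ".vcf")
  write_cohort_vcf(co, path)
  co2 <- read_cohort_vcf(path,
                         stats::setNames(co$samples$label,
                                         co$samples$sample),
                         quality_key = "GQ", quality_threshold = 20)
  expect_equal(co2$geno[rownames(co$geno), colnames(co$geno)], co$geno)
  expect_equal(co2$lowq[rownames(co$geno), colnames(co$geno)], co$lowq)
})

test_that("frequency panel reads VCF counts and TSV frequencies", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"x\">",
               "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"x\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO"), collapse = "\t"),
               "chr1\t100\t.\tA\tG\t.\tPASS\tAC=4;AN=758"), vcf)
  panel <- read_frequency_panel(vcf, n_individuals = 379)
  lk <- panel_lookup(panel, "chr1:100:A:G")
  expect_equal(lk$ac, 4L)
  expect_equal(lk$maf, 4 / 758)
  # absent variant is novel: frequency 0 over the full allele count
  nov <- panel_lookup(panel, "chr1:999:C:T")
  expect_equal(nov$ac, 0L)
  expect_equal(nov$an, 758L)

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tpos\tref\talt\tmaf", "chr1\t100\tA\tG\t0.01"), tsv)
  p2 <- read_frequency_panel(tsv, n_individuals = 379)
  expect_equal(p2$entries$ac, 8L)  # round(0.01 * 758)
  expect_equal(p2$entries$an, 758L)
  # write/read round trip preserves counts
  out <- tempfile(fileext = ".vcf")
  write_frequency_panel(p2, out)
  p3 <- read_frequency_panel(out, n_individuals = 379)
  expect_equal(p3$entries, p2$entries)
})

test_that("panel validation rejects AC > AN", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tpos\tref\talt\tmaf", "chr1\t100\tA\tG\t1.5"), tsv)
  expect_error(read_frequency_panel(tsv, n_individuals = 379), "AC exceeds")
})

test_that("known-variant sets have allele-aware set semantics", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tpos\tref\talt",
               "chr1\t100\tA\tG",
               "chr1\t100\tA\tG",      # duplicate collapses
               "chr2\t50\tC\tT",
               "chr2\t60\tCAT\tCGT"),  # normalised on read
             tsv)
  known <- read_known_variants(tsv)
  expect_length(known, 3L)
  expect_true("chr1:100:A:G" %in% known)
  expect_false("chr1:100:A:T" %in% known)  # different alt allele
  expect_true("chr2:61:A:G" %in% known)
})

test_that("variant table round-trips and reports no-call fractions", {
  tg <- toy_gene()
  geno <- rbind(c(1L, NA), c(0L, 1L), c(NA, NA), c(2L, 0L))
  co <- make_cohort(geno, c("case", "case", "control", "control"),
                    pos = c(19L, 38L), ref = c("C", "C"),
                    alt = c("T", "T"))
  ann <- annotate_cohort(co, tg$model, tg$reference)
  path <- tempfile(fileext = ".tsv")
  out <- write_variant_table(co, ann, path)
  back <- read_prefixed_tsv(path)
  expect_equal(nrow(back), nrow(out))
  expect_equal(back$category, out$category)
  expect_equal(back$gt_s001, out$gt_s001)
  # planted no-calls: 1 of 4 missing at site 1, 2 of 4 at site 2
  st <- variant_stats(co)
  expect_equal(st$nocall_fraction, c(0.25, 0.5))
  # empty annotation set yields a header-only file
  empty <- tempfile(fileext = ".tsv")
  write_variant_table(co, ann[0, ], empty)
  expect_equal(nrow(read_prefixed_tsv(empty)), 0L)
})

test_that("tidy() exposes the long genotype view", {
  co <- make_cohort(rbind(c(0L, 1L), c(NA, 2L)), c("case", "control"))
  long <- tidy(co)
  expect_equal(nrow(long), 4L)
  expect_equal(sum(!long$called), 1L)
  expect_setequal(unique(long$quality_tier), "high")
})
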