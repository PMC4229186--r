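# Hand-built single-gene reference used across consequence tests.
# Plus-strand gene on chromosome T1:
#   spacer(10) utr5(5) [ATG CGG AAA] GT..AG [GAT CAG TAC] GT..AG [CTG TAA]
#   utr3(5) spacer(10)
# CDS codons: M R K D Q Y L *  (8 codons, 24 bases over three exons)
toy_gene <- function() {
  seq1 <- paste0("AAAAAAAAAA",          # 1-10 spacer
                 "CCCCC",               # 11-15 utr5
                 "ATGCGGAAA",           # 16-24 cds exon 1
                 "GT", "TTTTTT", "AG",  # 25-34 intron 1
                 "GATCAGTAC",           # 35-43 cds exon 2
                 "GT", "CCCCCC", "AG",  # 44-53 intron 2
                 "CTGTAA",              # 54-59 cds exon 3
                 "GGGGG",               # 60-64 utr3
                 "AAAAAAAAAA")          # 65-74 spacer
  reference <- Biostrings::DNAStringSet(c(T1 = seq1))
  model <- gene_models(gene = "TOY1", transcript_id = "TOY1.t1",
                       chrom = "T1", strand = "+",
                       exon_start = list(c(11L, 35L, 54L)),
                       exon_end = list(c(24L, 43L, 64L)),
                       cds_start = 16L, cds_end = 59L)
  list(reference = reference, model = model)
}

# The same gene mirrored onto the minus strand of chromosome T2
# (reverse complement of T1); position p maps to L - p + 1.
toy_gene_minus <- function() {
  tg <- toy_gene()
  L <- Biostrings::width(tg$reference)[1]
  seq2 <- Biostrings::reverseComplement(tg$reference[[1]])
  reference <- Biostrings::DNAStringSet(c(T2 = as.character(seq2)))
  mirror <- function(v) sort(L - v + 1L)
  model <- gene_models(gene = "TOY1M", transcript_id = "TOY1M.t1",
                       chrom = "T2", strand = "-",
                       exon_start = list(mirror(c(24L, 43L, 64L))),
                       exon_end = list(mirror(c(11L, 35L, 54L))),
                       cds_start = L - 59L + 1L, cds_end = L - 16L + 1L)
  list(reference = reference, model = model, L = L)
}

comp <- c(A = "T", C = "G", G = "C", T = "A")

# mirror a plus-strand SNV onto the toy minus-strand gene
mirror_snv <- function(pos, ref, alt, L) {
  list(pos = L - pos + 1L, ref = comp[[ref]], alt = comp[[alt]])
}

# independent Fisher oracle: explicit enumeration of all tables at the
# observed margins using choose()
enum_fisher <- function(a, b, c, d, sided) {
  K <- a + c
  n1 <- a + b
  N <- a + b + c + d
  if (K == 0 || K == N || n1 == 0 || n1 == N) return(1)
  as <- max(0, K - (N - n1)):min(K, n1)
  pr <- vapply(as, function(x) {
    choose(n1, x) * choose(N - n1, K - x)
  }, numeric(1)) / choose(N, K)
  obs <- pr[as == a]
  if (sided == "one_greater") sum(pr[as >= a]) else {
    sum(pr[pr <= obs * (1 + 1e-7)])
  }
}

# closed-form boundary deviance for a gene carried by k of n1 cases (one
# distinct site each) and no controls
boundary_lrt <- function(k, n1, n0) {
  ll <- function(x, n) if (x == 0 || x == n) 0 else {
    x * log(x / n) + (n - x) * log(1 - x / n)
  }
  alt <- ll(n1 - k, n1 - k + n0)
  null <- ll(n1, n1 + n0)
  2 * (alt - null)
}

# write a small VCF from header + body lines
write_vcf_fixture <- function(body, samples = c("S1", "S2"),
                              format = "GT") {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Qual\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, ..., format = "GT") {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", format,
          unlist(list(...))), collapse = "\t")
}

# small cohort built directly from a genotype matrix
make_cohort <- function(geno, labels, chrom = "T1",
                        pos = NULL, ref = "A", alt = "G", lowq = NULL) {
  n_var <- ncol(geno)
  if (is.null(pos)) pos <- seq(100L, by = 10L, length.out = n_var)
  variants <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                             ref = ref, alt = alt)
  samples <- tibble::tibble(
    sample = sprintf("s%03d", seq_len(nrow(geno))), label = labels)
  new_cohort(variants, samples, geno, lowq)
}
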