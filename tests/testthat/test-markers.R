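test_that("MAF hand counts, including missing calls and multiallelics", {
  # all homozygous ref
  expect_equal(compute_maf(c(0L, 0L, 0L), c(0L, 0L, 0L)), 0)
  # 4 samples, 2 alt alleles of 8
  expect_equal(compute_maf(c(0L, 0L, 0L, 1L), c(0L, 0L, 1L, 0L)), 0.25)
  # (0/1, ./., 1/1): 3 alt of 4 non-missing alleles, minor allele is ref
  expect_equal(compute_maf(c(0L, NA, 1L), c(1L, NA, 1L)), 0.25)
  # multiallelic: alleles 0,1,2 with counts 3,2,1 -> largest non-major = 2/6
  expect_equal(compute_maf(c(0L, 0L, 1L), c(0L, 1L, 2L)), 2 / 6)
  expect_error(compute_maf(c(NA, NA), c(NA, NA)), "all calls missing")
})

sim_matrix <- function(n_sites, n_samples, seed, missing_rate = 0,
                       freqs = NULL) {
  set.seed(seed)
  if (is.null(freqs)) freqs <- runif(n_sites)
  sites <- data.frame(chromosome = "chr01",
                      position = sort(sample.int(1e6, n_sites)),
                      ref = "A", alt = "G", freq = freqs,
                      stringsAsFactors = FALSE)
  generate_genotypes(n_samples, sites, missing_rate = missing_rate,
                     seed = seed)
}

test_that("biallelic MAF is bounded by [0, 0.5] across simulated sites", {
  g <- sim_matrix(2000, 40, seed = 8, missing_rate = 0.05)
  maf <- site_maf(g$matrix)$maf
  expect_true(all(maf >= 0 & maf <= 0.5))
})

test_that("the MAF filter is strict, idempotent and threshold-monotone", {
  # engineered site at exactly MAF 0.2: 2 alt alleles in 10
  a1 <- matrix(c(1L, 1L, 0L, 0L, 0L), 1); a2 <- matrix(rep(0L, 5), 1)
  sites <- data.frame(chromosome = "c", position = 1L, id = ".",
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  m <- genotype_matrix(sites, paste0("s", 1:5), a1, a2)
  expect_equal(site_maf(m)$maf, 0.2)
  expect_equal(filter_snps(m, 0.2)$n_kept, 0L)  # strictly greater than

  g <- sim_matrix(500, 30, seed = 15)
  f1 <- filter_snps(g$matrix, 0.2)
  f2 <- filter_snps(f1$matrix, 0.2)
  expect_equal(f2$n_kept, f1$n_kept)
  expect_identical(f2$matrix$sites, f1$matrix$sites)
  # kept set shrinks as the threshold rises
  kept_ids <- function(thr) filter_snps(g$matrix, thr)$matrix$sites$id
  k1 <- kept_ids(0.1); k2 <- kept_ids(0.2); k3 <- kept_ids(0.35)
  expect_true(all(k2 %in% k1))
  expect_true(all(k3 %in% k2))
})

test_that("gene-SNP association uses closed bounds and matches a scan", {
  gene <- list(gene_id = "g", chromosome = "chr01", start = 1000L,
               end = 2000L)
  sites <- data.frame(chromosome = "chr01",
                      position = c(999L, 1000L, 1500L, 2000L, 2001L),
                      ref = "A", alt = "G", freq = 0.5)
  g <- generate_genotypes(4, sites, seed = 2)
  hit <- snps_in_gene(gene, g$matrix)
  expect_equal(hit$position, c(1000L, 1500L, 2000L))
  expect_equal(snps_in_gene(gene, g$matrix, flank_bp = 1L)$position,
               c(999L, 1000L, 1500L, 2000L, 2001L))

  set.seed(77)
  sites <- data.frame(chromosome = "chr01",
                      position = sort(sample.int(50000, 200)),
                      ref = "A", alt = "G", freq = 0.5)
  g <- generate_genotypes(2, sites, seed = 3)
  for (k in 1:20) {
    s <- sample.int(50000, 1); e <- s + sample.int(3000, 1)
    gene <- list(chromosome = "chr01", start = s, end = e)
    got <- snps_in_gene(gene, g$matrix)$position
    expect_equal(got, sites$position[sites$position >= s &
                                       sites$position <= e])
  }
})

test_that("flanking sequences are hand-sliceable and edge-truncated", {
  # 30 bp toy chromosome, written out explicitly
  chrom <- "TTGACCAGTCAGTCAmCCGATTGACCAGTC"
  chrom <- sub("m", "A", chrom)  # position 16 is A
  seqs <- c(chr = chrom)
  snp <- list(chromosome = "chr", position = 16L, ref = "A", alt = "G")
  rep <- flanking_sequence(snp, seqs, flank_bp = 5)
  expect_equal(rep$flank_left, substr(chrom, 11, 15))
  expect_equal(rep$flank_right, substr(chrom, 17, 21))
  expect_equal(rep$formatted, "AGTCA[A/G]CCGAT")

  # truncation: a SNP at position 3 keeps only 2 left bases
  snp3 <- list(chromosome = "chr", position = 3L, ref = "G", alt = "T")
  rep3 <- flanking_sequence(snp3, seqs, flank_bp = 1000)
  expect_equal(rep3$flank_left, "TT")
  expect_equal(nchar(rep3$flank_right), nchar(chrom) - 3L)
  # the default flank is 1 kbp
  expect_equal(formals(flanking_sequence)$flank_bp, 1000)

  expect_error(flanking_sequence(list(chromosome = "chr", position = 16L,
                                      ref = "C", alt = "G"), seqs),
               "reference mismatch")
  expect_error(flanking_sequence(snp, c(other = chrom)), "not in sequence")
})

test_that("bracket notation round-trips to the reference substring", {
  set.seed(6)
  chrom <- rand_dna(500)
  seqs <- c(c1 = chrom)
  for (pos in c(1L, 7L, 250L, 500L)) {
    ref <- substr(chrom, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    rep <- flanking_sequence(list(chromosome = "c1", position = pos,
                                  ref = ref, alt = alt), seqs,
                             flank_bp = 40)
    rebuilt <- sub("\\[([ACGT]+)/[ACGT/]+\\]", "\\1", rep$formatted)
    lo <- max(1L, pos - 40L); hi <- min(500L, pos + 40L)
    expect_equal(rebuilt, substr(chrom, lo, hi))
  }
})

test_that("sample sub-selection recomputes MAF consistently", {
  g <- sim_matrix(50, 20, seed = 44, missing_rate = 0.1)
  all_view <- marker_matrix_view(g$matrix)
  expect_equal(all_view$maf_table$maf, site_maf(g$matrix)$maf)

  set.seed(10)
  for (k in 1:10) {
    samp <- sample(g$matrix$samples, sample(5:15, 1))
    sites <- sort(sample.int(50, sample(3:40, 1)))
    v <- marker_matrix_view(g$matrix, samp, sites)
    sc <- match(samp, g$matrix$samples)
    want <- vapply(sites, function(i)
      compute_maf(g$matrix$a1[i, sc], g$matrix$a2[i, sc]), numeric(1))
    expect_equal(v$maf_table$maf, want)
  }
  # two samples homozygous alt: alt is the only allele, minor frequency 0
  a1 <- matrix(c(1L, 1L, 0L), 1); a2 <- matrix(c(1L, 1L, 0L), 1)
  sites <- data.frame(chromosome = "c", position = 5L, id = ".",
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  m <- genotype_matrix(sites, c("x", "y", "z"), a1, a2)
  v <- marker_matrix_view(m, samples = c("x", "y"))
  expect_equal(v$maf_table$maf, 0)
  expect_equal(v$text$x, "1/1")
  expect_error(marker_matrix_view(m, samples = character()), "non-empty")
})
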