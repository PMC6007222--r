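test_that("pairwise identity matches hand values and is symmetric", {
  s <- strrep("ACGTA", 4)
  expect_equal(pairwise_identity(s, s), 1.0)
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTACGTAA"), 0.9)
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
  set.seed(101)
  for (k in 1:20) {
    a <- rand_dna(sample(5:30, 1))
    b <- mutate_dna(a, runif(1, 0, 0.5))
    expect_identical(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("pairwise identity agrees with an independent quadratic DP oracle", {
  set.seed(7)
  for (k in 1:50) {
    a <- rand_dna(sample(4:30, 1))
    b <- if (runif(1) < 0.5) rand_dna(sample(4:30, 1)) else
      mutate_dna(a, runif(1, 0, 0.3))
    expect_equal(pairwise_identity(a, b), oracle_identity(a, b),
                 info = paste(a, b))
    expect_equal(pairwise_identity(a, b, "alignment_length"),
                 oracle_identity(a, b, "alignment_length"))
  }
})

test_that("alignment score agrees with a reference affine-gap aligner", {
  set.seed(12)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (k in 1:10) {
    a <- rand_dna(sample(10:40, 1))
    b <- mutate_dna(a, runif(1, 0, 0.3))
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 2, gapExtension = 1,
                                         scoreOnly = TRUE)
    expect_equal(orthomark:::align_stats_cpp(a, b)$score, ref)
  }
})

test_that("k-mer prefilter never rejects a pair at or above the cutoff", {
  expect_true(kmer_prefilter(strrep("ACGT", 20), strrep("ACGT", 20)))
  expect_false(kmer_prefilter(strrep("A", 40), strrep("C", 40),
                              word_size = 8, identity_cutoff = 0.95))
  set.seed(33)
  for (k in 1:200) {
    a <- rand_dna(sample(40:120, 1))
    b <- mutate_dna(a, runif(1, 0, 0.15))
    if (pairwise_identity(a, b) >= 0.95)
      expect_true(kmer_prefilter(a, b, 8, 0.95))
  }
})

test_that("greedy clustering handles degenerate and planted-family inputs", {
  seqs <- setNames(rep(strrep("ACGT", 30), 5), paste0("s", 1:5))
  genomes <- setNames(rep("g", 5), names(seqs))
  groups <- cluster_greedy(seqs, genomes)
  expect_equal(length(unique(groups$group_id)), 1L)
  expect_equal(nrow(groups), 5L)

  set.seed(9)
  seqs <- setNames(vapply(1:4, function(i) rand_dna(100), character(1)),
                   paste0("u", 1:4))
  groups <- cluster_greedy(seqs, setNames(rep("g", 4), names(seqs)))
  expect_equal(length(unique(groups$group_id)), 4L)

  # 3 families of seeded mutants: within-family divergence < 2%, between
  # families unrelated random sequence
  set.seed(21)
  founders <- vapply(1:3, function(i) rand_dna(500), character(1))
  seqs <- character(); fam <- integer()
  for (f in 1:3) {
    for (j in 1:7) {
      nm <- sprintf("f%d_m%d", f, j)
      seqs[[nm]] <- mutate_dna(founders[f], 0.015)
      fam[[nm]] <- f
    }
  }
  seqs <- seqs[-1]  # 20 sequences
  fam <- fam[-1]
  groups <- cluster_greedy(seqs, setNames(rep("g", 20), names(seqs)))
  expect_equal(length(unique(groups$group_id)), 3L)
  planted <- split(names(fam), fam)
  found <- split(groups$gene_id, groups$group_id)
  expect_setequal(unname(lapply(found, sort)), unname(lapply(planted, sort)))
})

test_that("clustering output is a partition satisfying the cutoff guarantee", {
  set.seed(14)
  founders <- vapply(1:4, function(i) rand_dna(sample(80:200, 1)),
                     character(1))
  seqs <- character()
  for (f in 1:4)
    for (j in 1:5)
      seqs[[sprintf("f%d_%d", f, j)]] <- mutate_dna(founders[f],
                                                    runif(1, 0, 0.08))
  genomes <- setNames(sample(c("ga", "gb"), length(seqs), TRUE), names(seqs))
  params <- clustering_params(identity_cutoff = 0.9)
  groups <- cluster_greedy(seqs, genomes, params)
  # partition of the identifier set
  expect_setequal(groups$gene_id, names(seqs))
  expect_equal(anyDuplicated(groups$gene_id), 0L)
  # every member reaches the cutoff against its representative
  for (i in seq_len(nrow(groups))) {
    expect_gte(pairwise_identity(seqs[[groups$gene_id[i]]],
                                 seqs[[groups$representative_id[i]]]), 0.9)
    expect_equal(groups$identity[i],
                 pairwise_identity(seqs[[groups$gene_id[i]]],
                                   seqs[[groups$representative_id[i]]]))
  }
  # representative is its own member at identity 1
  reps <- groups[groups$gene_id == groups$representative_id, ]
  expect_equal(reps$identity, rep(1, nrow(reps)))
})

test_that("the prefilter is admissible: enabling it never changes clusters", {
  set.seed(77)
  founders <- vapply(1:5, function(i) rand_dna(sample(50:120, 1)),
                     character(1))
  seqs <- character()
  for (f in 1:5)
    for (j in 1:6)
      seqs[[sprintf("p%d_%d", f, j)]] <- mutate_dna(founders[f],
                                                    runif(1, 0, 0.1))
  genomes <- setNames(rep("g", length(seqs)), names(seqs))
  with_pf <- cluster_greedy(seqs, genomes, use_prefilter = TRUE)
  without_pf <- cluster_greedy(seqs, genomes, use_prefilter = FALSE)
  expect_identical(with_pf, without_pf)
})

test_that("clustering is deterministic", {
  set.seed(3)
  seqs <- setNames(vapply(1:15, function(i) rand_dna(60), character(1)),
                   sprintf("d%02d", 1:15))
  genomes <- setNames(rep("g", 15), names(seqs))
  g1 <- cluster_greedy(seqs, genomes)
  g2 <- cluster_greedy(seqs[sample(15)], genomes)
  expect_identical(g1, g2)
})

test_that("cross-genome group filtering keeps only spanning groups", {
  groups <- data.frame(
    group_id = c(1L, 1L, 2L, 2L, 3L),
    representative_id = c("t1", "t1", "t2", "t2", "p9"),
    genome = c("tomato", "pepper", "tomato", "tomato", "pepper"),
    gene_id = c("t1", "p1", "t2", "t3", "p9"),
    identity = 1, stringsAsFactors = FALSE)
  kept <- cross_genome_groups(groups, "tomato", "pepper")
  expect_setequal(unique(kept$group_id), 1L)
  expect_error(cross_genome_groups(groups, "tomato", "potato"),
               "unknown genome")
})

test_that("group summaries count multi-genome membership per genome", {
  groups <- data.frame(
    group_id = c(1L, 1L, 2L, 3L, 3L),
    representative_id = c("a1", "a1", "a2", "b2", "b2"),
    genome = c("ga", "gb", "ga", "gb", "gb"),
    gene_id = c("a1", "b1", "a2", "b2", "b3"),
    identity = 1, stringsAsFactors = FALSE)
  s <- summarize_groups(groups)
  expect_equal(s$n_groups, 3L)
  expect_equal(s$n_multi_genome_groups, 1L)
  ga <- s$per_genome[s$per_genome$genome == "ga", ]
  expect_equal(ga$n_genes, 2L)
  expect_equal(ga$n_homologous, 1L)
  expect_equal(ga$pct_homologous, 50)
})
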