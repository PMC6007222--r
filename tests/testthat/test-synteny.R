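test_that("anchors carry catalog ordinals and fan out over one-to-many groups", {
  cat_a <- toy_catalog("A", c(c1 = 5L))
  cat_b <- toy_catalog("B", c(c1 = 5L))
  pairs <- data.frame(gene_a = "A_c1_g01", gene_b = "B_c1_g05",
                      stringsAsFactors = FALSE)
  anc <- make_anchors(pairs, cat_a, cat_b)
  expect_equal(anc$ord_a, 0L)
  expect_equal(anc$ord_b, 4L)

  groups <- data.frame(
    group_id = 1L, representative_id = "A_c1_g01",
    genome = c("A", "B", "B"),
    gene_id = c("A_c1_g01", "B_c1_g01", "B_c1_g02"),
    identity = 1, stringsAsFactors = FALSE)
  pairs <- ortholog_pairs(groups, "A", "B")
  expect_equal(nrow(pairs), 2L)
  anc <- make_anchors(pairs, cat_a, cat_b)
  expect_equal(nrow(anc), 2L)

  bad <- data.frame(gene_a = "A_c1_g99", gene_b = "B_c1_g01")
  expect_error(make_anchors(bad, cat_a, cat_b), "A_c1_g99")
})

test_that("anchor quality filters are strict on missing attributes", {
  anc <- toy_anchors(0:1, 0:1, identity = c(0.90, 0.97))
  expect_equal(filter_anchors(anc, identity_min = 0.95)$gene_a, "A02")
  expect_identical(filter_anchors(anc), anc)
  # a set filter fails an anchor whose attribute is absent
  anc$identity[2] <- NA_real_
  expect_message(kept <- filter_anchors(anc, identity_min = 0.5), "missing")
  expect_equal(nrow(kept), 1L)
})

test_that("a mixed 10-anchor fixture filters to the hand-enumerated survivors", {
  anc <- toy_anchors(0:9, 0:9,
                     identity = c(.99, .90, .96, NA, .98, .97, .95, .99, .96, .94),
                     e_value = c(1e-50, 1e-50, 1e-3, 1e-50, 1e-50, 1e-9,
                                 1e-50, NA, 1e-50, 1e-50),
                     coverage = c(.9, .9, .9, .9, .4, .9, .9, .9, NA, .9))
  # identity >= 0.95 drops rows 2, 10 and the NA row 4; e <= 1e-6 drops row 3
  # and the NA row 8; coverage >= 0.5 drops rows 5 and the NA row 9
  suppressMessages(
    kept <- filter_anchors(anc, e_value_max = 1e-6, identity_min = 0.95,
                           coverage_min = 0.5))
  expect_setequal(kept$gene_a, c("A01", "A06", "A07"))
})

test_that("diagonal and anti-diagonal anchors chain into single blocks", {
  res <- chain_anchors(toy_anchors(0:4, 0:4))
  expect_equal(nrow(res$blocks), 1L)
  expect_equal(res$blocks$orientation, "forward")
  expect_equal(res$blocks$n_anchors, 5L)

  res <- chain_anchors(toy_anchors(0:4, 4:0))
  expect_equal(nrow(res$blocks), 1L)
  expect_equal(res$blocks$orientation, "inverted")
  expect_equal(res$blocks$n_anchors, 5L)
  # anchors listed in chain order: ord_a increasing, ord_b decreasing
  expect_true(all(diff(res$anchors$ord_a) > 0))
  expect_true(all(diff(res$anchors$ord_b) < 0))
})

test_that("a displaced anchor is excluded from the main collinear block", {
  anc <- toy_anchors(0:5, c(0L, 1L, 9L, 3L, 4L, 5L))
  res <- chain_anchors(anc, chain_params(max_gap_genes = 10L))
  main <- res$anchors[res$anchors$block_id == 1L, ]
  expect_equal(main$ord_b, c(0L, 1L, 3L, 4L, 5L))
  expect_false(9L %in% main$ord_b)
})

test_that("the first extracted chain is optimal on random small instances", {
  set.seed(555)
  for (k in 1:30) {
    n <- sample(4:10, 1)
    anc <- toy_anchors(sample(0:14, n), sample(0:14, n))
    gap <- sample(c(2L, 5L, 10L), 1)
    res <- chain_anchors(anc, chain_params(max_gap_genes = gap,
                                           min_block_anchors = 1L))
    opt <- oracle_best_chain_len(anc$ord_a, anc$ord_b, gap)
    expect_equal(res$blocks$n_anchors[1], opt,
                 info = paste("case", k))
  }
})

test_that("blocks are anchor-disjoint and chain length is monotone in input", {
  set.seed(99)
  for (k in 1:10) {
    n <- sample(6:12, 1)
    anc <- toy_anchors(sample(0:19, n), sample(0:19, n))
    res <- chain_anchors(anc, chain_params(min_block_anchors = 1L))
    key <- paste(res$anchors$ord_a, res$anchors$ord_b)
    expect_equal(anyDuplicated(key), 0L)
    # removing anchors cannot lengthen the best chain
    sub <- anc[sample(n, n - 2L), ]
    res_sub <- chain_anchors(sub, chain_params(min_block_anchors = 1L))
    if (nrow(res_sub$blocks) > 0L)
      expect_gte(res$blocks$n_anchors[1], res_sub$blocks$n_anchors[1])
  }
})

test_that("reversing one genome's gene order swaps block orientation", {
  # when the best forward and best inverted chains tie in length the greedy
  # tie-break (forward first) legitimately breaks the mirror symmetry, so
  # only unambiguous instances are compared
  set.seed(31)
  checked <- 0L
  while (checked < 5L) {
    n <- sample(5:9, 1)
    anc <- toy_anchors(sample(0:11, n), sample(0:11, n))
    fwd <- oracle_best_chain_len(anc$ord_a, anc$ord_b, 10L, "forward")
    inv <- oracle_best_chain_len(anc$ord_a, anc$ord_b, 10L, "inverted")
    if (fwd == inv) next
    checked <- checked + 1L
    res <- chain_anchors(anc, chain_params(min_block_anchors = 2L))
    flipped <- anc
    flipped$ord_b <- max(anc$ord_b) - anc$ord_b
    res_f <- chain_anchors(flipped, chain_params(min_block_anchors = 2L))
    expect_equal(res_f$blocks$n_anchors[1], res$blocks$n_anchors[1])
    expect_equal(res_f$blocks$orientation[1],
                 ifelse(res$blocks$orientation[1] == "forward",
                        "inverted", "forward"))
    expect_setequal(
      res_f$anchors$gene_a[res_f$anchors$block_id == 1L],
      res$anchors$gene_a[res$anchors$block_id == 1L])
  }
})

test_that("block lookup by gene returns containing blocks or nothing", {
  anc <- toy_anchors(0:4, 0:4)
  res <- chain_anchors(anc)
  expect_equal(nrow(block_for_gene("A03", res)), 1L)
  expect_equal(nrow(block_for_gene("B03", res)), 1L)
  expect_equal(nrow(block_for_gene("unknown", res)), 0L)
})

test_that("window views clip at chromosome bounds and index genes from 0", {
  # 30 genes, 100 bp genes with 50 bp gaps: gene i occupies
  # [150(i-1)+51, 150(i-1)+150]
  cat_a <- toy_catalog("A", c(c1 = 30L))
  cat_b <- toy_catalog("B", c(c1 = 30L))
  pairs <- data.frame(gene_a = cat_a$genes$gene_id,
                      gene_b = cat_b$genes$gene_id,
                      stringsAsFactors = FALSE)
  res <- chain_anchors(make_anchors(pairs, cat_a, cat_b))

  wv <- window_view(cat_a, cat_b, res, "A_c1_g15", window_bp = 600)
  # midpoint of gene 15 is 150*14 + 100.5 = 2200.5; the 600 bp window is
  # [1900.5, 2500.5], overlapping genes 13..17 by interval arithmetic
  expect_equal(wv$genes_a$gene_id,
               sprintf("A_c1_g%02d", 13:17))
  expect_equal(wv$genes_a$rel_index, -2:2)
  expect_equal(wv$genes_a$rel_index[wv$genes_a$gene_id == "A_c1_g15"], 0L)
  expect_equal(wv$partner$block_id, 1L)
  expect_gt(nrow(wv$anchors), 0L)

  # centering on the first gene clips the left edge at 1
  wv1 <- window_view(cat_a, cat_b, res, "A_c1_g01", window_bp = 200000)
  expect_equal(wv1$window_start, 1)
  expect_error(window_view(cat_a, cat_b, res, "nope"), "not found")
})
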