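# Independent oracles and small fixture builders shared across tests.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

mutate_dna <- function(s, rate) {
  b <- strsplit(s, "")[[1]]
  hit <- which(runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  paste(b, collapse = "")
}

# Quadratic-time Gotoh global alignment, coded independently of the package's
# DP: full matrices, same scoring (match +1, mismatch -1, length-L gap costs
# 2 + L) and the same deterministic tie preference (aligned state, then gap
# consuming the first sequence, then gap consuming the second).
oracle_align <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  pM <- pX <- pY <- matrix(NA_integer_, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) { X[i, 1] <- -(2 + (i - 1)); pX[i, 1] <- if (i == 2) 1 else 2 }
  for (j in 2:(m + 1)) { Y[1, j] <- -(2 + (j - 1)); pY[1, j] <- if (j == 2) 1 else 3 }
  amax <- function(v) which.max(v)  # first max: M, X, Y preference
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) 1 else -1
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- amax(cand); M[i, j] <- cand[k] + s; pM[i, j] <- k
      cand <- c(M[i - 1, j] - 3, X[i - 1, j] - 1, Y[i - 1, j] - 3)
      k <- amax(cand); X[i, j] <- cand[k]; pX[i, j] <- k
      cand <- c(M[i, j - 1] - 3, X[i, j - 1] - 3, Y[i, j - 1] - 1)
      k <- amax(cand); Y[i, j] <- cand[k]; pY[i, j] <- k
    }
  }
  fin <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- amax(fin)
  score <- fin[state]
  i <- n + 1; j <- m + 1; matches <- 0; cols <- 0
  while (i > 1 || j > 1) {
    cols <- cols + 1
    if (state == 1) {
      if (av[i - 1] == bv[j - 1]) matches <- matches + 1
      state <- pM[i, j]; i <- i - 1; j <- j - 1
    } else if (state == 2) {
      state <- pX[i, j]; i <- i - 1
    } else {
      state <- pY[i, j]; j <- j - 1
    }
  }
  list(score = score, matches = matches, aln_length = cols)
}

oracle_identity <- function(a, b, denominator = "shorter_sequence") {
  # mirror the package's canonical argument order so tie-breaks agree
  if (nchar(a) < nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    tmp <- a; a <- b; b <- tmp
  }
  st <- oracle_align(a, b)
  denom <- if (denominator == "shorter_sequence") min(nchar(a), nchar(b))
  else st$aln_length
  st$matches / denom
}

# Exhaustive maximum monotone chain over all anchor subsets (both
# orientations), respecting the strictness and gap constraints. Feasibility
# of a subset is checked on its anchors sorted by ord_a.
oracle_best_chain_len <- function(oa, ob, max_gap, orientation = "both") {
  n <- length(oa)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) <= best) next
    o <- idx[order(oa[idx], ob[idx])]
    da <- diff(oa[o]); db <- diff(ob[o])
    fwd <- all(da > 0) && all(db > 0) && all(da - 1 <= max_gap) &&
      all(db - 1 <= max_gap)
    inv <- all(da > 0) && all(db < 0) && all(da - 1 <= max_gap) &&
      all(-db - 1 <= max_gap)
    ok <- switch(orientation, both = fwd || inv, forward = fwd,
                 inverted = inv)
    if (ok) best <- length(idx)
  }
  best
}

# in-memory toy catalog: evenly spaced genes on one or more chromosomes
toy_catalog <- function(genome, chrom_genes, gene_len = 100L, gap = 50L,
                        descriptions = NULL) {
  rows <- list(); k <- 0L
  for (ch in names(chrom_genes)) {
    n <- chrom_genes[[ch]]
    for (i in seq_len(n)) {
      k <- k + 1L
      start <- gap + (i - 1L) * (gene_len + gap) + 1L
      rows[[k]] <- data.frame(
        gene_id = sprintf("%s_%s_g%02d", genome, ch, i), chromosome = ch,
        start = start, end = start + gene_len - 1L, strand = "+",
        description = if (is.null(descriptions)) "" else
          descriptions[[(k - 1L) %% length(descriptions) + 1L]],
        stringsAsFactors = FALSE)
    }
  }
  gene_catalog(genome, do.call(rbind, rows))
}

# minimal in-memory anchor table
toy_anchors <- function(oa, ob, chrom_a = "c1", chrom_b = "c1",
                        identity = NA_real_, e_value = NA_real_,
                        coverage = NA_real_, span = 100L) {
  n <- length(oa)
  data.frame(gene_a = sprintf("A%02d", seq_len(n)),
             gene_b = sprintf("B%02d", seq_len(n)),
             chrom_a = chrom_a, chrom_b = chrom_b,
             ord_a = oa, ord_b = ob,
             start_a = oa * span + 1L, end_a = (oa + 1L) * span,
             start_b = ob * span + 1L, end_b = (ob + 1L) * span,
             identity = identity, e_value = e_value, coverage = coverage,
             stringsAsFactors = FALSE)
}

write_test_vcf <- function(lines, samples = c("S1", "S2")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               lines), path)
  path
}
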