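#' Chaining parameters for synteny-block detection
#'
#' @param max_gap_genes Maximum number of intervening gene ordinals allowed
#'   between consecutive anchors of a chain, on either genome. Default 10.
#' @param min_block_anchors Minimum anchors for a chain to be reported as a
#'   block. Default 3.
#' @param e_value_max,identity_min,coverage_min Optional anchor quality
#'   filters applied before chaining (see [filter_anchors()]).
#' @return A list of validated chaining parameters.
#' @export
chain_params <- function(max_gap_genes = 10L, min_block_anchors = 3L,
                         e_value_max = NULL, identity_min = NULL,
                         coverage_min = NULL) {
  if (max_gap_genes < 1L) stop("max_gap_genes must be >= 1")
  if (min_block_anchors < 1L) stop("min_block_anchors must be >= 1")
  list(max_gap_genes = as.integer(max_gap_genes),
       min_block_anchors = as.integer(min_block_anchors),
       e_value_max = e_value_max, identity_min = identity_min,
       coverage_min = coverage_min)
}

# 0-based ordinal of each gene along its chromosome, following catalog order
gene_ordinals <- function(catalog) {
  g <- catalog$genes
  ords <- integer(nrow(g))
  for (ch in unique(g$chromosome)) {
    idx <- which(g$chromosome == ch)
    ords[idx] <- seq_along(idx) - 1L
  }
  setNames(ords, g$gene_id)
}

#' Enumerate cross-genome ortholog pairs from homolog groups
#'
#' Every (genome A member, genome B member) pair inside each group spanning
#' both genomes becomes one candidate ortholog pair; a group linking one A
#' gene to k B genes fans out into k pairs (chaining later resolves which copy
#' is syntenic). When sequences are supplied, the exact pairwise identity of
#' each pair is computed; otherwise identity is `NA`.
#'
#' @param groups Group table from [cluster_greedy()].
#' @param genome_a,genome_b Genome labels.
#' @param sequences Optional named character vector covering the paired genes.
#' @return data.frame with columns gene_a, gene_b, group_id, identity,
#'   e_value, coverage.
#' @export
ortholog_pairs <- function(groups, genome_a, genome_b, sequences = NULL) {
  cg <- cross_genome_groups(groups, genome_a, genome_b)
  out <- do.call(rbind, lapply(split(cg, cg$group_id), function(gr) {
    ga <- sort(gr$gene_id[gr$genome == genome_a])
    gb <- sort(gr$gene_id[gr$genome == genome_b])
    expand.grid(gene_a = ga, gene_b = gb, KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE)[, c("gene_a", "gene_b")] |>
      transform(group_id = gr$group_id[1L])
  }))
  if (is.null(out))
    out <- data.frame(gene_a = character(), gene_b = character(),
                      group_id = integer(), stringsAsFactors = FALSE)
  out$identity <- NA_real_
  if (!is.null(sequences) && nrow(out) > 0L) {
    rep_of <- setNames(cg$representative_id, cg$gene_id)
    id_of <- setNames(cg$identity, cg$gene_id)
    out$identity <- vapply(seq_len(nrow(out)), function(i) {
      ga <- out$gene_a[i]; gb <- out$gene_b[i]
      # when one member is the group representative, the other member's
      # identity-to-representative is exactly this pair's identity
      if (rep_of[[ga]] == ga && rep_of[[gb]] == ga) return(id_of[[gb]])
      if (rep_of[[gb]] == gb && rep_of[[ga]] == gb) return(id_of[[ga]])
      pairwise_identity(sequences[[ga]], sequences[[gb]])
    }, numeric(1))
  }
  out$e_value <- NA_real_
  out$coverage <- NA_real_
  rownames(out) <- NULL
  out
}

#' Build positional anchors from ortholog pairs
#'
#' Attaches chromosome, 0-based gene ordinal and base-pair span to each
#' cross-genome ortholog pair, yielding the anchors that chaining operates on.
#'
#' @param pairs data.frame with columns gene_a, gene_b and optional identity,
#'   e_value, coverage (e.g. from [ortholog_pairs()] or an imported hit
#'   table).
#' @param catalog_a,catalog_b [gene_catalog()] objects for the two genomes.
#' @return data.frame of anchors with ordinals and coordinates on both
#'   genomes.
#' @export
make_anchors <- function(pairs, catalog_a, catalog_b) {
  ga <- catalog_a$genes; gb <- catalog_b$genes
  bad_a <- setdiff(pairs$gene_a, ga$gene_id)
  if (length(bad_a) > 0L)
    stop("gene not found in catalog '", catalog_a$genome, "': ", bad_a[1L])
  bad_b <- setdiff(pairs$gene_b, gb$gene_id)
  if (length(bad_b) > 0L)
    stop("gene not found in catalog '", catalog_b$genome, "': ", bad_b[1L])
  orda <- gene_ordinals(catalog_a)
  ordb <- gene_ordinals(catalog_b)
  ia <- match(pairs$gene_a, ga$gene_id)
  ib <- match(pairs$gene_b, gb$gene_id)
  out <- data.frame(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    chrom_a = ga$chromosome[ia], chrom_b = gb$chromosome[ib],
    ord_a = unname(orda[pairs$gene_a]), ord_b = unname(ordb[pairs$gene_b]),
    start_a = ga$start[ia], end_a = ga$end[ia],
    start_b = gb$start[ib], end_b = gb$end[ib],
    identity = if ("identity" %in% names(pairs)) pairs$identity else NA_real_,
    e_value = if ("e_value" %in% names(pairs)) pairs$e_value else NA_real_,
    coverage = if ("coverage" %in% names(pairs)) pairs$coverage else NA_real_,
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom_a, out$chrom_b, out$ord_a, out$ord_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter anchors on syntenic quality
#'
#' Keeps anchors satisfying every filter that is set: e_value <= e_value_max,
#' identity >= identity_min, coverage >= coverage_min. An anchor missing an
#' attribute passes when that filter is unset but fails when it is set
#' (strictness); the number of anchors dropped for missing attributes is
#' reported via `message()`.
#'
#' @param anchors Anchor table from [make_anchors()].
#' @param e_value_max,identity_min,coverage_min Optional thresholds.
#' @return The filtered anchor table.
#' @export
filter_anchors <- function(anchors, e_value_max = NULL, identity_min = NULL,
                           coverage_min = NULL) {
  keep <- rep(TRUE, nrow(anchors))
  missing_drop <- rep(FALSE, nrow(anchors))
  apply_one <- function(col, thr, cmp) {
    if (is.null(thr)) return()
    v <- anchors[[col]]
    absent <- is.na(v)
    fails <- absent | !cmp(v, thr)
    missing_drop <<- missing_drop | (absent & keep)
    keep <<- keep & !fails
  }
  apply_one("e_value", e_value_max, function(v, t) v <= t)
  apply_one("identity", identity_min, function(v, t) v >= t)
  apply_one("coverage", coverage_min, function(v, t) v >= t)
  n_missing <- sum(missing_drop)
  if (n_missing > 0L)
    message(n_missing, " anchor(s) dropped for missing quality attributes")
  out <- anchors[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Longest strictly-monotone chain under the gap cap, one orientation.
# `ob` is pre-negated for the inverted orientation. Returns integer vector of
# 1-based indices of the chain (deterministic: among maximum-length chains
# the one whose anchors take the smallest ord_a, then transformed ord_b, at
# every step from the start).
best_monotone_chain <- function(oa, ob, max_gap) {
  n <- length(oa)
  if (n == 0L) return(integer())
  ord <- order(oa, ob)
  oa <- oa[ord]; ob <- ob[ord]
  compat <- function(i, j) {
    oa[j] > oa[i] && ob[j] > ob[i] &&
      (oa[j] - oa[i] - 1L) <= max_gap && (ob[j] - ob[i] - 1L) <= max_gap
  }
  # longest chain starting at each anchor (scan right to left)
  L <- rep(1L, n)
  if (n > 1L) {
    for (i in (n - 1L):1L) {
      for (j in (i + 1L):n) {
        if (compat(i, j) && L[j] + 1L > L[i]) L[i] <- L[j] + 1L
      }
    }
  }
  target <- max(L)
  # smallest (oa, ob) start among maximum-length chains; indices are already
  # sorted by (oa, ob) so the first qualifying anchor wins
  cur <- which(L == target)[1L]
  chain <- cur
  remaining <- target - 1L
  while (remaining > 0L) {
    for (j in (cur + 1L):n) {
      if (L[j] == remaining && compat(cur, j)) { cur <- j; break }
    }
    chain <- c(chain, cur)
    remaining <- remaining - 1L
  }
  ord[chain]
}

#' Chain collinear anchors into synteny blocks
#'
#' Within each (chrom_a, chrom_b) pair, repeatedly extracts the
#' maximum-length strictly-monotone anchor chain (longest-increasing-
#' subsequence dynamic programming, run in the forward and inverted
#' orientations, with at most `max_gap_genes` intervening gene ordinals
#' between consecutive anchors on either genome), removes its anchors and
#' repeats until no chain reaches `min_block_anchors`. Ties between
#' equal-length chains are broken by smaller starting ord_a, then forward
#' before inverted. Duplicate (ord_a, ord_b) anchors are collapsed to the
#' first by (gene_a, gene_b) order before chaining.
#'
#' @param anchors Anchor table from [make_anchors()].
#' @param params [chain_params()]; any quality filters it carries are applied
#'   first via [filter_anchors()].
#' @return An object of class `synteny_blocks`: a list with `blocks` (one row
#'   per block: block_id, chrom_a, chrom_b, orientation, n_anchors, bp spans)
#'   and `anchors` (anchor rows keyed by block_id, in chain order).
#' @export
chain_anchors <- function(anchors, params = chain_params()) {
  anchors <- filter_anchors(anchors, params$e_value_max, params$identity_min,
                            params$coverage_min)
  anchors <- anchors[order(anchors$chrom_a, anchors$chrom_b, anchors$ord_a,
                           anchors$ord_b, anchors$gene_a, anchors$gene_b), ,
                     drop = FALSE]
  dup <- duplicated(anchors[, c("chrom_a", "chrom_b", "ord_a", "ord_b")])
  anchors <- anchors[!dup, , drop = FALSE]

  blocks <- list()
  block_anchors <- list()
  bid <- 0L
  keys <- unique(anchors[, c("chrom_a", "chrom_b")])
  keys <- keys[order(keys$chrom_a, keys$chrom_b), , drop = FALSE]
  for (k in seq_len(nrow(keys))) {
    sub <- anchors[anchors$chrom_a == keys$chrom_a[k] &
                     anchors$chrom_b == keys$chrom_b[k], , drop = FALSE]
    repeat {
      if (nrow(sub) < params$min_block_anchors) break
      fwd <- best_monotone_chain(sub$ord_a, sub$ord_b, params$max_gap_genes)
      rev <- best_monotone_chain(sub$ord_a, -sub$ord_b, params$max_gap_genes)
      use_fwd <- length(fwd) > length(rev) ||
        (length(fwd) == length(rev) &&
           sub$ord_a[fwd[1L]] <= sub$ord_a[rev[1L]])
      chain <- if (use_fwd) fwd else rev
      if (length(chain) < params$min_block_anchors) break
      bid <- bid + 1L
      picked <- sub[chain, , drop = FALSE]
      blocks[[bid]] <- data.frame(
        block_id = bid,
        chrom_a = keys$chrom_a[k], chrom_b = keys$chrom_b[k],
        orientation = if (use_fwd) "forward" else "inverted",
        n_anchors = length(chain),
        span_a_start = min(picked$start_a), span_a_end = max(picked$end_a),
        span_b_start = min(picked$start_b), span_b_end = max(picked$end_b),
        stringsAsFactors = FALSE)
      picked$block_id <- bid
      block_anchors[[bid]] <- picked
      sub <- sub[-chain, , drop = FALSE]
    }
  }
  empty_anchor <- anchors[0, , drop = FALSE]
  empty_anchor$block_id <- integer()
  structure(list(
    blocks = if (bid > 0L) do.call(rbind, blocks) else
      data.frame(block_id = integer(), chrom_a = character(),
                 chrom_b = character(), orientation = character(),
                 n_anchors = integer(), span_a_start = numeric(),
                 span_a_end = numeric(), span_b_start = numeric(),
                 span_b_end = numeric(), stringsAsFactors = FALSE),
    anchors = if (bid > 0L) {
      out <- do.call(rbind, block_anchors)
      rownames(out) <- NULL
      out
    } else empty_anchor),
    class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat("Synteny blocks: ", nrow(x$blocks), " block(s), ",
      nrow(x$anchors), " chained anchor(s)\n", sep = "")
  if (nrow(x$blocks) > 0L) print(utils::head(x$blocks, 10L))
  invisible(x)
}

#' Find the synteny blocks containing a gene
#'
#' @param gene_id A gene identifier from either genome.
#' @param blocks A `synteny_blocks` object from [chain_anchors()].
#' @return The rows of `blocks$blocks` whose anchors include the gene; zero
#'   rows means the gene is not in synteny.
#' @export
block_for_gene <- function(gene_id, blocks) {
  hit <- blocks$anchors$block_id[blocks$anchors$gene_a == gene_id |
                                   blocks$anchors$gene_b == gene_id]
  out <- blocks$blocks[blocks$blocks$block_id %in% hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Region report around a target gene
#'
#' Builds the fixed-width comparison window centred on a gene: all genome-A
#' genes overlapping `window_bp` centred on the gene's midpoint (clipped at
#' chromosome bounds), the genome-B genes of the partner region derived from
#' the containing synteny block's span, the anchors linking them, and relative
#' gene indices (..., -2, -1, 0, +1, +2, ...) with the centred gene tagged 0.
#'
#' @param catalog_a,catalog_b [gene_catalog()] objects.
#' @param blocks `synteny_blocks` from [chain_anchors()].
#' @param center_gene Gene identifier in genome A.
#' @param window_bp Window width in base pairs (default 200000, i.e. 0.2
#'   Mbp).
#' @return An object of class `window_view`.
#' @export
window_view <- function(catalog_a, catalog_b, blocks, center_gene,
                        window_bp = 200000) {
  ga <- catalog_a$genes
  ci <- match(center_gene, ga$gene_id)
  if (is.na(ci)) stop("center gene not found: ", center_gene)
  chrom <- ga$chromosome[ci]
  mid <- floor((ga$start[ci] + ga$end[ci]) / 2)
  chrom_len <- if (!is.null(catalog_a$chrom_lengths) &&
                   chrom %in% names(catalog_a$chrom_lengths))
    catalog_a$chrom_lengths[[chrom]] else max(ga$end[ga$chromosome == chrom])
  win_start <- max(1, mid - window_bp / 2)
  win_end <- min(chrom_len, mid + window_bp / 2)

  in_win <- ga$chromosome == chrom & ga$start <= win_end & ga$end >= win_start
  genes_a <- ga[in_win, , drop = FALSE]
  genes_a <- genes_a[order(genes_a$start), , drop = FALSE]
  genes_a$rel_index <- seq_len(nrow(genes_a)) -
    which(genes_a$gene_id == center_gene)

  cb <- block_for_gene(center_gene, blocks)
  if (nrow(cb) > 0L) {
    cb <- cb[1L, ]
    gb <- catalog_b$genes
    in_b <- gb$chromosome == cb$chrom_b & gb$start <= cb$span_b_end &
      gb$end >= cb$span_b_start
    genes_b <- gb[in_b, , drop = FALSE]
    genes_b <- genes_b[order(genes_b$start), , drop = FALSE]
    partner <- list(chrom = cb$chrom_b, start = cb$span_b_start,
                    end = cb$span_b_end, block_id = cb$block_id)
  } else {
    genes_b <- catalog_b$genes[0, , drop = FALSE]
    partner <- list(chrom = NA_character_, start = NA_real_, end = NA_real_,
                    block_id = NA_integer_)
  }
  rownames(genes_a) <- rownames(genes_b) <- NULL
  links <- blocks$anchors[blocks$anchors$gene_a %in% genes_a$gene_id &
                            blocks$anchors$gene_b %in% genes_b$gene_id, ,
                          drop = FALSE]
  rownames(links) <- NULL
  structure(list(center_gene = center_gene, chromosome = chrom,
                 window_start = win_start, window_end = win_end,
                 genes_a = genes_a, genes_b = genes_b, partner = partner,
                 anchors = links),
            class = "window_view")
}

#' @export
print.window_view <- function(x, ...) {
  cat("Window around ", x$center_gene, " (", x$chromosome, ":",
      x$window_start, "-", x$window_end, "): ", nrow(x$genes_a),
      " genes; partner region ",
      if (is.na(x$partner$chrom)) "none (not in synteny)" else
        paste0(x$partner$chrom, ":", x$partner$start, "-", x$partner$end),
      "; ", nrow(x$anchors), " anchor link(s)\n", sep = "")
  invisible(x)
}
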