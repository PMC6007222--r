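#' Clustering parameters for homolog-group detection
#'
#' @param identity_cutoff Minimum identity to the group representative, in
#'   (0, 1]. Default 0.95.
#' @param word_size k-mer length of the admissible prefilter; must be >= 4.
#' @param identity_denominator "shorter_sequence" (the shorter of the two
#'   sequences, the CD-HIT convention) or "alignment_length".
#' @return A list of validated clustering parameters.
#' @export
clustering_params <- function(identity_cutoff = 0.95, word_size = 8L,
                              identity_denominator = c("shorter_sequence",
                                                       "alignment_length")) {
  identity_denominator <- match.arg(identity_denominator)
  if (!(identity_cutoff > 0 && identity_cutoff <= 1))
    stop("identity_cutoff must be in (0, 1]")
  if (word_size < 4L) stop("word_size must be >= 4")
  list(identity_cutoff = identity_cutoff, word_size = as.integer(word_size),
       identity_denominator = identity_denominator)
}

#' Global-alignment sequence identity
#'
#' Aligns two nucleotide sequences globally (affine gap penalties: match +1,
#' mismatch -1, a gap of length L costs 2 + L) and returns the number of
#' matching alignment columns divided by the chosen denominator. Symmetric in
#' its arguments.
#'
#' @param seq_a,seq_b Nucleotide sequences (character scalars).
#' @param denominator "shorter_sequence" or "alignment_length".
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(seq_a, seq_b,
                              denominator = c("shorter_sequence",
                                              "alignment_length")) {
  denominator <- match.arg(denominator)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  # canonical argument order makes traceback tie-breaks symmetric
  if (nchar(seq_a) < nchar(seq_b) ||
      (nchar(seq_a) == nchar(seq_b) && seq_a > seq_b)) {
    tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp
  }
  st <- align_stats_cpp(seq_a, seq_b)
  denom <- if (denominator == "shorter_sequence")
    min(nchar(seq_a), nchar(seq_b)) else st$aln_length
  st$matches / denom
}

#' Admissible k-mer prefilter for the identity cutoff
#'
#' Fast screen run before alignment: a pair is rejected only when the number
#' of k-mers of the shorter sequence found in the other falls below the
#' minimum that any alignment at identity >= `identity_cutoff` would force
#' (`L - k(1-c)L - k + 1`, floored at 0, for shorter length L, word size k and
#' cutoff c). By construction the filter can reject only pairs that cannot
#' reach the cutoff, so enabling it never changes clustering results.
#'
#' @inheritParams pairwise_identity
#' @param word_size k-mer length (>= 4).
#' @param identity_cutoff Clustering cutoff the screen must respect.
#' @return TRUE (candidate) or FALSE (rejected).
#' @export
kmer_prefilter <- function(seq_a, seq_b, word_size = 8L,
                           identity_cutoff = 0.95) {
  if (word_size < 4L) stop("word_size must be >= 4")
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  len_short <- min(nchar(seq_a), nchar(seq_b))
  required <- floor(len_short - word_size * (1 - identity_cutoff) * len_short -
                      word_size + 1)
  if (required <= 0) return(TRUE)
  kmer_shared_cpp(seq_a, seq_b, as.integer(word_size)) >= required
}

#' Greedy incremental homolog clustering at an identity cutoff
#'
#' Groups gene sequences (possibly spanning several genomes) into homolog
#' groups the way greedy incremental clusterers do: sequences are sorted by
#' length descending (ties broken by identifier, ascending) and scanned in
#' order; each sequence joins the first existing group whose representative it
#' matches at identity >= the cutoff, otherwise it founds a new group with
#' itself as representative. Deterministic for fixed input.
#'
#' @param sequences Named character vector of sequences.
#' @param genomes Named character vector mapping every sequence identifier to
#'   its genome label.
#' @param params [clustering_params()].
#' @param use_prefilter Run the admissible k-mer screen before aligning
#'   (results are identical either way; see [kmer_prefilter()]).
#' @return A data.frame with columns group_id, representative_id, genome,
#'   gene_id, identity — one row per input sequence.
#' @export
cluster_greedy <- function(sequences, genomes,
                           params = clustering_params(),
                           use_prefilter = TRUE) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named")
  unresolved <- setdiff(names(sequences), names(genomes))
  if (length(unresolved) > 0L)
    stop("no genome label for sequence: ", unresolved[1L])
  ids <- names(sequences)
  ord <- order(-nchar(sequences), ids)
  seqs <- toupper(unname(sequences[ord]))
  ids <- ids[ord]
  res <- cluster_core_cpp(seqs, params$identity_cutoff, params$word_size,
                          if (params$identity_denominator ==
                              "shorter_sequence") 0L else 1L,
                          use_prefilter)
  out <- data.frame(group_id = res$group,
                    representative_id = ids[res$rep_index][res$group],
                    genome = unname(genomes[ids]),
                    gene_id = ids,
                    identity = res$identity,
                    stringsAsFactors = FALSE)
  out <- out[order(out$group_id, -out$identity, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict homolog groups to those spanning two genomes
#'
#' Keeps the groups with at least one member from each of the two genomes —
#' the putative-ortholog groups for that genome pair. Group order is
#' preserved.
#'
#' @param groups Group table from [cluster_greedy()].
#' @param genome_a,genome_b Genome labels.
#' @return The filtered group table.
#' @export
cross_genome_groups <- function(groups, genome_a, genome_b) {
  known <- unique(groups$genome)
  for (g in c(genome_a, genome_b))
    if (!g %in% known) stop("unknown genome label: ", g)
  keep <- vapply(split(groups$genome, groups$group_id),
                 function(gs) genome_a %in% gs && genome_b %in% gs,
                 logical(1))
  ids <- as.integer(names(keep)[keep])
  out <- groups[groups$group_id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count homolog groups and per-genome homologous genes
#'
#' Summarises a clustering: total groups, groups spanning more than one
#' genome, and per genome the number of genes whose group contains a member
#' of at least one other genome (the "homologous genes" of a cross-genome
#' comparison), with the percentage of that genome's genes.
#'
#' @param groups Group table from [cluster_greedy()].
#' @return A list with `n_groups`, `n_multi_genome_groups` and a per-genome
#'   summary data.frame.
#' @export
summarize_groups <- function(groups) {
  sizes <- split(groups$genome, groups$group_id)
  multi <- vapply(sizes, function(gs) length(unique(gs)) > 1L, logical(1))
  multi_ids <- as.integer(names(multi)[multi])
  per <- do.call(rbind, lapply(split(groups, groups$genome), function(gg) {
    n <- nrow(gg)
    nh <- sum(gg$group_id %in% multi_ids)
    data.frame(genome = gg$genome[1L], n_genes = n, n_homologous = nh,
               pct_homologous = round(100 * nh / n, 2),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(n_groups = length(sizes),
       n_multi_genome_groups = sum(multi),
       per_genome = per)
}
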