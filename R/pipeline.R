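#' Run the full ortholog-and-synteny pipeline on two genomes
#'
#' Convenience wrapper chaining the four analysis stages: greedy homolog
#' clustering at the identity cutoff, ortholog-pair anchoring, collinear
#' chaining into synteny blocks, and per-gene homology classification against
#' the derived chromosome pairing.
#'
#' @param catalog_a,catalog_b [gene_catalog()] objects.
#' @param seqs_a,seqs_b Named gene sequence vectors for the two genomes
#'   (e.g. from [read_fasta()]).
#' @param cluster_params [clustering_params()].
#' @param chaining [chain_params()].
#' @return An object of class `synteny_pipeline`: groups, anchors, blocks,
#'   pairing and the classification table.
#' @export
run_synteny_pipeline <- function(catalog_a, catalog_b, seqs_a, seqs_b,
                                 cluster_params = clustering_params(),
                                 chaining = chain_params()) {
  genomes <- c(setNames(rep(catalog_a$genome, length(seqs_a)), names(seqs_a)),
               setNames(rep(catalog_b$genome, length(seqs_b)), names(seqs_b)))
  sequences <- c(seqs_a, seqs_b)
  groups <- cluster_greedy(sequences, genomes, cluster_params)
  pairs <- ortholog_pairs(groups, catalog_a$genome, catalog_b$genome,
                          sequences)
  anchors <- make_anchors(pairs, catalog_a, catalog_b)
  blocks <- chain_anchors(anchors, chaining)
  pairing <- default_pairing(blocks,
                             chromosomes_a = unique(catalog_a$genes$chromosome))
  classification <- classify_genes(catalog_a, groups, pairing, blocks,
                                   catalog_b$genome, catalog_b)
  structure(list(groups = groups, anchors = anchors, blocks = blocks,
                 pairing = pairing, classification = classification,
                 genome_a = catalog_a$genome, genome_b = catalog_b$genome),
            class = "synteny_pipeline")
}

#' @export
print.synteny_pipeline <- function(x, ...) {
  counts <- table(factor(x$classification$category,
                         levels = c("same_chromosome", "different_chromosome",
                                    "no_homology")))
  cat("Synteny pipeline ", x$genome_a, " vs ", x$genome_b, ":\n",
      "  homolog groups: ", length(unique(x$groups$group_id)), "\n",
      "  anchors: ", nrow(x$anchors), "; blocks: ", nrow(x$blocks$blocks),
      "\n  classification: ", counts[[1L]], " same-chromosome, ",
      counts[[2L]], " different-chromosome, ", counts[[3L]],
      " no-homology\n", sep = "")
  invisible(x)
}
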