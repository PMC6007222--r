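#' Derive the default chromosome pairing from synteny blocks
#'
#' Maps each A-chromosome to the B-chromosome sharing the most chained
#' anchors with it (ties broken by lexicographic B-chromosome name). This
#' pairing is the comparison frame for same-chromosome versus
#' different-chromosome homology calls; an A-chromosome with no anchors maps
#' to `NA` and is reported via `message()`.
#'
#' @param blocks `synteny_blocks` from [chain_anchors()], or an anchor
#'   data.frame with chrom_a/chrom_b columns.
#' @param chromosomes_a Optional character vector of all A-chromosomes (so
#'   anchor-free chromosomes appear in the mapping as `NA`).
#' @return Named character vector: names are A-chromosomes, values the paired
#'   B-chromosome.
#' @export
default_pairing <- function(blocks, chromosomes_a = NULL) {
  anc <- if (inherits(blocks, "synteny_blocks")) blocks$anchors else blocks
  counts <- as.data.frame(table(anc$chrom_a, anc$chrom_b),
                          stringsAsFactors = FALSE)
  names(counts) <- c("chrom_a", "chrom_b", "n")
  counts <- counts[counts$n > 0L, , drop = FALSE]
  chroms <- sort(unique(c(counts$chrom_a, chromosomes_a)))
  pairing <- setNames(rep(NA_character_, length(chroms)), chroms)
  for (ch in chroms) {
    sub <- counts[counts$chrom_a == ch, , drop = FALSE]
    if (nrow(sub) == 0L) {
      message("chromosome '", ch, "' has no anchors; no pairing assigned")
      next
    }
    sub <- sub[order(-sub$n, sub$chrom_b), , drop = FALSE]
    pairing[[ch]] <- sub$chrom_b[1L]
  }
  pairing
}

#' Classify every genome-A gene by cross-genome homology status
#'
#' Assigns each gene of genome A exactly one category relative to the
#' chromosome pairing: `same_chromosome` (a homolog lies on the paired
#' B-chromosome; the pink class of a comparison view), `different_chromosome`
#' (homologs exist, none on the paired chromosome; navy) or `no_homology`
#' (no genome-B member shares its homolog group; mint). `in_synteny` flags
#' genes that are anchors of any synteny block.
#'
#' @param catalog_a Genome-A [gene_catalog()].
#' @param groups Group table from [cluster_greedy()].
#' @param pairing Named chromosome pairing (see [default_pairing()]).
#' @param blocks `synteny_blocks` from [chain_anchors()].
#' @param genome_b Genome-B label as used in `groups`.
#' @param catalog_b Genome-B [gene_catalog()].
#' @return data.frame with one row per genome-A gene: gene_id, chromosome,
#'   start, end, category, partner_ids (comma-joined), partner_chroms,
#'   group_id, in_synteny.
#' @export
classify_genes <- function(catalog_a, groups, pairing, blocks, genome_b,
                           catalog_b) {
  ga <- catalog_a$genes
  gb <- catalog_b$genes
  grp_of <- setNames(groups$group_id, groups$gene_id)
  b_rows <- groups[groups$genome == genome_b, , drop = FALSE]
  partners_by_group <- split(b_rows$gene_id, b_rows$group_id)
  chrom_of_b <- setNames(gb$chromosome, gb$gene_id)
  syntenic <- unique(c(blocks$anchors$gene_a))

  n <- nrow(ga)
  category <- character(n)
  partner_ids <- character(n)
  partner_chroms <- character(n)
  group_id <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    gid <- ga$gene_id[i]
    g <- grp_of[[gid]]
    partners <- if (!is.null(g)) partners_by_group[[as.character(g)]] else NULL
    if (!is.null(g)) group_id[i] <- g
    if (is.null(partners) || length(partners) == 0L) {
      category[i] <- "no_homology"
      partner_ids[i] <- ""
      partner_chroms[i] <- ""
    } else {
      partners <- sort(partners)
      pchr <- unname(chrom_of_b[partners])
      paired <- pairing[[ga$chromosome[i]]]
      category[i] <- if (!is.null(paired) && !is.na(paired) &&
                         any(pchr == paired)) "same_chromosome"
      else "different_chromosome"
      partner_ids[i] <- paste(partners, collapse = ",")
      partner_chroms[i] <- paste(pchr, collapse = ",")
    }
  }
  data.frame(gene_id = ga$gene_id, chromosome = ga$chromosome,
             start = ga$start, end = ga$end, category = category,
             partner_ids = partner_ids, partner_chroms = partner_chroms,
             group_id = group_id,
             in_synteny = ga$gene_id %in% syntenic,
             stringsAsFactors = FALSE)
}

#' Search genes by identifier (gene ID, transcript or protein alias)
#'
#' Exact, case-insensitive match against gene IDs and all aliases, so
#' transcript/protein-style identifiers (e.g. potato annotation IDs) resolve
#' to their parent gene.
#'
#' @param query Identifier to look up.
#' @param catalogs A [gene_catalog()] or list of catalogs.
#' @return data.frame of matching gene models (with a genome column); zero
#'   rows when nothing matches.
#' @export
search_by_id <- function(query, catalogs) {
  if (inherits(catalogs, "gene_catalog")) catalogs <- list(catalogs)
  q <- tolower(query)
  out <- do.call(rbind, lapply(catalogs, function(cat) {
    hits <- cat$genes$gene_id[tolower(cat$genes$gene_id) == q]
    via_alias <- cat$aliases$gene_id[tolower(cat$aliases$alias) == q]
    ids <- unique(c(hits, via_alias))
    g <- cat$genes[cat$genes$gene_id %in% ids, , drop = FALSE]
    if (nrow(g) > 0L) cbind(genome = cat$genome, g,
                            stringsAsFactors = FALSE) else NULL
  }))
  if (is.null(out))
    out <- cbind(genome = character(), catalogs[[1L]]$genes[0, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Search genes by description text
#'
#' Case-insensitive substring match on gene descriptions, sorted by genome,
#' chromosome, start.
#'
#' @param query Non-empty text to look for.
#' @inheritParams search_by_id
#' @return data.frame of matching gene models.
#' @export
search_by_description <- function(query, catalogs) {
  if (!nzchar(query)) stop("query must be non-empty")
  if (inherits(catalogs, "gene_catalog")) catalogs <- list(catalogs)
  out <- do.call(rbind, lapply(catalogs, function(cat) {
    hit <- grepl(tolower(query), tolower(cat$genes$description), fixed = TRUE)
    g <- cat$genes[hit, , drop = FALSE]
    if (nrow(g) > 0L) cbind(genome = cat$genome, g,
                            stringsAsFactors = FALSE) else NULL
  }))
  if (is.null(out))
    return(cbind(genome = character(), catalogs[[1L]]$genes[0, , drop = FALSE]))
  out <- out[order(out$genome, out$chromosome, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Search genes by chromosomal position
#'
#' Returns the genes whose closed interval \[start, end\] overlaps the query
#' interval, sorted by start.
#'
#' @param chromosome Chromosome name.
#' @param start,end Query interval (1-based inclusive, start <= end).
#' @param catalog A [gene_catalog()].
#' @return data.frame of overlapping gene models.
#' @export
search_by_position <- function(chromosome, start, end, catalog) {
  if (start > end) stop("start must be <= end")
  if (!chromosome %in% catalog$genes$chromosome &&
      !(chromosome %in% names(catalog$chrom_lengths %||% character())))
    stop("unknown chromosome: ", chromosome)
  g <- catalog$genes
  hit <- g$chromosome == chromosome & g$start <= end & g$end >= start
  out <- g[hit, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
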