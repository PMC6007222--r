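#' Read a FASTA file into a named sequence vector
#'
#' Parses a (possibly multi-record) nucleotide FASTA file. The identifier of
#' each record is the header token before the first whitespace; sequences are
#' uppercased so downstream identity computations are case-insensitive.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("failed to parse FASTA '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence identifier in '", path, "': ", dup[1L])
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    stop("empty sequence for identifier: ", ids[!nzchar(seqs)][1L])
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a gene catalog
#'
#' A gene catalog holds one genome's gene models (1-based inclusive
#' coordinates, as in GFF3), an alias table resolving transcript/protein
#' identifiers to their gene, and optional chromosome lengths. Genes are kept
#' sorted by chromosome then start.
#'
#' @param genome Genome label.
#' @param genes data.frame with columns gene_id, chromosome, start, end,
#'   strand ("+" or "-"), description.
#' @param aliases data.frame with columns alias, gene_id (may have 0 rows).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp, or
#'   NULL.
#' @return An object of class `gene_catalog`.
#' @export
gene_catalog <- function(genome, genes, aliases = NULL, chrom_lengths = NULL) {
  need <- c("gene_id", "chromosome", "start", "end", "strand", "description")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0L) stop("genes is missing columns: ",
                              paste(miss, collapse = ", "))
  if (any(genes$start < 1L)) stop("gene start < 1")
  bad <- genes$start > genes$end
  if (any(bad)) stop("gene with end < start: ", genes$gene_id[bad][1L])
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0L) stop("duplicate gene_id: ", dup[1L])
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (is.null(aliases))
    aliases <- data.frame(alias = character(), gene_id = character(),
                          stringsAsFactors = FALSE)
  if (nrow(aliases) > 0L) {
    amap <- unique(aliases[, c("alias", "gene_id")])
    if (anyDuplicated(amap$alias))
      stop("alias maps to more than one gene: ",
           amap$alias[duplicated(amap$alias)][1L])
    aliases <- amap
  }
  if (!is.null(chrom_lengths)) {
    known <- genes$chromosome %in% names(chrom_lengths)
    over <- known & genes$end > chrom_lengths[genes$chromosome]
    if (any(over, na.rm = TRUE))
      stop("gene extends past chromosome end: ", genes$gene_id[over][1L])
  }
  genes <- genes[order(genes$chromosome, genes$start, genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genome = genome, genes = genes, aliases = aliases,
                 chrom_lengths = chrom_lengths),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("Gene catalog '", x$genome, "': ", nrow(x$genes), " genes on ",
      length(unique(x$genes$chromosome)), " chromosome(s), ",
      nrow(x$aliases), " aliases\n", sep = "")
  invisible(x)
}

# Raw pre-scan of GFF3 coordinate sanity; keeps the hard-error contract
# independent of the backend parser's wording.
gff3_scan <- function(path) {
  lines <- readLines(path)
  fasta_at <- which(lines == "##FASTA")
  if (length(fasta_at) > 0L) lines <- lines[seq_len(fasta_at[1L] - 1L)]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) return(invisible(NULL))
  fields <- strsplit(body, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 9L
  if (any(!ok)) stop("malformed GFF3 line (fewer than 9 columns) in ", path)
  st <- as.numeric(vapply(fields, `[`, character(1), 4L))
  en <- as.numeric(vapply(fields, `[`, character(1), 5L))
  bad <- which(en < st)
  if (length(bad) > 0L)
    stop("GFF3 feature with end < start at line: ",
         body[bad[1L]])
  invisible(NULL)
}

#' Read gene models from a GFF3 file
#'
#' Loads features of `feature_type` as gene models. The `ID` attribute becomes
#' the gene identifier; `Alias`/`Name` attributes and the IDs of descendant
#' features (mRNA, CDS, ... resolved transitively through `Parent`) become
#' aliases, so transcript- or protein-style identifiers resolve to their gene
#' in searches. The description is taken from `Note`, falling back to
#' `description`, then `product`. Features of `feature_type` lacking an `ID`
#' are skipped with a warning reporting the skipped count.
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates).
#' @param feature_type Feature type to load (default "gene").
#' @param genome Genome label recorded in the catalog (default: file base
#'   name).
#' @return A [gene_catalog()].
#' @export
read_gff3 <- function(path, feature_type = "gene", genome = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  if (is.null(genome))
    genome <- sub("\\.gff3?$", "", basename(path))
  gff3_scan(path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else
    rep(NA_character_, length(gr))
  is_feat <- as.character(md$type) == feature_type
  feat_idx <- which(is_feat)
  no_id <- feat_idx[is.na(ids[feat_idx])]
  if (length(no_id) > 0L) {
    warning("skipped ", length(no_id), " '", feature_type,
            "' feature(s) without an ID attribute")
    feat_idx <- setdiff(feat_idx, no_id)
  }
  if (length(feat_idx) == 0L)
    stop("no usable '", feature_type, "' features in ", path)
  gene_ids <- ids[feat_idx]

  first_of <- function(col) {
    if (!col %in% names(md)) return(rep(NA_character_, length(gr)))
    v <- md[[col]]
    if (methods::is(v, "List") || is.list(v))
      vapply(v, function(x) if (length(x) > 0L) as.character(x[1L])
             else NA_character_, character(1))
    else as.character(v)
  }
  desc <- first_of("Note")
  for (fb in c("description", "product")) {
    alt <- first_of(fb)
    desc <- ifelse(is.na(desc), alt, desc)
  }

  # transitively resolve each identified feature to its gene-level ancestor
  parent1 <- first_of("Parent")
  names(parent1) <- ids
  ancestor <- function(id) {
    seen <- character()
    cur <- id
    while (!is.na(cur) && !cur %in% gene_ids && !cur %in% seen) {
      seen <- c(seen, cur)
      cur <- if (cur %in% names(parent1)) parent1[[cur]] else NA_character_
    }
    if (!is.na(cur) && cur %in% gene_ids) cur else NA_character_
  }
  child_idx <- which(!is.na(ids) & !is.na(parent1) & !is_feat)
  al_alias <- character(); al_gene <- character()
  for (i in child_idx) {
    g <- ancestor(ids[i])
    if (!is.na(g)) { al_alias <- c(al_alias, ids[i]); al_gene <- c(al_gene, g) }
  }
  for (col in c("Alias", "Name")) {
    if (!col %in% names(md)) next
    v <- md[[col]]
    for (k in seq_along(feat_idx)) {
      i <- feat_idx[k]
      vals <- as.character(unlist(v[i]))
      vals <- vals[!is.na(vals) & nzchar(vals) & vals != gene_ids[k]]
      if (length(vals) > 0L) {
        al_alias <- c(al_alias, vals)
        al_gene <- c(al_gene, rep(gene_ids[k], length(vals)))
      }
    }
  }
  aliases <- unique(data.frame(alias = al_alias, gene_id = al_gene,
                               stringsAsFactors = FALSE))

  genes <- data.frame(
    gene_id = gene_ids,
    chromosome = as.character(GenomicRanges::seqnames(gr))[feat_idx],
    start = GenomicRanges::start(gr)[feat_idx],
    end = GenomicRanges::end(gr)[feat_idx],
    strand = ifelse(as.character(GenomicRanges::strand(gr))[feat_idx] == "-",
                    "-", "+"),
    description = ifelse(is.na(desc[feat_idx]), "", desc[feat_idx]),
    stringsAsFactors = FALSE)
  sl <- GenomeInfoDb::seqlengths(gr)
  chrom_lengths <- if (all(is.na(sl))) NULL else sl[!is.na(sl)]
  gene_catalog(genome, genes, aliases, chrom_lengths)
}

#' Write a gene catalog to GFF3
#'
#' Emits one `gene` line per gene model (with `ID` and `Note`) and one `mRNA`
#' child line per alias, so that re-reading with [read_gff3()] reproduces the
#' catalog's gene models and alias table.
#'
#' @param catalog A [gene_catalog()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  g <- catalog$genes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(catalog$chrom_lengths))
    writeLines(sprintf("##sequence-region %s 1 %d",
                       names(catalog$chrom_lengths),
                       as.integer(catalog$chrom_lengths)), con)
  esc <- function(x) gsub("[;=,\t\n]", "_", x)
  for (i in seq_len(nrow(g))) {
    attrs <- paste0("ID=", g$gene_id[i])
    if (nzchar(g$description[i]))
      attrs <- paste0(attrs, ";Note=", esc(g$description[i]))
    writeLines(paste(g$chromosome[i], "orthomark", "gene", g$start[i],
                     g$end[i], ".", g$strand[i], ".", attrs, sep = "\t"), con)
    als <- catalog$aliases$alias[catalog$aliases$gene_id == g$gene_id[i]]
    for (a in als)
      writeLines(paste(g$chromosome[i], "orthomark", "mRNA", g$start[i],
                       g$end[i], ".", g$strand[i], ".",
                       paste0("ID=", a, ";Parent=", g$gene_id[i]),
                       sep = "\t"), con)
  }
  invisible(path)
}

#' Construct a genotype matrix
#'
#' Holds diploid calls for a panel of samples at a list of variant sites.
#' Allele indices follow VCF convention: 0 = REF, 1.. = ALT alleles; missing
#' calls are `NA` and are excluded from all frequency denominators.
#'
#' @param sites data.frame with columns chromosome, position, id, ref, alt
#'   (comma-separated for multiallelic sites).
#' @param samples Character vector of sample labels.
#' @param a1,a2 Integer matrices (sites x samples) of the two allele indices
#'   per call; `NA` marks a missing call.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, samples, a1, a2) {
  need <- c("chromosome", "position", "id", "ref", "alt")
  miss <- setdiff(need, names(sites))
  if (length(miss) > 0L) stop("sites is missing columns: ",
                              paste(miss, collapse = ", "))
  if (length(samples) == 0L) stop("genotype matrix has no samples")
  if (!all(dim(a1) == c(nrow(sites), length(samples))) ||
      !all(dim(a2) == dim(a1)))
    stop("call matrices must be |sites| x |samples|")
  if (any(sites$position < 1L)) stop("site position < 1")
  same <- mapply(function(r, a) r %in% strsplit(a, ",", fixed = TRUE)[[1L]],
                 sites$ref, sites$alt)
  if (any(same))
    stop("REF equals an ALT allele at ", sites$chromosome[same][1L], ":",
         sites$position[same][1L])
  n_alleles <- 1L + lengths(strsplit(sites$alt, ",", fixed = TRUE))
  if (any(a1 >= n_alleles | a2 >= n_alleles, na.rm = TRUE) ||
      any(a1 < 0L | a2 < 0L, na.rm = TRUE))
    stop("allele index outside the site's allele list")
  rownames(sites) <- NULL
  structure(list(sites = sites, samples = samples, a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix: ", nrow(x$sites), " sites x ", length(x$samples),
      " samples (", round(100 * mean(is.na(x$a1)), 2), "% missing)\n",
      sep = "")
  invisible(x)
}

#' Read a VCF into a genotype matrix
#'
#' Loads diploid GT calls from a VCF 4.x file. Biallelic and multiallelic
#' records are kept; missing calls (`./.`) are preserved as `NA` and excluded
#' from downstream frequency denominators. Positions are 1-based.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-record files drop to a named vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(v@gt) == 0L || ncol(v@gt) < 2L)
    stop("VCF has no sample columns: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  sites <- data.frame(chromosome = fix$CHROM,
                      position = as.integer(fix$POS),
                      id = ifelse(is.na(fix$ID), ".", fix$ID),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  samples <- colnames(gt)
  split_calls <- function(slot) {
    m <- matrix(NA_integer_, nrow(sites), length(samples))
    vals <- sub("[/|].*$", "", gt)
    if (slot == 2L) vals <- sub("^[^/|]*[/|]", "", gt)
    vals[vals == "."] <- NA
    m[] <- suppressWarnings(as.integer(vals))
    m
  }
  a1 <- split_calls(1L)
  a2 <- split_calls(2L)
  genotype_matrix(sites, samples, a1, a2)
}

#' Write rows to a TSV or JSON table
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @param format "tsv" or "json".
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  ok <- tryCatch({
    if (format == "tsv")
      utils::write.table(rows, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")
    else
      jsonlite::write_json(rows, path, dataframe = "rows", digits = NA,
                           na = "null")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write table to: ", path)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path Input path.
#' @param format "tsv" or "json".
#' @return A data.frame.
#' @export
read_table_file <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("table file not found: ", path)
  if (format == "tsv")
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  else
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
}

#' Read a precomputed pairwise-hit table
#'
#' Imports an external similarity-search result (e.g. from BLAST tabular
#' output reformatted to the expected schema) for use as anchor quality
#' evidence.
#'
#' @param path TSV with columns query_id, subject_id, identity (0-100),
#'   alignment_length, e_value, query_coverage (0-100).
#' @return A data.frame with identity and coverage rescaled to fractions.
#' @export
read_hit_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_id", "subject_id", "identity", "alignment_length",
            "e_value", "query_coverage")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("hit table is missing columns: ", paste(miss, collapse = ", "))
  tab$identity <- tab$identity / 100
  tab$query_coverage <- tab$query_coverage / 100
  tab
}
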