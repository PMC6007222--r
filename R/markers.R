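#' Minor allele frequency of one site
#'
#' Computes allele frequencies over the non-missing alleles of a site (each
#' diploid call contributes two) and returns the frequency of the
#' second-most-frequent allele — for multiallelic sites, the largest
#' non-major frequency. Biallelic sites therefore always yield a value in
#' \[0, 0.5\].
#'
#' @param a1,a2 Integer vectors of the two allele indices per sample (`NA` =
#'   missing call).
#' @return MAF as a fraction.
#' @export
compute_maf <- function(a1, a2) {
  alleles <- c(a1, a2)
  alleles <- alleles[!is.na(alleles)]
  if (length(alleles) == 0L)
    stop("MAF undefined: all calls missing at this site")
  freq <- sort(tabulate(alleles + 1L) / length(alleles), decreasing = TRUE)
  if (length(freq) < 2L) 0 else freq[2L]
}

#' Per-site minor allele frequencies of a genotype matrix
#'
#' @param matrix A [genotype_matrix()].
#' @return data.frame with chromosome, position, id, maf, n_called (diploid
#'   calls used).
#' @export
site_maf <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  n <- nrow(matrix$sites)
  maf <- numeric(n)
  n_called <- integer(n)
  for (i in seq_len(n)) {
    maf[i] <- compute_maf(matrix$a1[i, ], matrix$a2[i, ])
    n_called[i] <- sum(!is.na(matrix$a1[i, ]) & !is.na(matrix$a2[i, ]))
  }
  data.frame(chromosome = matrix$sites$chromosome,
             position = matrix$sites$position, id = matrix$sites$id,
             maf = maf, n_called = n_called, stringsAsFactors = FALSE)
}

#' Filter sites on minor allele frequency
#'
#' Keeps the sites whose MAF is STRICTLY greater than `maf_min` (the
#' marker-pool convention "MAF > 0.2": a site at exactly the threshold is
#' dropped). Site order is preserved.
#'
#' @param matrix A [genotype_matrix()].
#' @param maf_min MAF threshold, default 0.2.
#' @return A list: `matrix` (restricted [genotype_matrix()]), `maf_table`
#'   (per input site, with a `kept` flag), `n_kept`, `n_dropped`.
#' @export
filter_snps <- function(matrix, maf_min = 0.2) {
  tab <- site_maf(matrix)
  tab$kept <- tab$maf > maf_min
  keep <- which(tab$kept)
  kept <- genotype_matrix(matrix$sites[keep, , drop = FALSE],
                          matrix$samples,
                          matrix$a1[keep, , drop = FALSE],
                          matrix$a2[keep, , drop = FALSE])
  list(matrix = kept, maf_table = tab, n_kept = length(keep),
       n_dropped = nrow(tab) - length(keep))
}

#' SNPs located in (or near) a gene
#'
#' @param gene One row of a catalog's `genes` data.frame (or any list with
#'   gene_id, chromosome, start, end).
#' @param matrix A [genotype_matrix()].
#' @param flank_bp Extra flank around the gene to include, default 0
#'   (strictly within the gene).
#' @return The matching rows of `matrix$sites`, sorted by position.
#' @export
snps_in_gene <- function(gene, matrix, flank_bp = 0) {
  s <- matrix$sites
  hit <- s$chromosome == gene$chromosome &
    s$position >= gene$start - flank_bp &
    s$position <= gene$end + flank_bp
  out <- s[hit, , drop = FALSE]
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flanking sequence of a SNP in bracket notation
#'
#' Extracts up to `flank_bp` reference bases on each side of a variant
#' (truncated at chromosome edges) and formats the marker as
#' `LEFT[REF/ALT]RIGHT` — the plain-text form primer-design tools accept.
#' The reference base(s) at the site are validated against the chromosome
#' sequence.
#'
#' @param snp One row of a genotype matrix's `sites` (or a list with
#'   chromosome, position, ref, alt).
#' @param seqs Named character vector of chromosome sequences (e.g. from
#'   [read_fasta()]).
#' @param flank_bp Flank length, default 1000 (1 kbp).
#' @return An object of class `marker_report` with fields snp, flank_left,
#'   flank_right and formatted.
#' @export
flanking_sequence <- function(snp, seqs, flank_bp = 1000) {
  chrom <- snp$chromosome
  if (!chrom %in% names(seqs)) stop("chromosome not in sequence set: ", chrom)
  s <- seqs[[chrom]]
  pos <- snp$position
  ref <- toupper(snp$ref)
  ref_end <- pos + nchar(ref) - 1L
  if (pos < 1L || ref_end > nchar(s))
    stop("variant outside chromosome bounds at ", chrom, ":", pos)
  found <- toupper(substr(s, pos, ref_end))
  if (found != ref)
    stop("reference mismatch at ", chrom, ":", pos, " (VCF says '", ref,
         "', sequence has '", found, "')")
  left <- substr(s, max(1L, pos - flank_bp), pos - 1L)
  right <- substr(s, ref_end + 1L, min(nchar(s), ref_end + flank_bp))
  alts <- strsplit(snp$alt, ",", fixed = TRUE)[[1L]]
  bracket <- paste0("[", paste(c(ref, toupper(alts)), collapse = "/"), "]")
  structure(list(snp = snp, flank_left = toupper(left),
                 flank_right = toupper(right),
                 formatted = paste0(toupper(left), bracket, toupper(right))),
            class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat(">", x$snp$chromosome, ":", x$snp$position, " ", x$snp$ref, ">",
      x$snp$alt, "\n", x$formatted, "\n", sep = "")
  invisible(x)
}

#' Restrict a genotype matrix to selected samples and sites
#'
#' Returns the sub-matrix with MAF recomputed on the selected samples only,
#' plus a plain-text genotype table (VCF-style `a/b` calls, `./.` for
#' missing).
#'
#' @param matrix A [genotype_matrix()].
#' @param samples Sample labels to keep (default: all).
#' @param sites Integer site indices to keep (default: all).
#' @return A list: `matrix` (the sub-[genotype_matrix()]), `maf_table` (on
#'   the selection), `text` (data.frame of call strings, sites x samples).
#' @export
marker_matrix_view <- function(matrix, samples = matrix$samples,
                               sites = seq_len(nrow(matrix$sites))) {
  if (length(samples) == 0L) stop("sample selection must be non-empty")
  bad <- setdiff(samples, matrix$samples)
  if (length(bad) > 0L) stop("unknown sample: ", bad[1L])
  if (length(sites) == 0L || any(sites < 1L | sites > nrow(matrix$sites)))
    stop("site selection out of range")
  sc <- match(samples, matrix$samples)
  sub <- genotype_matrix(matrix$sites[sites, , drop = FALSE], samples,
                         matrix$a1[sites, sc, drop = FALSE],
                         matrix$a2[sites, sc, drop = FALSE])
  gt <- matrix(paste0(ifelse(is.na(sub$a1), ".", sub$a1), "/",
                      ifelse(is.na(sub$a2), ".", sub$a2)),
               nrow = nrow(sub$sites),
               dimnames = list(NULL, samples))
  text <- cbind(sub$sites[, c("chromosome", "position", "id", "ref", "alt")],
                as.data.frame(gt, stringsAsFactors = FALSE))
  rownames(text) <- NULL
  list(matrix = sub, maf_table = site_maf(sub), text = text)
}
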