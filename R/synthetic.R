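#' Parameters for the paired-genome simulator
#'
#' The defaults describe a pair of closely related diploid plant genomes with
#' conserved gene content and order: per-base divergence 2% between ortholog
#' copies (comfortably inside a 95% clustering cutoff for 1 kbp genes), a few
#' multi-gene inversions and one translocated segment — the regime the
#' pipeline is designed to resolve.
#'
#' @param n_chromosomes Number of chromosomes per genome.
#' @param genes_per_chromosome Genes per chromosome.
#' @param gene_length_bp Gene length in bp.
#' @param intergenic_bp Intergenic spacer length in bp.
#' @param divergence Per-base substitution rate between ortholog copies.
#' @param inversion_count Number of planted inversions.
#' @param inversion_length_genes Genes per inversion window.
#' @param translocation_count Number of planted translocated segments.
#' @param translocation_length_genes Genes per translocated segment.
#' @param gene_loss_fraction Fraction of genome-B genes deleted.
#' @param duplication_fraction Fraction of genome-B genes tandem-duplicated.
#' @param seed Integer seed fixing all randomness.
#' @return A validated parameter list.
#' @export
simulation_params <- function(n_chromosomes = 2L, genes_per_chromosome = 200L,
                              gene_length_bp = 1000L, intergenic_bp = 500L,
                              divergence = 0.02, inversion_count = 2L,
                              inversion_length_genes = 8L,
                              translocation_count = 1L,
                              translocation_length_genes = 5L,
                              gene_loss_fraction = 0,
                              duplication_fraction = 0, seed = 1L) {
  p <- list(n_chromosomes = as.integer(n_chromosomes),
            genes_per_chromosome = as.integer(genes_per_chromosome),
            gene_length_bp = as.integer(gene_length_bp),
            intergenic_bp = as.integer(intergenic_bp),
            divergence = divergence, inversion_count = as.integer(inversion_count),
            inversion_length_genes = as.integer(inversion_length_genes),
            translocation_count = as.integer(translocation_count),
            translocation_length_genes = as.integer(translocation_length_genes),
            gene_loss_fraction = gene_loss_fraction,
            duplication_fraction = duplication_fraction,
            seed = as.integer(seed))
  rates <- c(p$divergence, p$gene_loss_fraction, p$duplication_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates/fractions must be in [0, 1]")
  if (any(c(p$inversion_count, p$translocation_count) < 0L))
    stop("event counts must be >= 0")
  if (p$inversion_count > 0L &&
      p$inversion_length_genes > p$genes_per_chromosome)
    stop("inversion longer than a chromosome")
  if (p$translocation_count > 0L &&
      (p$translocation_length_genes > p$genes_per_chromosome ||
         p$n_chromosomes < 2L))
    stop("translocation needs >= 2 chromosomes and a segment that fits")
  p
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# substitute each base independently at `rate`, always to a different base
mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  bases <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

# pick `count` non-overlapping ordinal windows of `len` genes; returns a list
# of integer vectors (may error out if the windows cannot be placed)
pick_windows <- function(n_genes, len, count, used) {
  wins <- list()
  for (k in seq_len(count)) {
    ok <- FALSE
    for (try in 1:200) {
      s <- sample.int(n_genes - len + 1L, 1L)
      w <- s:(s + len - 1L)
      if (!any(w %in% used)) { used <- c(used, w); wins[[k]] <- w; ok <- TRUE
        break }
    }
    if (!ok) stop("could not place a non-overlapping event window")
  }
  list(windows = wins, used = used)
}

#' Generate a synthetic genome pair with planted homology and rearrangements
#'
#' Genome A is built from seeded random sequence with evenly spaced
#' single-exon gene models. Genome B is derived from it by per-base
#' substitution at the divergence rate, followed by the requested inversions
#' (a window of genes reversed in order with strands flipped), whole-segment
#' translocations to another chromosome, gene losses and tandem duplications.
#' Every event is recorded in the ground-truth object. Identical parameters
#' and seed give byte-identical outputs.
#'
#' @param params [simulation_params()].
#' @param outdir Optional directory; when given, gene FASTA, chromosome
#'   FASTA, GFF3 for both genomes and the truth JSON are written there.
#' @return An object of class `synthetic_genome_pair`: catalogs, gene and
#'   chromosome sequence sets for both genomes, and `truth` (ortholog map,
#'   planted inversion/translocation records, chromosome correspondence).
#' @export
generate_genome_pair <- function(params = simulation_params(),
                                 outdir = NULL) {
  set.seed(params$seed)
  nchr <- params$n_chromosomes
  npg <- params$genes_per_chromosome
  glen <- params$gene_length_bp
  ig <- params$intergenic_bp
  chroms <- sprintf("chr%02d", seq_len(nchr))

  # --- genome A ---
  genes_a <- list()   # per chromosome: data.frame(id, seq, strand)
  for (c in seq_len(nchr)) {
    ids <- sprintf("GA_%02d_%04d", c, seq_len(npg))
    seqs <- vapply(seq_len(npg), function(i) random_dna(glen), character(1))
    strands <- sample(c("+", "-"), npg, replace = TRUE)
    genes_a[[c]] <- data.frame(id = ids, seq = seqs, strand = strands,
                               stringsAsFactors = FALSE)
  }

  # --- genome B gene lists (start as mutated 1:1 copies) ---
  genes_b <- lapply(seq_len(nchr), function(c) {
    g <- genes_a[[c]]
    data.frame(id = sub("^GA_", "GB_", g$id), source_a = g$id,
               seq = vapply(g$seq, mutate_seq, character(1),
                            rate = params$divergence, USE.NAMES = FALSE),
               strand = g$strand, stringsAsFactors = FALSE)
  })

  inversions <- list()
  translocations <- list()
  used <- lapply(seq_len(nchr), function(c) integer())

  if (params$inversion_count > 0L) {
    inv_chr <- sample.int(nchr, params$inversion_count, replace = TRUE)
    for (k in seq_len(params$inversion_count)) {
      c <- inv_chr[k]
      pw <- pick_windows(nrow(genes_b[[c]]), params$inversion_length_genes,
                         1L, used[[c]])
      used[[c]] <- pw$used
      w <- pw$windows[[1L]]
      seg <- genes_b[[c]][w, , drop = FALSE]
      seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
      seg$strand <- ifelse(seg$strand == "+", "-", "+")
      genes_b[[c]][w, ] <- seg
      inversions[[k]] <- data.frame(
        chromosome = chroms[c], ord_start = w[1L] - 1L,
        ord_end = w[length(w)] - 1L, length = length(w),
        genes_a = paste(sort(seg$source_a), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }

  if (params$translocation_count > 0L) {
    for (k in seq_len(params$translocation_count)) {
      from <- sample.int(nchr, 1L)
      to <- if (nchr == 2L) 3L - from else
        sample(setdiff(seq_len(nchr), from), 1L)
      pw <- pick_windows(nrow(genes_b[[from]]),
                         params$translocation_length_genes, 1L, used[[from]])
      w <- pw$windows[[1L]]
      seg <- genes_b[[from]][w, , drop = FALSE]
      genes_b[[from]] <- genes_b[[from]][-w, , drop = FALSE]
      genes_b[[to]] <- rbind(genes_b[[to]], seg)
      # ordinals on `from` shifted; previously used windows there stay valid
      # only as gene identities, so track by dropping reuse of that chromosome
      used[[from]] <- c(used[[from]], w)
      translocations[[k]] <- data.frame(
        from_chrom = chroms[from], to_chrom = chroms[to],
        length = length(w),
        genes_a = paste(sort(seg$source_a), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }

  status <- setNames(rep("one_to_one", nchr * npg),
                     unlist(lapply(genes_a, `[[`, "id")))
  if (params$gene_loss_fraction > 0) {
    all_b <- do.call(rbind, genes_b)
    protected <- unlist(lapply(c(inversions, translocations),
                               function(e) strsplit(e$genes_a, ",")[[1L]]))
    candidates <- setdiff(all_b$source_a, protected)
    n_lose <- round(params$gene_loss_fraction * length(candidates))
    lost <- sample(candidates, n_lose)
    status[lost] <- "lost"
    for (c in seq_len(nchr))
      genes_b[[c]] <- genes_b[[c]][!genes_b[[c]]$source_a %in% lost, ,
                                   drop = FALSE]
  }
  if (params$duplication_fraction > 0) {
    for (c in seq_len(nchr)) {
      g <- genes_b[[c]]
      n_dup <- round(params$duplication_fraction * nrow(g))
      if (n_dup == 0L) next
      dup_at <- sort(sample.int(nrow(g), n_dup))
      status[g$source_a[dup_at]] <- "duplicated"
      rows <- lapply(seq_len(nrow(g)), function(i) {
        r <- g[i, , drop = FALSE]
        if (i %in% dup_at) {
          d <- r; d$id <- paste0(r$id, "_d1")
          rbind(r, d)
        } else r
      })
      genes_b[[c]] <- do.call(rbind, rows)
    }
  }

  # --- assemble catalogs and chromosome sequences ---
  assemble <- function(gene_list, genome) {
    cat_rows <- list(); chrom_seqs <- character(); gene_seqs <- character()
    chrom_lengths <- numeric()
    for (c in seq_along(gene_list)) {
      g <- gene_list[[c]]
      parts <- character(0)
      pos <- 0L
      rows <- vector("list", nrow(g))
      for (i in seq_len(nrow(g))) {
        spacer <- random_dna(ig)
        parts <- c(parts, spacer)
        start <- pos + ig + 1L
        end <- start + nchar(g$seq[i]) - 1L
        pos <- end
        parts <- c(parts, if (g$strand[i] == "+") g$seq[i] else
          revcomp(g$seq[i]))
        rows[[i]] <- data.frame(gene_id = g$id[i], chromosome = chroms[c],
                                start = start, end = end,
                                strand = g$strand[i],
                                description = paste("synthetic gene",
                                                    g$id[i]),
                                stringsAsFactors = FALSE)
        gene_seqs[[g$id[i]]] <- g$seq[i]
      }
      parts <- c(parts, random_dna(ig))
      chrom_seqs[[chroms[c]]] <- paste(parts, collapse = "")
      chrom_lengths[[chroms[c]]] <- nchar(chrom_seqs[[chroms[c]]])
      cat_rows[[c]] <- do.call(rbind, rows)
    }
    list(catalog = gene_catalog(genome, do.call(rbind, cat_rows),
                                chrom_lengths = chrom_lengths),
         genes = gene_seqs, chrom_seqs = chrom_seqs)
  }
  A <- assemble(genes_a, "genomeA")
  # genome-B assembly consumes RNG (spacers); order fixed for determinism
  gb_named <- lapply(genes_b, function(g) g)
  B <- assemble(gb_named, "genomeB")

  all_b <- do.call(rbind, genes_b)
  omap <- data.frame(gene_a = all_b$source_a, gene_b = all_b$id,
                     status = ifelse(grepl("_d1$", all_b$id), "duplicated",
                                     unname(status[all_b$source_a])),
                     stringsAsFactors = FALSE)
  lost_ids <- names(status)[status == "lost"]
  if (length(lost_ids) > 0L)
    omap <- rbind(omap, data.frame(gene_a = lost_ids, gene_b = NA_character_,
                                   status = "lost", stringsAsFactors = FALSE))
  omap <- omap[order(omap$gene_a, omap$gene_b), , drop = FALSE]
  rownames(omap) <- NULL

  truth <- list(
    ortholog_map = omap,
    inversions = if (length(inversions) > 0L) do.call(rbind, inversions) else
      NULL,
    translocations = if (length(translocations) > 0L)
      do.call(rbind, translocations) else NULL,
    chromosome_pairing = setNames(chroms, chroms),
    params = params)

  pair <- structure(list(catalog_a = A$catalog, catalog_b = B$catalog,
                         genes_a = A$genes, genes_b = B$genes,
                         chrom_seq_a = A$chrom_seqs,
                         chrom_seq_b = B$chrom_seqs, truth = truth),
                    class = "synthetic_genome_pair")
  if (!is.null(outdir)) write_genome_pair(pair, outdir)
  pair
}

#' @export
print.synthetic_genome_pair <- function(x, ...) {
  tr <- x$truth
  cat("Synthetic genome pair: ", nrow(x$catalog_a$genes), " A-genes / ",
      nrow(x$catalog_b$genes), " B-genes on ",
      x$truth$params$n_chromosomes, " chromosomes; ",
      if (is.null(tr$inversions)) 0L else nrow(tr$inversions),
      " inversion(s), ",
      if (is.null(tr$translocations)) 0L else nrow(tr$translocations),
      " translocation(s)\n", sep = "")
  invisible(x)
}

#' Write a synthetic genome pair to disk
#'
#' Emits `genes_<genome>.fa` (gene sequences), `genome_<genome>.fa`
#' (chromosome sequences) and `<genome>.gff3` for both genomes, plus
#' `truth.json`.
#'
#' @param pair A `synthetic_genome_pair`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, `outdir`.
#' @export
write_genome_pair <- function(pair, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(pair$genes_a, file.path(outdir, "genes_genomeA.fa"))
  write_fasta(pair$genes_b, file.path(outdir, "genes_genomeB.fa"))
  write_fasta(pair$chrom_seq_a, file.path(outdir, "genome_genomeA.fa"))
  write_fasta(pair$chrom_seq_b, file.path(outdir, "genome_genomeB.fa"))
  write_gff3(pair$catalog_a, file.path(outdir, "genomeA.gff3"))
  write_gff3(pair$catalog_b, file.path(outdir, "genomeB.gff3"))
  jsonlite::write_json(pair$truth, file.path(outdir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(outdir)
}

#' Simulate a genotype panel at planted allele frequencies
#'
#' Draws diploid calls per sample and site by Hardy-Weinberg sampling: each
#' of the two alleles is an independent Bernoulli draw of the ALT allele at
#' the planted frequency. With `inbred = TRUE` (a recombinant-inbred-line
#' panel) one allele is drawn per sample and both haplotypes carry it, so
#' every call is homozygous. Calls are then masked missing at `missing_rate`.
#'
#' @param n_samples Number of samples.
#' @param sites data.frame with columns chromosome, position, ref, alt and
#'   freq (planted ALT allele frequency in \[0, 1\]).
#' @param missing_rate Per-call missing probability.
#' @param seed Integer seed.
#' @param inbred Simulate a fully homozygous (RIL-like) panel.
#' @param out_vcf Optional path; when given, the panel is written as a plain
#'   VCF 4.2 file.
#' @return A list: `matrix` (a [genotype_matrix()]) and `truth` (the planted
#'   site table).
#' @export
generate_genotypes <- function(n_samples, sites, missing_rate = 0,
                               seed = 1L, inbred = FALSE, out_vcf = NULL) {
  if (any(sites$freq < 0 | sites$freq > 1))
    stop("planted frequencies must be in [0, 1]")
  set.seed(seed)
  n <- nrow(sites)
  a1 <- matrix(NA_integer_, n, n_samples)
  a2 <- matrix(NA_integer_, n, n_samples)
  for (i in seq_len(n)) {
    if (inbred) {
      a <- rbinom(n_samples, 1L, sites$freq[i])
      a1[i, ] <- a; a2[i, ] <- a
    } else {
      a1[i, ] <- rbinom(n_samples, 1L, sites$freq[i])
      a2[i, ] <- rbinom(n_samples, 1L, sites$freq[i])
    }
  }
  if (missing_rate > 0) {
    mask <- matrix(runif(n * n_samples) < missing_rate, n, n_samples)
    a1[mask] <- NA_integer_
    a2[mask] <- NA_integer_
  }
  samples <- sprintf("S%03d", seq_len(n_samples))
  site_df <- data.frame(chromosome = sites$chromosome,
                        position = sites$position,
                        id = sprintf("snp%05d", seq_len(n)),
                        ref = sites$ref, alt = sites$alt,
                        stringsAsFactors = FALSE)
  gm <- genotype_matrix(site_df, samples, a1, a2)
  if (!is.null(out_vcf)) write_vcf(gm, out_vcf)
  list(matrix = gm, truth = sites)
}

#' Write a genotype matrix as a plain VCF 4.2 file
#'
#' @param matrix A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(matrix, path) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", matrix$samples), collapse = "\t")),
             con)
  gt <- matrix(paste0(ifelse(is.na(matrix$a1), ".", matrix$a1), "/",
                      ifelse(is.na(matrix$a2), ".", matrix$a2)),
               nrow = nrow(matrix$sites))
  for (i in seq_len(nrow(matrix$sites))) {
    writeLines(paste(c(matrix$sites$chromosome[i], matrix$sites$position[i],
                       matrix$sites$id[i], matrix$sites$ref[i],
                       matrix$sites$alt[i], ".", "PASS", ".", "GT",
                       gt[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}
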