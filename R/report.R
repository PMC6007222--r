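# Static SVG exports of the three comparison views. SVG text is assembled
# directly (fixed attribute order, fixed rounding) so identical inputs give
# byte-identical files; every glyph carries a class attribute that mirrors
# the backing table, keeping figures machine-checkable.

svg_open <- function(width, height) {
  sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                 'height="%d" viewBox="0 0 %d %d">'),
          width, height, width, height)
}

svg_rect <- function(x, y, w, h, class, fill, extra = "") {
  sprintf('<rect class="%s" x="%.1f" y="%.1f" width="%.1f" height="%.1f" fill="%s"%s/>',
          class, x, y, w, h, fill, extra)
}

svg_line <- function(x1, y1, x2, y2, class, stroke) {
  sprintf('<line class="%s" x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="%s"/>',
          class, x1, y1, x2, y2, stroke)
}

svg_text <- function(x, y, class, content, size = 10) {
  sprintf('<text class="%s" x="%.1f" y="%.1f" font-size="%d">%s</text>',
          class, x, y, size, content)
}

category_colors <- c(same_chromosome = "#ffc0cb",
                     different_chromosome = "#000080",
                     no_homology = "#98fb98")

write_svg <- function(lines, path) {
  if (!is.null(path)) writeLines(lines, path, sep = "\n")
  paste(lines, collapse = "\n")
}

chrom_len_of <- function(catalog, chrom) {
  if (!is.null(catalog$chrom_lengths) &&
      chrom %in% names(catalog$chrom_lengths))
    return(catalog$chrom_lengths[[chrom]])
  max(catalog$genes$end[catalog$genes$chromosome == chrom])
}

#' Whole-genome view: chromosome ideograms with target genes
#'
#' Draws one to-scale ideogram per genome-A chromosome, marks the target
#' genes with their identifiers, and returns the companion table of their
#' homology records.
#'
#' @param classification Ortholog table from [classify_genes()].
#' @param catalog_a Genome-A [gene_catalog()].
#' @param targets Character vector of target gene IDs (may be empty).
#' @param path Optional output path for the SVG.
#' @return list(svg = SVG text, table = classification rows of the targets).
#' @export
render_whole_genome <- function(classification, catalog_a,
                                targets = character(), path = NULL) {
  chroms <- sort(unique(catalog_a$genes$chromosome))
  lens <- vapply(chroms, chrom_len_of, numeric(1), catalog = catalog_a)
  scale <- 400 / max(lens)
  width <- 80L * length(chroms) + 40L
  lines <- c(svg_open(width, 480L))
  for (i in seq_along(chroms)) {
    x <- 40 + 80 * (i - 1)
    lines <- c(lines,
               svg_rect(x, 30, 18, lens[i] * scale, "chromosome", "#dddddd"),
               svg_text(x, 20, "chrom-label", chroms[i]))
  }
  for (t in targets) {
    row <- catalog_a$genes[catalog_a$genes$gene_id == t, , drop = FALSE]
    if (nrow(row) == 0L) stop("target gene not in catalog: ", t)
    i <- match(row$chromosome, chroms)
    y <- 30 + (row$start + row$end) / 2 * scale
    lines <- c(lines,
               svg_line(36 + 80 * (i - 1), y, 62 + 80 * (i - 1), y,
                        "target", "#ff0000"),
               svg_text(62 + 80 * (i - 1), y + 3, "target-label", t, 8))
  }
  lines <- c(lines, "</svg>")
  tab <- classification[classification$gene_id %in% targets, , drop = FALSE]
  rownames(tab) <- NULL
  list(svg = write_svg(lines, path), table = tab)
}

#' Chromosome comparison view: per-gene homology status columns
#'
#' One column per genome-A chromosome; every gene is drawn as a block
#' colored by its homology category (pink = homolog on the paired
#' chromosome, navy = homolog elsewhere, mint = no homolog), with target
#' genes overdrawn as red lines and a legend.
#'
#' @inheritParams render_whole_genome
#' @param pairing Chromosome pairing from [default_pairing()] (shown in the
#'   column labels).
#' @return list(svg = SVG text, table = the classification table).
#' @export
render_chromosome_comparison <- function(classification, pairing,
                                         catalog_a, targets = character(),
                                         path = NULL) {
  chroms <- sort(unique(classification$chromosome))
  lens <- vapply(chroms, chrom_len_of, numeric(1), catalog = catalog_a)
  scale <- 400 / max(lens)
  width <- 100L * length(chroms) + 160L
  lines <- c(svg_open(width, 500L))
  for (i in seq_along(chroms)) {
    x <- 40 + 100 * (i - 1)
    partner <- pairing[[chroms[i]]]
    label <- paste0(chroms[i], " / ",
                    if (is.null(partner) || is.na(partner)) "-" else partner)
    lines <- c(lines,
               svg_rect(x, 30, 24, lens[i] * scale, "chromosome", "#f5f5f5"),
               svg_text(x - 4, 20, "chrom-label", label, 9))
    sub <- classification[classification$chromosome == chroms[i], ,
                          drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      y <- 30 + sub$start[j] * scale
      h <- max(0.8, (sub$end[j] - sub$start[j]) * scale)
      lines <- c(lines,
                 svg_rect(x, y, 24, h, sub$category[j],
                          category_colors[[sub$category[j]]]))
    }
    tg <- sub[sub$gene_id %in% targets, , drop = FALSE]
    for (j in seq_len(nrow(tg))) {
      y <- 30 + (tg$start[j] + tg$end[j]) / 2 * scale
      lines <- c(lines, svg_line(x - 6, y, x + 30, y, "target", "#ff0000"))
    }
  }
  lx <- 100 * length(chroms) + 50
  leg <- names(category_colors)
  for (k in seq_along(leg)) {
    lines <- c(lines,
               svg_rect(lx, 30 + 18 * (k - 1), 12, 12, "legend",
                        category_colors[[leg[k]]]),
               svg_text(lx + 16, 40 + 18 * (k - 1), "legend-label", leg[k], 9))
  }
  lines <- c(lines, "</svg>")
  list(svg = write_svg(lines, path), table = classification)
}

#' Synteny block view: two gene tracks with anchor connectors
#'
#' Renders the region report of [window_view()] as two parallel gene tracks
#' (strand shown by arrow direction), connector lines for the anchors
#' linking them, and relative gene indices with the centred gene labeled
#' "0". The ordered gene table mirrors the figure.
#'
#' @param wv A `window_view` object.
#' @param path Optional output path for the SVG.
#' @return list(svg = SVG text, table = ordered genome-A gene table with
#'   relative indices).
#' @export
render_synteny_block <- function(wv, path = NULL) {
  width <- 800L
  xmap_a <- function(bp)
    50 + 700 * (bp - wv$window_start) /
      max(1, wv$window_end - wv$window_start)
  lines <- c(svg_open(width, 300L),
             svg_line(50, 80, 750, 80, "track-a", "#888888"),
             svg_line(50, 220, 750, 220, "track-b", "#888888"),
             svg_text(10, 84, "track-label", wv$chromosome, 9))
  ga <- wv$genes_a
  centers_a <- setNames(numeric(nrow(ga)), ga$gene_id)
  for (i in seq_len(nrow(ga))) {
    x1 <- xmap_a(max(ga$start[i], wv$window_start))
    x2 <- xmap_a(min(ga$end[i], wv$window_end))
    centers_a[i] <- (x1 + x2) / 2
    cls <- if (ga$rel_index[i] == 0L) "gene-a center" else "gene-a"
    fill <- if (ga$rel_index[i] == 0L) "#ff0000" else "#6699cc"
    arrow <- if (ga$strand[i] == "+")
      sprintf('<polygon class="%s" points="%.1f,72 %.1f,72 %.1f,76 %.1f,80 %.1f,80" fill="%s"/>',
              cls, x1, x2 - 3, x2, x2 - 3, x1, fill)
    else
      sprintf('<polygon class="%s" points="%.1f,72 %.1f,72 %.1f,80 %.1f,80 %.1f,76" fill="%s"/>',
              cls, x1 + 3, x2, x2, x1 + 3, x1, fill)
    lines <- c(lines, arrow,
               svg_text(centers_a[i] - 3, 68, "rel-index",
                        as.character(ga$rel_index[i]), 8))
  }
  gb <- wv$genes_b
  centers_b <- setNames(numeric(max(1L, nrow(gb))), gb$gene_id)
  if (nrow(gb) > 0L) {
    xmap_b <- function(bp)
      50 + 700 * (bp - wv$partner$start) /
        max(1, wv$partner$end - wv$partner$start)
    lines <- c(lines, svg_text(10, 224, "track-label", wv$partner$chrom, 9))
    for (i in seq_len(nrow(gb))) {
      x1 <- xmap_b(max(gb$start[i], wv$partner$start))
      x2 <- xmap_b(min(gb$end[i], wv$partner$end))
      centers_b[i] <- (x1 + x2) / 2
      arrow <- if (gb$strand[i] == "+")
        sprintf('<polygon class="gene-b" points="%.1f,220 %.1f,220 %.1f,224 %.1f,228 %.1f,228" fill="#99cc66"/>',
                x1, x2 - 3, x2, x2 - 3, x1)
      else
        sprintf('<polygon class="gene-b" points="%.1f,220 %.1f,220 %.1f,228 %.1f,228 %.1f,224" fill="#99cc66"/>',
                x1 + 3, x2, x2, x1 + 3, x1)
      lines <- c(lines, arrow)
    }
  }
  if (nrow(wv$anchors) > 0L && nrow(gb) > 0L) {
    for (i in seq_len(nrow(wv$anchors))) {
      xa <- centers_a[[wv$anchors$gene_a[i]]]
      xb <- centers_b[[wv$anchors$gene_b[i]]]
      lines <- c(lines, svg_line(xa, 82, xb, 218, "connector", "#bbbbbb"))
    }
  }
  lines <- c(lines, "</svg>")
  tab <- ga[, c("rel_index", "gene_id", "chromosome", "start", "end",
                "strand", "description")]
  rownames(tab) <- NULL
  list(svg = write_svg(lines, path), table = tab)
}
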