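#' @import ggplot2
#' @importFrom grDevices png dev.off
NULL

.savePlot <- function(p, path, width = 7, height = 5, dpi = 96) {
  png(path, width = width * dpi, height = height * dpi, res = dpi)
  on.exit(dev.off())
  print(p)
  invisible(path)
}

.categoryPalette <- c(CDS = "#d62728", nCDS = "#1f77b4",
                      tIG = "#9467bd", US = "#e8c60b")

#' Per-category scatter plots of methylations per gene
#'
#' One plot per feature category: gene (or intergenic interval) identifiers
#' on the y axis, number of methylations on the x axis. Every plot gets a
#' numeric TSV twin (`geneID`, `count`) so results can be checked without
#' parsing images; an empty category yields a blank plot plus an empty TSV.
#'
#' @param bedTables Named list from [makeBedTables()].
#' @param outdir Output directory.
#' @param dpi Image resolution.
#' @return Named list of `c(image, tsv)` path pairs, invisibly.
#' @export
plotScatterMeth <- function(bedTables, outdir, dpi = 96) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- lapply(names(bedTables), function(ct) {
    df <- bedTables[[ct]]
    tsv <- file.path(outdir, paste0("scatter_", ct, ".tsv"))
    write.table(df[, c("geneID", "count")], tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    img <- file.path(outdir, paste0("scatter_", ct, ".png"))
    p <- if (nrow(df)) {
      ggplot(df, aes(x = .data$count,
                     y = stats::reorder(.data$geneID, .data$count))) +
        geom_point(colour = .categoryPalette[[ct]], size = 1) +
        labs(x = "methylations", y = "geneID", title = ct) +
        theme_minimal(base_size = 9) +
        theme(axis.text.y = element_blank(), axis.ticks.y = element_blank())
    } else {
      ggplot() + labs(title = paste(ct, "(no features)")) + theme_void()
    }
    .savePlot(p, img, dpi = dpi)
    c(image = img, tsv = tsv)
  })
  invisible(stats::setNames(out, names(bedTables)))
}

#' Row-scale a count matrix to its per-row maximum
#'
#' Each row is divided by its maximum so values lie in `[0, 1]`; an
#' all-zero row stays all zero (no division blow-up).
#'
#' @param mat Numeric matrix (motifs in rows, strains/samples in columns).
#' @return Matrix of the same shape with row maxima 1 (or all-zero rows).
#' @export
scaleRowsToMax <- function(mat) {
  mx <- apply(mat, 1L, max)
  mx[mx == 0] <- 1
  sweep(mat, 1L, mx, "/")
}

#' Motif-by-strain heatmap of methylated-site counts
#'
#' Counts are scaled per motif (row) as a ratio to the row maximum, so each
#' motif's most methylated strain reads 1.0. The scaled matrix is written
#' as a TSV twin next to the image.
#'
#' @param countMatrix Numeric matrix, motifs in rows, one column per
#'   strain/run.
#' @param outdir Output directory.
#' @param dpi Image resolution.
#' @return `c(image, tsv)` paths, invisibly.
#' @export
plotMotifHeatmap <- function(countMatrix, outdir, dpi = 96) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  scaled <- scaleRowsToMax(countMatrix)
  tsv <- file.path(outdir, "motif_heatmap.tsv")
  write.table(data.frame(motif = rownames(scaled), scaled,
                         check.names = FALSE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  df <- expand.grid(motif = rownames(scaled), strain = colnames(scaled),
                    stringsAsFactors = FALSE)
  df$value <- scaled[cbind(df$motif, df$strain)]
  img <- file.path(outdir, "motif_heatmap.png")
  p <- ggplot(df, aes(x = .data$strain, y = .data$motif,
                      fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#d62728", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "ratio to\nrow max") +
    theme_minimal(base_size = 9)
  .savePlot(p, img, dpi = dpi)
  invisible(c(image = img, tsv = tsv))
}

#' Circular per-category methylation density
#'
#' Bins the genome (replicons laid head to tail around a circle) into
#' fixed windows and draws four inner rings of per-window methylation
#' counts — CDS (red), nCDS (blue), tIG (purple), US (yellow) — below an
#' outer ring marking CDS positions. The per-window count table is written
#' as a TSV twin.
#'
#' @param crossed `GRanges` from [crossMethylation()] (typically one
#'   motif's rows).
#' @param seqlengths Named replicon lengths.
#' @param genes `GRanges` of genes (outer annotation ring).
#' @param windowBp Window size in bp (default 10000).
#' @param outdir Output directory.
#' @param dpi Image resolution.
#' @return `c(image, tsv)` paths, invisibly.
#' @export
plotCircularDensity <- function(crossed, seqlengths, genes,
                                windowBp = 10000, outdir, dpi = 96) {
  stopifnot(windowBp > 0)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cats <- c("CDS", "nCDS", "tIG", "US")
  wins <- do.call(rbind, lapply(names(seqlengths), function(sq) {
    starts <- seq(1L, seqlengths[[sq]], by = windowBp)
    data.frame(seqid = sq, winStart = starts,
               winEnd = pmin(starts + windowBp - 1L, seqlengths[[sq]]),
               stringsAsFactors = FALSE)
  }))
  counts <- matrix(0L, nrow = nrow(wins), ncol = length(cats),
                   dimnames = list(NULL, cats))
  if (length(crossed)) {
    pos <- start(crossed)
    sq <- as.character(seqnames(crossed))
    wi <- match(paste0(sq, ":", ((pos - 1L) %/% windowBp) * windowBp + 1L),
                paste0(wins$seqid, ":", wins$winStart))
    tab <- table(wi, factor(mcols(crossed)$category, levels = cats))
    counts[as.integer(rownames(tab)), ] <- counts[as.integer(rownames(tab)), ,
                                                  drop = FALSE] + unclass(tab)
  }
  df <- cbind(wins, as.data.frame(counts))
  tsv <- file.path(outdir, "circular_density.tsv")
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  ## linearised genome coordinate for plotting
  offs <- c(0, cumsum(as.numeric(seqlengths)))[seq_along(seqlengths)]
  names(offs) <- names(seqlengths)
  long <- do.call(rbind, lapply(cats, function(ct)
    data.frame(x = offs[df$seqid] + (df$winStart + df$winEnd) / 2,
               width = df$winEnd - df$winStart + 1,
               count = df[[ct]], category = ct, stringsAsFactors = FALSE)))
  long$category <- factor(long$category, levels = cats)
  ring <- c(CDS = 4, nCDS = 3, tIG = 2, US = 1)
  long$base <- ring[as.character(long$category)]
  mx <- max(long$count, 1)
  long$h <- 0.8 * long$count / mx
  geneDf <- if (length(genes))
    data.frame(x = offs[as.character(seqnames(genes))] + start(genes))
  else data.frame(x = numeric(0))
  img <- file.path(outdir, "circular_density.png")
  p <- ggplot(long) +
    geom_rect(aes(xmin = .data$x - .data$width / 2,
                  xmax = .data$x + .data$width / 2,
                  ymin = .data$base, ymax = .data$base + .data$h,
                  fill = .data$category)) +
    scale_fill_manual(values = .categoryPalette) +
    coord_polar(theta = "x") +
    ylim(0, 6) +
    theme_void(base_size = 9) +
    labs(fill = NULL)
  if (nrow(geneDf))
    p <- p + geom_segment(data = geneDf,
                          aes(x = .data$x, xend = .data$x,
                              y = 5.2, yend = 5.6),
                          linewidth = 0.1)
  .savePlot(p, img, width = 6, height = 6, dpi = dpi)
  invisible(c(image = img, tsv = tsv))
}
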