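.featureGR <- function(seqid, start, end, strand, category, geneID, product,
                       orientation = NA_character_) {
  n <- length(start)
  GRanges(seqid, IRanges(start, end), strand = strand,
          category = rep_len(category, n), geneID = rep_len(geneID, n),
          product = rep_len(product, n),
          orientation = rep_len(orientation, n))
}

#' Derive CDS intervals from the annotation
#'
#' One interval per gene, with the gene's own coordinates and strand: a
#' methylation inside it on the *accordant* (sense) strand belongs to this
#' category.
#'
#' @param genes `GRanges` with `geneID`/`product` metadata.
#' @return `GRanges` with `category = "CDS"` and owner `geneID`.
#' @export
deriveCds <- function(genes) {
  if (!length(genes))
    return(.featureGR(character(0), integer(0), integer(0), character(0),
                      character(0), character(0), character(0)))
  .featureGR(as.character(seqnames(genes)), start(genes), end(genes),
             as.character(strand(genes)), "CDS", mcols(genes)$geneID,
             mcols(genes)$product)
}

#' Derive nCDS intervals (antisense coding sequence)
#'
#' The same genomic extents as the CDS intervals but on the opposite
#' strand: a methylation *discordant* with its gene's strand is counted
#' here.
#'
#' @inheritParams deriveCds
#' @return `GRanges` with `category = "nCDS"`.
#' @export
deriveNcds <- function(genes) {
  out <- deriveCds(genes)
  if (length(out)) {
    st <- as.character(strand(out))
    strand(out) <- ifelse(st == "+", "-", "+")
    mcols(out)$category <- rep("nCDS", length(out))
  }
  out
}

## Classify one inter-gene gap given its flanking genes (either may be
## missing at the replicon termini).  Same-orientation flanks make the gap
## an upstream (US) region owned by the downstream-reading gene; opposite
## orientations make it true intergenic (tIG).  Terminal gaps are US when
## the single flanking gene reads away from the replicon edge into the gap
## boundary, i.e. the gap left of a '+' first gene, or right of a '-' last
## gene; otherwise tIG.
.classifyGap <- function(gapStart, gapEnd, leftGene, rightGene, upstreamRange) {
  usRows <- NULL
  tigRows <- NULL
  addTig <- function(s, e, owner, orient) {
    if (s <= e)
      tigRows <<- rbind(tigRows, data.frame(start = s, end = e, strand = "*",
                                            geneID = owner,
                                            orientation = orient,
                                            stringsAsFactors = FALSE))
  }
  addUs <- function(s, e, owner, strand) {
    if (s > e) return()
    if (!is.null(upstreamRange)) {
      if (strand == "+") {        # owner on the right; US abuts its start
        usS <- max(s, e - upstreamRange + 1L)
        addTig(s, usS - 1L, owner, "clipped_us")
        s <- usS
      } else {                    # owner on the left; US abuts its 3'->5' start
        usE <- min(e, s + upstreamRange - 1L)
        addTig(usE + 1L, e, owner, "clipped_us")
        e <- usE
      }
    }
    usRows <<- rbind(usRows, data.frame(start = s, end = e, strand = strand,
                                        geneID = owner,
                                        orientation = NA_character_,
                                        stringsAsFactors = FALSE))
  }

  ls <- if (is.null(leftGene)) NA_character_ else leftGene$strand
  rs <- if (is.null(rightGene)) NA_character_ else rightGene$strand
  if (is.na(ls) && is.na(rs)) {           # no genes at all: whole replicon tIG
    addTig(gapStart, gapEnd, "", "no_genes")
  } else if (is.na(ls)) {                 # terminal gap before the first gene
    if (rs == "+") addUs(gapStart, gapEnd, rightGene$geneID, "+")
    else addTig(gapStart, gapEnd, rightGene$geneID, "terminal")
  } else if (is.na(rs)) {                 # terminal gap after the last gene
    if (ls == "-") addUs(gapStart, gapEnd, leftGene$geneID, "-")
    else addTig(gapStart, gapEnd, leftGene$geneID, "terminal")
  } else if (ls == rs) {                  # same orientation: upstream region
    owner <- if (ls == "+") rightGene else leftGene
    addUs(gapStart, gapEnd, owner$geneID, ls)
  } else {                                # opposite orientations: tIG
    orient <- if (ls == "+") "converging" else "diverging"
    addTig(gapStart, gapEnd,
           paste(leftGene$geneID, rightGene$geneID, sep = ","), orient)
  }
  list(us = usRows, tig = tigRows)
}

#' Derive upstream (US) and true intergenic (tIG) intervals
#'
#' Partitions the non-genic part of one replicon. Each maximal gap between
#' consecutive gene bodies (plus the two terminal gaps) is classified by
#' the orientation of its flanking genes: same orientation makes the gap an
#' upstream (US) region — strand and owner taken from the downstream gene
#' in reading orientation (the right gene for `+`, the left for `-`) —
#' while opposite orientations (converging or diverging) make it true
#' intergenic (tIG). Under a fixed upstream range, each US interval is
#' clipped to at most `upstreamRange` bp adjacent to its owner's start and
#' the remainder reclassified tIG.
#'
#' @param genes `GRanges` of genes on one replicon.
#' @param repliconLength Length of the replicon in bp.
#' @param upstreamRange `NULL` for the default full-gap mode, or a positive
#'   integer bp limit.
#' @param seqid Replicon identifier for the output (default: from `genes`).
#' @return `GRanges` of US and tIG intervals, with `category`, owner
#'   `geneID` (the two flanking geneIDs, comma-separated, for tIG) and a
#'   tIG `orientation` note (`converging`/`diverging`/`terminal`/
#'   `clipped_us`).
#' @export
deriveIntergenic <- function(genes, repliconLength, upstreamRange = NULL,
                             seqid = NULL) {
  if (!is.null(upstreamRange)) {
    upstreamRange <- as.integer(upstreamRange)
    stopifnot(upstreamRange > 0L)
  }
  if (is.null(seqid))
    seqid <- if (length(genes)) as.character(seqnames(genes))[1L] else "seq"
  emptyOut <- .featureGR(character(0), integer(0), integer(0), character(0),
                         character(0), character(0), character(0))

  gdf <- if (length(genes))
    data.frame(start = start(genes), end = end(genes),
               strand = as.character(strand(genes)),
               geneID = mcols(genes)$geneID, stringsAsFactors = FALSE)
  else data.frame(start = integer(0), end = integer(0),
                  strand = character(0), geneID = character(0))
  gdf <- gdf[order(gdf$start, gdf$end), , drop = FALSE]

  ## maximal gene-free blocks
  red <- if (nrow(gdf))
    reduce(IRanges(gdf$start, gdf$end)) else IRanges()
  bounds <- data.frame(s = c(1L, end(red) + 1L),
                       e = c(start(red) - 1L, repliconLength))
  bounds <- bounds[bounds$s <= bounds$e, , drop = FALSE]

  pickFlank <- function(gapStart, gapEnd) {
    left <- which(gdf$end == gapStart - 1L)
    right <- which(gdf$start == gapEnd + 1L)
    ## on ties (overlapping genes sharing a boundary) take the first by
    ## geneID for determinism
    pick <- function(idx) {
      if (!length(idx)) return(NULL)
      i <- idx[order(gdf$geneID[idx])][1L]
      list(strand = gdf$strand[i], geneID = gdf$geneID[i])
    }
    list(left = pick(left), right = pick(right))
  }

  us <- NULL; tig <- NULL
  for (i in seq_len(nrow(bounds))) {
    fl <- pickFlank(bounds$s[i], bounds$e[i])
    cl <- .classifyGap(bounds$s[i], bounds$e[i], fl$left, fl$right,
                       upstreamRange)
    us <- rbind(us, cl$us)
    tig <- rbind(tig, cl$tig)
  }
  mk <- function(df, category) {
    if (is.null(df) || !nrow(df)) {
      g <- emptyOut
      seqlevels(g) <- seqid
      return(g)
    }
    .featureGR(seqid, df$start, df$end, df$strand, category, df$geneID,
               "", df$orientation)
  }
  out <- c(mk(us, "US"), mk(tig, "tIG"))
  out[order(start(out))]
}

#' Partition a genome into CDS, nCDS, tIG and US feature intervals
#'
#' Applies [deriveCds()], [deriveNcds()] and [deriveIntergenic()] per
#' replicon and concatenates the results. For non-overlapping annotations
#' the CDS, US and tIG intervals tile each replicon exactly once (nCDS
#' duplicates the CDS extents on the opposite strand and is excluded from
#' the tiling).
#'
#' @param x A [MethylomeDataSet-class], or a `GRanges` of genes (then
#'   `seqlengths` must be supplied).
#' @param upstreamRange `NULL` (full-gap mode) or positive integer bp.
#' @param seqlengths Named integer vector of replicon lengths (ignored for
#'   a `MethylomeDataSet`).
#' @return `GRanges` of feature intervals with `category`, `geneID`,
#'   `product`, `orientation` metadata columns.
#' @export
partitionFeatures <- function(x, upstreamRange = NULL, seqlengths = NULL) {
  if (is(x, "MethylomeDataSet")) {
    seqlengths <- stats::setNames(Biostrings::width(genomeSeq(x)),
                                  names(genomeSeq(x)))
    genes <- geneRanges(x)
  } else {
    genes <- x
    if (is.null(seqlengths))
      stop("seqlengths required when passing a plain GRanges", call. = FALSE)
  }
  parts <- lapply(names(seqlengths), function(sq) {
    g <- genes[as.character(seqnames(genes)) == sq]
    p <- list(deriveCds(g), deriveNcds(g),
              deriveIntergenic(g, seqlengths[[sq]], upstreamRange,
                               seqid = sq))
    p <- lapply(p, function(x) { seqlevels(x) <- names(seqlengths); x })
    do.call(c, p)
  })
  out <- do.call(c, parts)
  seqlevels(out) <- names(seqlengths)
  seqlengths(out) <- seqlengths
  out
}

#' Coverage report for a feature partition
#'
#' Asserts that the strand-insensitive union of CDS, US and tIG intervals
#' covers each replicon exactly once (a gap or double cover signals a bug
#' or overlapping-gene input) and reports per-category bp totals. With
#' overlapping genes in the input the double-cover check downgrades to a
#' warning, since overlapped bp is deliberately CDS of every overlapping
#' gene.
#'
#' @param features `GRanges` from [partitionFeatures()].
#' @param seqlengths Named replicon lengths; default taken from `features`.
#' @return data.frame: one row per (seqid, category) with `bp`, plus the
#'   per-seqid covered total as attribute `covered`.
#' @export
partitionReport <- function(features, seqlengths = NULL) {
  if (is.null(seqlengths)) {
    seqlengths <- seqlengths(features)
    if (anyNA(seqlengths))
      stop("seqlengths unavailable; pass them explicitly", call. = FALSE)
  }
  cat3 <- mcols(features)$category
  tiling <- features[cat3 %in% c("CDS", "US", "tIG")]
  cdsOnly <- granges(features[cat3 == "CDS"])
  overlapping <- length(cdsOnly) > 0L &&
    sum(width(reduce(cdsOnly, ignore.strand = TRUE))) < sum(width(cdsOnly))
  flag <- function(msg) {
    if (overlapping) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  covered <- integer(0)
  for (sq in names(seqlengths)) {
    t1 <- tiling[as.character(seqnames(tiling)) == sq]
    cov <- sum(width(reduce(granges(t1), ignore.strand = TRUE)))
    tot <- sum(width(t1))
    if (cov != seqlengths[[sq]])
      flag(paste0("replicon '", sq, "': CDS+US+tIG cover ", cov, " of ",
                  seqlengths[[sq]], " bp"))
    if (tot != cov)
      flag(paste0("replicon '", sq, "': CDS/US/tIG overlap (", tot,
                  " bp of intervals over ", cov, " bp covered)"))
    covered[sq] <- cov
  }
  cats <- c("CDS", "nCDS", "tIG", "US")
  grid <- expand.grid(seqid = names(seqlengths), category = cats,
                      stringsAsFactors = FALSE)
  grid$bp <- mapply(function(sq, ct)
    sum(width(features[as.character(seqnames(features)) == sq &
                         mcols(features)$category == ct])),
    grid$seqid, grid$category)
  attr(grid, "covered") <- covered
  grid
}
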