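#' Cross methylation records with motif matches and feature intervals
#'
#' The pipeline's integration step. A methylation record enters motif M's
#' output iff its position lies inside an occurrence of M *on the record's
#' strand* (a `.`/`*` strand record matches an occurrence on either
#' strand). Category assignment is strand-aware: inside a gene body, record
#' strand equal to the gene strand gives CDS, opposite gives nCDS (an
#' unstranded record counts as accordant); outside genes, a same-strand US
#' interval containing the position gives US, anything else tIG. A record
#' inside overlapping gene bodies yields one output row per overlapping
#' gene; the shared `recordId` lets totals count records rather than
#' record-gene pairs.
#'
#' @param x A [MethylomeDataSet-class], or a width-1 `GRanges` of
#'   methylation records.
#' @param matches Named list of per-motif `GRanges` from [scanMotifs()]
#'   (computed from `x` when omitted and `x` is a `MethylomeDataSet`).
#' @param features `GRanges` from [partitionFeatures()] (likewise derived
#'   when omitted).
#' @param upstreamRange Used only when `features` is derived here.
#' @return A `GRanges` of crossed rows with metadata columns `recordId`,
#'   `motif`, `category`, `geneID` (empty for tIG), `product`,
#'   `featureStart`/`featureEnd` (the owning interval, used by the BED
#'   writer), `modType`, `source`, `score`, `attributes`.
#' @export
crossMethylation <- function(x, matches = NULL, features = NULL,
                             upstreamRange = NULL) {
  if (is(x, "MethylomeDataSet")) {
    meth <- methCalls(x)
    if (is.null(matches)) matches <- scanMotifs(x)
    if (is.null(features)) features <- partitionFeatures(x, upstreamRange)
  } else {
    meth <- x
    if (is.null(matches) || is.null(features))
      stop("matches and features are required for a plain GRanges",
           call. = FALSE)
  }
  ## default the pass-through columns when absent (in-memory callers)
  n <- length(meth)
  for (nm in c("modType", "source", "score", "attributes"))
    if (!nm %in% colnames(mcols(meth)))
      mcols(meth)[[nm]] <- rep(if (nm == "modType") "modified_base" else ".",
                               n)

  cat3 <- mcols(features)$category
  cds <- features[cat3 == "CDS"]
  us <- features[cat3 == "US"]
  tig <- features[cat3 == "tIG"]
  methStrand <- as.character(strand(meth))

  empty <- GRanges()
  mcols(empty) <- DataFrame(
    recordId = integer(0), motif = character(0), category = character(0),
    geneID = character(0), product = character(0),
    featureStart = integer(0), featureEnd = integer(0),
    modType = character(0), source = character(0), score = character(0),
    attributes = character(0))

  rows <- list()
  for (mo in names(matches)) {
    mm <- matches[[mo]]
    hit <- findOverlaps(meth, mm, type = "within", ignore.strand = TRUE)
    sOK <- methStrand[queryHits(hit)] == "*" |
      methStrand[queryHits(hit)] == as.character(strand(mm))[subjectHits(hit)]
    inMotif <- sort(unique(queryHits(hit)[sOK]))
    if (!length(inMotif)) next
    sub <- meth[inMotif]
    subStrand <- methStrand[inMotif]

    ## gene bodies first
    gHit <- findOverlaps(sub, cds, ignore.strand = TRUE)
    gq <- queryHits(gHit); gs <- subjectHits(gHit)
    if (length(gq)) {
      accord <- subStrand[gq] == "*" |
        subStrand[gq] == as.character(strand(cds))[gs]
      rows[[length(rows) + 1L]] <- .crossedRows(
        sub[gq], recordId = inMotif[gq], motif = mo,
        category = ifelse(accord, "CDS", "nCDS"),
        geneID = mcols(cds)$geneID[gs], product = mcols(cds)$product[gs],
        featureStart = start(cds)[gs], featureEnd = end(cds)[gs])
    }
    inGene <- unique(gq)
    rest <- setdiff(seq_along(sub), inGene)
    if (!length(rest)) next
    sub2 <- sub[rest]
    subStrand2 <- subStrand[rest]

    ## same-strand US interval -> US; anything else intergenic -> tIG
    uHit <- findOverlaps(sub2, us, ignore.strand = TRUE)
    uAcc <- subStrand2[queryHits(uHit)] == "*" |
      subStrand2[queryHits(uHit)] ==
        as.character(strand(us))[subjectHits(uHit)]
    usQ <- queryHits(uHit)[uAcc]; usS <- subjectHits(uHit)[uAcc]
    if (length(usQ))
      rows[[length(rows) + 1L]] <- .crossedRows(
        sub2[usQ], recordId = inMotif[rest][usQ], motif = mo,
        category = "US", geneID = mcols(us)$geneID[usS],
        product = mcols(us)$product[usS],
        featureStart = start(us)[usS], featureEnd = end(us)[usS])

    tigIdx <- setdiff(seq_along(sub2), usQ)
    if (length(tigIdx)) {
      sub3 <- sub2[tigIdx]
      ## owning interval: the tIG interval containing the position, else the
      ## (strand-discordant) US interval it fell into
      tHit <- findOverlaps(sub3, tig, ignore.strand = TRUE)
      fs <- fe <- rep(NA_integer_, length(sub3))
      fs[queryHits(tHit)] <- start(tig)[subjectHits(tHit)]
      fe[queryHits(tHit)] <- end(tig)[subjectHits(tHit)]
      u2 <- findOverlaps(sub3, us, ignore.strand = TRUE)
      miss <- is.na(fs[queryHits(u2)])
      fs[queryHits(u2)[miss]] <- start(us)[subjectHits(u2)[miss]]
      fe[queryHits(u2)[miss]] <- end(us)[subjectHits(u2)[miss]]
      rows[[length(rows) + 1L]] <- .crossedRows(
        sub3, recordId = inMotif[rest][tigIdx], motif = mo,
        category = "tIG", geneID = "", product = "",
        featureStart = fs, featureEnd = fe)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(c, rows)
  out <- out[order(match(mcols(out)$motif, names(matches)),
                   match(as.character(seqnames(out)), seqlevels(out)),
                   start(out))]
  out
}

.crossedRows <- function(gr, recordId, motif, category, geneID, product,
                         featureStart, featureEnd) {
  out <- granges(gr)
  n <- length(out)
  mcols(out) <- DataFrame(
    recordId = recordId, motif = rep(motif, length.out = n),
    category = rep(category, length.out = n),
    geneID = rep(geneID, length.out = n),
    product = rep(product, length.out = n),
    featureStart = rep(featureStart, length.out = n),
    featureEnd = rep(featureEnd, length.out = n),
    modType = mcols(gr)$modType, source = mcols(gr)$source,
    score = mcols(gr)$score, attributes = mcols(gr)$attributes)
  out
}

#' Split crossed rows by motif and category
#'
#' @param crossed `GRanges` from [crossMethylation()].
#' @return Nested list: motif -> category -> `GRanges`.
#' @export
splitCrossed <- function(crossed) {
  cats <- c("CDS", "nCDS", "tIG", "US")
  motifs <- unique(mcols(crossed)$motif)
  out <- lapply(motifs, function(mo) {
    sub <- crossed[mcols(crossed)$motif == mo]
    stats::setNames(lapply(cats, function(ct)
      sub[mcols(sub)$category == ct]), cats)
  })
  stats::setNames(out, motifs)
}

#' Per-category methylation statistics
#'
#' Computes, per feature category, the number of features, the number of
#' methylated sites (distinct records), the number of methylated genes
#' (distinct owners), and the most methylated gene with its product (ties
#' broken by lexicographic geneID, for deterministic output). With a Roary
#' table each methylated geneID is additionally labelled `core` (present in
#' every strain) or `dispensable`; IDs absent from the table are labelled
#' `unknown` with a warning. Optionally written as a human-readable log.
#'
#' @param crossed `GRanges` from [crossMethylation()] (one motif or merged).
#' @param features `GRanges` from [partitionFeatures()].
#' @param roary Optional list from [readRoary()].
#' @param logPath Optional path for the text log.
#' @return data.frame with one row per category: `category`, `nFeatures`,
#'   `nMethylatedSites`, `nMethylatedGenes`, `topGeneID`, `topGeneProduct`;
#'   per-gene core/dispensable labels in attribute `geneClass`.
#' @export
summarizeMethylation <- function(crossed, features, roary = NULL,
                                 logPath = NULL) {
  cats <- c("CDS", "nCDS", "tIG", "US")
  fcat <- mcols(features)$category
  ccat <- mcols(crossed)$category
  res <- lapply(cats, function(ct) {
    sub <- crossed[ccat == ct]
    nSites <- length(unique(mcols(sub)$recordId))
    owner <- mcols(sub)$geneID
    if (ct == "tIG")
      owner <- paste0(as.character(seqnames(sub)), ":",
                      mcols(sub)$featureStart, "-", mcols(sub)$featureEnd)
    perGene <- if (length(sub))
      vapply(split(mcols(sub)$recordId, owner),
             function(v) length(unique(v)), integer(1L))
    else integer(0)
    top <- if (length(perGene)) {
      mx <- names(perGene)[perGene == max(perGene)]
      sort(mx)[1L]
    } else ""
    topProd <- if (nzchar(top) && ct != "tIG")
      mcols(sub)$product[match(top, mcols(sub)$geneID)] else ""
    data.frame(category = ct,
               nFeatures = sum(fcat == ct),
               nMethylatedSites = nSites,
               nMethylatedGenes = length(perGene),
               topGeneID = top, topGeneProduct = topProd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)

  geneClass <- NULL
  if (!is.null(roary)) {
    ids <- unique(mcols(crossed)$geneID)
    ids <- ids[nzchar(ids)]
    geneClass <- stats::setNames(
      unname(roary$geneClass[ids]), ids)
    if (anyNA(geneClass)) {
      warning("geneID(s) absent from the Roary table: ",
              paste(names(geneClass)[is.na(geneClass)], collapse = ", "),
              call. = FALSE)
      geneClass[is.na(geneClass)] <- "unknown"
    }
    attr(out, "geneClass") <- geneClass
  }

  if (!is.null(logPath)) {
    con <- file(logPath, "w")
    on.exit(close(con))
    writeLines("# methylation summary by feature category", con)
    for (i in seq_len(nrow(out))) {
      writeLines(sprintf(
        "%s: features=%d methylated_sites=%d methylated_genes=%d top=%s (%s)",
        out$category[i], out$nFeatures[i], out$nMethylatedSites[i],
        out$nMethylatedGenes[i],
        ifelse(nzchar(out$topGeneID[i]), out$topGeneID[i], "-"),
        ifelse(nzchar(out$topGeneProduct[i]), out$topGeneProduct[i], "-")),
        con)
    }
    if (!is.null(geneClass)) {
      writeLines("# pangenome membership of methylated genes", con)
      for (g in names(geneClass))
        writeLines(paste0(g, "\t", geneClass[[g]]), con)
    }
  }
  out
}

.crossedAttributes <- function(crossed) {
  if (!length(crossed)) return(character(0))
  extra <- paste0(";motif=", mcols(crossed)$motif)
  gid <- mcols(crossed)$geneID
  extra <- paste0(extra, ifelse(nzchar(gid), paste0(";geneID=", gid), ""))
  paste0(mcols(crossed)$attributes, extra)
}

#' Write crossed records as per-feature or per-chromosome GFF3s
#'
#' Feature level writes one `<motif>_<category>.gff3` per motif and
#' category; chromosome level writes one `<motif>_<seqid>.gff3` per motif
#' and replicon, with identical rows regrouped. Column 3 carries the
#' category; the original attributes are preserved with `motif=` (and
#' `geneID=` where known) appended. Empty groups still produce a
#' header-only file so downstream scripts can glob deterministically.
#'
#' @param crossed `GRanges` from [crossMethylation()].
#' @param outdir Output directory.
#' @param level `"feature"` or `"chromosome"`.
#' @param seqids All replicon names (for empty chromosome files); default
#'   from `seqlevels(crossed)`.
#' @return Character vector of files written, invisibly.
#' @export
writeCrossedGFF <- function(crossed, outdir,
                            level = c("feature", "chromosome"),
                            seqids = NULL) {
  level <- match.arg(level)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(seqids)) seqids <- seqlevels(crossed)
  motifs <- unique(mcols(crossed)$motif)
  asGff <- function(sub) {
    out <- granges(sub)
    mcols(out) <- DataFrame(source = mcols(sub)$source,
                            type = mcols(sub)$category,
                            score = mcols(sub)$score,
                            attributes = .crossedAttributes(sub))
    out
  }
  files <- character(0)
  for (mo in motifs) {
    sub <- crossed[mcols(crossed)$motif == mo]
    groups <- if (level == "feature") {
      stats::setNames(lapply(c("CDS", "nCDS", "tIG", "US"), function(ct)
        sub[mcols(sub)$category == ct]), c("CDS", "nCDS", "tIG", "US"))
    } else {
      stats::setNames(lapply(seqids, function(sq)
        sub[as.character(seqnames(sub)) == sq]), seqids)
    }
    for (g in names(groups)) {
      path <- file.path(outdir, paste0(mo, "_", g, ".gff3"))
      writeGFF3(asGff(groups[[g]]), path)
      files <- c(files, path)
    }
  }
  invisible(files)
}

#' Build per-category BED tables of methylation counts
#'
#' One row per feature: genes (CDS/nCDS rows, gene coordinates), US
#' intervals (owner gene, interval coordinates) and tIG intervals (the two
#' flanking geneIDs, interval coordinates), each with the number of
#' distinct methylation records assigned to it in that category.
#' Coordinates are BED-style 0-based half-open. Features with zero
#' methylations are kept by default so the files double as complete
#' per-feature tables.
#'
#' @param crossed `GRanges` from [crossMethylation()].
#' @param features `GRanges` from [partitionFeatures()].
#' @param onlyMethylated Drop zero-count rows when `TRUE`.
#' @return Named list of data.frames (`CDS`, `nCDS`, `tIG`, `US`) with
#'   columns `chrom`, `start`, `end`, `geneID`, `count`, `product`.
#' @export
makeBedTables <- function(crossed, features, onlyMethylated = FALSE) {
  fcat <- mcols(features)$category
  ccat <- mcols(crossed)$category
  out <- lapply(c("CDS", "nCDS", "tIG", "US"), function(ct) {
    fx <- features[fcat == ct]
    cx <- crossed[ccat == ct]
    key <- paste0(as.character(seqnames(fx)), ":", start(fx), "-", end(fx))
    ckey <- paste0(as.character(seqnames(cx)), ":",
                   mcols(cx)$featureStart, "-", mcols(cx)$featureEnd)
    cnt <- vapply(split(mcols(cx)$recordId, ckey),
                  function(v) length(unique(v)), integer(1L))
    df <- data.frame(chrom = as.character(seqnames(fx)),
                     start = start(fx) - 1L, end = end(fx),
                     geneID = mcols(fx)$geneID,
                     count = unname(ifelse(is.na(cnt[key]), 0L, cnt[key])),
                     product = mcols(fx)$product,
                     stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    if (onlyMethylated) df <- df[df$count > 0L, , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  stats::setNames(out, c("CDS", "nCDS", "tIG", "US"))
}
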