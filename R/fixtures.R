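#' Generate a synthetic methylome fixture with planted ground truth
#'
#' Writes a fully synthetic input set — genome FASTA, annotation GFF3,
#' SMRT-dialect modified-base GFF3, motif file and a Roary-style
#' gene_presence_absence.csv — plus a `ground_truth.tsv` listing every
#' planted motif occurrence, its feature category and whether it carries a
#' methylation. Planted counts are exact per category because the random
#' background is rejection-sampled until it contains no occurrence of any
#' planted motif (on either strand) outside the planted loci; the whole
#' set is deterministic given `seed`.
#'
#' Replicon layout alternates gene bodies with inter-gene gaps whose
#' flanking-strand pattern is chosen so that enough upstream (same
#' orientation) and true intergenic (opposite orientation) gaps exist to
#' hold the requested plantings. Methylations are planted inside motif
#' occurrences: accordant with the gene strand for CDS, discordant for
#' nCDS, accordant with the owner gene for US, and on the plus strand for
#' tIG.
#'
#' @param outdir Output directory (created).
#' @param seed Integer seed; the same seed reproduces byte-identical files.
#' @param motif IUPAC motif to plant (default `GANTC`, the CcrM site).
#' @param plantCounts Named integer vector: methylated motif occurrences to
#'   plant per category, default `c(CDS = 40, nCDS = 25, tIG = 10, US = 5)`.
#' @param nRepl Number of replicons.
#' @param replLengths Integer vector of replicon lengths (recycled to
#'   `nRepl`).
#' @param geneLen,gapLen Mean gene body / gap lengths in bp.
#' @param gcContent Background GC fraction.
#' @param methylatedFraction Fraction of planted occurrences that carry a
#'   methylation record (default 1: exact recovery).
#' @param motifFree Keep the background free of chance motif hits
#'   (default `TRUE`; disable for realism tests).
#' @param nStrains,coreFraction Roary fixture: number of strains and
#'   fraction of genes present in all of them.
#' @return List with `paths` (named file paths) and `groundTruth`
#'   (data.frame: `seqid`, `start`, `end`, `matchStrand`, `category`,
#'   `geneID`, `motif`, `methPos`, `methStrand`, `methylated`).
#' @export
simulateMethylome <- function(outdir, seed = 1L, motif = "GANTC",
                              plantCounts = c(CDS = 40L, nCDS = 25L,
                                              tIG = 10L, US = 5L),
                              nRepl = 2L, replLengths = c(60000L, 40000L),
                              geneLen = 900L, gapLen = 400L,
                              gcContent = 0.5, methylatedFraction = 1,
                              motifFree = TRUE,
                              nStrains = 2L, coreFraction = 0.7) {
  set.seed(as.integer(seed))
  motif <- .checkMotif(motif)
  m <- nchar(motif)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  replLengths <- rep_len(as.integer(replLengths), nRepl)
  seqids <- sprintf("ctg%02d", seq_len(nRepl))

  probs <- c(A = (1 - gcContent) / 2, C = gcContent / 2,
             G = gcContent / 2, T = (1 - gcContent) / 2)
  fwdWords <- expandIupac(motif)
  revWords <- expandIupac(reverseComplementIupac(motif))
  allWords <- unique(c(fwdWords, revWords))

  ## ---- gene/gap layout per replicon --------------------------------------
  layouts <- lapply(seq_len(nRepl), function(r) {
    L <- replLengths[r]
    genes <- NULL
    gaps <- NULL
    pos <- 1L + gapLen %/% 2L           # leading terminal gap
    strandPrev <- NA_character_
    gi <- 0L
    while (TRUE) {
      gl <- as.integer(round(stats::runif(1, 0.6, 1.4) * geneLen))
      if (pos + gl - 1L + gapLen %/% 2L > L) break
      gi <- gi + 1L
      ## alternate wanting US (same strand) and tIG (opposite) gaps
      st <- if (is.na(strandPrev)) "+"
            else if (gi %% 2L == 0L) strandPrev
            else if (strandPrev == "+") "-" else "+"
      genes <- rbind(genes, data.frame(
        start = pos, end = pos + gl - 1L, strand = st,
        geneID = sprintf("%s_g%03d", seqids[r], gi),
        stringsAsFactors = FALSE))
      if (nrow(genes) > 1L) {
        prev <- genes[nrow(genes) - 1L, ]
        gaps <- rbind(gaps, data.frame(
          start = prev$end + 1L, end = pos - 1L,
          type = if (prev$strand == st) "US" else "tIG",
          strand = if (prev$strand == st) st else "*",
          ownerID = if (prev$strand == st) {
            if (st == "+") genes$geneID[nrow(genes)] else prev$geneID
          } else paste(prev$geneID, genes$geneID[nrow(genes)], sep = ","),
          stringsAsFactors = FALSE))
      }
      pos <- pos + gl - 1L +
        as.integer(round(stats::runif(1, 0.6, 1.4) * gapLen)) + 1L
      strandPrev <- st
    }
    list(genes = genes, gaps = gaps)
  })

  ## ---- choose planting sites ---------------------------------------------
  truth <- NULL
  plantAt <- function(seqid, lo, hi, category, geneID, methStrand) {
    ## lo..hi: interval that must contain the whole motif occurrence
    if (hi - lo + 1L < m) return(FALSE)
    s <- lo + sample.int(hi - lo + 2L - m, 1L) - 1L
    word <- if (methStrand == "-" && !isPalindromic(motif))
      sample(revWords, 1L) else sample(fwdWords, 1L)
    matchStrand <- if (word %in% fwdWords) "+" else "-"
    truth <<- rbind(truth, data.frame(
      seqid = seqid, start = s, end = s + m - 1L,
      matchStrand = matchStrand, category = category, geneID = geneID,
      motif = motif, word = word,
      methPos = s + sample.int(m, 1L) - 1L, methStrand = methStrand,
      methylated = NA, stringsAsFactors = FALSE))
    TRUE
  }

  counts <- plantCounts[c("CDS", "nCDS", "tIG", "US")]
  counts[is.na(counts)] <- 0L
  names(counts) <- c("CDS", "nCDS", "tIG", "US")
  pad <- 3L  # keep plantings clear of interval edges

  for (ct in names(counts)) {
    need <- counts[[ct]]
    placed <- 0L
    guard <- 0L
    while (placed < need) {
      guard <- guard + 1L
      if (guard > 50L * need)
        stop("unsatisfiable fixture spec: cannot place ", need, " ", ct,
             " plantings", call. = FALSE)
      r <- sample.int(nRepl, 1L)
      ly <- layouts[[r]]
      ok <- FALSE
      if (ct %in% c("CDS", "nCDS")) {
        g <- ly$genes[sample.int(nrow(ly$genes), 1L), ]
        ms <- if (ct == "CDS") g$strand else if (g$strand == "+") "-" else "+"
        ok <- plantAt(seqids[r], g$start + pad, g$end - pad, ct, g$geneID, ms)
      } else {
        gp <- ly$gaps[ly$gaps$type == ct, , drop = FALSE]
        if (nrow(gp)) {
          g <- gp[sample.int(nrow(gp), 1L), ]
          ms <- if (ct == "US") g$strand else "+"
          ok <- plantAt(seqids[r], g$start + pad, g$end - pad, ct,
                        g$ownerID, ms)
        }
      }
      if (ok) {
        ## reject overlaps with earlier plantings
        k <- nrow(truth)
        same <- truth$seqid[seq_len(k - 1L)] == truth$seqid[k]
        if (any(same & truth$start[seq_len(k - 1L)] <= truth$end[k] &
                  truth$end[seq_len(k - 1L)] >= truth$start[k])) {
          truth <- truth[seq_len(k - 1L), , drop = FALSE]
          ok <- FALSE
        }
      }
      if (ok) placed <- placed + 1L
    }
  }
  if (is.null(truth))
    truth <- data.frame(seqid = character(0), start = integer(0),
                        end = integer(0), matchStrand = character(0),
                        category = character(0), geneID = character(0),
                        motif = character(0), word = character(0),
                        methPos = integer(0), methStrand = character(0),
                        methylated = logical(0), stringsAsFactors = FALSE)
  nT <- nrow(truth)
  truth$methylated <- rep(FALSE, nT)
  if (nT)
    truth$methylated[stats::runif(nT) <= methylatedFraction] <- TRUE

  ## ---- assemble sequences, motif-free background --------------------------
  seqs <- lapply(seq_len(nRepl), function(r) {
    L <- replLengths[r]
    s <- sample(names(probs), L, replace = TRUE, prob = probs)
    tr <- truth[truth$seqid == seqids[r], , drop = FALSE]
    for (i in seq_len(nrow(tr)))
      s[tr$start[i]:tr$end[i]] <- strsplit(tr$word[i], "", fixed = TRUE)[[1L]]
    if (motifFree) {
      planted <- rep(FALSE, L)
      for (i in seq_len(nrow(tr))) planted[tr$start[i]:tr$end[i]] <- TRUE
      for (iter in seq_len(100L)) {
        txt <- paste(s, collapse = "")
        stray <- integer(0)
        for (w in allWords) {
          hits <- gregexpr(w, txt, fixed = TRUE)[[1L]]
          ## fixed gregexpr misses overlapping hits; catch them next sweep
          if (hits[1L] != -1L)
            for (h in hits) {
              span <- h:(h + m - 1L)
              if (!all(planted[span]))
                stray <- c(stray, span[!planted[span]])
            }
        }
        if (!length(stray)) break
        stray <- unique(stray)
        s[stray] <- sample(names(probs), length(stray), replace = TRUE,
                           prob = probs)
        if (iter == 100L)
          stop("background rejection sampling failed to converge",
               call. = FALSE)
      }
    }
    paste(s, collapse = "")
  })
  names(seqs) <- seqids

  ## ---- write files --------------------------------------------------------
  paths <- c(fasta = file.path(outdir, "genome.fna"),
             annotation = file.path(outdir, "annotation.gff3"),
             methylation = file.path(outdir, "methylation.gff3"),
             motifs = file.path(outdir, "motifs.txt"),
             roary = file.path(outdir, "gene_presence_absence.csv"),
             groundTruth = file.path(outdir, "ground_truth.tsv"))

  fa <- unlist(lapply(seqids, function(sq) {
    body <- seqs[[sq]]
    c(paste0(">", sq),
      substring(body, seq(1L, nchar(body), 70L),
                pmin(seq(1L, nchar(body), 70L) + 69L, nchar(body))))
  }))
  writeLines(fa, paths[["fasta"]])

  annLines <- "##gff-version 3"
  geneTbl <- NULL
  for (r in seq_len(nRepl)) {
    g <- layouts[[r]]$genes
    g$seqid <- seqids[r]
    geneTbl <- rbind(geneTbl, g)
    annLines <- c(annLines, sprintf(
      "%s\tsynthetic\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=hypothetical protein %s",
      seqids[r], g$start, g$end, g$strand, g$geneID, g$geneID))
  }
  writeLines(annLines, paths[["annotation"]])

  methLines <- "##gff-version 3"
  mt <- truth[truth$methylated, , drop = FALSE]
  if (nrow(mt)) {
    ord <- order(mt$seqid, mt$methPos)
    mt <- mt[ord, , drop = FALSE]
    cov <- 50L + sample.int(150L, nrow(mt), replace = TRUE)
    methLines <- c(methLines, sprintf(
      "%s\tkinModCall\tm6A\t%d\t%d\t%d\t%s\t.\tcoverage=%d;IPDRatio=%.2f",
      mt$seqid, mt$methPos, mt$methPos,
      20L + sample.int(40L, nrow(mt), replace = TRUE),
      mt$methStrand, cov, 2 + round(stats::runif(nrow(mt), 0, 4), 2)))
  }
  writeLines(methLines, paths[["methylation"]])

  writeLines(c("# planted motifs", motif), paths[["motifs"]])

  ## Roary table: strain 1 carries our geneIDs; a core gene is present in
  ## every strain column
  ng <- nrow(geneTbl)
  core <- seq_len(ng) <= round(coreFraction * ng)
  meta <- c("Gene", "Non-unique Gene name", "Annotation", "No. isolates",
            "No. sequences", "Avg sequences per isolate", "Genome Fragment",
            "Order within Fragment", "Accessory Fragment",
            "Accessory Order with Fragment", "QC", "Min group size nuc",
            "Max group size nuc", "Avg group size nuc")
  strains <- c("strain1", sprintf("strain%d", 1L + seq_len(nStrains - 1L)))
  hdr <- paste(c(sprintf('"%s"', meta), sprintf('"%s"', strains)),
               collapse = ",")
  rows <- vapply(seq_len(ng), function(i) {
    metaVals <- c(sprintf("group_%04d", i), "", "synthetic product",
                  as.character(if (core[i]) nStrains else 1L),
                  as.character(if (core[i]) nStrains else 1L),
                  "1", "1", as.character(i), "", "", "", "100", "100", "100")
    cells <- c(geneTbl$geneID[i],
               if (nStrains > 1L)
                 ifelse(rep(core[i], nStrains - 1L),
                        sprintf("%s_o%d", geneTbl$geneID[i],
                                seq_len(nStrains - 1L)), ""))
    paste(sprintf('"%s"', c(metaVals, cells)), collapse = ",")
  }, character(1L))
  writeLines(c(hdr, rows), paths[["roary"]])

  truthOut <- truth[, c("seqid", "start", "end", "matchStrand", "category",
                        "geneID", "motif", "methPos", "methStrand",
                        "methylated")]
  write.table(truthOut, paths[["groundTruth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)

  invisible(list(paths = paths, groundTruth = truthOut,
                 genes = geneTbl, coreGenes = geneTbl$geneID[core]))
}
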