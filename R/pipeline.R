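#' Run the full methylome-mapping pipeline
#'
#' Orchestrates the whole analysis: seqid harmonization and validation
#' ([normalizeSeqids()], [validateInputs()]), motif scanning
#' ([scanMotifs()]), genome partitioning ([partitionFeatures()]), crossing
#' ([crossMethylation()]), per-feature (and optionally per-chromosome)
#' GFF3 output, the statistics log with optional Roary core/dispensable
#' labelling, per-category BED tables, and plots with numeric TSV twins.
#' A JSON run manifest records inputs, parameters and headline counts. The
#' analysis path is fully deterministic.
#'
#' @param fasta,annotation,methylation,motifs Paths to the four inputs.
#' @param outdir Output directory (created if absent).
#' @param upstreamRange `NULL` (full-gap upstream regions) or positive bp.
#' @param roary Optional path to a Roary `gene_presence_absence.csv`.
#' @param makeChrom Also write chromosome-level GFF3s (per replicon
#'   instead of per category).
#' @param makeBed Write per-category BED tables (default `TRUE`).
#' @param plots Draw scatter/heatmap/circular plots (default `TRUE`).
#' @param windowBp Circular-density window size in bp.
#' @param seqidRules Named replacement rules for [normalizeSeqids()].
#' @param onlyMethylated Drop zero-count BED rows.
#' @param circular Scan motif windows across the replicon origin.
#' @param dpi Plot resolution.
#' @return Invisibly, a list with the `MethylomeDataSet`, `matches`,
#'   `features`, `crossed`, `stats`, `bed` tables and output `paths`.
#' @export
runPipeline <- function(fasta, annotation, methylation, motifs, outdir,
                        upstreamRange = NULL, roary = NULL,
                        makeChrom = FALSE, makeBed = TRUE, plots = TRUE,
                        windowBp = 10000, seqidRules = c("|" = "_"),
                        onlyMethylated = FALSE, circular = FALSE, dpi = 96) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  norm <- normalizeSeqids(fasta, annotation, methylation,
                          file.path(outdir, "normalized"), seqidRules)
  validateInputs(norm$paths[["fasta"]], norm$paths[["annotation"]],
                 norm$paths[["methylation"]])
  mds <- readMethylomeDataSet(norm$paths[["fasta"]],
                              norm$paths[["annotation"]],
                              norm$paths[["methylation"]], motifs)
  matches <- scanMotifs(mds, circular = circular)
  features <- partitionFeatures(mds, upstreamRange)
  report <- partitionReport(features)
  crossed <- crossMethylation(methCalls(mds), matches, features)

  featDir <- file.path(outdir, "features")
  dir.create(featDir, showWarnings = FALSE)
  for (ct in c("CDS", "nCDS", "tIG", "US")) {
    fx <- features[mcols(features)$category == ct]
    gx <- granges(fx)
    mcols(gx) <- DataFrame(
      source = rep("bacMethMap", length(fx)), type = mcols(fx)$category,
      score = rep(".", length(fx)),
      attributes = paste0("geneID=", mcols(fx)$geneID,
                          ifelse(is.na(mcols(fx)$orientation), "",
                                 paste0(";orientation=",
                                        mcols(fx)$orientation))))
    writeGFF3(gx, file.path(featDir, paste0(ct, ".gff3")))
  }

  gffFiles <- writeCrossedGFF(crossed, outdir, "feature",
                              seqids = names(genomeSeq(mds)))
  if (makeChrom)
    gffFiles <- c(gffFiles,
                  writeCrossedGFF(crossed, outdir, "chromosome",
                                  seqids = names(genomeSeq(mds))))

  roaryTbl <- if (!is.null(roary)) readRoary(roary) else NULL
  stats <- summarizeMethylation(crossed, features, roaryTbl,
                                logPath = file.path(outdir, "stats.log"))

  bed <- NULL
  if (makeBed) {
    bed <- makeBedTables(crossed, features, onlyMethylated)
    for (ct in names(bed))
      writeBed(bed[[ct]], file.path(outdir, paste0(ct, ".bed")))
  }

  if (plots) {
    plotDir <- file.path(outdir, "plots")
    bedForPlot <- if (!is.null(bed)) bed else makeBedTables(crossed, features)
    plotScatterMeth(bedForPlot, plotDir, dpi = dpi)
    siteCounts <- vapply(names(matches), function(mo)
      length(unique(mcols(crossed)$recordId[mcols(crossed)$motif == mo])),
      integer(1L))
    plotMotifHeatmap(matrix(siteCounts, ncol = 1L,
                            dimnames = list(names(matches), "run")),
                     plotDir, dpi = dpi)
    plotCircularDensity(crossed,
                        stats::setNames(Biostrings::width(genomeSeq(mds)),
                                        names(genomeSeq(mds))),
                        geneRanges(mds), windowBp, plotDir, dpi = dpi)
  }

  manifest <- list(
    inputs = list(fasta = fasta, annotation = annotation,
                  methylation = methylation, motifs = motifs,
                  roary = roary),
    parameters = list(upstreamRange = upstreamRange, windowBp = windowBp,
                      makeChrom = makeChrom, makeBed = makeBed,
                      onlyMethylated = onlyMethylated, circular = circular,
                      seqidRules = as.list(seqidRules)),
    package = list(name = "bacMethMap",
                   version = as.character(utils::packageVersion("bacMethMap"))),
    counts = list(
      replicons = length(genomeSeq(mds)),
      genomeBp = sum(Biostrings::width(genomeSeq(mds))),
      genes = length(geneRanges(mds)),
      methylationRecords = length(methCalls(mds)),
      motifMatches = stats::setNames(
        lapply(matches, length), names(matches)),
      crossedSites = length(unique(mcols(crossed)$recordId))))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(mds = mds, matches = matches, features = features,
                 partition = report, crossed = crossed, stats = stats,
                 bed = bed, outdir = outdir))
}
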