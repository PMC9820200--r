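## small in-memory scenario used across crossing tests:
## replicon c1 (200 bp), gene g1 (10,30,+), gene g2 (50,80,-),
## GANTC match at [13,17] (both strands, palindromic)
crossScenario <- function(methPos, methStrand) {
  genes <- makeGenes("c1", c(10L, 50L), c(30L, 80L), c("+", "-"))
  features <- partitionFeatures(genes, seqlengths = c(c1 = 200L))
  matches <- list(GANTC = GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(13L, 13L), c(17L, 17L)),
    strand = c("+", "-"), motif = "GANTC"))
  meth <- GenomicRanges::GRanges("c1", IRanges::IRanges(methPos, methPos),
                                 strand = methStrand,
                                 modType = "m6A", source = "kinModCall",
                                 score = "40", attributes = "coverage=10")
  crossMethylation(meth, matches, features)
}

test_that("strand-aware category assignment inside a motif match", {
  cr <- crossScenario(15L, "+")
  expect_identical(S4Vectors::mcols(cr)$category, "CDS")
  expect_identical(S4Vectors::mcols(cr)$geneID, "g1")
  cr2 <- crossScenario(15L, "-")
  expect_identical(S4Vectors::mcols(cr2)$category, "nCDS")
  ## unstranded record counts as accordant
  cr3 <- crossScenario(15L, "*")
  expect_identical(S4Vectors::mcols(cr3)$category, "CDS")
})

test_that("a methylation outside every motif match is dropped", {
  expect_length(crossScenario(40L, "+"), 0L)
})

test_that("attributes survive the crossing verbatim, with keys appended", {
  cr <- crossScenario(15L, "+")
  expect_identical(S4Vectors::mcols(cr)$attributes, "coverage=10")
  d <- tempfile("gff"); dir.create(d)
  files <- writeCrossedGFF(cr, d, "feature")
  row <- grep("^[^#]", readLines(file.path(d, "GANTC_CDS.gff3")),
              value = TRUE)
  expect_match(row, "^c1\tkinModCall\tCDS\t15\t15\t40\t\\+\t")
  expect_match(row, "coverage=10;motif=GANTC;geneID=g1")
})

test_that("planted fixture methylations are recovered by exact category", {
  fx <- simulateMethylome(tempfile("fx"), seed = 41)
  mds <- readMethylomeDataSet(fx$paths[["fasta"]], fx$paths[["annotation"]],
                              fx$paths[["methylation"]],
                              fx$paths[["motifs"]])
  crossed <- crossMethylation(mds)
  got <- table(S4Vectors::mcols(crossed)$category)
  expect_identical(as.integer(got[c("CDS", "nCDS", "tIG", "US")]),
                   c(40L, 25L, 10L, 5L))
  ## conservation: crossed sites cannot exceed records inside matches
  expect_identical(length(unique(S4Vectors::mcols(crossed)$recordId)),
                   length(methCalls(mds)))
})

test_that("crossing agrees with a brute-force triple-loop oracle", {
  set.seed(97)
  for (rep in 1:5) {
    len <- 3000L
    genes <- makeGenes("c1",
                       c(200L, 900L, 1700L), c(600L, 1400L, 2300L),
                       sample(c("+", "-"), 3L, TRUE))
    features <- partitionFeatures(genes, seqlengths = c(c1 = len))
    mstarts <- sample(seq(5L, len - 10L), 40L)
    matches <- list(MOT = GenomicRanges::GRanges(
      "c1", IRanges::IRanges(mstarts, mstarts + 4L),
      strand = sample(c("+", "-"), 40L, TRUE), motif = "MOT"))
    pos <- sample(seq_len(len), 60L)
    st <- sample(c("+", "-", "*"), 60L, TRUE)
    meth <- GenomicRanges::GRanges("c1", IRanges::IRanges(pos, pos),
                                   strand = st)
    got <- crossMethylation(meth, matches, features)
    ct <- S4Vectors::mcols(features)$category
    fdf <- function(cat) data.frame(
      seqid = as.character(GenomicRanges::seqnames(features[ct == cat])),
      start = GenomicRanges::start(features[ct == cat]),
      end = GenomicRanges::end(features[ct == cat]),
      strand = as.character(GenomicRanges::strand(features[ct == cat])),
      stringsAsFactors = FALSE)
    want <- oracleCross(
      data.frame(seqid = "c1", pos = pos, strand = st,
                 stringsAsFactors = FALSE),
      data.frame(seqid = "c1", start = mstarts, end = mstarts + 4L,
                 strand = as.character(
                   GenomicRanges::strand(matches$MOT)),
                 stringsAsFactors = FALSE),
      fdf("CDS"), fdf("US"))
    gotTab <- sort(paste(GenomicRanges::start(got),
                         S4Vectors::mcols(got)$category))
    wantTab <- if (is.null(want)) character(0) else
      sort(paste(want$pos, want$category))
    expect_identical(gotTab, wantTab)
  }
})

test_that("flipping every record strand swaps CDS and nCDS exactly", {
  fx <- simulateMethylome(tempfile("fx"), seed = 19)
  mds <- readMethylomeDataSet(fx$paths[["fasta"]], fx$paths[["annotation"]],
                              fx$paths[["methylation"]],
                              fx$paths[["motifs"]])
  matches <- scanMotifs(mds)
  features <- partitionFeatures(mds)
  meth <- methCalls(mds)
  base <- table(S4Vectors::mcols(
    crossMethylation(meth, matches, features))$category)
  flipped <- meth
  st <- as.character(GenomicRanges::strand(meth))
  GenomicRanges::strand(flipped) <- ifelse(st == "+", "-",
                                           ifelse(st == "-", "+", st))
  flip <- table(S4Vectors::mcols(
    crossMethylation(flipped, matches, features))$category)
  expect_identical(as.integer(flip["CDS"]), as.integer(base["nCDS"]))
  expect_identical(as.integer(flip["nCDS"]), as.integer(base["CDS"]))
  ## a flipped upstream record becomes strand-discordant with its US
  ## interval and reclassifies as tIG, so the intergenic total is conserved
  tally <- function(tab, ct) {
    v <- tab[ct]
    sum(as.integer(ifelse(is.na(v), 0L, v)))
  }
  expect_identical(tally(flip, c("tIG", "US")), tally(base, c("tIG", "US")))
})

test_that("feature-level and chromosome-level GFF outputs hold identical rows", {
  fx <- simulateMethylome(tempfile("fx"), seed = 11)
  mds <- readMethylomeDataSet(fx$paths[["fasta"]], fx$paths[["annotation"]],
                              fx$paths[["methylation"]],
                              fx$paths[["motifs"]])
  crossed <- crossMethylation(mds)
  d1 <- tempfile("feat"); d2 <- tempfile("chrom")
  f1 <- writeCrossedGFF(crossed, d1, "feature")
  f2 <- writeCrossedGFF(crossed, d2, "chromosome",
                        seqids = names(genomeSeq(mds)))
  rows <- function(files) sort(unlist(lapply(files, function(f)
    grep("^[^#]", readLines(f), value = TRUE))))
  expect_identical(rows(f1), rows(f2))
  ## empty groups still get header-only files
  expect_identical(length(f2), length(genomeSeq(mds)))
})

test_that("summaries count sites and genes, break top-gene ties lexically", {
  fx <- simulateMethylome(tempfile("fx"), seed = 41)
  mds <- readMethylomeDataSet(fx$paths[["fasta"]], fx$paths[["annotation"]],
                              fx$paths[["methylation"]],
                              fx$paths[["motifs"]])
  features <- partitionFeatures(mds)
  crossed <- crossMethylation(mds)
  logPath <- tempfile(fileext = ".log")
  st <- summarizeMethylation(crossed, features, logPath = logPath)
  expect_identical(st$category, c("CDS", "nCDS", "tIG", "US"))
  expect_identical(st$nMethylatedSites, c(40L, 25L, 10L, 5L))
  expect_true(all(st$nMethylatedGenes <= st$nFeatures))
  expect_identical(st$nFeatures[1], length(geneRanges(mds)))
  ## the top gene attains the per-gene maximum
  cds <- crossed[S4Vectors::mcols(crossed)$category == "CDS"]
  perGene <- table(S4Vectors::mcols(cds)$geneID)
  expect_identical(as.integer(perGene[st$topGeneID[1]]),
                   as.integer(max(perGene)))
  expect_true(file.exists(logPath))
  expect_match(readLines(logPath)[2], "^CDS: features=")

  ## empty crossing: zeros and empty top gene
  empty <- crossed[0]
  st0 <- summarizeMethylation(empty, features)
  expect_identical(st0$nMethylatedSites, rep(0L, 4L))
  expect_identical(st0$topGeneID, rep("", 4L))

  ## deterministic lexicographic tie-break
  genes <- makeGenes("c1", c(10L, 50L), c(30L, 80L), c("+", "+"),
                     geneID = c("gB", "gA"))
  features2 <- partitionFeatures(genes, seqlengths = c(c1 = 200L))
  matches <- list(M = GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(12L, 52L), c(16L, 56L)), strand = "+",
    motif = "M"))
  meth <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(13L, 53L),
                                                        c(13L, 53L)),
                                 strand = "+")
  cr <- crossMethylation(meth, matches, features2)
  st2 <- summarizeMethylation(cr, features2)
  expect_identical(st2$topGeneID[1], "gA")
})

test_that("Roary labels methylated genes core or dispensable", {
  fx <- simulateMethylome(tempfile("fx"), seed = 41)
  mds <- readMethylomeDataSet(fx$paths[["fasta"]], fx$paths[["annotation"]],
                              fx$paths[["methylation"]],
                              fx$paths[["motifs"]])
  features <- partitionFeatures(mds)
  crossed <- crossMethylation(mds)
  roary <- readRoary(fx$paths[["roary"]])
  st <- summarizeMethylation(crossed, features, roary = roary)
  gc <- attr(st, "geneClass")
  expect_true(all(gc %in% c("core", "dispensable")))
  coreIds <- intersect(names(gc), fx$coreGenes)
  expect_true(all(gc[coreIds] == "core"))
  expect_true(all(gc[setdiff(names(gc), fx$coreGenes)] == "dispensable"))
  ## an unknown gene is labelled with a warning
  fake <- crossed[1]
  S4Vectors::mcols(fake)$geneID <- "not_in_roary"
  expect_warning(st2 <- summarizeMethylation(fake, features, roary = roary),
                 "not_in_roary")
  expect_identical(unname(attr(st2, "geneClass")["not_in_roary"]), "unknown")
})

test_that("BED tables keep zero-count features and conserve totals", {
  fx <- simulateMethylome(tempfile("fx"), seed = 41)
  mds <- readMethylomeDataSet(fx$paths[["fasta"]], fx$paths[["annotation"]],
                              fx$paths[["methylation"]],
                              fx$paths[["motifs"]])
  features <- partitionFeatures(mds)
  crossed <- crossMethylation(mds)
  bed <- makeBedTables(crossed, features)
  expect_named(bed, c("CDS", "nCDS", "tIG", "US"))
  ## complete per-feature tables with zero rows kept
  expect_identical(nrow(bed$CDS), length(geneRanges(mds)))
  expect_true(any(bed$CDS$count == 0L))
  ## conservation per category
  for (ct in names(bed))
    expect_identical(sum(bed[[ct]]$count),
                     length(unique(S4Vectors::mcols(
                       crossed[S4Vectors::mcols(crossed)$category == ct]
                     )$recordId)), label = ct)
  ## coordinate law against the annotation
  g1 <- geneRanges(mds)[1]
  row <- bed$CDS[bed$CDS$geneID == S4Vectors::mcols(g1)$geneID, ]
  expect_identical(row$start, GenomicRanges::start(g1) - 1L)
  expect_identical(row$end, GenomicRanges::end(g1))
  ## --only-methylated drops the zeros
  bedM <- makeBedTables(crossed, features, onlyMethylated = TRUE)
  expect_true(all(bedM$CDS$count > 0L))
  expect_identical(sum(bedM$CDS$count), sum(bed$CDS$count))
})
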