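test_that("FASTA reading normalizes case, tokenizes headers, rejects bad input", {
  fa <- tempfile(fileext = ".fna")
  writeLines(c(">c1 some description", "acgt"), fa)
  g <- readGenomeFasta(fa)
  expect_identical(names(g), "c1")
  expect_identical(as.character(g[[1]]), "ACGT")
  expect_identical(Biostrings::width(g), 4L)

  writeLines(c(">c1", "AC", ">c1", "GT"), fa)
  expect_error(readGenomeFasta(fa), "duplicate seqid.*c1")

  writeLines(c(">c1", "ACQT"), fa)
  expect_error(readGenomeFasta(fa), "c1.*non-nucleotide")

  writeLines(character(0), fa)
  expect_error(readGenomeFasta(fa))
})

test_that("a multi-replicon FASTA round-trips its generated lengths", {
  fa <- tempfile(fileext = ".fna")
  set.seed(11)
  lens <- c(500L, 300L, 200L)
  lines <- unlist(lapply(seq_along(lens), function(i)
    c(paste0(">r", i), randomSeq(lens[i]))))
  writeLines(lines, fa)
  g <- readGenomeFasta(fa)
  expect_length(g, 3L)
  expect_identical(unname(Biostrings::width(g)), lens)
  expect_identical(sum(Biostrings::width(g)), 1000L)
})

test_that("annotation GFF3 reading maps fields and de-duplicates gene/CDS pairs", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tProkka\tCDS\t10\t30\t.\t+\t0\tID=g1;product=hypothetical protein"),
             gff)
  gr <- readGeneAnnotation(gff)
  expect_identical(as.character(GenomicRanges::seqnames(gr)), "c1")
  expect_identical(GenomicRanges::start(gr), 10L)
  expect_identical(GenomicRanges::end(gr), 30L)
  expect_identical(as.character(GenomicRanges::strand(gr)), "+")
  expect_identical(S4Vectors::mcols(gr)$geneID, "g1")
  expect_identical(S4Vectors::mcols(gr)$product, "hypothetical protein")

  writeLines(c("c1\tx\tCDS\t10\t9\t.\t+\t0\tID=g1"), gff)
  expect_error(readGeneAnnotation(gff), "end < start")

  ## paired gene + CDS rows for the same loci give one record each, CDS wins
  set.seed(3)
  starts <- seq(10L, by = 100L, length.out = 20L)
  rows <- unlist(lapply(seq_along(starts), function(i) c(
    sprintf("c1\tx\tgene\t%d\t%d\t.\t+\t.\tID=gene%02d", starts[i],
            starts[i] + 50L, i),
    sprintf("c1\tx\tCDS\t%d\t%d\t.\t+\t0\tID=cds%02d;product=p%d", starts[i],
            starts[i] + 50L, i, i))))
  writeLines(c("##gff-version 3", rows), gff)
  gr <- readGeneAnnotation(gff)
  expect_length(gr, 20L)
  expect_true(all(startsWith(S4Vectors::mcols(gr)$geneID, "cds")))

  ## locus_tag fallback
  writeLines("c1\tx\tCDS\t5\t9\t.\t-\t0\tlocus_tag=lt1", gff)
  expect_identical(S4Vectors::mcols(readGeneAnnotation(gff))$geneID, "lt1")
  writeLines("c1\tx\tCDS\t5\t9\t.\t-\t0\tnote=none", gff)
  expect_error(readGeneAnnotation(gff), "ID= or locus_tag=")
})

test_that("modified-base GFF3 reading filters, midpoints and preserves attributes", {
  gff <- tempfile(fileext = ".gff3")
  writeLines("c1\tkinModCall\tm6A\t15\t15\t40\t+\t.\tcoverage=120", gff)
  gr <- readMethylationGFF(gff)
  expect_identical(GenomicRanges::start(gr), 15L)
  expect_identical(as.character(GenomicRanges::strand(gr)), "+")
  expect_identical(S4Vectors::mcols(gr)$modType, "m6A")
  expect_identical(S4Vectors::mcols(gr)$attributes, "coverage=120")
  expect_length(readMethylationGFF(gff, modTypes = "m4C"), 0L)

  ## 2-bp context -> midpoint with a warning, not an error
  writeLines("c1\tkinModCall\tm6A\t15\t16\t40\t+\t.\tcoverage=9", gff)
  expect_warning(gr <- readMethylationGFF(gff), "midpoint")
  expect_identical(GenomicRanges::start(gr), 15L)

  ## mixed-type counts recovered under a filter
  lines <- c(sprintf("c1\tkinModCall\tm6A\t%d\t%d\t30\t+\t.\tcoverage=1",
                     1:50 * 3L, 1:50 * 3L),
             sprintf("c1\tkinModCall\tm4C\t%d\t%d\t30\t-\t.\tcoverage=1",
                     200L + 1:30 * 2L, 200L + 1:30 * 2L))
  writeLines(lines, gff)
  expect_length(readMethylationGFF(gff, modTypes = "m6A"), 50L)
  expect_length(readMethylationGFF(gff), 80L)
})

test_that("GFF3 writing round-trips and groups by seqid with sorted starts", {
  set.seed(5)
  n <- 100L
  sq <- sample(c("c2", "c1"), n, replace = TRUE)
  st <- sample(1:5000, n)
  gr <- GenomicRanges::GRanges(sq, IRanges::IRanges(st, st + 4L),
                               strand = sample(c("+", "-"), n, TRUE),
                               source = "x", type = "motif_match",
                               score = ".",
                               attributes = sprintf("k=%d;note=a b", 1:n))
  GenomeInfoDb::seqlevels(gr) <- c("c2", "c1")
  path <- tempfile(fileext = ".gff3")
  writeGFF3(gr, path)
  expect_identical(readLines(path, n = 1L), "##gff-version 3")
  back <- readGFF3(path)
  ## identical field multisets
  key <- function(g) sort(paste(GenomicRanges::seqnames(g),
                                GenomicRanges::start(g),
                                GenomicRanges::end(g),
                                GenomicRanges::strand(g),
                                S4Vectors::mcols(g)$attributes))
  expect_identical(key(back), key(gr))
  ## grouping: seqids in seqlevels order, ascending start within
  df <- read.delim(path, header = FALSE, comment.char = "#")
  expect_identical(rle(as.character(df$V1))$values, c("c2", "c1"))
  expect_false(is.unsorted(df$V4[df$V1 == "c1"]))
  expect_false(is.unsorted(df$V4[df$V1 == "c2"]))

  writeGFF3(GenomicRanges::GRanges(), path)
  expect_identical(readLines(path), "##gff-version 3")
})

test_that("BED serialization keeps the six-column contract and 0-based starts", {
  path <- tempfile(fileext = ".bed")
  rows <- data.frame(chrom = "c1", start = 9L, end = 30L, geneID = "g1",
                     count = 4L, product = "hypothetical protein")
  writeBed(rows, path)
  expect_identical(readLines(path), "c1\t9\t30\tg1\t4\thypothetical protein")
  back <- readBed(path)
  expect_identical(back$start, 9L)
  expect_identical(back$end, 30L)
  ## BED width equals the GFF width of the 10..30 gene
  expect_identical(back$end - back$start, 30L - 10L + 1L)
  writeBed(rows[0, ], path)
  expect_identical(file.size(path), 0)
  expect_identical(nrow(readBed(path)), 0L)
  expect_error(writeBed(transform(rows, start = 30L), path), "start < end")
})

test_that("Roary tables resolve core vs dispensable membership", {
  path <- tempfile(fileext = ".csv")
  meta <- paste(rep("\"m\"", 14L), collapse = ",")
  writeLines(c(paste(c(sprintf('"c%d"', 1:14), '"s1"', '"s2"'), collapse = ","),
               paste0(meta, ',"geneA_1","geneA_2"'),
               paste0(meta, ',"geneB_1",""')), path)
  r <- readRoary(path)
  expect_identical(r$nStrains, 2L)
  expect_identical(unname(r$core), c(TRUE, FALSE))
  expect_identical(unname(r$geneClass[c("geneA_1", "geneA_2", "geneB_1")]),
                   c("core", "core", "dispensable"))
  ## missing strain columns
  writeLines(paste(sprintf('"c%d"', 1:14), collapse = ","), path)
  expect_error(readRoary(path), "strain")
})

test_that("fixture Roary files recover their planted core/dispensable counts", {
  fx <- simulateMethylome(tempfile("fx"), seed = 23, nRepl = 1L,
                          replLengths = 20000L,
                          plantCounts = c(CDS = 2L, nCDS = 2L, tIG = 1L,
                                          US = 1L),
                          coreFraction = 2 / 3)
  r <- readRoary(fx$paths[["roary"]])
  expect_identical(sum(r$core), length(fx$coreGenes))
  expect_setequal(names(r$geneClass)[r$geneClass == "core" &
                                       names(r$geneClass) %in%
                                         fx$genes$geneID],
                  fx$coreGenes)
})

test_that("annotation parsing agrees with rtracklayer on a fixture", {
  fx <- simulateMethylome(tempfile("fx"), seed = 61, nRepl = 1L,
                          replLengths = 15000L,
                          plantCounts = c(CDS = 2L, nCDS = 1L, tIG = 1L,
                                          US = 1L))
  ours <- readGeneAnnotation(fx$paths[["annotation"]])
  ref <- rtracklayer::import(fx$paths[["annotation"]], format = "gff3")
  ref <- ref[ref$type == "CDS"]
  expect_identical(GenomicRanges::start(ours), GenomicRanges::start(ref))
  expect_identical(GenomicRanges::end(ours), GenomicRanges::end(ref))
  expect_identical(as.character(GenomicRanges::strand(ours)),
                   as.character(GenomicRanges::strand(ref)))
  expect_identical(S4Vectors::mcols(ours)$geneID, ref$ID)
})

test_that("motif files are validated at load time", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# comment", " GANTC ", "GCCAGG", ""), path)
  expect_identical(readMotifFile(path), c("GANTC", "GCCAGG"))
  writeLines(c("GANTC", "GANTC"), path)
  expect_error(readMotifFile(path), "duplicate")
  writeLines("GAXTC", path)
  expect_error(readMotifFile(path), "invalid IUPAC")
  writeLines("# only comments", path)
  expect_error(readMotifFile(path), "no motifs")
})
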