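#' MethylomeDataSet: the three harmonized inputs plus the motif list
#'
#' Central container tying together one bacterial methylome analysis:
#' the genome (one `DNAStringSet` entry per replicon), the gene annotation
#' (`GRanges` with `geneID`/`product`), the modified-base calls (width-1
#' `GRanges` with `modType` and verbatim `attributes`), and the IUPAC
#' motifs to map. Validity enforces a shared seqid namespace (every
#' annotation/methylation seqid present in the genome), in-range
#' coordinates, and a valid, duplicate-free motif list.
#'
#' @slot genome Named `DNAStringSet` of replicon sequences.
#' @slot genes `GRanges` of gene/CDS records.
#' @slot meth Width-1 `GRanges` of modified-base calls.
#' @slot motifs Character vector of IUPAC motifs.
#'
#' @seealso [readMethylomeDataSet()] to build one from files,
#'   [scanMotifs()], [partitionFeatures()], [crossMethylation()].
#' @export
setClass("MethylomeDataSet",
         slots = c(genome = "DNAStringSet",
                   genes = "GRanges",
                   meth = "GRanges",
                   motifs = "character"))

setValidity("MethylomeDataSet", function(object) {
  msgs <- character(0)
  g <- object@genome
  if (!length(g)) msgs <- c(msgs, "genome holds no replicons")
  if (is.null(names(g)) || anyDuplicated(names(g)))
    msgs <- c(msgs, "replicon names must be unique and non-NULL")
  lens <- stats::setNames(Biostrings::width(g), names(g))
  for (nm in c("genes", "meth")) {
    gr <- slot(object, nm)
    unknown <- setdiff(unique(as.character(seqnames(gr))), names(g))
    if (length(unknown))
      msgs <- c(msgs, paste0(nm, " seqid(s) absent from genome: ",
                             paste(unknown, collapse = ", ")))
    else if (length(gr)) {
      if (any(start(gr) < 1L) ||
          any(end(gr) > lens[as.character(seqnames(gr))]))
        msgs <- c(msgs, paste0(nm, " has coordinates outside its replicon"))
    }
  }
  if (length(object@meth) && any(width(object@meth) != 1L))
    msgs <- c(msgs, "methylation records must have width 1")
  if (length(object@genes)) {
    if (!all(c("geneID", "product") %in% colnames(mcols(object@genes))))
      msgs <- c(msgs, "genes need geneID and product metadata columns")
    else if (anyDuplicated(mcols(object@genes)$geneID))
      msgs <- c(msgs, "duplicate geneID(s) in annotation")
  }
  if (length(object@motifs)) {
    ok <- vapply(object@motifs, function(m)
      !inherits(try(.checkMotif(m), silent = TRUE), "try-error"),
      logical(1L))
    if (!all(ok))
      msgs <- c(msgs, paste0("invalid motif(s): ",
                             paste(object@motifs[!ok], collapse = ", ")))
    if (anyDuplicated(object@motifs))
      msgs <- c(msgs, "duplicate motifs")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MethylomeDataSet from in-memory objects
#'
#' @param genome Named `DNAStringSet`.
#' @param genes `GRanges` with `geneID` and `product` metadata columns.
#' @param meth Width-1 `GRanges` of modified-base calls.
#' @param motifs Character vector of IUPAC motifs.
#' @return A validated [MethylomeDataSet-class] object.
#' @export
MethylomeDataSet <- function(genome, genes = GRanges(), meth = GRanges(),
                             motifs = character(0)) {
  motifs <- if (length(motifs))
    vapply(motifs, .checkMotif, character(1L), USE.NAMES = FALSE)
  else character(0)
  new("MethylomeDataSet", genome = genome, genes = genes, meth = meth,
      motifs = motifs)
}

#' Build a MethylomeDataSet from the four input files
#'
#' Convenience constructor reading the genome FASTA, the annotation GFF3,
#' the SMRT-dialect modified-base GFF3 and the motif text file. Inputs are
#' expected to share a seqid namespace already (see [normalizeSeqids()]).
#'
#' @param fasta,annotation,methylation,motifs File paths.
#' @param featureTypes Passed to [readGeneAnnotation()].
#' @param modTypes Passed to [readMethylationGFF()].
#' @return A [MethylomeDataSet-class].
#' @export
readMethylomeDataSet <- function(fasta, annotation, methylation, motifs,
                                 featureTypes = c("CDS", "gene"),
                                 modTypes = NULL) {
  genome <- readGenomeFasta(fasta)
  genes <- readGeneAnnotation(annotation, featureTypes, genome = genome)
  meth <- readMethylationGFF(methylation, modTypes, genome = genome)
  MethylomeDataSet(genome, genes, meth, readMotifFile(motifs))
}

#' @describeIn MethylomeDataSet-class Replicon sequences (`DNAStringSet`).
#' @param x,object A `MethylomeDataSet`.
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @export
setMethod("genomeSeq", "MethylomeDataSet", function(x) x@genome)

#' @describeIn MethylomeDataSet-class Gene annotation (`GRanges`).
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @export
setMethod("geneRanges", "MethylomeDataSet", function(x) x@genes)

#' @describeIn MethylomeDataSet-class Modified-base calls (`GRanges`).
#' @export
setGeneric("methCalls", function(x) standardGeneric("methCalls"))

#' @export
setMethod("methCalls", "MethylomeDataSet", function(x) x@meth)

#' @describeIn MethylomeDataSet-class IUPAC motif list (character).
#' @export
setGeneric("motifPatterns", function(x) standardGeneric("motifPatterns"))

#' @export
setMethod("motifPatterns", "MethylomeDataSet", function(x) x@motifs)

#' @export
setMethod("show", "MethylomeDataSet", function(object) {
  lens <- Biostrings::width(object@genome)
  cat("MethylomeDataSet\n",
      " replicons : ", length(object@genome), " (",
      format(sum(lens), big.mark = ","), " bp)\n",
      " genes     : ", length(object@genes), "\n",
      " meth calls: ", length(object@meth),
      if (length(object@meth))
        paste0(" (", paste(names(sort(table(mcols(object@meth)$modType),
                                      decreasing = TRUE)),
                           collapse = ", "), ")") else "", "\n",
      " motifs    : ", paste(object@motifs, collapse = ", "), "\n",
      sep = "")
})
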