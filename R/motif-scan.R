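.encodeSequence <- function(sequence) {
  chars <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1L]]
  enc <- match(chars, .GENOME_BASES)
  if (anyNA(enc))
    stop("sequence contains non-ACGTN character(s): ",
         paste(unique(chars[is.na(enc)]), collapse = ", "), call. = FALSE)
  enc
}

## Naive scan of one strand: every window of length m is tested code-by-code
## against the pattern, vectorised over window start positions with early
## exit once no window survives.  O(m * (n - m + 1)) comparisons.
.scanOneStrand <- function(enc, patChars) {
  n <- length(enc)
  m <- length(patChars)
  if (m > n) return(integer(0))
  ok <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    allowed <- .IUPAC_MATCH[patChars[j], ]
    ok <- ok & allowed[enc[j:(j + n - m)]]
    if (!any(ok)) return(integer(0))
  }
  which(ok)
}

#' Scan one replicon for an IUPAC motif on both strands
#'
#' Naive window-by-window matcher: every length-`m` window of the plus
#' strand is tested against the pattern (a hit is reported on strand `+`)
#' and against the pattern's reverse complement (reported on strand `-`).
#' All coordinates are plus-strand, 1-based inclusive. Overlapping hits are
#' all reported, and a palindromic motif yields one hit per strand at the
#' same locus. Results are sorted by start, then strand (`+` before `-`).
#'
#' @param sequence A single replicon: character string, `DNAString`, or a
#'   length-1 `DNAStringSet`. Alphabet `A,C,G,T,N` after uppercasing.
#' @param motif IUPAC motif string.
#' @param seqid Sequence identifier used in the result (default `"seq"` or
#'   the `DNAStringSet` name).
#' @param circular If `TRUE`, windows wrapping across the replicon origin
#'   are also tested (default `FALSE`: assemblies are treated as linear).
#' @return A `GRanges` with strand and a `motif` metadata column.
#' @examples
#' scanReplicon("GAATCGG", "GANTC", seqid = "c1")
#' @export
scanReplicon <- function(sequence, motif, seqid = NULL, circular = FALSE) {
  if (is(sequence, "DNAStringSet")) {
    if (length(sequence) != 1L)
      stop("scanReplicon() takes a single replicon", call. = FALSE)
    if (is.null(seqid)) seqid <- names(sequence)
    sequence <- as.character(sequence[[1L]])
  }
  if (is.null(seqid)) seqid <- "seq"
  motif <- .checkMotif(motif)
  patChars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  rcChars <- strsplit(reverseComplementIupac(motif), "", fixed = TRUE)[[1L]]
  enc <- .encodeSequence(sequence)
  n <- length(enc)
  m <- length(patChars)

  scanEnc <- enc
  if (circular && m > 1L && n >= m)
    scanEnc <- c(enc, enc[seq_len(m - 1L)])

  fwd <- .scanOneStrand(scanEnc, patChars)
  rev <- .scanOneStrand(scanEnc, rcChars)
  fwd <- fwd[fwd <= n]
  rev <- rev[rev <= n]

  nHit <- length(fwd) + length(rev)
  gr <- GRanges(seqnames = rep(seqid, nHit),
                ranges = IRanges(start = c(fwd, rev), width = m),
                strand = rep(c("+", "-"), c(length(fwd), length(rev))))
  if (!nHit) seqlevels(gr) <- seqid
  mcols(gr)$motif <- rep(motif, length(gr))
  gr <- gr[order(start(gr), match(as.character(strand(gr)), c("+", "-")))]
  gr
}

#' Scan a whole genome for a set of motifs
#'
#' Runs [scanReplicon()] for each motif over each replicon and concatenates
#' the per-replicon results in FASTA order, giving a deterministic ordering
#' (replicon, then start, then strand).
#'
#' @param genome A named `DNAStringSet` (one entry per replicon) or a
#'   [MethylomeDataSet].
#' @param motifs Character vector of IUPAC motifs. For a `MethylomeDataSet`
#'   the default is its own motif list.
#' @param circular Passed to [scanReplicon()].
#' @return A named `GRangesList`-like list, one `GRanges` per motif.
#' @export
scanMotifs <- function(genome, motifs = NULL, circular = FALSE) {
  if (is(genome, "MethylomeDataSet")) {
    if (is.null(motifs)) motifs <- motifPatterns(genome)
    genome <- genomeSeq(genome)
  }
  if (is.null(motifs) || !length(motifs))
    stop("no motifs supplied", call. = FALSE)
  motifs <- vapply(motifs, .checkMotif, character(1L), USE.NAMES = FALSE)
  if (anyDuplicated(motifs))
    stop("duplicate motifs: ",
         paste(unique(motifs[duplicated(motifs)]), collapse = ", "),
         call. = FALSE)
  sl <- stats::setNames(Biostrings::width(genome), names(genome))
  out <- lapply(motifs, function(mo) {
    per <- lapply(names(genome), function(sq) {
      g <- scanReplicon(as.character(genome[[sq]]), mo, seqid = sq,
                        circular = circular)
      seqlevels(g) <- names(genome)
      g
    })
    gr <- do.call(c, per)
    seqlengths(gr) <- sl
    gr
  })
  names(out) <- motifs
  out
}
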