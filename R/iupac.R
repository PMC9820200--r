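## IUPAC nucleotide codes and the base sets they stand for.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_CODES <- names(.IUPAC_SETS)
.GENOME_BASES <- c("A", "C", "G", "T", "N")

## Match table: rows = motif codes, cols = genome bases.  A genome N is an
## unknown base: it matches only the motif code N, never a concrete code --
## methylation cannot be evidenced on an unknown base, and assembly gaps must
## not inflate match counts.
.IUPAC_MATCH <- local({
  m <- matrix(FALSE, nrow = length(.IUPAC_CODES), ncol = length(.GENOME_BASES),
              dimnames = list(.IUPAC_CODES, .GENOME_BASES))
  for (code in .IUPAC_CODES) m[code, .IUPAC_SETS[[code]]] <- TRUE
  m[, "N"] <- FALSE
  m["N", "N"] <- TRUE
  m
})

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

.checkMotif <- function(pattern) {
  pattern <- toupper(trimws(pattern))
  if (!nzchar(pattern))
    stop("empty motif pattern", call. = FALSE)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), .IUPAC_CODES)
  if (length(bad))
    stop("invalid IUPAC code(s) in motif '", pattern, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  pattern
}

#' Does an IUPAC code match a genome base?
#'
#' Vectorised lookup into the IUPAC nucleotide table. A genome `N`
#' (unknown base) matches only the motif code `N`; concrete and degenerate
#' codes never match it, so assembly gaps cannot produce motif hits.
#'
#' @param code Character vector of IUPAC nucleotide codes (motif side).
#' @param base Character vector over `A,C,G,T,N` (genome side).
#' @return Logical vector.
#' @examples
#' iupacMatches(c("N", "R", "R", "Y"), c("A", "A", "C", "T"))
#' @export
iupacMatches <- function(code, base) {
  code <- toupper(code)
  base <- toupper(base)
  bad <- setdiff(unique(code), .IUPAC_CODES)
  if (length(bad))
    stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  badb <- setdiff(unique(base), .GENOME_BASES)
  if (length(badb))
    stop("invalid genome base(s): ", paste(badb, collapse = ", "), call. = FALSE)
  .IUPAC_MATCH[cbind(code, base)]
}

#' Reverse complement of an IUPAC pattern
#'
#' Complements every code under the IUPAC complement table
#' (A<->T, C<->G, R<->Y, K<->M, B<->V, D<->H; S, W, N are self-complementary)
#' and reverses the string.
#'
#' @param pattern IUPAC nucleotide string (may be empty).
#' @return The reverse-complemented IUPAC string.
#' @examples
#' reverseComplementIupac("GANTC")   # palindromic
#' reverseComplementIupac("GCCAGG")
#' @export
reverseComplementIupac <- function(pattern) {
  if (!nzchar(pattern)) return(pattern)
  pattern <- .checkMotif(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  paste(rev(unname(.IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Degeneracy of an IUPAC pattern
#'
#' Product over positions of the number of concrete bases each code allows;
#' 1 exactly when the pattern is a plain `A/C/G/T` word.
#'
#' @param pattern IUPAC nucleotide string.
#' @return Integer degeneracy (>= 1).
#' @export
motifDegeneracy <- function(pattern) {
  pattern <- .checkMotif(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  prod(lengths(.IUPAC_SETS[chars]))
}

#' Is a motif palindromic?
#'
#' A motif is palindromic when it equals its own reverse complement under
#' IUPAC complementation (e.g. `GANTC`, the CcrM recognition site). Such
#' motifs match the same locus on both strands.
#'
#' @param pattern IUPAC nucleotide string.
#' @return Logical scalar.
#' @export
isPalindromic <- function(pattern) {
  pattern <- .checkMotif(pattern)
  identical(pattern, reverseComplementIupac(pattern))
}

#' Expand an IUPAC pattern into all concrete words
#'
#' Enumerates the `motifDegeneracy(pattern)` plain `A/C/G/T` words the
#' pattern stands for. Used by the fixture generator to keep background
#' sequence motif-free, and by tests as a brute-force matching oracle.
#'
#' @param pattern IUPAC nucleotide string.
#' @return Character vector of concrete words.
#' @export
expandIupac <- function(pattern) {
  pattern <- .checkMotif(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  words <- ""
  for (ch in chars)
    words <- as.vector(outer(words, .IUPAC_SETS[[ch]], paste0))
  words
}
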