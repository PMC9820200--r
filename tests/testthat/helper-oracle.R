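## Independent brute-force oracles used to check the implementation.
## They share no code with the package's matcher or crosser.

## Expand-and-substring-search motif oracle: enumerate every concrete word
## of the motif (plus strand) and of its reverse complement (minus strand),
## then test every window of the sequence by string equality. Overlapping
## hits are found because every window is tested.
oracleScan <- function(sequence, motif) {
  sequence <- toupper(sequence)
  m <- nchar(motif)
  n <- nchar(sequence)
  if (m > n || m == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  fwd <- bacMethMap::expandIupac(motif)
  rev <- bacMethMap::expandIupac(bacMethMap::reverseComplementIupac(motif))
  wins <- substring(sequence, seq_len(n - m + 1L), seq_len(n - m + 1L) + m - 1L)
  plus <- which(wins %in% fwd)
  minus <- which(wins %in% rev)
  out <- data.frame(start = c(plus, minus),
                    end = c(plus, minus) + m - 1L,
                    strand = rep(c("+", "-"), c(length(plus), length(minus))),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

matchesAsDf <- function(gr) {
  df <- data.frame(start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## Random IUPAC motif with a bounded number of ambiguity codes, so the
## expansion oracle stays small.
randomMotif <- function(minLen = 4L, maxLen = 10L, maxAmbig = 3L) {
  len <- sample(minLen:maxLen, 1L)
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  nAmb <- sample(0:min(maxAmbig, len), 1L)
  if (nAmb > 0L) {
    amb <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
    chars[sample(len, nAmb)] <- sample(amb, nAmb, replace = TRUE)
  }
  paste(chars, collapse = "")
}

## Brute-force crossing oracle: a triple loop over (record, match, interval),
## applying the category rules directly.
oracleCross <- function(methDf, matchDf, cdsDf, usDf) {
  out <- NULL
  for (i in seq_len(nrow(methDf))) {
    p <- methDf$pos[i]; s <- methDf$strand[i]; sq <- methDf$seqid[i]
    inMatch <- FALSE
    for (j in seq_len(nrow(matchDf))) {
      if (matchDf$seqid[j] == sq && matchDf$start[j] <= p &&
          p <= matchDf$end[j] &&
          (s == "*" || s == matchDf$strand[j])) { inMatch <- TRUE; break }
    }
    if (!inMatch) next
    cat3 <- NULL
    for (j in seq_len(nrow(cdsDf))) {
      if (cdsDf$seqid[j] == sq && cdsDf$start[j] <= p && p <= cdsDf$end[j]) {
        cat3 <- c(cat3, if (s == "*" || s == cdsDf$strand[j]) "CDS" else "nCDS")
      }
    }
    if (is.null(cat3)) {
      inUs <- FALSE
      for (j in seq_len(nrow(usDf))) {
        if (usDf$seqid[j] == sq && usDf$start[j] <= p && p <= usDf$end[j] &&
            (s == "*" || s == usDf$strand[j])) { inUs <- TRUE; break }
      }
      cat3 <- if (inUs) "US" else "tIG"
    }
    out <- rbind(out, data.frame(pos = p, category = cat3,
                                 stringsAsFactors = FALSE))
  }
  out
}

## Small in-memory annotation helper for unit tests.
makeGenes <- function(seqid, start, end, strand, geneID = NULL,
                      product = "") {
  if (is.null(geneID)) geneID <- sprintf("g%d", seq_along(start))
  GenomicRanges::GRanges(rep_len(seqid, length(start)),
                         IRanges::IRanges(start, end),
                         strand = strand, geneID = geneID,
                         product = rep_len(product, length(start)))
}
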