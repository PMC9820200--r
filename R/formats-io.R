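#' Read a genome FASTA file
#'
#' Reads a (multi-)FASTA genome. Sequences are uppercased; the sequence
#' identifier is the header token before the first whitespace. Characters
#' outside `A,C,G,T,N` and duplicate identifiers are hard errors naming the
#' offending record (rather than being silently mapped to `N`).
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`, one entry per replicon.
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, ">"))
    stop("not a FASTA file (no '>' header): ", path, call. = FALSE)
  seqs <- readBStringSet(path)
  if (!length(seqs)) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate seqid(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(seqs) <- ids
  up <- toupper(as.character(seqs))
  for (i in seq_along(up)) {
    bad <- setdiff(unique(strsplit(up[[i]], "", fixed = TRUE)[[1L]]),
                   .GENOME_BASES)
    if (length(bad))
      stop("record '", ids[i], "' in ", path,
           " contains non-nucleotide character(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  DNAStringSet(stats::setNames(up, ids))
}

## Raw 9-column GFF3 reader; returns a data.frame plus original line numbers
## and the verbatim line, so dialect-specific readers can report precise
## errors and preserve attributes byte-for-byte.
.readGff3Raw <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L))
    stop("malformed GFF3 in ", path, ": line ", keep[which(nf != 9L)[1L]],
         " has ", nf[nf != 9L][1L], " column(s), expected 9", call. = FALSE)
  if (!length(keep)) {
    return(data.frame(seqid = character(0), source = character(0),
                      type = character(0), start = integer(0),
                      end = integer(0), score = character(0),
                      strand = character(0), frame = character(0),
                      attributes = character(0), line = integer(0),
                      stringsAsFactors = FALSE))
  }
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  data.frame(seqid = m[, 1L], source = m[, 2L], type = m[, 3L],
             start = as.integer(m[, 4L]), end = as.integer(m[, 5L]),
             score = m[, 6L], strand = m[, 7L], frame = m[, 8L],
             attributes = m[, 9L], line = keep, stringsAsFactors = FALSE)
}

.gffAttr <- function(attributes, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attributes, regexec(pat, attributes))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
         character(1L))
}

#' Read a gene annotation GFF3
#'
#' Extracts gene/CDS records from a standard annotation GFF3 (e.g. Prokka
#' output). When both a `CDS` and a `gene` row describe the same locus
#' (identical seqid/start/end span) the `CDS` row is kept. The gene
#' identifier is taken from the `ID=` attribute, falling back to
#' `locus_tag=`; the product from `product=` (empty when absent).
#'
#' @param path Path to a GFF3 file.
#' @param featureTypes Feature types (column 3) to keep; default
#'   `c("CDS", "gene")` with CDS preferred on shared loci.
#' @param genome Optional `DNAStringSet`; when given, seqids and coordinate
#'   ranges are cross-checked against it.
#' @return A `GRanges` with metadata columns `geneID`, `product`,
#'   `sourceLine`.
#' @export
readGeneAnnotation <- function(path, featureTypes = c("CDS", "gene"),
                               genome = NULL) {
  raw <- .readGff3Raw(path)
  raw <- raw[raw$type %in% featureTypes, , drop = FALSE]
  bad <- which(raw$end < raw$start)
  if (length(bad))
    stop("annotation ", path, " line ", raw$line[bad[1L]],
         ": end < start", call. = FALSE)
  ## CDS preferred when CDS and gene rows describe the same span
  if (nrow(raw)) {
    key <- paste(raw$seqid, raw$start, raw$end, sep = "\r")
    pref <- order(match(raw$type, featureTypes))
    raw <- raw[pref, , drop = FALSE][!duplicated(key[pref]), , drop = FALSE]
    raw <- raw[order(raw$line), , drop = FALSE]
  }
  geneID <- .gffAttr(raw$attributes, "ID")
  lt <- .gffAttr(raw$attributes, "locus_tag")
  geneID[is.na(geneID)] <- lt[is.na(geneID)]
  if (anyNA(geneID) || any(!nzchar(geneID)))
    stop("annotation ", path, " line ",
         raw$line[which(is.na(geneID) | !nzchar(geneID))[1L]],
         ": no ID= or locus_tag= attribute", call. = FALSE)
  if (anyDuplicated(geneID))
    stop("duplicate geneID(s) in ", path, ": ",
         paste(unique(geneID[duplicated(geneID)]), collapse = ", "),
         call. = FALSE)
  product <- .gffAttr(raw$attributes, "product")
  product[is.na(product)] <- ""
  st <- raw$strand
  if (any(!st %in% c("+", "-")))
    stop("annotation ", path, " line ",
         raw$line[which(!st %in% c("+", "-"))[1L]],
         ": gene strand must be '+' or '-'", call. = FALSE)
  gr <- GRanges(raw$seqid, IRanges(raw$start, raw$end), strand = st,
                geneID = geneID, product = product,
                sourceLine = paste(raw$seqid, raw$source, raw$type, raw$start,
                                   raw$end, raw$score, raw$strand, raw$frame,
                                   raw$attributes, sep = "\t"))
  if (!is.null(genome)) .checkAgainstGenome(gr, genome, path, raw$line)
  gr
}

.checkAgainstGenome <- function(gr, genome, path, lines) {
  unknown <- setdiff(unique(as.character(seqnames(gr))), names(genome))
  if (length(unknown))
    stop(path, ": seqid(s) absent from the genome FASTA: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  lens <- stats::setNames(width(genome), names(genome))
  over <- which(end(gr) > lens[as.character(seqnames(gr))] | start(gr) < 1L)
  if (length(over))
    stop(path, " line ", lines[over[1L]], ": coordinates outside replicon '",
         as.character(seqnames(gr))[over[1L]], "' (length ",
         lens[as.character(seqnames(gr))[over[1L]]], ")", call. = FALSE)
  invisible(TRUE)
}

#' Read a SMRT-dialect modified-base GFF3
#'
#' Reads sequencer-produced modified-base calls where column 3 holds the
#' modification type (`m6A`, `m4C`, `modified_base`, ...) and columns 4-5 a
#' 1-bp interval. Rows with `start != end` (occasional 2-bp contexts) use
#' the midpoint, rounded down, with a warning. The attributes column is
#' preserved byte-for-byte, as are source and score.
#'
#' @param path Path to the modified-base GFF3.
#' @param modTypes Optional character vector; keep only these modification
#'   types (default: keep all).
#' @param genome Optional `DNAStringSet` for coordinate cross-checks.
#' @return A width-1 `GRanges` with metadata columns `modType`, `source`,
#'   `score`, `attributes`.
#' @export
readMethylationGFF <- function(path, modTypes = NULL, genome = NULL) {
  raw <- .readGff3Raw(path)
  wide <- which(raw$start != raw$end)
  if (length(wide)) {
    warning(length(wide), " modified-base record(s) in ", path,
            " span more than 1 bp; using the midpoint (rounded down)",
            call. = FALSE)
    raw$start[wide] <- (raw$start[wide] + raw$end[wide]) %/% 2L
    raw$end[wide] <- raw$start[wide]
  }
  if (!is.null(modTypes))
    raw <- raw[raw$type %in% modTypes, , drop = FALSE]
  st <- raw$strand
  if (any(!st %in% c("+", "-", ".")))
    stop("methylation ", path, " line ",
         raw$line[which(!st %in% c("+", "-", "."))[1L]],
         ": strand must be '+', '-' or '.'", call. = FALSE)
  st[st == "."] <- "*"
  gr <- GRanges(raw$seqid, IRanges(raw$start, width = 1L), strand = st,
                modType = raw$type, source = raw$source, score = raw$score,
                attributes = raw$attributes)
  if (!is.null(genome)) .checkAgainstGenome(gr, genome, path, raw$line)
  gr
}

#' Read a newline-delimited motif file
#'
#' One IUPAC motif per line; `#` comment lines are ignored and surrounding
#' whitespace is stripped. Invalid IUPAC characters, duplicates and an
#' empty list are hard errors (motifs are validated at load time, not match
#' time).
#'
#' @param path Path to the motif text file.
#' @return Character vector of uppercase IUPAC motifs.
#' @export
readMotifFile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("motif file ", path, " holds no motifs",
                           call. = FALSE)
  motifs <- vapply(lines, .checkMotif, character(1L), USE.NAMES = FALSE)
  if (anyDuplicated(motifs))
    stop("duplicate motif(s) in ", path, ": ",
         paste(unique(motifs[duplicated(motifs)]), collapse = ", "),
         call. = FALSE)
  motifs
}

#' Read a Roary gene_presence_absence.csv
#'
#' Parses the standard Roary pangenome table (14 metadata columns followed
#' by one column per strain; quoted commas handled). A gene cluster is
#' *core* when its cell is non-empty in every strain column, *dispensable*
#' otherwise.
#'
#' @param path Path to `gene_presence_absence.csv`.
#' @return A list with `presence` (logical gene-by-strain matrix), `strains`,
#'   `nStrains`, `core` (logical per cluster), and `geneClass` (named
#'   character vector mapping every per-strain geneID to
#'   `"core"`/`"dispensable"`).
#' @export
readRoary <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = "character")
  if (ncol(df) < 15L)
    stop("Roary table ", path, " has no strain columns (", ncol(df),
         " column(s); expected 14 metadata columns + >=1 strain)",
         call. = FALSE)
  strains <- colnames(df)[-(1:14)]
  cells <- as.matrix(df[, strains, drop = FALSE])
  presence <- nzchar(cells) & !is.na(cells)
  rownames(presence) <- df[[1L]]
  core <- rowSums(presence) == length(strains)
  ids <- lapply(seq_len(nrow(cells)), function(i) {
    v <- unlist(strsplit(cells[i, ], "[;\t]"))
    v[nzchar(v)]
  })
  geneClass <- stats::setNames(
    rep(ifelse(core, "core", "dispensable"), lengths(ids)), unlist(ids))
  list(presence = presence, strains = strains, nStrains = length(strains),
       core = core, geneClass = geneClass)
}

#' Write records as GFF3
#'
#' Serialises feature-annotated records as GFF3 with a `##gff-version 3`
#' header, 1-based inclusive coordinates, the record category in column 3,
#' and the attributes column passed through verbatim. Rows are grouped by
#' seqid (seqlevels order) with ascending start within each seqid.
#'
#' @param records A `GRanges` whose metadata columns may include `source`,
#'   `type` (column 3), `score` and `attributes`; missing columns default
#'   to `.` / `bacMethMap`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeGFF3 <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!length(records)) return(invisible(path))
  mc <- mcols(records)
  getcol <- function(nm, default) {
    if (nm %in% colnames(mc)) as.character(mc[[nm]]) else
      rep(default, length(records))
  }
  st <- as.character(strand(records))
  st[st == "*"] <- "."
  df <- data.frame(
    seqid = as.character(seqnames(records)),
    source = getcol("source", "bacMethMap"),
    type = getcol("type", "."),
    start = start(records), end = end(records),
    score = getcol("score", "."), strand = st,
    frame = getcol("frame", "."),
    attributes = getcol("attributes", "."),
    stringsAsFactors = FALSE)
  ord <- order(match(df$seqid, seqlevels(records)), df$start)
  df <- df[ord, , drop = FALSE]
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a pipeline-written GFF3 back into a GRanges
#'
#' Generic reader for GFF3 files written by [writeGFF3()]; columns map to a
#' `GRanges` with `source`, `type`, `score`, `frame` and verbatim
#' `attributes` metadata columns.
#'
#' @param path Path to a GFF3 file.
#' @return A `GRanges`.
#' @export
readGFF3 <- function(path) {
  raw <- .readGff3Raw(path)
  st <- raw$strand
  st[!st %in% c("+", "-")] <- "*"
  GRanges(raw$seqid, IRanges(raw$start, raw$end), strand = st,
          source = raw$source, type = raw$type, score = raw$score,
          frame = raw$frame, attributes = raw$attributes)
}

#' Write a per-gene BED table
#'
#' Tab-separated, headerless, six columns in fixed order: chrom, start
#' (0-based half-open), end, geneID, methylation count, protein product.
#'
#' @param rows A data.frame with columns `chrom`, `start`, `end`, `geneID`,
#'   `count`, `product` (BED coordinates, i.e. already 0-based half-open).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeBed <- function(rows, path) {
  stopifnot(all(c("chrom", "start", "end", "geneID", "count", "product")
                %in% colnames(rows)))
  if (nrow(rows) && any(rows$start >= rows$end))
    stop("BED rows must satisfy start < end", call. = FALSE)
  if (nrow(rows) && any(rows$count < 0))
    stop("BED counts must be non-negative", call. = FALSE)
  write.table(rows[, c("chrom", "start", "end", "geneID", "count", "product")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED table written by [writeBed()]
#' @param path Path to the BED file.
#' @return A data.frame with the six canonical columns.
#' @export
readBed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), geneID = character(0),
                      count = integer(0), product = character(0),
                      stringsAsFactors = FALSE))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   quote = "", col.names = c("chrom", "start", "end",
                                             "geneID", "count", "product"))
  df$product <- as.character(df$product)
  df
}
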