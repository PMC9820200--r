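#' Harmonize sequence identifiers across the three inputs
#'
#' The genome FASTA, annotation GFF3 and modified-base GFF3 often come from
#' different tools whose seqids differ only in separator conventions (most
#' commonly a pipe vs. an underscore). This step copies the three files to
#' the output directory with an ordered list of replacement rules applied
#' to every seqid (FASTA header token, GFF3 column 1); the originals are
#' never touched. The FASTA is the authority: after normalization every
#' annotation/methylation seqid must map into the FASTA seqid set, or the
#' run stops listing the unresolved identifiers.
#'
#' @param fasta,annotation,methylation Paths to the three input files.
#' @param outdir Directory for the normalized copies (created if absent).
#' @param rules Named character vector, applied left-to-right; names are
#'   fixed strings to replace, values their replacements. Default: pipe to
#'   underscore.
#' @return A seqid report: list with `fasta`, `annotation`, `methylation`
#'   (per-file seqid sets after normalization), `mapping` (old -> new pairs
#'   actually applied), `unresolved` (always empty on success) and `paths`
#'   (the normalized copies).
#' @examples
#' \dontrun{
#' rep <- normalizeSeqids("genome.fna", "genes.gff", "calls.gff", "out/")
#' }
#' @export
normalizeSeqids <- function(fasta, annotation, methylation, outdir,
                            rules = c("|" = "_")) {
  for (p in c(fasta, annotation, methylation))
    if (!file.exists(p)) stop("no such file: ", p, call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  applyRules <- function(id) {
    for (i in seq_along(rules))
      id <- gsub(names(rules)[i], rules[[i]], id, fixed = TRUE)
    id
  }
  mapping <- new.env(parent = emptyenv())
  note <- function(old, new) if (old != new) assign(old, new, envir = mapping)

  ## FASTA: rewrite the header token before the first whitespace
  fl <- readLines(fasta)
  hdr <- startsWith(fl, ">")
  fastaIds <- character(0)
  for (i in which(hdr)) {
    tok <- sub("^>(\\S*).*$", "\\1", fl[i])
    newTok <- applyRules(tok)
    note(tok, newTok)
    fl[i] <- sub(tok, newTok, fl[i], fixed = TRUE)
    fastaIds <- c(fastaIds, newTok)
  }

  normGff <- function(path) {
    gl <- readLines(path)
    body <- !startsWith(gl, "#") & nzchar(trimws(gl))
    ids <- character(0)
    for (i in which(body)) {
      tab <- regexpr("\t", gl[i], fixed = TRUE)
      if (tab < 0) next
      old <- substr(gl[i], 1L, tab - 1L)
      new <- applyRules(old)
      note(old, new)
      if (old != new)
        gl[i] <- paste0(new, substr(gl[i], tab, nchar(gl[i])))
      ids <- c(ids, new)
    }
    list(lines = gl, ids = unique(ids))
  }
  ann <- normGff(annotation)
  met <- normGff(methylation)

  paths <- file.path(outdir, basename(c(fasta, annotation, methylation)))
  names(paths) <- c("fasta", "annotation", "methylation")
  writeLines(fl, paths[["fasta"]])
  writeLines(ann$lines, paths[["annotation"]])
  writeLines(met$lines, paths[["methylation"]])

  unresolved <- setdiff(union(ann$ids, met$ids), fastaIds)
  if (length(unresolved))
    stop("seqid(s) not present in the genome FASTA after normalization: ",
         paste(unresolved, collapse = ", "), call. = FALSE)

  mapList <- as.list(mapping)
  applied <- if (length(mapList))
    unlist(mapList[base::order(names(mapList))]) else character(0)
  list(fasta = fastaIds, annotation = ann$ids, methylation = met$ids,
       mapping = applied, unresolved = character(0), paths = paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate normalized inputs against the genome
#'
#' Reads the (already seqid-normalized) trio and asserts that every
#' annotation and methylation coordinate lies within its replicon; an
#' out-of-range record is a hard error naming file and record. An empty
#' methylation file is valid (with a warning).
#'
#' @param fasta,annotation,methylation Paths to normalized inputs.
#' @return A data.frame with one row per replicon: `seqid`, `length`,
#'   `nGenes`, `nMeth`.
#' @export
validateInputs <- function(fasta, annotation, methylation) {
  genome <- readGenomeFasta(fasta)
  genes <- readGeneAnnotation(annotation, genome = genome)
  meth <- readMethylationGFF(methylation, genome = genome)
  if (!length(meth))
    warning("methylation file ", methylation, " holds no records",
            call. = FALSE)
  ids <- names(genome)
  data.frame(
    seqid = ids,
    length = unname(Biostrings::width(genome)),
    nGenes = vapply(ids, function(s)
      sum(as.character(seqnames(genes)) == s), integer(1L)),
    nMeth = vapply(ids, function(s)
      sum(as.character(seqnames(meth)) == s), integer(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
}
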