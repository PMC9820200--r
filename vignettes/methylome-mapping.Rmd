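---
title: "Mapping bacterial methylation calls onto motifs and genomic features"
author: "bacMethMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping bacterial methylation calls onto motifs and genomic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacMethMap)
```

## The problem

Single-molecule (SMRT) sequencing calls base modifications — chiefly
N6-methyladenine (m6A) and N4-methylcytosine (m4C) — directly from
polymerase kinetics, and bacterial methylation is laid down by
methyltransferases at short, often degenerate recognition sites (for
example `GANTC`, the target of the cell-cycle-regulated CcrM enzyme of
alphaproteobacteria). The biological questions sit one level up from the
raw calls: *which* motif does each methylated base belong to, and *where*
does it fall relative to the gene annotation — inside a coding sequence on
the sense strand, on the antisense strand, between genes, or in the
putative promoter region upstream of a gene?

`bacMethMap` answers this by crossing three inputs — a genome FASTA, its
annotation GFF3 and the sequencer-produced modified-base GFF3 — with a
user-supplied list of IUPAC motifs, and assigning every methylation record
to one of four feature categories:

* **CDS** — inside a gene body, methylation strand *accordant* with the
  gene;
* **nCDS** — the same interval on the antisense strand (methylation
  *discordant* with the gene);
* **tIG** (true intergenic) — a gap flanked by genes in opposite
  orientations;
* **US** (upstream sequence) — a gap flanked by genes in the same
  orientation, assigned to the downstream-reading gene; operationally the
  promoter-proximal region.

## Pipeline model

The analysis is deterministic and proceeds in five stages, each usable on
its own or through `runPipeline()`.

**Seqid harmonization.** The three inputs frequently come from different
tools whose sequence identifiers differ only by separator (pipe vs.
underscore being the classic case). `normalizeSeqids()` copies the inputs
into the output directory with an ordered list of string replacement rules
(default `| -> _`) applied to every seqid, leaving the originals
untouched. The FASTA is the authority: any annotation or methylation seqid
that does not map into the FASTA set after normalization stops the run.
`validateInputs()` then range-checks every coordinate against its
replicon's length.

**Motif scanning.** `scanReplicon()` is a naive window matcher: every
window of length $m$ on a replicon of length $n$ is tested code-by-code
against the motif (reported on `+`) and against its IUPAC reverse
complement (reported on `-`), giving $O(m \times (n - m + 1))$ character
comparisons, implemented as $m$ vectorised sweeps with an early exit once
no window survives. Conventions that matter:

* a palindromic motif (equal to its reverse complement, like `GANTC`)
  yields one hit per strand at the same locus — both are kept, because the
  downstream crossing is strand-aware and collapsing them would erase the
  CDS/nCDS distinction;
* a genome `N` matches only the motif code `N`, never a concrete or
  degenerate code — methylation cannot be evidenced on an unknown base,
  and this keeps assembly gaps from inflating counts;
* overlapping occurrences (tandem repeats) are all reported;
* replicons are treated as linear by default; `circular = TRUE` also
  tests the windows spanning the origin.

**Feature partitioning.** `partitionFeatures()` tiles each replicon from
the annotation. Gene bodies give CDS (and nCDS by strand flip); each
maximal gene-free gap is classified by its flanking strands — same
orientation gives US (strand and owner from the downstream-reading gene:
the right gene for `+`, the left for `-`), opposite orientations give tIG,
with the converging/diverging sub-orientation recorded in an attribute.
Choices the category definitions leave open were settled as follows:

* *Terminal gaps.* The gap left of a `+`-strand first gene, and the gap
  right of a `-`-strand last gene, are that gene's US; all other terminal
  gaps are tIG. This extends the between-genes rule to the replicon edges
  using the same reading-direction logic.
* *Upstream range.* By default US is the whole gap (`full_gap`); with
  `upstreamRange = r` each US interval is clipped to at most `r` bp
  adjacent to its owner's start and the remainder reclassified tIG.
  Shrinking `r` therefore never increases US bp nor decreases tIG bp, and
  CDS is invariant — a property the tests exercise.
* *Overlapping genes.* Gene bodies win over gaps, and overlapped bp is
  CDS of every overlapping gene; `partitionReport()`, which otherwise
  hard-fails on any gap or double cover in the CDS∪US∪tIG tiling,
  downgrades to a warning for such input.

**Crossing.** `crossMethylation()` admits a methylation record into a
motif's output only when its position lies inside a match of that motif
*on the record's strand* (unstranded `.` records match either strand).
Category assignment is strand-aware as defined above; a record in a US gap
whose strand is discordant with the US interval counts as tIG. A
consequence worth knowing: flipping the strand of every record swaps CDS
and nCDS counts exactly and conserves the intergenic (tIG + US) total, but
moves accordant US records into tIG — the US category is inherently
strand-defined. Records inside overlapping gene bodies produce one output
row per gene, sharing a `recordId` so that totals count records, not
record–gene pairs. Ties for the most-methylated gene are broken by
lexicographic geneID purely for deterministic output.

**Outputs.** Per motif and category (and, with `makeChrom`, per replicon —
the same rows regrouped) the crossed records are written as GFF3 with the
category in column 3 and the original attributes preserved byte-for-byte,
with `motif=` and `geneID=` keys appended. `makeBedTables()` emits one
headerless six-column BED row per feature — chrom, 0-based start, end,
geneID, methylation count, product — keeping zero-count features so each
file doubles as a complete per-feature table (`onlyMethylated` drops
them). tIG rows carry the interval's own coordinates and the two flanking
geneIDs. The statistics log reports, per category, the feature count,
methylated-site and methylated-gene counts and the most methylated gene;
with a Roary `gene_presence_absence.csv` each methylated gene is labelled
core (present in every strain column) or dispensable.

## Plots and their numeric twins

Every figure writes a TSV alongside the image, and all testing is against
the TSV: per-category scatter data (geneID, count), the motif-by-strain
heatmap matrix scaled per row to its maximum (an all-zero row stays zero),
and per-window category counts for the circular density plot. The
circular view lays replicons head-to-tail around a circle, bins them into
windows (default 10 kb — the binning is a free display choice), and draws
four inner rings coloured CDS red, nCDS blue, tIG purple, US yellow under
an outer ring of CDS positions.

## The synthetic fixture generator

`simulateMethylome()` builds a complete input set with known ground truth:
a gene/gap layout whose flanking-strand pattern guarantees both US and tIG
gaps, planted motif occurrences carrying methylation records per category
(default `c(CDS = 40, nCDS = 25, tIG = 10, US = 5)` on two replicons of
60 kb and 40 kb), a Roary table with a configurable core fraction
(default 0.7 over 2 strains), and background sequence rejection-sampled
until it holds **no** chance occurrence of the planted motif on either
strand. That last property makes recovery tests exact rather than
statistical: the pipeline must return precisely the planted counts, and
any discrepancy is a bug, not noise. Everything is deterministic given
`seed`.

What the generator does *not* emulate: kinetics-level realism (IPD ratios,
modification QVs, coverage-dependent call quality), motif discovery (the
motif list is an input by design), overlapping or nested genes, and
compositional structure such as GC skew. Passing the recovery tests
therefore demonstrates the correctness of the mapping logic, not
robustness to upstream base-calling error — records are taken as called.

## A worked example

```{r example, eval = FALSE}
fx <- simulateMethylome("fixture", seed = 1)
res <- runPipeline(fx$paths[["fasta"]], fx$paths[["annotation"]],
                   fx$paths[["methylation"]], fx$paths[["motifs"]],
                   outdir = "out", roary = fx$paths[["roary"]],
                   makeChrom = TRUE)
res$stats
```

On the default fixture this prints 40/25/10/5 methylated sites for
CDS/nCDS/tIG/US — the planted truth — along with per-category feature
counts and top genes.

## Numerical and scale choices

Property tests run the matcher against an independent
expand-and-substring-search oracle on 200 random sequence/motif pairs (up
to 50 kb, motifs up to 10 bp with at most three ambiguity codes so the
expansion stays enumerable), the partition law on 100 random annotations
(3–30 kb), and end-to-end recovery on the default 100 kb fixture; these
sizes exercise every code path while keeping the default suite around a
minute. Coordinates are 1-based inclusive in GFF3 and 0-based half-open
in BED throughout, rare 2-bp modified-base contexts collapse to their
midpoint (rounded down) with a warning, and gene identifiers resolve
`ID=` then `locus_tag=`, failing loudly otherwise.

## Known limitations

Reproducing published per-strain motif tables requires the corresponding
assemblies and sequencer calls, which are not bundled; the package ships
only synthetic data. ONT-style modified-base formats, PWM motifs,
bisulfite data, operon-aware promoter definitions and differential
methylation between strains are out of scope.
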