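Package: bacMethMap
Title: Map Bacterial DNA Methylation Calls onto Motifs and Genomic Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maps single-molecule (SMRT) modified-base calls onto occurrences
    of user-supplied IUPAC-degenerate sequence motifs and onto four
    annotation-derived genomic feature categories - coding sequence (CDS),
    antisense coding sequence (nCDS), true intergenic (tIG) and upstream
    (US) regions - in bacterial genomes. Provides readers and writers for
    FASTA, annotation GFF3, SMRT-dialect modified-base GFF3, BED and Roary
    gene_presence_absence.csv; seqid harmonization across inputs; a naive
    IUPAC motif matcher scanning both strands; a genome partitioner;
    strand-aware crossing of methylation records with motifs and features;
    per-feature and per-chromosome GFF3 output, per-gene BED tables,
    summary statistics with pangenome core/dispensable labelling; and
    scatter, heatmap and circular-density plots. A synthetic-fixture
    generator with planted ground truth supports fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
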