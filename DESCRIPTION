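Package: genomap
Title: Whole-Genome Feature Maps from Tab-Delimited Track Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds, queries and renders whole-genome feature maps for
    small to medium sized genomes (fungi, oomycetes, nematodes, insects).
    A map project is a plain directory of tab-delimited track files in five
    grammars (posn, blast, expr, freq, graph) plus chromosome, gene, colour
    and optional FASTA files; the package parses and writes every grammar,
    partitions genes onto chromosomes and computes per-chromosome
    statistics, answers region and gene-id queries with copy-pasteable
    gene lists, extracts FASTA sub-sequences for selected regions, renders
    deterministic publication-quality maps of the entire genome or a zoomed
    window to SVG and PNG, converts standard formats (GFF3, BED, BLAST
    tabular, SNP position lists) into track files, and generates seeded
    synthetic projects for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    png,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
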