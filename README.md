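# genomap

Whole-genome feature maps from tab-delimited track files.

`genomap` is for research groups who have a newly sequenced small or medium
sized genome (fungi, oomycetes, nematodes, insects, ...) plus a growing pile
of *other* evidence about it — classical-genetics marker maps, forward and
reverse genetics hits, transcriptomics calls, proteomics, blast searches
against external databases — and who want all of it drawn onto the whole
genome at once, at any scale, in publication-quality figures, without a
database or a web stack. Every chromosome is drawn to scale as a grey
horizontal bar and any number of feature tracks are layered onto it; any
region can be queried for the features it contains, and its sequence
extracted.

## The map project model

A map is a plain directory tree:

* `_data/` — the genome definition: a `chromosomes` file (`id = length`
  per line, e.g. `1 = 11723881`; up to 1000 chromosomes/scaffolds), a
  tab-delimited `genes` file (chromosome id, first nt, last nt, strand,
  gene id, then free annotation fields), an optional `colors` file
  (`clName = $RRGGBB`, overlaying the 16 built-in Windows colour names), an
  optional `credits` text, and optional per-chromosome `id.fasta`
  sequences.
* `_seqs/` — FASTA fragments saved for selected regions
  (`id_firstnt-lastnt.fasta`).
* `_stats/` — derived per-chromosome statistics, regenerated on every scan.
* every other folder is a **menu node**; nesting is preserved, and each
  contained track file is a displayable leaf.

Tracks come in five tab-delimited grammars, distinguished by extension:

| kind     | displays                            | styling payload |
|----------|-------------------------------------|-----------------|
| `.posn`  | features at their position          | one colour (first `#`-line) |
| `.blast` | regions hit by a similarity search  | colour + E-value cut-off; hits whose best E-value exceeds the cut-off are not displayed |
| `.expr`  | features in per-row colours (e.g. induced red / repressed blue) | colour in the last field |
| `.freq`  | valued regions through a colour gradient (gene density, %GC, recombination frequency) | up to 20 colours with ascending cut-offs, e.g. `# clBeige 1 clKhaki 2 clGold 3 clGoldenRod 4 clTomato 8 clCrimson` |
| `.graph` | a histogram along each chromosome (e.g. SNPs per 50,000 nt window) | value in the last field |

All coordinates are 1-based and inclusive at both ends, everywhere.
Converters are provided from GFF3, BED, tabular BLAST (outfmt 6), SNP
position lists and FASTA (%GC windows, pseudo-chromosome assembly from
contigs).

## Worked example

The package ships a generator for a miniature demonstration project: four
chromosomes with a cluster of ten toxin-biosynthesis-style genes planted in
the middle of chromosome 2, displayed through a blue `posn` track.

```r
library(genomap)

root <- file.path(tempdir(), "demo")
make_worked_example(root)
project <- scan_project(root)
project$stats
#>   chrom_id length gene_count bp_per_gene mean_gene_length
#> 1        1 117000          8       14625         1500.000
#> 2        2  90000         18        5000         1777.778
#> 3        3  78000          8        9750         1500.000
#> 4        4  96000          8       12000         1500.000
```

`bp_per_gene` is chromosome length over gene count; `mean_gene_length` is
the mean feature span. Select the cluster region on chromosome 2 and list
what the displayed track shows there (the equivalent of dragging a
rectangle on the map):

```r
tr <- load_track(project, "Toxin_cluster/cluster")
gl <- features_in_region(tr, region_selection("2", 39000, 66000),
                         chromosomes = project$genome$chromosomes)
cat(format_gene_list(gl))
#> chrom  gene_length  first  last   strand  id      annotation                         track
#> 2      2000         40000  41999  +       TOX_01  toxin biosynthesis cluster gene 1  cluster
#> 2      2000         42600  44599  -       TOX_02  toxin biosynthesis cluster gene 2  cluster
#> ...                                               (10 rows, TAB-separated)
```

Exactly the ten planted genes are reported, with their length
(`last − first + 1`), strand and annotation — ready to paste into a
spreadsheet. Render the whole genome with the cluster exaggerated so the
2 kb genes stay visible at genome scale, and pull the sequence under the
first gene:

```r
img <- render_map(project$genome, tr,
                  full_viewport(project$genome, width_px = 900,
                                exaggerate = TRUE))
save_map(img, file.path(root, "map.svg"))   # byte-stable SVG; PNG too

extract_region_sequences(project, region_selection("2", 40000, 40059))
#> written: _seqs/2_40000-40059.fasta, 60 nt — the verbatim slice
#> of _data/2.fasta at those 1-based inclusive coordinates
```

A command-line wrapper over the same functions is installed at
`system.file("cli", "genomap", package = "genomap")` with subcommands
`scan`, `stats`, `render`, `region`, `search`, `extract`, `convert` and
`fixtures`.

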