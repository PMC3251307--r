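---
title: "Building, querying and rendering whole-genome feature maps"
author: "genomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building, querying and rendering whole-genome feature maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomap)
```

## The model

`genomap` treats a genome map as three layers:

1. **A chromosome backbone** — an ordered list of (id, length) pairs.
   Order is display order, deliberately *not* size order: for species
   whose chromosome numbers come from a genetic map, physical size and
   numbering disagree, and the file order is authoritative. The backbone
   is capped at 1000 chromosomes/scaffolds; genomes assembled only to
   supercontig level are handled identically, and unassigned contigs can
   be joined into a pseudo-chromosome (`concat_contigs()`, N spacers
   between contigs) so they display as one unit.

2. **Feature tracks** — named, typed collections of records in five
   grammars (`posn`, `blast`, `expr`, `freq`, `graph`). Every record has
   the same five-field core (chromosome id, first nt, last nt, strand,
   id); the kind adds its payload: one track colour, an E-value cut-off,
   per-row colours, a binned numeric value, or a histogram value. The
   grammars are deliberately plain tab-delimited text so that tracks can
   be produced from any upstream analysis with a few lines of scripting —
   or with the converters in this package.

3. **A project directory** that ties them together. The three
   underscore folders (`_data`, `_seqs`, `_stats`) are infrastructure and
   are auto-created; every other folder is a menu node, so the user's
   directory layout *is* the user interface taxonomy.

All coordinates in the package are 1-based and inclusive at both ends.
This is enforced at the boundaries: the BED converter shifts half-open
0-based intervals (`chromStart + 1`), GFF3 passes through unchanged, and
everything downstream assumes one convention only.

## Parameter and rule choices

**Blast retention.** A data line may carry many `query id + E-value`
pairs; only the first (smallest) E-value is compared with the cut-off,
which is why pairs must be sorted ascending. Files with unsorted pairs
are repaired (re-sorted) with a warning rather than rejected, consistent
with the package's tolerant-reader policy for community-generated files.
Records above the cut-off are dropped at parse time with a count
reported, since they would never be displayed.

**Gradient binning.** A `freq` gradient is k colours (k ≤ 20) with k − 1
strictly ascending boundaries. Whether a value exactly on a boundary
belongs to the lower or upper bin is under-determined by the grammar;
the package fixes half-open bins `[lower, upper)` — the colour index is
the count of boundaries ≤ value — with the first bin open below and the
last open above. This makes `assign_gradient_colour()` total over finite
values and monotone in the value, which the test suite checks against an
independent `findInterval()` oracle.

**Colour encoding.** `colors` entries are `clName = $RRGGBB` read in
red, green, blue byte order, exactly as documented for the file format —
note this is the *opposite* of the BGR order some GUI toolkits use
internally for the same notation. Unknown colour names never abort a
render: they fall back to mid-grey (`#808080`) with a warning.

**Per-chromosome statistics.** "Base pairs per gene" is interpreted as
chromosome length ÷ gene count (genome bp per gene), the chromosome-level
density figure; the mean feature length is also emitted as a separate,
clearly labelled column so neither reading is lost. Geneless chromosomes
report `NA` rather than a division by zero.

**Region queries.** Overlap is any-overlap on closed intervals
(`start ≤ sel.last` and `end ≥ sel.first`): a partially visible block is
still drawn, so it is still listed. The indexed path uses
`IRanges::findOverlaps()`; the brute-force scan survives in the test
suite as the oracle. Gene-list rows are ordered by track (display order)
then start. For `freq`/`graph` records — which are regions, not genes —
the numeric value is reported in the annotation column and the strand/id
columns are blanked; for `blast` records the best query id and E-value
are shown. Multi-line annotation (the optional extra fields of the genes
file) is collapsed with `"; "` into one TSV cell so pasted output keeps
its column structure.

**Gene search.** Matching is exact and case-sensitive by default (ids
are database accessions), with an `ignore_case` option. Ambiguous ids
return the first hit in (chromosome order, start) with a warning. Hits
are persisted as `Temp/<name>.posn` tracks so a search result is
redisplayable like any other track.

**Windowed tracks.** Density (`positions_to_graph()`) and %GC
(`fasta_to_gc_freq()`) tile each chromosome with fixed windows anchored
at nt 1, final window truncated at the chromosome end; the default
window is 50,000 nt, the conventional SNPs-per-50-kb scale. Counts (not
rates) are kept in the truncated final window so window values always
sum to the number of positions. %GC is `100 (G + C) / (non-N length)`;
all-N windows have no defined value and are skipped with a warning.
Window anchoring at nt 1 is this package's choice — upstream analyses
may anchor differently, which matters only for the final partial window.

## Rendering

The renderer is a pure function from (genome, tracks, viewport, style)
to a scene of axis-aligned filled rectangles. The interactive zoom stack
of a GUI browser is replaced by the explicit `viewport()`: a global
`first_nt..last_nt` window applied to every chromosome, plus pixel
geometry. The coordinate map is
`x = floor((nt − first) / span × width)`; `px_to_nt()` is its
pseudo-inverse, exact to one pixel's worth of nucleotides.

Layout: one row group per chromosome in backbone order — grey bar first
(length proportional to the visible part of the chromosome, accurate to
±1 px), then one sub-row per displayed track in display order. Blocks
are at least 1 px wide; the exaggerate option raises that floor to 3 px
(widening rightward, clamped to the canvas) so sub-pixel features remain
visible at whole-genome scale. Strand does not alter placement; it is
reported in the gene list instead. Graph rows scale values linearly so
the data range `[min(y, 0), max(y, 0)]` spans the row height with the
baseline at 0 — an all-zero track degenerates to a flat baseline, and
negative values hang below the baseline with sign preserved. The scale
is computed from the whole track, so the per-chromosome rows of one
track share a y-axis.

Output determinism is a design requirement, not an accident: SVG is
generated directly from the scene (no graphics device state, no
timestamps), labels are drawn with a built-in 5×7 block glyph font as
rectangles rather than text elements (no font metrics), and the PNG
rasterizer fills the same rectangles into a pixel array. Repeated runs
are byte-identical, which makes figures reproducible artefacts and
lets the test suite assert equality on bytes.

## The synthetic-data generator

`make_project()` builds a complete project from one integer seed:
chromosome lengths uniform in 0.5–1.2 Mb over four chromosomes, 400
genes of mean length 1.5 kb placed non-overlapping (one gene per
equal-width slot, so interval-query oracles stay simple), uniform-ACGT
FASTA, SNPs planted at one per 3.5 kb, freq values drawn per window,
and blast records planted half at E = 1e-20 and half at 1e-05 around a
1e-10 cut-off. These defaults sketch a small fungal genome: the right
orders of magnitude for chromosome count, gene density and SNP rate.
The generator returns the planted truth, and tests check that every
downstream statistic (per-chromosome gene counts, window counts, blast
retention) recovers it exactly.

What the generator does *not* emulate: realistic base composition or
isochores, overlapping genes and nested features, assembly gaps,
scaffolding errors, or any evolutionary structure. Passing tests
therefore demonstrate the correctness of parsing, bookkeeping, query
and rendering arithmetic on well-formed data of realistic shape — not
robustness to the pathological content of real community files beyond
the tolerant-reader behaviours (reversed coordinates, unknown colours,
unknown chromosomes, unsorted blast pairs) that are tested explicitly.

Test problem sizes are chosen to keep the full suite fast while still
exercising every code path at scale: fuzzed round-trips use 1000 random
tracks per grammar, region queries 1000 random selections against a
300-record track, and the statistics anchor runs a 13,331-gene genome.

## Degenerate inputs and failure policy

Hard errors (malformed grammar, capacity overruns, out-of-range
extractions, infeasible packing) are R errors naming the file line where
possible. Recoverable irregularities (reversed coordinates, duplicate
search ids, unknown chromosomes or colours, unsorted pairs, all-N
windows) are repaired or set aside with warnings, and the affected
counts are reported — the map should still draw. Empty tracks are valid
everywhere: they parse, write as header-only files, render as an empty
row that still reserves its height, and list zero features.

## Known limitations

* Single genome per project; no comparative (multi-genome) views.
* No streaming: files are read whole, which is comfortable for the
  genome sizes targeted (tens of Mb) but not for gigabase genomes.
* The renderer produces static SVG/PNG only — no interactivity, PDF or
  tooltips.
* Legal strand tokens are not enumerated by the grammars; tokens are
  stored and reported verbatim.
* Locale-specific number formats (decimal commas) are not accepted;
  files are UTF-8 with LF or CRLF endings.
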