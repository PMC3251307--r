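# ---------------------------------------------------------------------------
# Builders that turn standard bioinformatics outputs (GFF3, BED, BLAST
# tabular, SNP position lists, FASTA) into map track files -- the jobs
# otherwise done with small AWK/Python scripts. Converters are the only
# place coordinate systems are translated; everything downstream is
# uniformly 1-based and inclusive at both ends.
# ---------------------------------------------------------------------------

gff_strand <- function(x) {
  x <- as.character(x)
  ifelse(x %in% c("+", "-"), x, ".")
}

#' Build a posn track from GFF3
#'
#' Keeps rows of one feature type and maps (seqid, start, end, strand, ID
#' attribute) onto a posn track. GFF3 is already 1-based inclusive, so
#' coordinates pass through unchanged. Rows without an `ID` attribute get a
#' synthesized id `type_chrom_start` with a warning.
#'
#' @param gff3 path to a GFF3 file.
#' @param out optional output path for the `.posn` file.
#' @param feature_type GFF3 `type` column filter (default `"gene"`).
#' @param colour track colour name.
#' @param name track name; defaults from `out` or `feature_type`.
#' @return The [track()], invisibly when written.
#' @export
gff3_to_posn <- function(gff3, out = NULL, feature_type = "gene",
                         colour = "clBlue", name = NULL) {
  g <- rtracklayer::import(gff3, format = "gff3")
  g <- g[as.character(g$type) == feature_type]
  if (is.null(name)) {
    name <- if (!is.null(out)) tools::file_path_sans_ext(basename(out))
            else feature_type
  }
  if (length(g) == 0L) {
    warning("no GFF3 rows of type '", feature_type, "'; track is empty")
    tr <- track(name, "posn",
                features(character(0), numeric(0), numeric(0),
                         character(0), character(0)),
                colour = colour)
  } else {
    ids <- if ("ID" %in% names(S4Vectors::mcols(g))) as.character(g$ID)
           else rep(NA_character_, length(g))
    miss <- is.na(ids) | !nzchar(ids)
    if (any(miss)) {
      warning(sum(miss), " GFF3 row(s) lack an ID attribute; ids synthesized")
      ids[miss] <- sprintf("%s_%s_%s", feature_type,
                           as.character(GenomeInfoDb::seqnames(g))[miss],
                           BiocGenerics::start(g)[miss])
    }
    tr <- track(name, "posn",
                features(as.character(GenomeInfoDb::seqnames(g)),
                         BiocGenerics::start(g), BiocGenerics::end(g),
                         gff_strand(BiocGenerics::strand(g)), ids),
                colour = colour)
  }
  if (!is.null(out)) { write_track(tr, out); return(invisible(tr)) }
  tr
}

#' Build a posn track from BED
#'
#' BED intervals are 0-based half-open `(chromStart, chromEnd)`; they map to
#' 1-based inclusive `(chromStart + 1, chromEnd)`. The name column (4th)
#' becomes the feature id (`"seq"` when absent) and the strand column (6th)
#' the strand (`"."` when absent).
#'
#' @param bed path to a BED file (3 or more columns).
#' @param out optional output path for the `.posn` file.
#' @param colour track colour name.
#' @param name track name.
#' @return The [track()], invisibly when written.
#' @export
bed_to_posn <- function(bed, out = NULL, colour = "clBlue", name = NULL) {
  if (is.null(name)) {
    name <- tools::file_path_sans_ext(basename(if (!is.null(out)) out
                                               else bed))
  }
  lns <- data_lines_of(readLines(bed, warn = FALSE))
  n <- length(lns)
  chrom <- character(n); first <- numeric(n); last <- numeric(n)
  strand <- character(n); id <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lns[[i]]$line, "[\t ]+")[[1]]
    if (length(f) < 3L) {
      stop("BED line ", lns[[i]]$n, ": expected at least 3 columns")
    }
    if (!grepl(int_re, f[2]) || !grepl(int_re, f[3])) {
      stop("BED line ", lns[[i]]$n, ": non-integer chromStart/chromEnd")
    }
    s <- as.numeric(f[2]); e <- as.numeric(f[3])
    if (s >= e) {
      stop("BED line ", lns[[i]]$n, ": chromStart >= chromEnd (", s, " >= ",
           e, ")")
    }
    chrom[i] <- f[1]; first[i] <- s + 1; last[i] <- e
    id[i] <- if (length(f) >= 4L) f[4] else "seq"
    strand[i] <- if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else "."
  }
  tr <- track(name, "posn", features(chrom, first, last, strand, id),
              colour = colour)
  if (!is.null(out)) { write_track(tr, out); return(invisible(tr)) }
  tr
}

#' Build a blast track from tabular BLAST output
#'
#' Consumes 12-column tabular output (outfmt 6: qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore). For each
#' aligned region on the chosen side, coordinates are the min/max of the
#' coordinate pair -- minus-strand subject hits with reversed coordinates
#' normalise correctly -- the feature id is `"seq"` (a bare region, not a
#' gene), and the paired ids from the other side are written as
#' `query id + E-value` pairs sorted ascending so the smallest E-value comes
#' first. Hits whose spans are identical collapse to one data line;
#' overlapping-but-unequal spans stay separate. All hits are written -- ones
#' above the cut-off are dropped when the file is parsed for display.
#'
#' @param tab path to the tabular BLAST file.
#' @param cutoff E-value cut-off written to the second `#`-line.
#' @param out optional output path for the `.blast` file.
#' @param colour track colour name.
#' @param target which side carries the map coordinates: `"subject"`
#'   (default; hits of external queries onto the mapped genome) or
#'   `"query"`.
#' @param name track name.
#' @return The [track()] as parsed back from its own file (i.e. with
#'   above-cutoff records dropped), invisibly when written.
#' @export
blast_tab_to_blast <- function(tab, cutoff, out = NULL, colour = "clRed",
                               target = c("subject", "query"), name = NULL) {
  target <- match.arg(target)
  if (is.null(name)) {
    name <- tools::file_path_sans_ext(basename(if (!is.null(out)) out
                                               else tab))
  }
  cols <- utils::read.table(tab, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("qseqid", "sseqid", "pident",
                                          "length", "mismatch", "gapopen",
                                          "qstart", "qend", "sstart", "send",
                                          "evalue", "bitscore"))
  if (!is.numeric(cols$evalue)) {
    stop("non-numeric E-value column in ", tab)
  }
  if (target == "subject") {
    chrom <- as.character(cols$sseqid); a <- cols$sstart; b <- cols$send
    other <- as.character(cols$qseqid)
  } else {
    chrom <- as.character(cols$qseqid); a <- cols$qstart; b <- cols$qend
    other <- as.character(cols$sseqid)
  }
  first <- pmin(a, b); last <- pmax(a, b)
  key <- paste(chrom, first, last, sep = "\r")
  groups <- split(seq_len(nrow(cols)), key)
  # stable region order: chromosome then start
  ord <- order(vapply(groups, function(i) chrom[i[1]], ""),
               vapply(groups, function(i) first[i[1]], 0),
               method = "radix")
  groups <- groups[ord]
  n <- length(groups)
  recs <- features(
    vapply(groups, function(i) chrom[i[1]], ""),
    vapply(groups, function(i) first[i[1]], 0),
    vapply(groups, function(i) last[i[1]], 0),
    rep(".", n), rep("seq", n)
  )
  recs$pairs <- I(lapply(groups, function(i) {
    o <- i[order(cols$evalue[i])]
    data.frame(query = other[o], evalue = cols$evalue[o],
               stringsAsFactors = FALSE)
  }))
  tr <- track(name, "blast", recs, colour = colour, cutoff = cutoff)
  if (!is.null(out)) {
    write_track(tr, out)
    return(invisible(suppressMessages(read_track(out, name = name))))
  }
  tr
}

#' Bin genomic positions into a density graph track
#'
#' The windowed-count construction behind SNP-density displays: each
#' chromosome is tiled with fixed windows anchored at nt 1 (the default
#' window is 50,000 nt, i.e. counts of SNPs/50,000 nt; the final window is
#' truncated at the chromosome end) and the track value of a window is the
#' number of positions falling in it. Empty windows are emitted with value
#' 0, so the sum of values equals the number of positions.
#'
#' @param positions data frame with columns `chrom` and `pos` (1-based), or
#'   a two-column matrix-like. Positions beyond their chromosome length are
#'   an error.
#' @param chromosomes a [chromosome_set()]; every chromosome is tiled, even
#'   ones with no positions.
#' @param window_nt window size in nucleotides (default 50000).
#' @param out optional output path for the `.graph` file.
#' @param name track name.
#' @return The [track()] of kind `"graph"`, invisibly when written.
#' @export
positions_to_graph <- function(positions, chromosomes, window_nt = 50000,
                               out = NULL, name = "density") {
  stopifnot(inherits(chromosomes, "chromosome_set"), window_nt >= 1)
  positions <- as.data.frame(positions)
  names(positions)[1:2] <- c("chrom", "pos")
  positions$chrom <- as.character(positions$chrom)
  bad <- !positions$chrom %in% chromosomes$id
  if (any(bad)) {
    stop("position(s) on unknown chromosome(s): ",
         paste(unique(positions$chrom[bad]), collapse = ", "))
  }
  lens <- stats::setNames(chromosomes$length, chromosomes$id)
  if (any(positions$pos < 1 | positions$pos > lens[positions$chrom])) {
    stop("position beyond chromosome length")
  }
  rows <- lapply(seq_len(nrow(chromosomes)), function(ci) {
    cid <- chromosomes$id[ci]; len <- chromosomes$length[ci]
    n_win <- ceiling(len / window_nt)
    firsts <- (seq_len(n_win) - 1) * window_nt + 1
    lasts <- pmin(firsts + window_nt - 1, len)
    p <- positions$pos[positions$chrom == cid]
    counts <- tabulate((p - 1) %/% window_nt + 1, nbins = n_win)
    df <- features(rep(cid, n_win), firsts, lasts, rep(".", n_win),
                   rep("seq", n_win))
    df$value <- as.numeric(counts)
    df
  })
  recs <- do.call(rbind, rows)
  tr <- track(name, "graph", recs)
  if (!is.null(out)) { write_track(tr, out); return(invisible(tr)) }
  tr
}

#' Windowed %GC as a freq track
#'
#' Tiles each sequence with fixed windows (anchored at nt 1, final window
#' truncated) and computes `100 * (G + C) / (non-N length)` per window, the
#' own-analysis GC-content track of a map. Windows consisting entirely of N
#' are skipped with a warning. The gradient header is written verbatim.
#'
#' @param fasta path to a FASTA file (record names up to the first
#'   whitespace are the chromosome ids).
#' @param gradient a [gradient_spec()] binning the percentages.
#' @param window_nt window size in nucleotides.
#' @param out optional output path for the `.freq` file.
#' @param name track name.
#' @return The [track()] of kind `"freq"`, invisibly when written.
#' @export
fasta_to_gc_freq <- function(fasta, gradient, window_nt = 50000, out = NULL,
                             name = "gc") {
  stopifnot(inherits(gradient, "gradient_spec"), window_nt >= 1)
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L || all(Biostrings::width(seqs) == 0L)) {
    stop("empty sequence in ", fasta)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  rows <- list()
  n_allN <- 0L
  for (si in seq_along(seqs)) {
    len <- Biostrings::width(seqs)[si]
    n_win <- ceiling(len / window_nt)
    firsts <- (seq_len(n_win) - 1) * window_nt + 1
    lasts <- pmin(firsts + window_nt - 1, len)
    v <- Biostrings::Views(seqs[[si]], start = firsts, end = lasts)
    counts <- Biostrings::letterFrequency(v, c("G", "C", "N"))
    non_n <- (lasts - firsts + 1) - counts[, "N"]
    keep <- non_n > 0
    n_allN <- n_allN + sum(!keep)
    if (!any(keep)) next
    df <- features(rep(names(seqs)[si], sum(keep)), firsts[keep],
                   lasts[keep], rep(".", sum(keep)), rep("seq", sum(keep)))
    df$value <- 100 * (counts[keep, "G"] + counts[keep, "C"]) / non_n[keep]
    rows[[length(rows) + 1L]] <- df
  }
  if (n_allN > 0L) {
    warning(n_allN, " all-N window(s) skipped (no defined GC content)")
  }
  recs <- do.call(rbind, rows)
  tr <- track(name, "freq", recs, gradient = gradient)
  if (!is.null(out)) { write_track(tr, out); return(invisible(tr)) }
  tr
}

#' Concatenate contigs into a pseudo-chromosome
#'
#' Unassigned contigs can be displayed as a single unit by concatenating
#' their DNA with runs of N between them. Returns (and optionally writes)
#' the pseudo-chromosome FASTA, its chromosomes-file entry, and a posn
#' track recording each contig's span so the original sequences can always
#' be recovered by slicing.
#'
#' @param fasta path to a multi-record FASTA of contigs (ids must be
#'   unique).
#' @param pseudo_id id of the pseudo-chromosome.
#' @param spacer_n number of N characters between consecutive contigs.
#' @param out_dir optional directory: writes `<pseudo_id>.fasta` and
#'   `<pseudo_id>_contigs.posn` there.
#' @param colour colour for the contig-span track.
#' @return List with `sequence` (a `DNAStringSet` of length 1),
#'   `chromosome` (a one-row [chromosome_set()]) and `spans` (a posn
#'   [track()]).
#' @export
concat_contigs <- function(fasta, pseudo_id, spacer_n = 1000,
                           out_dir = NULL, colour = "clGray") {
  stopifnot(spacer_n >= 0)
  contigs <- Biostrings::readDNAStringSet(fasta)
  if (length(contigs) == 0L) stop("no contigs in ", fasta)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  if (anyDuplicated(names(contigs))) {
    stop("duplicate contig id(s): ",
         paste(unique(names(contigs)[duplicated(names(contigs))]),
               collapse = ", "))
  }
  widths <- Biostrings::width(contigs)
  firsts <- cumsum(c(1, widths[-length(widths)] + spacer_n))
  lasts <- firsts + widths - 1
  total <- sum(widths) + spacer_n * (length(contigs) - 1L)
  spacer <- paste(rep("N", spacer_n), collapse = "")
  pseudo <- Biostrings::DNAStringSet(
    paste(vapply(seq_along(contigs),
                 function(i) as.character(contigs[[i]]), ""),
          collapse = spacer))
  names(pseudo) <- pseudo_id
  spans <- track(paste0(pseudo_id, "_contigs"), "posn",
                 features(rep(pseudo_id, length(contigs)), firsts, lasts,
                          rep(".", length(contigs)), names(contigs)),
                 colour = colour)
  chrom <- chromosome_set(pseudo_id, total)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    Biostrings::writeXStringSet(pseudo,
                                file.path(out_dir,
                                          paste0(pseudo_id, ".fasta")),
                                width = 60L)
    write_track(spans, file.path(out_dir,
                                 paste0(pseudo_id, "_contigs.posn")))
  }
  list(sequence = pseudo, chromosome = chrom, spans = spans)
}
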