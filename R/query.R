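# ---------------------------------------------------------------------------
# Gene-List / search / sequence-extraction engine: the pure-function
# equivalents of the interactive region selection and search boxes.
# ---------------------------------------------------------------------------

# Overlap semantics throughout: closed 1-based intervals, any overlap, i.e.
# start <= sel.last AND end >= sel.first. IRanges provides the indexed fast
# path; the brute-force scan lives in the test suite as the oracle.
overlapping_idx <- function(records, sel) {
  on_chrom <- which(records$chrom == sel$chrom)
  if (length(on_chrom) == 0L) return(integer(0))
  q <- IRanges::IRanges(start = sel$first, end = sel$last)
  s <- IRanges::IRanges(start = records$first[on_chrom],
                        end = records$last[on_chrom])
  hits <- IRanges::findOverlaps(q, s)
  idx <- on_chrom[S4Vectors::subjectHits(hits)]
  idx[order(records$first[idx], records$last[idx], method = "radix")]
}

# One displayable annotation cell per record, by track kind.
record_annotation <- function(track, idx) {
  recs <- track$records
  switch(track$kind,
    blast = vapply(idx, function(i) {
      p <- recs$pairs[[i]]
      sprintf("%s E=%s", p$query[1], fmt_value(p$evalue[1]))
    }, ""),
    freq = fmt_value(recs$value[idx]),
    graph = fmt_value(recs$value[idx]),
    vapply(idx, function(i) paste(recs$extras[[i]], collapse = "; "), "")
  )
}

#' List the features displayed in a selected region
#'
#' The Gene List: one row for every record of the displayed tracks that
#' overlaps the selection (closed intervals, partial overlaps included --
#' partially visible blocks are still drawn, so they are still listed).
#' Rows are ordered by track (display order) then start position. Columns
#' follow the on-screen gene list: chromosome id, gene length in nt, first
#' and last nt, coding strand, gene id and annotation, plus the source
#' track. freq/graph records report their numeric value in the annotation
#' column with strand and id blank.
#'
#' @param tracks a [track()] or list of tracks, in display order.
#' @param sel a [region_selection()].
#' @param chromosomes optional [chromosome_set()]; when given, a selection
#'   on an unknown chromosome is an error.
#' @return A data frame of class `gene_list` with columns `chrom`,
#'   `gene_length`, `first`, `last`, `strand`, `id`, `annotation`, `track`.
#' @seealso [format_gene_list()] for the copy-pasteable TSV form.
#' @export
features_in_region <- function(tracks, sel, chromosomes = NULL) {
  stopifnot(inherits(sel, "region_selection"))
  if (inherits(tracks, "track")) tracks <- list(tracks)
  if (!is.null(chromosomes) && !sel$chrom %in% chromosomes$id) {
    stop("unknown chromosome in selection: ", sel$chrom)
  }
  rows <- lapply(tracks, function(tr) {
    idx <- overlapping_idx(tr$records, sel)
    recs <- tr$records
    valued <- tr$kind %in% c("freq", "graph")
    data.frame(
      chrom = recs$chrom[idx],
      gene_length = recs$last[idx] - recs$first[idx] + 1,
      first = recs$first[idx],
      last = recs$last[idx],
      strand = if (valued) rep("", length(idx)) else recs$strand[idx],
      id = if (valued) rep("", length(idx)) else recs$id[idx],
      annotation = record_annotation(tr, idx),
      track = rep(tr$name, length(idx)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gene_list", "data.frame")
  out
}

#' Format a gene list as tab-separated text
#'
#' The text form of the Gene List Dialog, suitable for pasting into a
#' spreadsheet: a header line then one TAB-separated row per feature.
#'
#' @param x a [features_in_region()] result.
#' @return A single string.
#' @export
format_gene_list <- function(x) {
  header <- paste(c("chrom", "gene_length", "first", "last", "strand", "id",
                    "annotation", "track"), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(x$chrom[i], fmt_coord(x$gene_length[i]), fmt_coord(x$first[i]),
            fmt_coord(x$last[i]), x$strand[i], x$id[i], x$annotation[i],
            x$track[i]), collapse = "\t")
  }, "")
  paste(c(header, body), collapse = "\n")
}

# All genes of a genome in chromosome order then start order.
all_genes <- function(genome) {
  out <- do.call(rbind, genome$genes_by_chrom)
  rownames(out) <- NULL
  out
}

#' Find a single gene by id
#'
#' Exact, case-sensitive match against the master gene list (optionally
#' case-insensitive). When several features share the id, the first in
#' (chromosome order, start position) is returned with a warning. When a
#' project catalogue is supplied the hit is also written as a one-record
#' `Temp/temp.posn` track so it can be redisplayed later.
#'
#' @param genome a [build_genome()] result.
#' @param gene_id the id to look up (non-empty).
#' @param project optional [scan_project()] catalogue to persist the hit
#'   into.
#' @param colour display colour for the persisted track.
#' @param ignore_case match case-insensitively.
#' @return A one-row feature table, or `NULL` when the id is absent (absence
#'   is not an error).
#' @export
find_gene <- function(genome, gene_id, project = NULL, colour = "clBlack",
                      ignore_case = FALSE) {
  if (length(gene_id) != 1L || !nzchar(gene_id)) {
    stop("gene_id must be a single non-empty string")
  }
  genes <- all_genes(genome)
  hit <- if (ignore_case) {
    which(tolower(genes$id) == tolower(gene_id))
  } else {
    which(genes$id == gene_id)
  }
  if (length(hit) == 0L) return(NULL)
  if (length(hit) > 1L) {
    warning("gene id '", gene_id, "' matches ", length(hit),
            " features; returning the first by (chromosome, start)")
  }
  found <- genes[hit[1], , drop = FALSE]
  rownames(found) <- NULL
  if (!is.null(project)) {
    dir.create(file.path(project$root, "Temp"), showWarnings = FALSE)
    write_track(track("temp", "posn", found, colour = colour),
                file.path(project$root, "Temp", "temp.posn"))
  }
  found
}

#' Search for a list of gene ids
#'
#' The batch form of [find_gene()]: looks up each id in the master gene
#' list, writes the found features as a named temporary posn track
#' (`Temp/<list_name>.posn`) in the chosen colour, and reports the ids that
#' were not found. Duplicate input ids are de-duplicated with a warning.
#'
#' @param project a [scan_project()] catalogue with a loaded genome.
#' @param ids character vector of gene ids (non-empty).
#' @param list_name name for the temporary track (menu item `Temp/<name>`).
#' @param colour display colour name.
#' @param overwrite replace an existing temp list of the same name.
#' @param ignore_case match case-insensitively.
#' @return List with `found` (feature table), `missing` (character vector)
#'   and `path` (the written posn file).
#' @export
search_ids <- function(project, ids, list_name, colour = "clBlack",
                       overwrite = FALSE, ignore_case = FALSE) {
  stopifnot(inherits(project, "project_catalogue"))
  if (is.null(project$genome)) stop("project has no loaded genome")
  if (length(list_name) != 1L || !nzchar(list_name)) {
    stop("list_name must be a single non-empty string")
  }
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0L) stop("empty gene id list")
  if (anyDuplicated(ids)) {
    warning(sum(duplicated(ids)), " duplicate id(s) removed from the list")
    ids <- unique(ids)
  }
  path <- file.path(project$root, "Temp", paste0(list_name, ".posn"))
  if (file.exists(path) && !overwrite) {
    stop("temp list '", list_name, "' already exists; set overwrite = TRUE ",
         "to replace it")
  }
  genes <- all_genes(project$genome)
  key <- if (ignore_case) tolower(genes$id) else genes$id
  want <- if (ignore_case) tolower(ids) else ids
  hit <- match(want, key)
  missing <- ids[is.na(hit)]
  found <- genes[hit[!is.na(hit)], , drop = FALSE]
  rownames(found) <- NULL
  dir.create(dirname(path), showWarnings = FALSE)
  write_track(track(list_name, "posn", found, colour = colour), path)
  list(found = found, missing = missing, path = path)
}

#' Extract and save the sequences of selected regions
#'
#' For each selection, slices the chromosome FASTA (`_data/<id>.fasta`) at
#' the 1-based inclusive coordinates and writes the fragment to
#' `_seqs/<id>_<first>-<last>.fasta` (60-column FASTA, header recording the
#' chromosome and coordinates). The fragment length always equals
#' `last - first + 1`.
#'
#' @param project a [scan_project()] catalogue.
#' @param selections a [region_selection()] or list of them.
#' @return Character vector of written file paths, invisibly.
#' @export
extract_region_sequences <- function(project, selections) {
  stopifnot(inherits(project, "project_catalogue"))
  if (inherits(selections, "region_selection")) selections <- list(selections)
  out <- character(0)
  for (sel in selections) {
    fasta <- file.path(project$root, "_data", paste0(sel$chrom, ".fasta"))
    if (!file.exists(fasta)) {
      stop("no chromosome FASTA for '", sel$chrom, "' (expected ", fasta, ")")
    }
    seqs <- Biostrings::readDNAStringSet(fasta)
    if (sel$last > Biostrings::width(seqs)[1]) {
      stop("selection ", sel$chrom, ":", fmt_coord(sel$first), "-",
           fmt_coord(sel$last), " out of range (chromosome has ",
           Biostrings::width(seqs)[1], " nt)")
    }
    frag <- Biostrings::subseq(seqs[1], start = sel$first, end = sel$last)
    names(frag) <- sprintf("%s_%s-%s", sel$chrom, fmt_coord(sel$first),
                           fmt_coord(sel$last))
    path <- file.path(project$root, "_seqs",
                      sprintf("%s_%s-%s.fasta", sel$chrom,
                              fmt_coord(sel$first), fmt_coord(sel$last)))
    Biostrings::writeXStringSet(frag, path, width = 60L)
    out <- c(out, path)
  }
  invisible(out)
}
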