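# ---------------------------------------------------------------------------
# The five track-file grammars plus the chromosomes/genes/colors files.
#
# All data files are tab-delimited UTF-8 text (LF or CRLF). Three line types:
#   * "#"-lines: the first one(s) carry drawing directives (colour, E-value
#     cut-off, gradient); later ones are comments/metadata.
#   * blank lines: ignored.
#   * data lines: chrom id, start, end, strand, feature id, then
#     kind-specific trailing fields.
# Coordinates are 1-based and inclusive at both ends throughout.
# ---------------------------------------------------------------------------

# Split file content into lines; accepts a single string with embedded
# newlines, a character vector of lines, or a file path read upstream.
as_lines <- function(text) {
  if (is.null(text)) return(character(0))
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  sub("\r$", "", text)
}

is_blank_line <- function(x) grepl("^\\s*$", x)
is_hash_line <- function(x) grepl("^\\s*#", x)

# Iterate the data lines of a file, keeping 1-based line numbers for error
# messages. Returns list of list(line=, n=).
data_lines_of <- function(text) {
  lines <- as_lines(text)
  keep <- !is_blank_line(lines) & !is_hash_line(lines)
  Map(function(l, n) list(line = l, n = n), lines[keep], which(keep))
}

# Leading "#"-directive lines (before the first data line), stripped of the
# "#" and surrounding whitespace.
directive_lines <- function(text) {
  lines <- as_lines(text)
  out <- character(0)
  for (line in lines) {
    if (is_blank_line(line)) next
    if (!is_hash_line(line)) break
    out <- c(out, trimws(sub("^\\s*#", "", line)))
  }
  out
}

int_re <- "^[0-9]+$"

# Split a data line on TABs, preserving trailing empty fields (strsplit
# silently drops them, which would corrupt verbatim extras).
split_tsv <- function(line) {
  f <- strsplit(paste0(line, "\t\x01"), "\t", fixed = TRUE)[[1]]
  f[-length(f)]
}

parse_coord <- function(x, lineno, what = "coordinate") {
  if (!grepl(int_re, x)) {
    stop("line ", lineno, ": non-integer ", what, " '", x, "'")
  }
  as.numeric(x)
}

#' Parse a chromosomes file
#'
#' One chromosome per line in `id = length` form, e.g. `1 = 11723881` for an
#' 11.7 Mb chromosome called "1". Blank and `#` lines are ignored; order is
#' preserved and becomes the display order of the map.
#'
#' @param text file content (single string or character vector of lines).
#' @return A [chromosome_set()].
#' @examples
#' parse_chromosomes("1 = 11723881\n2 = 8939884")
#' @export
parse_chromosomes <- function(text) {
  lns <- data_lines_of(text)
  if (length(lns) == 0L) stop("no chromosomes: the chromosomes file is empty")
  ids <- character(0); lens <- numeric(0)
  for (ln in lns) {
    m <- regmatches(ln$line,
                    regexec("^\\s*(\\S+)\\s*=\\s*(\\S+)\\s*$", ln$line))[[1]]
    if (length(m) != 3L) {
      stop("chromosomes line ", ln$n, ": expected 'id = length', got: ",
           ln$line)
    }
    if (!grepl(int_re, m[3])) {
      stop("chromosomes line ", ln$n, ": non-integer length '", m[3], "'")
    }
    len <- as.numeric(m[3])
    if (len < 1) stop("chromosomes line ", ln$n, ": non-positive length")
    ids <- c(ids, m[2]); lens <- c(lens, len)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate chromosome id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(ids) > 1000L) {
    stop("chromosome cap exceeded: at most 1000 chromosomes/scaffolds ",
         "are supported (got ", length(ids), ")")
  }
  chromosome_set(ids, lens)
}

# Parse the 5 mandatory fields (+ optional extras) of one data line into a
# one-row feature; swaps reversed coordinates. Returns list(row, swapped).
parse_feature_fields <- function(fields, lineno) {
  if (length(fields) < 5L) {
    stop("line ", lineno, ": expected at least 5 tab-separated fields ",
         "(chrom, first, last, strand, id), got ", length(fields))
  }
  first <- parse_coord(fields[2], lineno, "start coordinate")
  last <- parse_coord(fields[3], lineno, "end coordinate")
  swapped <- first > last
  if (swapped) { tmp <- first; first <- last; last <- tmp }
  list(chrom = fields[1], first = first, last = last, strand = fields[4],
       id = fields[5],
       extras = if (length(fields) > 5L) fields[6:length(fields)]
                else character(0),
       swapped = swapped)
}

# Shared parser for the gene-like data lines of genes/posn files.
# tail_fields reserves that many trailing fields for the caller (expr colour,
# freq/graph value).
parse_feature_lines <- function(text, tail_fields = 0L, min_fields = 5L) {
  lns <- data_lines_of(text)
  n <- length(lns)
  chrom <- character(n); first <- numeric(n); last <- numeric(n)
  strand <- character(n); id <- character(n)
  extras <- vector("list", n); tails <- vector("list", n)
  n_swapped <- 0L
  for (i in seq_len(n)) {
    fields <- split_tsv(lns[[i]]$line)
    if (length(fields) < min_fields) {
      stop("line ", lns[[i]]$n, ": expected at least ", min_fields,
           " tab-separated fields, got ", length(fields))
    }
    k <- length(fields)
    tails[[i]] <- if (tail_fields > 0L) fields[(k - tail_fields + 1L):k]
                  else character(0)
    body <- if (tail_fields > 0L) fields[1:(k - tail_fields)] else fields
    f <- parse_feature_fields(body, lns[[i]]$n)
    if (f$swapped) n_swapped <- n_swapped + 1L
    chrom[i] <- f$chrom; first[i] <- f$first; last[i] <- f$last
    strand[i] <- f$strand; id[i] <- f$id; extras[[i]] <- f$extras
  }
  if (n_swapped > 0L) {
    warning(n_swapped, " feature(s) had first > last; coordinates swapped")
  }
  df <- features(chrom, first, last, strand, id, extras)
  attr(df, "tails") <- tails
  df
}

#' Parse a genes file
#'
#' The master gene list of a project: tab-delimited lines of chromosome id,
#' first and last nucleotide positions, strand and gene id, optionally
#' followed by further annotation fields which are preserved verbatim. Blank
#' lines and lines beginning with `#` are treated as comments and ignored.
#' Reversed coordinates (first > last) are swapped with a warning.
#'
#' @param text file content.
#' @return A feature table (see [features()]); zero rows for an all-comment
#'   file.
#' @examples
#' parse_genes("2\t100\t500\t+\tgeneA\ttrichothecene biosynthesis")
#' @export
parse_genes <- function(text) {
  df <- parse_feature_lines(text)
  attr(df, "tails") <- NULL
  df
}

#' Parse a posn track file
#'
#' Draws genes or features at their genomic position in one colour. The
#' first `#`-line contains the colour name used for every record; data lines
#' follow the genes-file layout.
#'
#' @param text file content.
#' @param name track name (conventionally the file name without extension).
#' @return A [track()] of kind `"posn"`.
#' @export
parse_posn <- function(text, name = "posn") {
  dirs <- directive_lines(text)
  if (length(data_lines_of(text)) > 0L && length(dirs) == 0L) {
    stop("missing colour header: a posn file needs a '# colour' line ",
         "before any data")
  }
  if (length(dirs) == 0L) {
    stop("missing colour header in posn file '", name, "'")
  }
  colour <- strsplit(trimws(dirs[1]), "[\t ]+")[[1]][1]
  track(name, "posn", parse_genes(text), colour = colour)
}

#' Parse a blast track file
#'
#' Displays regions hit by a sequence-similarity search. The first `#`-line
#' gives the display colour and the second the E-value cut-off: records
#' whose best (first) E-value exceeds the cut-off are dropped at parse time
#' with a count reported, mirroring the display rule that such hits are not
#' shown. After the five positional fields each data line carries one or
#' more `query id` + `E-value` pairs, arranged lowest-to-highest E-value so
#' only the first needs checking; unsorted pairs are re-sorted with a
#' warning. A feature id of `"seq"` marks a bare chromosome region rather
#' than a gene.
#'
#' @inheritParams parse_posn
#' @return A [track()] of kind `"blast"` whose records carry a `pairs`
#'   list-column of `(query, evalue)` data frames.
#' @export
parse_blast <- function(text, name = "blast") {
  dirs <- directive_lines(text)
  if (length(dirs) < 1L) {
    stop("missing colour header in blast file '", name, "'")
  }
  if (length(dirs) < 2L) {
    stop("missing E-value cut-off header in blast file '", name, "'")
  }
  colour <- strsplit(trimws(dirs[1]), "[\t ]+")[[1]][1]
  cutoff <- suppressWarnings(as.numeric(strsplit(trimws(dirs[2]),
                                                 "[\t ]+")[[1]][1]))
  if (is.na(cutoff) || cutoff < 0) {
    stop("blast file '", name, "': E-value cut-off header is not a ",
         "non-negative number")
  }

  lns <- data_lines_of(text)
  rows <- list(); pairs <- list()
  n_unsorted <- 0L; n_dropped <- 0L
  for (ln in lns) {
    fields <- split_tsv(ln$line)
    if (length(fields) < 7L) {
      stop("line ", ln$n, ": a blast data line needs the 5 positional ",
           "fields plus at least one query id + E-value pair")
    }
    tail <- fields[6:length(fields)]
    if (length(tail) %% 2L != 0L) {
      stop("line ", ln$n, ": unpaired query id / E-value fields")
    }
    q <- tail[seq(1L, length(tail), by = 2L)]
    e <- suppressWarnings(as.numeric(tail[seq(2L, length(tail), by = 2L)]))
    if (any(is.na(e)) || any(e < 0)) {
      stop("line ", ln$n, ": non-numeric or negative E-value")
    }
    if (is.unsorted(e)) {
      n_unsorted <- n_unsorted + 1L
      o <- order(e)
      q <- q[o]; e <- e[o]
    }
    if (e[1] > cutoff) { n_dropped <- n_dropped + 1L; next }
    f <- parse_feature_fields(fields[1:5], ln$n)
    if (f$swapped) warning("line ", ln$n, ": first > last, swapped")
    rows[[length(rows) + 1L]] <- f
    pairs[[length(pairs) + 1L]] <-
      data.frame(query = q, evalue = e, stringsAsFactors = FALSE)
  }
  if (n_unsorted > 0L) {
    warning(n_unsorted, " blast line(s) had pairs not ascending in E-value;",
            " re-sorted")
  }
  if (n_dropped > 0L) {
    message(n_dropped, " blast record(s) above E-value cut-off ",
            format(cutoff), " dropped")
  }
  recs <- features(
    vapply(rows, `[[`, "", "chrom"),
    vapply(rows, `[[`, 0, "first"),
    vapply(rows, `[[`, 0, "last"),
    vapply(rows, `[[`, "", "strand"),
    vapply(rows, `[[`, "", "id"),
    lapply(rows, `[[`, "extras")
  )
  recs$pairs <- I(pairs)
  track(name, "blast", recs, colour = colour, cutoff = cutoff)
}

#' Parse an expr track file
#'
#' Displays features of one data set in different colours, e.g. microarray
#' expression with up-regulated genes in red and down-regulated genes in
#' blue. All `#`-lines are ignored; the last field of each data line is the
#' colour for that record. Unknown colour names fall back to mid-grey
#' (`clGray`) with a warning.
#'
#' @inheritParams parse_posn
#' @param colours a `colour_table` used to validate per-row colour names.
#' @return A [track()] of kind `"expr"` whose records carry a `colour`
#'   column.
#' @export
parse_expr <- function(text, name = "expr", colours = default_colours()) {
  df <- parse_feature_lines(text, tail_fields = 1L, min_fields = 6L)
  cols <- vapply(attr(df, "tails"), `[[`, "", 1L)
  attr(df, "tails") <- NULL
  unknown <- !(cols %in% names(colours))
  if (any(unknown)) {
    warning(sum(unknown), " expr record(s) name unknown colour(s) (",
            paste(unique(cols[unknown]), collapse = ", "),
            "); falling back to clGray")
    cols[unknown] <- "clGray"
  }
  df$colour <- cols
  track(name, "expr", df)
}

#' Parse a freq track file
#'
#' Displays valued regions through a colour gradient -- gene density, %GC or
#' recombination frequency maps. The first `#`-line holds the gradient as an
#' alternating list of colour names and strictly increasing cut-off values
#' (`colour boundary colour ... colour`, so k colours and k-1 boundaries, up
#' to 20 colours); tabs or runs of spaces both separate tokens. The last
#' field of each data line is the numeric value binned by the gradient.
#'
#' @inheritParams parse_posn
#' @return A [track()] of kind `"freq"` with a [gradient_spec()] and records
#'   carrying a numeric `value` column.
#' @examples
#' txt <- c("# clBeige\t1\tclKhaki\t2\tclGold\t3\tclGoldenRod\t4\tclTomato\t8\tclCrimson",
#'          "1\t1\t27000\t.\tseq\t0.4")
#' parse_freq(txt)$gradient
#' @export
parse_freq <- function(text, name = "freq") {
  dirs <- directive_lines(text)
  if (length(dirs) == 0L) {
    stop("missing gradient header: a freq file needs a '# colour cutoff ",
         "colour ...' line before any data")
  }
  tokens <- strsplit(trimws(dirs[1]), "[\t ]+")[[1]]
  if (length(tokens) %% 2L == 0L) {
    stop("freq gradient header must alternate k colours with k-1 ",
         "boundaries (odd token count); got ", length(tokens), " tokens")
  }
  colours <- tokens[seq(1L, length(tokens), by = 2L)]
  bounds <- tokens[seq_len(length(tokens)) %% 2L == 0L]
  bounds <- suppressWarnings(as.numeric(bounds))
  if (any(is.na(bounds))) {
    stop("freq gradient header: boundary values must be numeric")
  }
  g <- gradient_spec(colours, bounds)
  df <- parse_value_records(text, "freq")
  track(name, "freq", df, gradient = g)
}

# Common body for freq/graph data lines: last field is a numeric value.
parse_value_records <- function(text, kind) {
  df <- parse_feature_lines(text, tail_fields = 1L, min_fields = 6L)
  vals <- vapply(attr(df, "tails"), `[[`, "", 1L)
  attr(df, "tails") <- NULL
  value <- suppressWarnings(as.numeric(vals))
  if (any(is.na(value))) {
    stop(kind, " file: non-numeric value field '",
         vals[which(is.na(value))[1]], "'")
  }
  df$value <- value
  df
}

#' Parse a graph track file
#'
#' Displays a histogram along each chromosome, e.g. SNP density as the count
#' of SNPs per 50,000 nt window. The last field of each data line is the
#' y-value of the bar drawn over that region; `#`-lines are ignored.
#'
#' @inheritParams parse_posn
#' @return A [track()] of kind `"graph"` with a numeric `value` column.
#' @export
parse_graph <- function(text, name = "graph") {
  track(name, "graph", parse_value_records(text, "graph"))
}

#' Bin a value through a colour gradient
#'
#' Returns `colours[i + 1]` where `i` is the number of boundaries `<=`
#' `value`: bins are half-open `[lower, upper)` with the first bin open
#' below and the last open above, so the colour index is monotone
#' non-decreasing in the value.
#'
#' @param value numeric vector of finite values.
#' @param gradient a [gradient_spec()].
#' @return Character vector of colour names, one per value.
#' @examples
#' g <- gradient_spec(c("clBeige", "clKhaki", "clGold", "clGoldenRod",
#'                      "clTomato", "clCrimson"), c(1, 2, 3, 4, 8))
#' assign_gradient_colour(c(0.5, 1, 100), g)
#' @export
assign_gradient_colour <- function(value, gradient) {
  stopifnot(inherits(gradient, "gradient_spec"))
  if (any(!is.finite(value))) {
    stop("gradient values must be finite numbers")
  }
  idx <- vapply(value, function(v) sum(gradient$boundaries <= v), 0) + 1
  gradient$colours[idx]
}

# ---------------------------------------------------------------------------
# Writers: emit files that re-parse to the same payload and record multiset.
# Data lines are written sorted by chromosome id then start position, the
# recommended layout for finding features by position.
# ---------------------------------------------------------------------------

fmt_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)
fmt_value <- function(x) {
  vapply(x, function(v) format(v, trim = TRUE, digits = 15), "")
}

record_order <- function(records) {
  order(records$chrom, records$first, method = "radix")
}

feature_line_body <- function(records, i) {
  c(records$chrom[i], fmt_coord(records$first[i]), fmt_coord(records$last[i]),
    records$strand[i], records$id[i], records$extras[[i]])
}

#' Write a track file
#'
#' Emits the header `#`-lines a track's kind requires (colour, E-value
#' cut-off, gradient) followed by its data lines sorted by chromosome id and
#' start position. Re-parsing the file reproduces the track's payload and
#' record set (numbers to 15 significant digits).
#'
#' @param x a [track()].
#' @param path output file path; its extension conventionally matches the
#'   track kind.
#' @return `path`, invisibly.
#' @export
write_track <- function(x, path) {
  stopifnot(inherits(x, "track"))
  header <- switch(x$kind,
    posn = sprintf("# %s", x$colour),
    blast = c(sprintf("# %s", x$colour),
              sprintf("# %s", fmt_value(x$cutoff))),
    expr = character(0),
    freq = {
      g <- x$gradient
      toks <- character(2L * length(g$colours) - 1L)
      toks[seq(1L, length(toks), by = 2L)] <- g$colours
      if (length(g$boundaries)) {
        toks[seq(2L, length(toks), by = 2L)] <- fmt_value(g$boundaries)
      }
      sprintf("# %s", paste(toks, collapse = "\t"))
    },
    graph = character(0)
  )
  recs <- x$records
  lines <- character(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    body <- feature_line_body(recs, i)
    # the blast grammar has no extras: everything after field 5 is pairs
    if (x$kind == "blast") body <- body[1:5]
    tail <- switch(x$kind,
      posn = character(0),
      blast = {
        p <- recs$pairs[[i]]
        as.vector(rbind(p$query, fmt_value(p$evalue)))
      },
      expr = recs$colour[i],
      freq = fmt_value(recs$value[i]),
      graph = fmt_value(recs$value[i])
    )
    lines[i] <- paste(c(body, tail), collapse = "\t")
  }
  writeLines(c(header, lines[record_order(recs)]), path)
  invisible(path)
}

#' Write a chromosomes file
#'
#' @param x a [chromosome_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chromosomes <- function(x, path) {
  stopifnot(inherits(x, "chromosome_set"))
  writeLines(sprintf("%s = %s", x$id, fmt_coord(x$length)), path)
  invisible(path)
}

#' Write a genes file
#'
#' @param x a feature table (see [features()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(x, path) {
  lines <- vapply(seq_len(nrow(x)),
                  function(i) paste(feature_line_body(x, i), collapse = "\t"),
                  "")
  writeLines(lines[record_order(x)], path)
  invisible(path)
}

TRACK_EXTENSIONS <- c(posn = "posn", blast = "blast", expr = "expr",
                      freq = "freq", graph = "graph")

#' Read a track file, dispatching on its extension
#'
#' @param path path to a `.posn`, `.blast`, `.expr`, `.freq` or `.graph`
#'   file.
#' @param name track name; defaults to the file name without extension.
#' @param colours colour table passed to [parse_expr()].
#' @return A [track()].
#' @export
read_track <- function(path, name = NULL,
                       colours = default_colours()) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% TRACK_EXTENSIONS) {
    stop("unknown track extension '.", ext, "' for ", path,
         " (expected one of .", paste(TRACK_EXTENSIONS, collapse = ", ."),
         ")")
  }
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  text <- readLines(path, warn = FALSE, encoding = "UTF-8")
  switch(ext,
         posn = parse_posn(text, name),
         blast = parse_blast(text, name),
         expr = parse_expr(text, name, colours),
         freq = parse_freq(text, name),
         graph = parse_graph(text, name))
}
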