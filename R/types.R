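#' Construct a chromosome set
#'
#' The chromosome set is the backbone of every map: an ordered table of
#' chromosome (or supercontig/scaffold) ids and their lengths in base pairs.
#' Display order is the order given here, not size order -- for some species
#' chromosome numbering follows the genetic map rather than physical size.
#'
#' @param id character vector of chromosome ids (unique, non-empty tokens).
#' @param length numeric vector of chromosome lengths in base pairs
#'   (positive integers; stored as doubles so lengths above 2^31 are safe).
#' @return A data frame of class `chromosome_set` with columns `id` and
#'   `length`, one row per chromosome, in input order.
#' @examples
#' chromosome_set(c("1", "2"), c(11723881, 8939884))
#' @export
chromosome_set <- function(id, length) {
  id <- as.character(id)
  length <- as.numeric(length)
  if (length(id) == 0L) {
    stop("no chromosomes: a chromosome set needs at least one entry")
  }
  if (length(id) != length(length)) {
    stop("'id' and 'length' must have the same number of entries")
  }
  if (length(id) > 1000L) {
    stop("chromosome cap exceeded: at most 1000 chromosomes/scaffolds ",
         "are supported (got ", length(id), ")")
  }
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate chromosome id(s): ", paste(dup, collapse = ", "))
  }
  if (any(is.na(length)) || any(length < 1) || any(length != floor(length))) {
    stop("chromosome lengths must be positive integers (base pairs)")
  }
  structure(
    data.frame(id = id, length = length, stringsAsFactors = FALSE),
    class = c("chromosome_set", "data.frame")
  )
}

#' @export
print.chromosome_set <- function(x, ...) {
  cat("chromosome set:", nrow(x), "chromosome(s),",
      format(sum(x$length), big.mark = ",", scientific = FALSE), "bp total\n")
  print.data.frame(x, ...)
  invisible(x)
}

# Empty extras placeholder: one character(0) per row.
empty_extras <- function(n) I(rep(list(character(0)), n))

#' Construct a feature table
#'
#' A feature is one gene or genomic region: chromosome id, first and last
#' nucleotide positions (1-based, inclusive at both ends), strand token,
#' feature id, and any further annotation fields carried verbatim.
#'
#' @param chrom character, chromosome ids.
#' @param first,last numeric, 1-based inclusive nucleotide coordinates with
#'   `first <= last` row-wise.
#' @param strand character strand tokens (stored verbatim, e.g. "+", "-", ".").
#' @param id character feature ids.
#' @param extras optional list of character vectors, one per row, holding the
#'   annotation fields after the five mandatory ones.
#' @return A data frame with columns `chrom`, `first`, `last`, `strand`, `id`
#'   and list-column `extras`.
#' @export
features <- function(chrom, first, last, strand, id, extras = NULL) {
  n <- length(chrom)
  first <- as.numeric(first)
  last <- as.numeric(last)
  stopifnot(length(first) == n, length(last) == n,
            length(strand) == n, length(id) == n)
  if (any(is.na(first)) || any(is.na(last)) || any(first < 1)) {
    stop("feature coordinates must be positive integers")
  }
  if (any(first > last)) {
    stop("feature coordinates must satisfy first <= last ",
         "(use parse_genes() for tolerant swapping)")
  }
  df <- data.frame(chrom = as.character(chrom), first = first, last = last,
                   strand = as.character(strand), id = as.character(id),
                   stringsAsFactors = FALSE)
  if (is.null(extras)) {
    df$extras <- empty_extras(n)
  } else {
    stopifnot(length(extras) == n)
    df$extras <- I(lapply(extras, as.character))
  }
  df
}

#' Construct a colour gradient specification
#'
#' A gradient is an ordered list of `k` colour names separated by `k - 1`
#' strictly increasing boundary values. A value `v` falls in bin `i` when
#' `boundaries[i - 1] <= v < boundaries[i]`; the first bin is open below and
#' the last open above, so every finite value maps to exactly one colour.
#'
#' @param colours character vector of 1 to 20 colour names.
#' @param boundaries numeric vector of `length(colours) - 1` strictly
#'   increasing cut-off values.
#' @return An object of class `gradient_spec`.
#' @examples
#' gradient_spec(c("clBeige", "clKhaki", "clGold", "clGoldenRod",
#'                 "clTomato", "clCrimson"),
#'               c(1, 2, 3, 4, 8))
#' @export
gradient_spec <- function(colours, boundaries = numeric(0)) {
  colours <- as.character(colours)
  boundaries <- as.numeric(boundaries)
  if (length(colours) < 1L) stop("a gradient needs at least one colour")
  if (length(colours) > 20L) {
    stop("gradient cap exceeded: up to 20 colours can be used (got ",
         length(colours), ")")
  }
  if (length(boundaries) != length(colours) - 1L) {
    stop("a gradient with ", length(colours), " colours needs exactly ",
         length(colours) - 1L, " boundary values")
  }
  if (length(boundaries) && (any(!is.finite(boundaries)) ||
                             any(diff(boundaries) <= 0))) {
    stop("gradient boundaries must be finite and strictly increasing")
  }
  structure(list(colours = colours, boundaries = boundaries),
            class = "gradient_spec")
}

#' @export
print.gradient_spec <- function(x, ...) {
  cat("gradient:", paste(x$colours, collapse = " | "), "\n")
  if (length(x$boundaries))
    cat("boundaries:", paste(x$boundaries, collapse = ", "), "\n")
  invisible(x)
}

TRACK_KINDS <- c("posn", "blast", "expr", "freq", "graph")

#' Construct a track
#'
#' A track is a named, typed collection of displayable records plus the
#' styling payload its kind requires: posn and blast tracks carry one track
#' colour, blast tracks an E-value cut-off, freq tracks a [gradient_spec()],
#' expr records each carry their own colour, and freq/graph records each
#' carry a numeric value.
#'
#' @param name track name (shown in menus and gene lists).
#' @param kind one of `"posn"`, `"blast"`, `"expr"`, `"freq"`, `"graph"`.
#' @param records a feature table (see [features()]); expr tracks add a
#'   `colour` column, freq/graph tracks a numeric `value` column, blast
#'   tracks a `pairs` list-column of `(query, evalue)` data frames sorted by
#'   ascending E-value.
#' @param colour track colour name (posn/blast).
#' @param cutoff E-value cut-off (blast): records whose best E-value exceeds
#'   it are not displayed.
#' @param gradient a [gradient_spec()] (freq).
#' @return An object of class `track`.
#' @export
track <- function(name, kind, records, colour = NULL, cutoff = NULL,
                  gradient = NULL) {
  kind <- match.arg(kind, TRACK_KINDS)
  if (kind %in% c("posn", "blast") && is.null(colour)) {
    stop(kind, " tracks need a track colour")
  }
  if (kind == "blast") {
    if (is.null(cutoff)) stop("blast tracks need an E-value cut-off")
    if (!"pairs" %in% names(records)) {
      stop("blast records need a 'pairs' list-column of (query, evalue)")
    }
  }
  if (kind == "freq") {
    if (is.null(gradient)) stop("freq tracks need a gradient")
    stopifnot(inherits(gradient, "gradient_spec"))
  }
  if (kind %in% c("freq", "graph") && !"value" %in% names(records)) {
    stop(kind, " records need a numeric 'value' column")
  }
  if (kind == "expr" && !"colour" %in% names(records)) {
    stop("expr records need a per-row 'colour' column")
  }
  structure(list(name = as.character(name), kind = kind, colour = colour,
                 cutoff = cutoff, gradient = gradient, records = records),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("track '%s' (%s): %d record(s)\n", x$name, x$kind,
              nrow(x$records)))
  if (!is.null(x$colour)) cat("  colour:", x$colour, "\n")
  if (!is.null(x$cutoff)) cat("  E-value cut-off:", format(x$cutoff), "\n")
  if (!is.null(x$gradient))
    cat("  gradient:", paste(x$gradient$colours, collapse = " | "), "\n")
  invisible(x)
}

#' Construct a region selection
#'
#' The library equivalent of dragging a rectangle over the map: one
#' chromosome and an inclusive 1-based nucleotide window.
#'
#' @param chrom chromosome id.
#' @param first,last 1-based inclusive window bounds, `first <= last`.
#' @return An object of class `region_selection`.
#' @export
region_selection <- function(chrom, first, last) {
  first <- as.numeric(first); last <- as.numeric(last)
  if (length(chrom) != 1L || length(first) != 1L || length(last) != 1L) {
    stop("a region selection covers exactly one chromosome window; ",
         "use a list of selections for multi-chromosome rectangles")
  }
  if (is.na(first) || is.na(last) || first < 1 || first > last) {
    stop("invalid selection: need 1 <= first <= last")
  }
  structure(list(chrom = as.character(chrom), first = first, last = last),
            class = "region_selection")
}

#' @export
print.region_selection <- function(x, ...) {
  cat(sprintf("selection %s:%s-%s (%s nt)\n", x$chrom,
              format(x$first, scientific = FALSE),
              format(x$last, scientific = FALSE),
              format(x$last - x$first + 1, scientific = FALSE)))
  invisible(x)
}
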