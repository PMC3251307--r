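# The 16 standard Windows colour names: always available as built-ins, any
# colors file only adds to (or overrides) them.
WINDOWS_COLOURS <- c(
  clBlack   = "#000000", clMaroon = "#800000", clGreen   = "#008000",
  clOlive   = "#808000", clNavy   = "#000080", clPurple  = "#800080",
  clTeal    = "#008080", clGray   = "#808080", clSilver  = "#C0C0C0",
  clRed     = "#FF0000", clLime   = "#00FF00", clYellow  = "#FFFF00",
  clBlue    = "#0000FF", clFuchsia = "#FF00FF", clAqua   = "#00FFFF",
  clWhite   = "#FFFFFF"
)

# Mid-grey: the documented fallback for colour names with no definition.
FALLBACK_COLOUR <- "#808080"

#' The built-in colour table
#'
#' @return A named character vector of class `colour_table` mapping the 16
#'   standard Windows colour names (clBlack, clRed, ...) to `#RRGGBB` hex.
#' @seealso [parse_colors()] to extend it from a project colors file.
#' @export
default_colours <- function() {
  structure(WINDOWS_COLOURS, class = "colour_table")
}

#' Parse a colors file
#'
#' Each line defines one colour as `clName = $RRGGBB`, hex digits in red,
#' green, blue byte order. (Note this is plain RGB order even though some
#' GUI toolkits store the reversed order internally.) Definitions are laid
#' over the 16 built-in Windows colours; a missing or empty file yields
#' exactly the built-ins. Names are conventionally "cl"-prefixed; a name
#' without the prefix is kept with a warning.
#'
#' @param text file content: a single string or a character vector of lines.
#'   `NULL` (no colors file) is allowed.
#' @return A `colour_table`: named character vector of `#RRGGBB` values.
#' @examples
#' tab <- parse_colors("clPureRed = $FF0000")
#' tab[["clPureRed"]]
#' @export
parse_colors <- function(text = NULL) {
  table <- default_colours()
  for (ln in data_lines_of(text)) {
    line <- ln$line
    m <- regmatches(line, regexec("^\\s*(\\S+)\\s*=\\s*(\\S+)\\s*$", line))[[1]]
    if (length(m) != 3L) {
      stop("colors line ", ln$n, ": expected 'clName = $RRGGBB', got: ", line)
    }
    name <- m[2]; value <- m[3]
    if (!grepl("^\\$[0-9A-Fa-f]{6}$", value)) {
      stop("colors line ", ln$n, ": malformed hex value '", value,
           "' (expected $RRGGBB)")
    }
    if (!startsWith(name, "cl")) {
      warning("colour name '", name, "' has no 'cl' prefix; entry kept")
    }
    table[[name]] <- paste0("#", toupper(substring(value, 2)))
  }
  structure(table, class = "colour_table")
}

#' @export
print.colour_table <- function(x, ...) {
  cat("colour table:", length(x), "colour(s)\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Look up a colour's red/green/blue bytes
#'
#' @param table a `colour_table`.
#' @param name a colour name present in the table.
#' @return Integer vector `c(red, green, blue)`, each 0..255.
#' @export
colour_rgb <- function(table, name) {
  hex <- resolve_colour(table, name)
  as.integer(grDevices::col2rgb(hex)[, 1])
}

# Resolve a colour name to hex; unknown names fall back to mid-grey with a
# warning (tolerant-reader policy for community files).
resolve_colour <- function(table, name) {
  vapply(as.character(name), function(nm) {
    if (!is.na(nm) && nm %in% names(table)) {
      table[[nm]]
    } else if (grepl("^#[0-9A-Fa-f]{6}$", nm)) {
      toupper(nm)
    } else {
      warning("unknown colour name '", nm, "'; using mid-grey fallback",
              call. = FALSE)
      FALLBACK_COLOUR
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Write a colors file
#'
#' Emits every non-built-in entry (plus built-ins that were overridden) in
#' `clName = $RRGGBB` form so that [parse_colors()] round-trips the table.
#'
#' @param table a `colour_table`.
#' @param path output file path.
#' @param all write every entry including unmodified built-ins.
#' @return `path`, invisibly.
#' @export
write_colors <- function(table, path, all = FALSE) {
  keep <- if (all) names(table) else {
    names(table)[!(names(table) %in% names(WINDOWS_COLOURS)) |
                   table[names(table)] != WINDOWS_COLOURS[names(table)]]
  }
  lines <- sprintf("%s = $%s", keep, substring(table[keep], 2))
  writeLines(lines, path)
  invisible(path)
}
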