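# A built-in 5x7 block glyph font. Labels (chromosome ids, coordinates) are
# drawn as filled cells of this grid -- rectangles in SVG, pixels in PNG --
# so output never depends on system fonts and is byte-stable everywhere.
# Each glyph is 7 strings of 5 cells; "X" marks a filled cell.

GLYPHS <- list(
  "0" = c(".XXX.", "X...X", "X..XX", "X.X.X", "XX..X", "X...X", ".XXX."),
  "1" = c("..X..", ".XX..", "..X..", "..X..", "..X..", "..X..", ".XXX."),
  "2" = c(".XXX.", "X...X", "....X", "...X.", "..X..", ".X...", "XXXXX"),
  "3" = c(".XXX.", "X...X", "....X", "..XX.", "....X", "X...X", ".XXX."),
  "4" = c("...X.", "..XX.", ".X.X.", "X..X.", "XXXXX", "...X.", "...X."),
  "5" = c("XXXXX", "X....", "XXXX.", "....X", "....X", "X...X", ".XXX."),
  "6" = c(".XXX.", "X....", "X....", "XXXX.", "X...X", "X...X", ".XXX."),
  "7" = c("XXXXX", "....X", "...X.", "..X..", ".X...", ".X...", ".X..."),
  "8" = c(".XXX.", "X...X", "X...X", ".XXX.", "X...X", "X...X", ".XXX."),
  "9" = c(".XXX.", "X...X", "X...X", ".XXXX", "....X", "....X", ".XXX."),
  "A" = c(".XXX.", "X...X", "X...X", "XXXXX", "X...X", "X...X", "X...X"),
  "B" = c("XXXX.", "X...X", "X...X", "XXXX.", "X...X", "X...X", "XXXX."),
  "C" = c(".XXX.", "X...X", "X....", "X....", "X....", "X...X", ".XXX."),
  "D" = c("XXXX.", "X...X", "X...X", "X...X", "X...X", "X...X", "XXXX."),
  "E" = c("XXXXX", "X....", "X....", "XXXX.", "X....", "X....", "XXXXX"),
  "F" = c("XXXXX", "X....", "X....", "XXXX.", "X....", "X....", "X...."),
  "G" = c(".XXX.", "X...X", "X....", "X.XXX", "X...X", "X...X", ".XXXX"),
  "H" = c("X...X", "X...X", "X...X", "XXXXX", "X...X", "X...X", "X...X"),
  "I" = c(".XXX.", "..X..", "..X..", "..X..", "..X..", "..X..", ".XXX."),
  "J" = c("..XXX", "...X.", "...X.", "...X.", "...X.", "X..X.", ".XX.."),
  "K" = c("X...X", "X..X.", "X.X..", "XX...", "X.X..", "X..X.", "X...X"),
  "L" = c("X....", "X....", "X....", "X....", "X....", "X....", "XXXXX"),
  "M" = c("X...X", "XX.XX", "X.X.X", "X.X.X", "X...X", "X...X", "X...X"),
  "N" = c("X...X", "XX..X", "X.X.X", "X..XX", "X...X", "X...X", "X...X"),
  "O" = c(".XXX.", "X...X", "X...X", "X...X", "X...X", "X...X", ".XXX."),
  "P" = c("XXXX.", "X...X", "X...X", "XXXX.", "X....", "X....", "X...."),
  "Q" = c(".XXX.", "X...X", "X...X", "X...X", "X.X.X", "X..X.", ".XX.X"),
  "R" = c("XXXX.", "X...X", "X...X", "XXXX.", "X.X..", "X..X.", "X...X"),
  "S" = c(".XXXX", "X....", "X....", ".XXX.", "....X", "....X", "XXXX."),
  "T" = c("XXXXX", "..X..", "..X..", "..X..", "..X..", "..X..", "..X.."),
  "U" = c("X...X", "X...X", "X...X", "X...X", "X...X", "X...X", ".XXX."),
  "V" = c("X...X", "X...X", "X...X", "X...X", "X...X", ".X.X.", "..X.."),
  "W" = c("X...X", "X...X", "X...X", "X.X.X", "X.X.X", "XX.XX", "X...X"),
  "X" = c("X...X", "X...X", ".X.X.", "..X..", ".X.X.", "X...X", "X...X"),
  "Y" = c("X...X", "X...X", ".X.X.", "..X..", "..X..", "..X..", "..X.."),
  "Z" = c("XXXXX", "....X", "...X.", "..X..", ".X...", "X....", "XXXXX"),
  "." = c(".....", ".....", ".....", ".....", ".....", ".XX..", ".XX.."),
  "-" = c(".....", ".....", ".....", "XXXXX", ".....", ".....", "....."),
  "_" = c(".....", ".....", ".....", ".....", ".....", ".....", "XXXXX"),
  ":" = c(".....", ".XX..", ".XX..", ".....", ".XX..", ".XX..", "....."),
  " " = c(".....", ".....", ".....", ".....", ".....", ".....", ".....")
)

GLYPH_W <- 5L
GLYPH_H <- 7L

# Rectangles (one per filled cell) drawing `text` with its top-left corner
# at (x, y). Unknown characters advance without drawing. Uppercases input.
glyph_rects <- function(text, x, y, scale = 1, fill = "#000000") {
  chars <- strsplit(toupper(text), "")[[1]]
  out <- vector("list", length(chars))
  cx <- x
  for (k in seq_along(chars)) {
    g <- GLYPHS[[chars[k]]]
    if (!is.null(g)) {
      cells <- which(do.call(rbind, lapply(g, function(row) {
        strsplit(row, "")[[1]] == "X"
      })), arr.ind = TRUE)
      if (nrow(cells)) {
        out[[k]] <- data.frame(
          x = cx + (cells[, "col"] - 1L) * scale,
          y = y + (cells[, "row"] - 1L) * scale,
          w = scale, h = scale, fill = fill,
          stringsAsFactors = FALSE)
      }
    }
    cx <- cx + (GLYPH_W + 1L) * scale
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

# Pixel width of a label at a given scale.
glyph_text_width <- function(text, scale = 1) {
  nchar(text) * (GLYPH_W + 1L) * scale - scale
}
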