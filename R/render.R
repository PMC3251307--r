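# ---------------------------------------------------------------------------
# Deterministic static rendering. A map is a scene of axis-aligned filled
# rectangles (bars, feature blocks, gradient cells, histogram bars, label
# glyph cells) computed as a pure function of (genome, tracks, viewport,
# style); SVG output is generated directly from the scene so repeated runs
# are byte-identical, and PNG output rasterizes the same scene.
# ---------------------------------------------------------------------------

#' Construct a viewport
#'
#' The rendering coordinate contract: a global `first_nt..last_nt` window
#' applied to every chromosome (the zoom state) plus pixel geometry.
#' "Zoomed fully out" is `viewport(1, max chromosome length)`.
#'
#' @param first_nt,last_nt 1-based inclusive window bounds applied to all
#'   chromosomes.
#' @param width_px width of the drawing area in pixels (>= 100).
#' @param row_height_px height of one chromosome/track row.
#' @param exaggerate widen small feature blocks to at least `exaggerate_px`
#'   so sub-pixel features stay visible at whole-genome scale.
#' @param min_block_px minimum block width when `exaggerate` is off.
#' @param exaggerate_px minimum block width when `exaggerate` is on.
#' @return An object of class `viewport`.
#' @export
viewport <- function(first_nt = 1, last_nt, width_px = 1600L,
                     row_height_px = 12L, exaggerate = FALSE,
                     min_block_px = 1L, exaggerate_px = 3L) {
  first_nt <- as.numeric(first_nt); last_nt <- as.numeric(last_nt)
  if (is.na(first_nt) || is.na(last_nt) || first_nt < 1 ||
      first_nt > last_nt) {
    stop("viewport needs 1 <= first_nt <= last_nt")
  }
  if (width_px < 100L) stop("viewport width must be at least 100 px")
  structure(list(first_nt = first_nt, last_nt = last_nt,
                 width_px = as.integer(width_px),
                 row_height_px = as.integer(row_height_px),
                 exaggerate = isTRUE(exaggerate),
                 min_block_px = as.integer(min_block_px),
                 exaggerate_px = as.integer(exaggerate_px)),
            class = "viewport")
}

#' Whole-genome viewport
#'
#' @param genome a [build_genome()] result (or a [chromosome_set()]).
#' @param ... passed to [viewport()].
#' @return A [viewport()] spanning nt 1 to the longest chromosome.
#' @export
full_viewport <- function(genome, ...) {
  cs <- if (inherits(genome, "chromosome_set")) genome else genome$chromosomes
  viewport(1, max(cs$length), ...)
}

#' Map a nucleotide position to a pixel column
#'
#' `x = floor((nt - first_nt) / (last_nt - first_nt + 1) * width_px)`:
#' monotone non-decreasing, with `first_nt` on column 0. This is also the
#' status-bar arithmetic linking mouse position to nucleotide position.
#'
#' @param nt nucleotide position(s) inside the viewport window.
#' @param vp a [viewport()].
#' @return Integer pixel column(s) in `0 .. width_px - 1`.
#' @export
nt_to_px <- function(nt, vp) {
  nt <- as.numeric(nt)
  if (any(nt < vp$first_nt | nt > vp$last_nt)) {
    stop("nucleotide position outside the viewport window")
  }
  span <- vp$last_nt - vp$first_nt + 1
  floor((nt - vp$first_nt) / span * vp$width_px)
}

#' Map a pixel column back to a nucleotide position
#'
#' Pseudo-inverse of [nt_to_px()]: returns the first nucleotide of the bin
#' a pixel column covers, always within one pixel's worth of nucleotides of
#' any position mapping to that column.
#'
#' @param x pixel column(s) in `0 .. width_px - 1`.
#' @param vp a [viewport()].
#' @return Nucleotide position(s).
#' @export
px_to_nt <- function(x, vp) {
  x <- as.numeric(x)
  if (any(x < 0 | x >= vp$width_px)) {
    stop("pixel column outside the canvas")
  }
  span <- vp$last_nt - vp$first_nt + 1
  pmin(vp$first_nt + ceiling(x * span / vp$width_px), vp$last_nt)
}

#' Default rendering style
#'
#' @return A named list: colour table, bar/background/graph colours (hex),
#'   margins and gaps in pixels, and whether to draw id labels.
#' @seealso [read_style()] to override entries from a `key=value` file.
#' @export
default_style <- function() {
  list(
    colours = default_colours(),
    background = "#FFFFFF",
    bar_colour = "#A8A8A8",   # the grey chromosome bars
    track_bg = "#EeEEEE",
    graph_colour = "#404040",
    label_colour = "#000000",
    left_margin = 70, right_margin = 10,
    top_margin = 10, bottom_margin = 10,
    row_gap = 2, group_gap = 8,
    labels = TRUE, label_scale = 1
  )
}

#' Read a style configuration file
#'
#' Plain `key=value` lines (blank and `#` lines ignored) overriding
#' [default_style()] entries; numeric-looking values are converted.
#'
#' @param path file path.
#' @param base style list to override.
#' @return A style list.
#' @export
read_style <- function(path, base = default_style()) {
  for (ln in data_lines_of(readLines(path, warn = FALSE))) {
    m <- regmatches(ln$line,
                    regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$",
                            ln$line))[[1]]
    if (length(m) != 3L) stop("style line ", ln$n, ": expected key=value")
    val <- m[3]
    num <- suppressWarnings(as.numeric(val))
    base[[m[2]]] <- if (!is.na(num)) num else val
  }
  base
}

# Fix the hex case once so scene output is byte-stable.
norm_hex <- function(x) toupper(x)

# Pixel span of a (possibly clipped) closed interval inside the viewport.
# Returns NULL when the interval misses the window. `limit` clips at the
# chromosome end.
block_span <- function(first, last, vp, limit = Inf, widen = TRUE) {
  s <- max(first, vp$first_nt)
  e <- min(last, limit, vp$last_nt)
  if (s > e) return(NULL)
  x1 <- nt_to_px(s, vp)
  x2 <- if (e >= vp$last_nt) vp$width_px else nt_to_px(e + 1, vp)
  w <- max(x2 - x1, vp$min_block_px)
  if (widen && vp$exaggerate) w <- max(w, vp$exaggerate_px)
  # widening extends rightward, then clamps to the canvas
  x1 <- max(0, min(x1, vp$width_px - w))
  list(x = x1, w = w)
}

rect_df <- function(x, y, w, h, fill) {
  data.frame(x = x, y = y, w = w, h = h, fill = norm_hex(fill),
             stringsAsFactors = FALSE)
}

#' Gradient-row primitives for a freq track
#'
#' Each region becomes a cell filled with the gradient colour of its value;
#' regions that abut in nucleotide coordinates tile without pixel gaps.
#' Coordinates are relative to the row (x within the drawing area, y from
#' the row top).
#'
#' @param track a freq [track()].
#' @param vp a [viewport()].
#' @param chrom optional chromosome id to restrict to.
#' @return Data frame with columns `x`, `w`, `colour` (gradient colour
#'   name) and `value`; zero rows for an empty track (the row still
#'   reserves its height when drawn).
#' @export
render_freq_row <- function(track, vp, chrom = NULL) {
  stopifnot(inherits(track, "track"), track$kind == "freq")
  recs <- track$records
  if (!is.null(chrom)) recs <- recs[recs$chrom == chrom, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(recs))) {
    sp <- block_span(recs$first[i], recs$last[i], vp, widen = FALSE)
    if (is.null(sp)) next
    out[[length(out) + 1L]] <- data.frame(
      x = sp$x, w = sp$w,
      colour = assign_gradient_colour(recs$value[i], track$gradient),
      value = recs$value[i], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(x = numeric(0), w = numeric(0), colour = character(0),
                      value = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Histogram-row primitives for a graph track
#'
#' Bars span their region's width. Values are scaled linearly so that the
#' track's data range `[min(y, 0), max(y, 0)]` spans `row_height` pixels
#' with the baseline at value 0; an all-zero track is a flat baseline (no
#' division by zero), and a negative minimum shifts the baseline so bars
#' keep their sign.
#'
#' @param track a graph [track()].
#' @param vp a [viewport()].
#' @param row_height row height in pixels.
#' @param chrom optional chromosome id to restrict to.
#' @return Data frame with columns `x`, `w`, `y` (offset of the bar top
#'   from the row top), `h` (bar height in px) and `value`. The scaling is
#'   computed from the whole track so rows of different chromosomes share
#'   one y-axis.
#' @export
render_graph_row <- function(track, vp, row_height, chrom = NULL) {
  stopifnot(inherits(track, "track"), track$kind == "graph")
  all_vals <- track$records$value
  ymax <- max(all_vals, 0); ymin <- min(all_vals, 0)
  range <- ymax - ymin
  scale <- if (range > 0) row_height / range else 0
  baseline <- ymax * scale  # offset of value 0 from the row top
  recs <- track$records
  if (!is.null(chrom)) recs <- recs[recs$chrom == chrom, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(recs))) {
    sp <- block_span(recs$first[i], recs$last[i], vp, widen = FALSE)
    if (is.null(sp)) next
    v <- recs$value[i]
    h <- round(abs(v) * scale)
    y <- if (v >= 0) baseline - h else baseline
    out[[length(out) + 1L]] <- data.frame(
      x = sp$x, w = sp$w, y = y, h = h, value = v, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(x = numeric(0), w = numeric(0), y = numeric(0),
                      h = numeric(0), value = numeric(0)))
  }
  do.call(rbind, out)
}

#' Render the genome map
#'
#' Draws one row group per chromosome (in chromosome-set order): the grey
#' chromosome bar, its length proportional to the part of the chromosome
#' inside the window, then one sub-row per displayed track in the given
#' order. posn/blast/expr records become coloured blocks at their scaled
#' position and length (at least `min_block_px` wide, widened to
#' `exaggerate_px` when the viewport's exaggerate flag is on); freq records
#' become gradient cells and graph records histogram bars. Chromosomes
#' entirely outside the window are omitted. Rendering is a pure function of
#' its inputs: repeated calls give identical scenes.
#'
#' @param genome a [build_genome()] result.
#' @param tracks list of [track()]s to display (possibly empty).
#' @param vp a [viewport()]; defaults to the whole genome.
#' @param style a style list, see [default_style()].
#' @return An object of class `map_image`: `width`, `height`, `primitives`
#'   (a data frame of filled rectangles in drawing order).
#' @seealso [save_map()] for SVG/PNG export.
#' @export
render_map <- function(genome, tracks = list(), vp = NULL,
                       style = default_style()) {
  stopifnot(inherits(genome, "genome"))
  if (inherits(tracks, "track")) tracks <- list(tracks)
  if (is.null(vp)) vp <- full_viewport(genome)
  cs <- genome$chromosomes
  visible <- cs$length >= vp$first_nt
  if (!any(visible)) stop("no chromosome intersects the viewport window")

  row_h <- vp$row_height_px
  n_rows <- 1L + length(tracks)
  group_h <- n_rows * row_h + (n_rows - 1L) * style$row_gap
  n_vis <- sum(visible)
  width <- style$left_margin + vp$width_px + style$right_margin
  height <- style$top_margin + n_vis * group_h +
    (n_vis - 1L) * style$group_gap + style$bottom_margin

  prims <- list(rect_df(0, 0, width, height, style$background))
  x0 <- style$left_margin
  y <- style$top_margin
  colours <- style$colours

  for (ci in which(visible)) {
    cid <- cs$id[ci]
    clen <- cs$length[ci]
    bar <- block_span(1, clen, vp, widen = FALSE)
    # chromosome bar row
    prims[[length(prims) + 1L]] <-
      rect_df(x0 + bar$x, y, bar$w, row_h, style$bar_colour)
    if (isTRUE(style$labels)) {
      lab <- glyph_rects(cid, 2, y + floor((row_h - GLYPH_H) / 2),
                         scale = style$label_scale,
                         fill = style$label_colour)
      if (!is.null(lab) && nrow(lab)) {
        lab <- lab[lab$x + lab$w <= style$left_margin - 2, , drop = FALSE]
        prims[[length(prims) + 1L]] <- lab
      }
    }
    ry <- y + row_h + style$row_gap
    for (tr in tracks) {
      # pale backbone so sparse tracks keep their chromosome context
      prims[[length(prims) + 1L]] <-
        rect_df(x0 + bar$x, ry, bar$w, row_h, style$track_bg)
      prims_tr <- switch(tr$kind,
        freq = {
          cells <- render_freq_row(tr, vp, chrom = cid)
          if (nrow(cells)) {
            rect_df(x0 + cells$x, ry, cells$w, row_h,
                    resolve_colour(colours, cells$colour))
          }
        },
        graph = {
          bars <- render_graph_row(tr, vp, row_h, chrom = cid)
          bars <- bars[bars$h > 0, , drop = FALSE]
          if (nrow(bars)) {
            rect_df(x0 + bars$x, ry + bars$y, bars$w, bars$h,
                    style$graph_colour)
          }
        },
        {
          recs <- tr$records
          recs <- recs[recs$chrom == cid, , drop = FALSE]
          blocks <- list()
          for (i in seq_len(nrow(recs))) {
            sp <- block_span(recs$first[i], recs$last[i], vp, limit = clen)
            if (is.null(sp)) next
            col <- if (tr$kind == "expr") recs$colour[i] else tr$colour
            blocks[[length(blocks) + 1L]] <-
              rect_df(x0 + sp$x, ry, sp$w, row_h,
                      resolve_colour(colours, col))
          }
          if (length(blocks)) do.call(rbind, blocks)
        })
      if (!is.null(prims_tr) && nrow(prims_tr)) {
        prims[[length(prims) + 1L]] <- prims_tr
      }
      ry <- ry + row_h + style$row_gap
    }
    y <- y + group_h + style$group_gap
  }

  primitives <- do.call(rbind, prims)
  rownames(primitives) <- NULL
  structure(list(width = width, height = height, primitives = primitives),
            class = "map_image")
}

#' @export
print.map_image <- function(x, ...) {
  cat(sprintf("map image %d x %d px, %d primitive(s)\n", x$width, x$height,
              nrow(x$primitives)))
  invisible(x)
}

svg_document <- function(image) {
  p <- image$primitives
  fmt <- function(v) {
    out <- formatC(v, format = "fg", width = 1)
    sub("\\.0+$", "", out)
  }
  c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            image$width, image$height, image$width, image$height),
    sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
            fmt(p$x), fmt(p$y), fmt(p$w), fmt(p$h), p$fill),
    "</svg>"
  )
}

# Rasterize the scene into an H x W x 3 array in [0, 1].
rasterize_scene <- function(image) {
  arr <- array(1, dim = c(image$height, image$width, 3L))
  p <- image$primitives
  for (i in seq_len(nrow(p))) {
    x1 <- max(0L, as.integer(round(p$x[i])))
    y1 <- max(0L, as.integer(round(p$y[i])))
    x2 <- min(image$width, as.integer(round(p$x[i] + p$w[i])))
    y2 <- min(image$height, as.integer(round(p$y[i] + p$h[i])))
    if (x2 <= x1 || y2 <= y1) next
    rgb <- grDevices::col2rgb(p$fill[i])[, 1] / 255
    for (ch in 1:3) arr[(y1 + 1L):y2, (x1 + 1L):x2, ch] <- rgb[ch]
  }
  arr
}

#' Save a map image
#'
#' SVG output is generated directly from the scene and is byte-identical
#' across runs; PNG output rasterizes the same scene (pixel-identical
#' across runs on one platform).
#'
#' @param image a [render_map()] result.
#' @param path output file path.
#' @param format `"svg"` or `"png"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
save_map <- function(image, path, format = NULL) {
  stopifnot(inherits(image, "map_image"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (!format %in% c("svg", "png")) {
    stop("unknown map format '", format, "' (use \"svg\" or \"png\")")
  }
  if (format == "svg") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(svg_document(image), con, sep = "\n", useBytes = TRUE)
  } else {
    png::writePNG(rasterize_scene(image), path)
  }
  invisible(path)
}
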