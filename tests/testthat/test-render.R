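# Coordinate mapping and deterministic rendering.

test_that("nt_to_px maps the window onto pixel columns", {
  vp <- viewport(1, 1000, width_px = 1000)
  expect_identical(nt_to_px(1, vp), 0)          # first nt on column 0
  expect_identical(nt_to_px(500, vp), 499)      # direct formula evaluation
  expect_identical(nt_to_px(1000, vp), 999)
  expect_error(nt_to_px(1001, vp), "outside")
  expect_error(nt_to_px(0, vp), "outside")
  # monotone non-decreasing
  vp2 <- viewport(100, 10099, width_px = 250)
  xs <- nt_to_px(seq(100, 10099, by = 7), vp2)
  expect_true(all(diff(xs) >= 0))
})

test_that("px_to_nt is a pseudo-inverse of nt_to_px", {
  for (vp in list(viewport(1, 1000, width_px = 1000),
                  viewport(1, 100, width_px = 500),
                  viewport(5000, 250000, width_px = 640))) {
    res_unit <- max(1, (vp$last_nt - vp$first_nt + 1) / vp$width_px)
    nts <- round(seq(vp$first_nt, vp$last_nt, length.out = 200))
    back <- px_to_nt(nt_to_px(nts, vp), vp)
    expect_true(all(abs(back - nts) <= res_unit))
    expect_true(all(back >= vp$first_nt & back <= vp$last_nt))
  }
  vp <- viewport(1, 1000, width_px = 1000)
  expect_error(px_to_nt(1000, vp), "outside")
})

test_that("viewport validation", {
  expect_error(viewport(10, 5), "first_nt <= last_nt")
  expect_error(viewport(0, 5), "first_nt")
  expect_error(viewport(1, 100, width_px = 50), "at least 100")
})

test_that("chromosome bars are proportional to length within a pixel", {
  g <- tiny_genome()     # lengths 1e6, 7.5e5, 5e5, 2.5e5
  vp <- full_viewport(g, width_px = 1000)
  style <- default_style()
  img <- render_map(g, list(), vp, style)
  bars <- img$primitives[img$primitives$fill ==
                           toupper(style$bar_colour), , drop = FALSE]
  expect_identical(nrow(bars), 4L)
  lens <- g$chromosomes$length
  span <- vp$last_nt - vp$first_nt + 1
  for (i in 1:4) {
    expect_lte(abs(bars$w[i] - lens[i] / span * vp$width_px), 1)
  }
  # pairwise proportionality within 2/width relative error
  for (i in 1:3) {
    expect_lte(abs(bars$w[i] / bars$w[4] - lens[i] / lens[4]),
               2 / vp$width_px * (lens[i] / lens[4]) * span / lens[4] + 0.02)
  }
})

test_that("feature blocks honour minimum width and the exaggerate option", {
  cs <- chromosome_set("1", 1000000)
  g <- build_genome(cs, features("1", 500000, 500000, "+", "tiny"))
  tr <- track("t", "posn", g$genes_by_chrom[["1"]], colour = "clBlue")
  style <- default_style()

  img_off <- render_map(g, tr, viewport(1, 1000000, width_px = 1000), style)
  blocks <- img_off$primitives[img_off$primitives$fill == "#0000FF", ,
                               drop = FALSE]
  expect_identical(blocks$w, 1)   # 1-nt feature at genome zoom: 1 px

  img_on <- render_map(g, tr, viewport(1, 1000000, width_px = 1000,
                                       exaggerate = TRUE), style)
  blocks_on <- img_on$primitives[img_on$primitives$fill == "#0000FF", ,
                                 drop = FALSE]
  expect_identical(blocks_on$w, 3)  # widened to exaggerate_px
  # same left edge, widened rightward
  expect_identical(blocks_on$x, blocks$x)
})

test_that("block x-spans equal the brute-force coordinate mapping", {
  set.seed(41)
  cs <- chromosome_set("1", 200000)
  recs <- random_features(25, chroms = "1")
  recs$last <- pmin(recs$last, 200000)
  g <- build_genome(cs, recs)
  tr <- track("t", "posn", recs, colour = "clLime")
  vp <- viewport(1, 200000, width_px = 800)
  style <- default_style()
  img <- render_map(g, tr, vp, style)
  blocks <- img$primitives[img$primitives$fill == "#00FF00", , drop = FALSE]
  expect_identical(nrow(blocks), nrow(recs))
  x0 <- style$left_margin
  for (i in seq_len(nrow(recs))) {     # blocks emitted in record order
    x1 <- floor((recs$first[i] - 1) / 200000 * 800)
    x2 <- floor(recs$last[i] / 200000 * 800)
    expect_identical(blocks$x[i] - x0, x1)
    expect_identical(blocks$w[i], max(x2 - x1, 1))
  }
})

test_that("freq rows bin by gradient and tile abutting regions seamlessly", {
  recs <- features(c("1", "1"), c(1, 50001), c(50000, 100000),
                   c(".", "."), c("seq", "seq"))
  recs$value <- c(0.5, 9)
  tr <- track("rec", "freq", recs, gradient = doc_gradient())
  vp <- viewport(1, 100000, width_px = 500)
  row <- render_freq_row(tr, vp)
  expect_identical(row$colour, c("clBeige", "clCrimson"))
  # no pixel gap or overlap between abutting regions
  expect_identical(row$x[1] + row$w[1], row$x[2])
  expect_identical(row$x[2] + row$w[2], 500)

  # a region spanning the window is a full-width block
  one <- features("1", 1, 100000, ".", "seq")
  one$value <- 3
  full <- render_freq_row(track("f", "freq", one,
                                gradient = doc_gradient()), vp)
  expect_identical(full$x, 0)
  expect_identical(full$w, 500)

  # empty track: zero cells
  empty <- track("e", "freq",
                 { z <- features(character(0), numeric(0), numeric(0),
                                 character(0), character(0))
                   z$value <- numeric(0); z },
                 gradient = doc_gradient())
  expect_identical(nrow(render_freq_row(empty, vp)), 0L)
})

test_that("graph rows rescale values linearly onto the row height", {
  recs <- features(rep("1", 3), c(1, 101, 201), c(100, 200, 300),
                   rep(".", 3), rep("seq", 3))
  recs$value <- c(0, 5, 10)
  tr <- track("g", "graph", recs)
  vp <- viewport(1, 300, width_px = 300)
  bars <- render_graph_row(tr, vp, row_height = 40)
  expect_identical(bars$h, c(0, 20, 40))   # oracle: linear rescale
  # bar bottoms sit on the baseline for non-negative data
  expect_identical(bars$y + bars$h, rep(40, 3))

  # all-zero track: flat baseline, no division by zero
  recs0 <- recs; recs0$value <- c(0, 0, 0)
  bars0 <- render_graph_row(track("z", "graph", recs0), vp, 40)
  expect_identical(bars0$h, c(0, 0, 0))

  # negative minimum: baseline shifts, sign preserved
  recs_n <- recs; recs_n$value <- c(-10, 0, 10)
  bars_n <- render_graph_row(track("n", "graph", recs_n), vp, 40)
  expect_identical(bars_n$h, c(20, 0, 20))
  expect_identical(bars_n$y, c(20, 20, 0))  # down-bar starts at baseline

  # single point: full height
  one <- features("1", 1, 50, ".", "seq"); one$value <- 7
  b1 <- render_graph_row(track("o", "graph", one), vp, 40)
  expect_identical(b1$h, 40)
})

test_that("rendering is deterministic: repeated SVG saves are
           byte-identical", {
  d <- tmp_dir()
  res <- make_project(synthetic_spec(n_chrom = 3, n_genes = 45,
                                     length_range = c(1e5, 2e5), seed = 17,
                                     fasta = FALSE), d)
  cat_obj <- scan_project(d)
  tracks <- suppressMessages(
    lapply(c("Genes/all_genes", "Recombination/recombination",
             "SNPs/snp_density"),
           function(nm) load_track(cat_obj, nm)))
  style <- default_style()
  style$colours <- cat_obj$colours
  render_once <- function() {
    render_map(cat_obj$genome, tracks,
               full_viewport(cat_obj$genome, width_px = 600), style)
  }
  f1 <- file.path(d, "a.svg"); f2 <- file.path(d, "b.svg")
  save_map(render_once(), f1)
  save_map(render_once(), f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))

  p1 <- file.path(d, "a.png"); p2 <- file.path(d, "b.png")
  save_map(render_once(), p1)
  save_map(render_once(), p2)
  expect_identical(readBin(p1, "raw", file.size(p1) + 10),
                   readBin(p2, "raw", file.size(p2) + 10))
  unlink(d, recursive = TRUE)
})

test_that("image height follows the group layout arithmetic", {
  g <- tiny_genome()
  style <- default_style()
  vp <- full_viewport(g, width_px = 400, row_height_px = 12)
  for (n_tracks in 0:2) {
    tracks <- rep(list(track("t", "posn", g$genes_by_chrom[["1"]],
                             colour = "clBlue")), n_tracks)
    img <- render_map(g, tracks, vp, style)
    rows <- 1 + n_tracks
    group_h <- rows * 12 + (rows - 1) * style$row_gap
    want <- style$top_margin + 4 * group_h + 3 * style$group_gap +
      style$bottom_margin
    expect_identical(img$height, want)
    expect_identical(img$width,
                     style$left_margin + 400 + style$right_margin)
  }
})

test_that("chromosomes outside the window are omitted; none visible errors", {
  g <- tiny_genome()
  img <- render_map(g, list(), viewport(800000, 1000000, width_px = 400))
  style <- default_style()
  bars <- img$primitives[img$primitives$fill == toupper(style$bar_colour), ,
                         drop = FALSE]
  expect_identical(nrow(bars), 1L)   # only the 1 Mb chromosome reaches 800 kb
  expect_error(render_map(g, list(), viewport(2000000, 3000000)),
               "no chromosome")
})

test_that("save_map rejects unknown formats and zero-track maps save", {
  g <- tiny_genome()
  img <- render_map(g, list(), full_viewport(g, width_px = 400))
  f <- tempfile(fileext = ".svg")
  expect_error(save_map(img, f, format = "pdf"), "unknown map format")
  save_map(img, f)
  expect_gt(file.size(f), 0)
  svg <- readLines(f)
  expect_match(svg[1], "^<\\?xml")
  expect_match(svg[2], "<svg")
  unlink(f)
})

test_that("style files override defaults", {
  f <- tempfile()
  writeLines(c("# comment", "left_margin = 20", "bar_colour = #123456"), f)
  st <- read_style(f)
  expect_identical(st$left_margin, 20)
  expect_identical(st$bar_colour, "#123456")
  expect_identical(st$top_margin, default_style()$top_margin)
  unlink(f)
})
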