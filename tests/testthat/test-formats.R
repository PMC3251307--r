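# Parsers and writers for the chromosomes/colors/genes files and the five
# track grammars.

test_that("chromosomes file grammar: id = length with tolerant whitespace", {
  cs <- parse_chromosomes("1 = 11723881")
  expect_s3_class(cs, "chromosome_set")
  expect_identical(cs$id, "1")
  expect_identical(cs$length, 11723881)

  cs2 <- parse_chromosomes(c("# a comment", "", "  chrA=5  ",
                             "chrB   =   10"))
  expect_identical(cs2$id, c("chrA", "chrB"))
  expect_identical(cs2$length, c(5, 10))
})

test_that("chromosomes file errors: empty, duplicates, bad lengths", {
  expect_error(parse_chromosomes(""), "no chromosomes")
  expect_error(parse_chromosomes("# only a comment"), "no chromosomes")
  expect_error(parse_chromosomes(c("a = 5", "a = 6")), "duplicate")
  expect_error(parse_chromosomes("a = five"), "non-integer")
  expect_error(parse_chromosomes("a = 0"), "non-positive")
  expect_error(parse_chromosomes("a = -4"), "non-integer")
  expect_error(parse_chromosomes("just a line"), "id = length")
})

test_that("the thousand-chromosome capacity limit is enforced exactly", {
  at_cap <- sprintf("c%d = 100", 1:1000)
  expect_identical(nrow(parse_chromosomes(at_cap)), 1000L)
  over <- sprintf("c%d = 100", 1:1001)
  expect_error(parse_chromosomes(over), "chromosome cap exceeded")
})

test_that("colors file overlays definitions on the 16 built-ins", {
  expect_length(default_colours(), 16L)
  tab <- parse_colors(NULL)
  expect_identical(unclass(tab), unclass(default_colours()))

  tab <- parse_colors(c("clBlack = $000000", "clPureRed = $FF0000"))
  expect_identical(colour_rgb(tab, "clBlack"), c(0L, 0L, 0L))
  expect_identical(colour_rgb(tab, "clPureRed"), c(255L, 0L, 0L))
  # stated R,G,B byte order
  tab2 <- parse_colors("clOrange = $FF7F00")
  expect_identical(colour_rgb(tab2, "clOrange"), c(255L, 127L, 0L))

  expect_error(parse_colors("clBad = $GGHHII"), "malformed hex")
  expect_error(parse_colors("clBad = $FFF"), "malformed hex")
  expect_warning(tab3 <- parse_colors("orange = $FF7F00"), "prefix")
  expect_true("orange" %in% names(tab3))
})

test_that("unknown colour names resolve to the mid-grey fallback", {
  expect_warning(
    hex <- genomap:::resolve_colour(default_colours(), "clNotAColour"),
    "unknown colour")
  expect_identical(hex, "#808080")
})

test_that("genes file: field mapping, comments, extras preservation", {
  g <- parse_genes("2\t100\t500\t+\tgeneA\tdesc")
  expect_identical(g$chrom, "2")
  expect_identical(g$first, 100)
  expect_identical(g$last, 500)
  expect_identical(g$strand, "+")
  expect_identical(g$id, "geneA")
  expect_identical(g$extras[[1]], "desc")

  # comments and blank lines ignored
  expect_identical(nrow(parse_genes(c("# header", ""))), 0L)

  # extras are preserved byte-identically, including odd content
  raw <- "1\t1\t2\t+\tg\t  spaced  \t$pec!al\t"
  g2 <- parse_genes(raw)
  expect_identical(g2$extras[[1]], c("  spaced  ", "$pec!al", ""))
})

test_that("genes file: reversed coordinates are swapped with a warning", {
  expect_warning(g <- parse_genes("2\t500\t100\t-\tg"), "swapped")
  # oracle: min/max of the two printed coordinates
  expect_identical(g$first, min(100, 500))
  expect_identical(g$last, max(100, 500))
})

test_that("genes file: malformed lines are rejected with their line number", {
  expect_error(parse_genes(c("# ok", "1\t2\t3\t+")), "line 2")
  expect_error(parse_genes("1\ta\t3\t+\tg"), "non-integer")
  expect_error(parse_genes("1\t1.5\t3\t+\tg"), "non-integer")
})

test_that("posn track: first #-line is the colour; header is mandatory", {
  tr <- parse_posn(c("# clBlue", "2\t100\t500\t+\tgeneA"), "TRI_genes")
  expect_identical(tr$kind, "posn")
  expect_identical(tr$colour, "clBlue")
  expect_identical(tr$name, "TRI_genes")
  expect_identical(nrow(tr$records), 1L)

  # colour header only: a valid empty track
  empty <- parse_posn("# clRed")
  expect_identical(nrow(empty$records), 0L)
  expect_identical(empty$colour, "clRed")

  expect_error(parse_posn("1\t1\t2\t+\tg"), "missing colour header")
})

test_that("blast track: only the first (lowest) E-value decides retention", {
  txt <- c("# clRed", "# 1e-10",
           "1\t100\t200\t+\tgA\tq1\t1e-20",
           "1\t300\t400\t+\tgB\tq2\t1e-5",
           "1\t500\t600\t+\tseq\tq3\t1e-12\tq4\t0.2")
  expect_message(tr <- parse_blast(txt), "2.*dropped|dropped")
  expect_identical(tr$cutoff, 1e-10)
  expect_identical(tr$records$id, c("gA", "seq"))
  expect_identical(tr$records$pairs[[2]]$query, c("q3", "q4"))
})

test_that("blast track: unsorted pairs re-sorted with warning (oracle sort)", {
  txt <- c("# clRed", "# 1",
           "1\t1\t9\t+\tg\tqa\t1e-3\tqb\t1e-9")
  expect_warning(tr <- parse_blast(txt), "not ascending")
  e <- tr$records$pairs[[1]]$evalue
  expect_identical(e, sort(c(1e-3, 1e-9)))
  expect_identical(tr$records$pairs[[1]]$query, c("qb", "qa"))
})

test_that("blast track: structural errors", {
  expect_error(parse_blast("# clRed"), "cut-off")
  expect_error(parse_blast(c("# clRed", "# 1e-10", "1\t1\t2\t+\tg")),
               "pair")
  expect_error(parse_blast(c("# clRed", "# 1e-10",
                             "1\t1\t2\t+\tg\tq1\t1e-3\tq2")),
               "unpaired")
  expect_error(parse_blast(c("# clRed", "# xyz", "1\t1\t2\t+\tg\tq\t1")),
               "cut-off")
  expect_error(parse_blast(c("# clRed", "# 1", "1\t1\t2\t+\tg\tq\t-1")),
               "negative")
})

test_that("expr track: per-row colours, fallback for unknown names", {
  txt <- c("# any comment is ignored",
           "1\t1\t10\t+\tup1\tclRed",
           "1\t20\t30\t-\tdown1\tclBlue")
  tr <- parse_expr(txt)
  expect_identical(tr$records$colour, c("clRed", "clBlue"))

  expect_identical(nrow(parse_expr("# nothing")$records), 0L)

  expect_warning(tr2 <- parse_expr("1\t1\t10\t+\tg\tclNotAColour"),
                 "clGray")
  expect_identical(tr2$records$colour, "clGray")
})

test_that("freq track header parses the documented six-colour gradient", {
  hdr <- paste("#", paste(c("clBeige", "1", "clKhaki", "2", "clGold", "3",
                            "clGoldenRod", "4", "clTomato", "8",
                            "clCrimson"), collapse = "\t"))
  tr <- parse_freq(c(hdr, "1\t1\t27000\t.\tseq\t0.4"))
  expect_identical(tr$gradient$colours,
                   c("clBeige", "clKhaki", "clGold", "clGoldenRod",
                     "clTomato", "clCrimson"))
  expect_identical(tr$gradient$boundaries, c(1, 2, 3, 4, 8))
  expect_identical(tr$records$value, 0.4)

  # space-separated header is accepted too
  tr2 <- parse_freq(c("# clRed 5 clBlue", "1\t1\t10\t.\tseq\t7"))
  expect_identical(tr2$gradient$colours, c("clRed", "clBlue"))

  # degenerate single-colour gradient
  tr3 <- parse_freq(c("# clRed", "1\t1\t10\t.\tseq\t3"))
  expect_identical(assign_gradient_colour(c(-1e6, 0, 1e6), tr3$gradient),
                   rep("clRed", 3))
})

test_that("freq track: twenty-colour gradient cap enforced exactly", {
  mk <- function(k) {
    toks <- character(2 * k - 1)
    toks[seq(1, length(toks), 2)] <- sprintf("cl%d", seq_len(k))
    toks[seq_len(length(toks)) %% 2 == 0] <- as.character(seq_len(k - 1))
    paste("#", paste(toks, collapse = "\t"))
  }
  expect_length(parse_freq(mk(20))$gradient$colours, 20L)
  expect_error(parse_freq(mk(21)), "gradient cap exceeded")
  expect_error(parse_freq("# clA\t5\tclB\t5\tclC"), "strictly increasing")
  expect_error(parse_freq("# clA\t5\tclB\t2\tclC"), "strictly increasing")
})

test_that("gradient binning follows half-open bins and the worked examples", {
  g <- doc_gradient()
  expect_identical(assign_gradient_colour(0.5, g), "clBeige")
  expect_identical(assign_gradient_colour(1, g), "clKhaki")   # boundary
  expect_identical(assign_gradient_colour(100, g), "clCrimson")
  expect_error(assign_gradient_colour(NaN, g), "finite")
  expect_error(assign_gradient_colour(Inf, g), "finite")
})

test_that("gradient binning agrees with the findInterval oracle and is
           monotone", {
  set.seed(11)
  for (rep in 1:50) {
    g <- random_gradient()
    vals <- sort(c(g$boundaries,
                   round(stats::runif(40, -2, max(c(g$boundaries, 1)) + 2),
                         3)))
    got <- assign_gradient_colour(vals, g)
    expect_identical(got, oracle_gradient(vals, g))
    idx <- match(got, g$colours)
    expect_true(all(diff(idx) >= 0))  # monotone in the value
  }
})

test_that("graph track: numeric values including negatives; errors", {
  tr <- parse_graph(c("# any", "1\t1\t50\t.\tseq\t12",
                      "1\t51\t100\t.\tseq\t-3"))
  expect_identical(tr$records$value, c(12, -3))
  expect_identical(range(tr$records$value), c(-3, 12))
  expect_error(parse_graph("1\t1\t50\t.\tseq\ttwelve"), "non-numeric")
})

test_that("write/parse round-trips every track kind", {
  set.seed(42)
  for (kind in c("posn", "blast", "expr", "freq", "graph")) {
    tr <- random_track(kind)
    back <- round_trip(tr)
    expect_identical(back$kind, tr$kind)
    expect_identical(back$colour, tr$colour)
    if (kind == "blast") expect_equal(back$cutoff, tr$cutoff)
    if (kind == "freq") {
      expect_identical(back$gradient$colours, tr$gradient$colours)
      expect_equal(back$gradient$boundaries, tr$gradient$boundaries)
    }
    expect_same_records(back$records, tr$records)
  }
})

test_that("writers sort data lines by chromosome id then start position", {
  set.seed(7)
  tr <- random_track("posn", n = 12)
  path <- tempfile(fileext = ".posn")
  write_track(tr, path)
  lines <- readLines(path)[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  chroms <- vapply(parts, `[[`, "", 1)
  firsts <- as.numeric(vapply(parts, `[[`, "", 2))
  # oracle: an independently computed sort of the same keys
  o <- order(chroms, firsts, method = "radix")
  expect_identical(o, seq_along(lines))
  unlink(path)
})

test_that("empty tracks write header-only files that re-parse as empty", {
  tr <- track("none", "posn",
              features(character(0), numeric(0), numeric(0), character(0),
                       character(0)),
              colour = "clBlue")
  back <- round_trip(tr)
  expect_identical(nrow(back$records), 0L)
  expect_identical(back$colour, "clBlue")
})

test_that("chromosomes file round-trips", {
  cs <- chromosome_set(c("1", "chr_X"), c(11723881, 42))
  path <- tempfile()
  write_chromosomes(cs, path)
  expect_identical(parse_chromosomes(readLines(path)), cs)
  unlink(path)
})

test_that("read_track rejects unknown extensions", {
  path <- tempfile(fileext = ".unknown")
  writeLines("# clRed", path)
  expect_error(read_track(path), "unknown track extension")
  unlink(path)
})

test_that("CRLF line endings are accepted everywhere", {
  txt <- "1 = 500\r\n2 = 300\r"
  cs <- parse_chromosomes(txt)
  expect_identical(cs$length, c(500, 300))
  g <- parse_genes("1\t1\t10\t+\tg\tann\r")
  expect_identical(g$extras[[1]], "ann")
})
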