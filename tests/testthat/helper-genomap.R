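# Shared fixtures and independent oracles for the suite. Everything random
# is generated under an explicit seed inside the test that uses it.

tmp_dir <- function() {
  d <- tempfile("genomap-test-")
  dir.create(d)
  d
}

# --- independent oracles -----------------------------------------------------

# O(n) brute-force overlap scan (closed intervals, any overlap).
brute_force_overlap <- function(records, sel) {
  which(records$chrom == sel$chrom &
          records$first <= sel$last &
          records$last >= sel$first)
}

# Gradient bin lookup through findInterval, an independent code path from
# the package's boundary count.
oracle_gradient <- function(value, g) {
  g$colours[findInterval(value, g$boundaries) + 1L]
}

# --- random track generation for fuzz/round-trip properties ------------------

random_features <- function(n, chroms = c("1", "2", "scaff_3"),
                            with_extras = TRUE) {
  first <- sample.int(100000L, n, replace = TRUE)
  len <- sample.int(5000L, n, replace = TRUE)
  extras <- lapply(seq_len(n), function(i) {
    if (with_extras && stats::runif(1) < 0.7) {
      c(sprintf("annotation %d", i), "extra field")
    } else {
      character(0)
    }
  })
  features(sample(chroms, n, replace = TRUE), first, first + len - 1,
           sample(c("+", "-", "."), n, replace = TRUE),
           sprintf("g%05d", sample.int(99999L, n)),
           extras)
}

random_gradient <- function() {
  k <- sample(1:20, 1)
  gradient_spec(sprintf("cl%02d", seq_len(k)),
                if (k > 1) cumsum(round(stats::runif(k - 1, 0.1, 5), 3))
                else numeric(0))
}

random_track <- function(kind, n = sample(3:8, 1)) {
  recs <- random_features(n, with_extras = kind != "blast")
  switch(kind,
    posn = track("fuzz", "posn", recs, colour = "clBlue"),
    expr = {
      recs$colour <- sample(names(default_colours()), n, replace = TRUE)
      track("fuzz", "expr", recs)
    },
    freq = {
      g <- random_gradient()
      recs$value <- round(stats::runif(n, 0, max(c(g$boundaries, 1)) * 1.5),
                          3)
      track("fuzz", "freq", recs, gradient = g)
    },
    graph = {
      recs$value <- round(stats::runif(n, -5, 50), 3)
      track("fuzz", "graph", recs)
    },
    blast = {
      cutoff <- 1e-5
      recs$pairs <- I(lapply(seq_len(n), function(i) {
        k <- sample(1:3, 1)
        e <- sort(signif(stats::runif(k) * 10^-sample(5:30, k,
                                                      replace = TRUE), 3))
        data.frame(query = sprintf("q%03d", sample.int(999L, k)),
                   evalue = e, stringsAsFactors = FALSE)
      }))
      track("fuzz", "blast", recs, colour = "clRed", cutoff = cutoff)
    })
}

# Canonical record order for multiset comparison.
normalize_records <- function(recs) {
  o <- order(recs$chrom, recs$first, recs$last, recs$id, method = "radix")
  recs <- recs[o, , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

expect_same_records <- function(got, want, tol = 1e-9) {
  got <- normalize_records(got)
  want <- normalize_records(want)
  expect_equal(nrow(got), nrow(want))
  for (col in c("chrom", "strand", "id")) {
    expect_identical(got[[col]], want[[col]])
  }
  expect_equal(got$first, want$first)
  expect_equal(got$last, want$last)
  expect_identical(unclass(got$extras), unclass(want$extras))
  if (!is.null(want$value)) expect_equal(got$value, want$value,
                                         tolerance = tol)
  if (!is.null(want$colour)) expect_identical(got$colour, want$colour)
  if (!is.null(want$pairs)) {
    for (i in seq_len(nrow(want))) {
      expect_identical(got$pairs[[i]]$query, want$pairs[[i]]$query)
      expect_equal(got$pairs[[i]]$evalue, want$pairs[[i]]$evalue,
                   tolerance = tol)
    }
  }
}

# Write a track, re-read it through the extension dispatcher, and return it.
round_trip <- function(tr) {
  path <- tempfile(fileext = paste0(".", tr$kind))
  on.exit(unlink(path))
  write_track(tr, path)
  suppressWarnings(suppressMessages(read_track(path, name = tr$name)))
}

# The six-colour recombination-style gradient used in documentation
# examples (clBeige .. clCrimson with boundaries 1, 2, 3, 4, 8).
doc_gradient <- function() {
  gradient_spec(c("clBeige", "clKhaki", "clGold", "clGoldenRod", "clTomato",
                  "clCrimson"),
                c(1, 2, 3, 4, 8))
}

# A tiny deterministic genome for render/query tests.
tiny_genome <- function() {
  cs <- chromosome_set(c("1", "2", "3", "4"),
                       c(1000000, 750000, 500000, 250000))
  genes <- features(c("1", "1", "2", "2", "3"),
                    c(100, 5000, 100000, 200000, 1),
                    c(1099, 6999, 101999, 202999, 500),
                    c("+", "-", "+", "-", "+"),
                    c("gA", "gB", "gC", "gD", "gE"),
                    extras = list("alpha", "beta", "gamma", "delta",
                                  character(0)))
  build_genome(cs, genes)
}
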