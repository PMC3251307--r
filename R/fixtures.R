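# ---------------------------------------------------------------------------
# Seeded synthetic-project generator: builds a complete, self-consistent
# map project (chromosomes, genes, FASTA, colours, credits, one track of
# each kind) from one integer seed, recording the planted truth so every
# downstream statistic can be checked against what was planted.
# ---------------------------------------------------------------------------

# Run code under a private RNG stream, leaving global RNG state untouched.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Colour definitions beyond the 16 built-ins used by generated projects
# (standard web colour values).
EXTRA_COLOURS <- c(
  clBeige = "#F5F5DC", clKhaki = "#F0E68C", clGold = "#FFD700",
  clGoldenRod = "#DAA520", clTomato = "#FF6347", clCrimson = "#DC143C"
)

# The six-colour recombination-style gradient used by generated freq tracks.
example_gradient <- function() {
  gradient_spec(names(EXTRA_COLOURS), c(1, 2, 3, 4, 8))
}

#' Specify a synthetic project
#'
#' Defaults emulate a small fungal genome: four chromosomes in the
#' 0.5-1.2 Mb range, genes of ~1.5 kb mean length placed without overlap,
#' SNPs at roughly one per 3.5 kb (the density seen when a second isolate
#' is sequenced at low coverage), and blast hits planted on both sides of a
#' 1e-10 E-value cut-off.
#'
#' @param n_chrom number of chromosomes.
#' @param length_range numeric `(min, max)` chromosome length in nt.
#' @param n_genes total genes across the genome.
#' @param mean_gene_len mean gene length in nt.
#' @param seed integer seed; the same spec always produces a byte-identical
#'   project.
#' @param tracks which track kinds to emit (subset of posn, blast, expr,
#'   freq, graph).
#' @param fasta also write per-chromosome FASTA sequences.
#' @param snp_per_nt planted SNP rate (positions per nt) for the graph
#'   track.
#' @param n_blast number of planted blast regions (half at E = 1e-20,
#'   passing the cut-off; half at E = 1e-05, failing it).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_chrom = 4L, length_range = c(5e5, 1.2e6),
                           n_genes = 400L, mean_gene_len = 1500L,
                           seed = 1L,
                           tracks = c("posn", "blast", "expr", "freq",
                                      "graph"),
                           fasta = TRUE, snp_per_nt = 1 / 3500,
                           n_blast = 40L) {
  stopifnot(n_chrom >= 1, n_genes >= 1, mean_gene_len >= 1,
            length_range[1] >= 1, length_range[1] <= length_range[2],
            n_blast %% 2 == 0)
  tracks <- match.arg(tracks, TRACK_KINDS, several.ok = TRUE)
  structure(list(n_chrom = as.integer(n_chrom),
                 length_range = as.numeric(length_range),
                 n_genes = as.integer(n_genes),
                 mean_gene_len = as.integer(mean_gene_len),
                 seed = as.integer(seed), tracks = tracks,
                 fasta = isTRUE(fasta), snp_per_nt = snp_per_nt,
                 n_blast = as.integer(n_blast)),
            class = "synthetic_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Allocate n items over chromosomes proportionally to length, at least the
# rounding allows.
allocate_proportional <- function(n, lengths) {
  raw <- n * lengths / sum(lengths)
  alloc <- floor(raw)
  rem <- n - sum(alloc)
  if (rem > 0) {
    extra <- order(raw - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }
  as.integer(alloc)
}

# Non-overlapping gene placement: one gene per equal-width slot.
place_genes <- function(cid, len, n, mean_len, id_offset) {
  if (n == 0L) return(NULL)
  slot <- floor(len / n)
  if (slot < mean_len + 10) {
    stop("infeasible packing: ", n, " genes of mean length ", mean_len,
         " nt do not fit on a ", fmt_coord(len), " nt chromosome")
  }
  glen <- pmin(pmax(round(stats::rnorm(n, mean_len, mean_len / 4)), 150),
               slot - 2)
  offset <- vapply(seq_len(n), function(i) {
    sample.int(slot - glen[i], 1L)
  }, 0L)
  first <- (seq_len(n) - 1) * slot + offset
  features(rep(cid, n), first, first + glen - 1,
           sample(c("+", "-"), n, replace = TRUE),
           sprintf("SYN_%05d", id_offset + seq_len(n)),
           extras = lapply(id_offset + seq_len(n),
                           function(k) sprintf("synthetic gene %d", k)))
}

#' Generate a synthetic map project
#'
#' Writes a complete project directory -- `_data` (chromosomes, genes,
#' colors, credits and optionally per-chromosome FASTA) plus one menu
#' folder per requested track kind -- and returns the planted truth:
#' the gene table, the SNP positions and their per-window counts, which
#' blast records pass the cut-off, and the freq values. Everything is
#' deterministic under the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir directory to create the project in.
#' @return Invisibly, a list with `root`, `spec` and `truth` (fields
#'   `chromosomes`, `genes`, `snp_positions`, `snp_window_counts`,
#'   `blast_pass_n`, `blast_total_n`, `freq_values`, `expr_colours`).
#' @export
make_project <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data_dir <- file.path(out_dir, "_data")
    dir.create(data_dir, showWarnings = FALSE)

    lens <- round(stats::runif(spec$n_chrom, spec$length_range[1],
                               spec$length_range[2]))
    chroms <- chromosome_set(as.character(seq_len(spec$n_chrom)), lens)
    write_chromosomes(chroms, file.path(data_dir, "chromosomes"))

    alloc <- allocate_proportional(spec$n_genes, lens)
    genes_parts <- lapply(seq_len(spec$n_chrom), function(ci) {
      place_genes(chroms$id[ci], lens[ci], alloc[ci], spec$mean_gene_len,
                  id_offset = sum(alloc[seq_len(ci - 1)]))
    })
    genes <- do.call(rbind, genes_parts)
    write_genes(genes, file.path(data_dir, "genes"))

    colours <- default_colours()
    for (nm in names(EXTRA_COLOURS)) colours[[nm]] <- EXTRA_COLOURS[[nm]]
    write_colors(structure(colours, class = "colour_table"),
                 file.path(data_dir, "colors"))
    writeLines(c("Synthetic map project generated by the genomap package.",
                 sprintf("seed = %d", spec$seed)),
               file.path(data_dir, "credits"))

    if (spec$fasta) {
      for (ci in seq_len(spec$n_chrom)) {
        s <- Biostrings::DNAStringSet(random_dna(lens[ci]))
        names(s) <- chroms$id[ci]
        Biostrings::writeXStringSet(
          s, file.path(data_dir, paste0(chroms$id[ci], ".fasta")),
          width = 60L)
      }
    }

    truth <- list(chromosomes = chroms, genes = genes)

    if ("posn" %in% spec$tracks) {
      dir.create(file.path(out_dir, "Genes"), showWarnings = FALSE)
      write_track(track("all_genes", "posn", genes, colour = "clBlue"),
                  file.path(out_dir, "Genes", "all_genes.posn"))
    }

    if ("expr" %in% spec$tracks) {
      dir.create(file.path(out_dir, "Expression"), showWarnings = FALSE)
      n_up <- max(1L, nrow(genes) %/% 8L)
      idx <- sample.int(nrow(genes), 2L * n_up)
      expr <- genes[idx, , drop = FALSE]
      expr$colour <- rep(c("clRed", "clBlue"), each = n_up)
      write_track(track("expression", "expr", expr),
                  file.path(out_dir, "Expression", "expression.expr"))
      truth$expr_colours <- stats::setNames(expr$colour, expr$id)
    }

    if ("freq" %in% spec$tracks) {
      dir.create(file.path(out_dir, "Recombination"), showWarnings = FALSE)
      win <- 50000
      parts <- lapply(seq_len(spec$n_chrom), function(ci) {
        n_win <- ceiling(lens[ci] / win)
        firsts <- (seq_len(n_win) - 1) * win + 1
        df <- features(rep(chroms$id[ci], n_win), firsts,
                       pmin(firsts + win - 1, lens[ci]),
                       rep(".", n_win), rep("seq", n_win))
        df$value <- round(stats::rexp(n_win, rate = 1 / 2), 3)
        df
      })
      freq_recs <- do.call(rbind, parts)
      write_track(track("recombination", "freq", freq_recs,
                        gradient = example_gradient()),
                  file.path(out_dir, "Recombination", "recombination.freq"))
      truth$freq_values <- freq_recs$value
    }

    if ("graph" %in% spec$tracks) {
      dir.create(file.path(out_dir, "SNPs"), showWarnings = FALSE)
      n_snp <- pmax(1L, round(lens * spec$snp_per_nt))
      snps <- do.call(rbind, lapply(seq_len(spec$n_chrom), function(ci) {
        data.frame(chrom = chroms$id[ci],
                   pos = sort(sample.int(lens[ci], n_snp[ci])),
                   stringsAsFactors = FALSE)
      }))
      tr <- positions_to_graph(snps, chroms,
                               out = file.path(out_dir, "SNPs",
                                               "snp_density.graph"),
                               name = "snp_density")
      truth$snp_positions <- snps
      truth$snp_window_counts <- tr$records$value
    }

    if ("blast" %in% spec$tracks) {
      dir.create(file.path(out_dir, "Homologues"), showWarnings = FALSE)
      n <- spec$n_blast
      idx <- sample.int(nrow(genes), min(n, nrow(genes)))
      hits <- genes[idx, , drop = FALSE]
      pass <- rep(c(TRUE, FALSE), length.out = nrow(hits))
      evals <- ifelse(pass, 1e-20, 1e-05)
      hits$pairs <- I(lapply(seq_len(nrow(hits)), function(i) {
        data.frame(query = sprintf("HOM_%03d", i),
                   evalue = evals[i], stringsAsFactors = FALSE)
      }))
      write_track(track("homologues", "blast", hits, colour = "clRed",
                        cutoff = 1e-10),
                  file.path(out_dir, "Homologues", "homologues.blast"))
      truth$blast_pass_n <- sum(pass)
      truth$blast_total_n <- nrow(hits)
      truth$blast_pass_ids <- hits$id[pass]
    }

    invisible(list(root = out_dir, spec = spec, truth = truth))
  })
}

#' Generate the miniature worked-example project
#'
#' A deterministic four-chromosome project with a planted cluster of ten
#' toxin-biosynthesis-style genes in the middle of chromosome 2, displayed
#' through a blue posn track -- the data behind the README's worked
#' example. Chromosome FASTA files are included so region sequences can be
#' extracted.
#'
#' @param out_dir directory to create the project in.
#' @return Invisibly, a list with `root` and `truth` (`cluster` = the
#'   ten-gene feature table, `cluster_region` = its enclosing
#'   [region_selection()]).
#' @export
make_worked_example <- function(out_dir) {
  with_local_seed(20110447L, {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data_dir <- file.path(out_dir, "_data")
    dir.create(data_dir, showWarnings = FALSE)

    lens <- c(117000, 90000, 78000, 96000)
    chroms <- chromosome_set(as.character(1:4), lens)
    write_chromosomes(chroms, file.path(data_dir, "chromosomes"))

    # ten clustered genes mid-chromosome 2, ~2 kb each with short gaps
    starts <- 40000 + (0:9) * 2600
    cluster <- features(rep("2", 10), starts, starts + 1999,
                        rep(c("+", "-"), 5),
                        sprintf("TOX_%02d", 1:10),
                        extras = lapply(1:10, function(i) {
                          sprintf("toxin biosynthesis cluster gene %d", i)
                        }))
    background <- do.call(rbind, lapply(1:4, function(ci) {
      n <- 8L
      first <- round(seq(5000, lens[ci] - 7000, length.out = n))
      features(rep(as.character(ci), n), first, first + 1499,
               rep("+", n), sprintf("BG_%d_%02d", ci, seq_len(n)),
               extras = lapply(seq_len(n), function(i) "background gene"))
    }))
    genes <- rbind(background, cluster)
    write_genes(genes, file.path(data_dir, "genes"))
    writeLines("Miniature worked-example project (synthetic data).",
               file.path(data_dir, "credits"))

    for (ci in 1:4) {
      s <- Biostrings::DNAStringSet(random_dna(lens[ci]))
      names(s) <- as.character(ci)
      Biostrings::writeXStringSet(
        s, file.path(data_dir, paste0(ci, ".fasta")), width = 60L)
    }

    dir.create(file.path(out_dir, "Toxin_cluster"), showWarnings = FALSE)
    write_track(track("cluster", "posn", cluster, colour = "clBlue"),
                file.path(out_dir, "Toxin_cluster", "cluster.posn"))

    invisible(list(
      root = out_dir,
      truth = list(cluster = cluster,
                   cluster_region = region_selection("2", 39000, 66000))))
  })
}
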