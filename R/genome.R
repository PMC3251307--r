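# ---------------------------------------------------------------------------
# In-memory genome: chromosomes + per-chromosome sorted gene lists, the
# derived statistics written under _stats, and the project-directory scan
# that turns the folder tree into a track catalogue (the library analogue of
# the menu bar).
# ---------------------------------------------------------------------------

#' Build an in-memory genome
#'
#' Partitions the master gene list by chromosome and sorts each partition by
#' start position. Features referencing unknown chromosomes are not an
#' error: they are collected into a `rejected` table and reported, so a
#' partly mismatched community file still loads. Features overhanging their
#' chromosome end are kept (they are clipped at render time) and counted in
#' a warning.
#'
#' @param chromosomes a [chromosome_set()].
#' @param genes a feature table (see [parse_genes()]).
#' @return An object of class `genome` with fields `chromosomes`,
#'   `genes_by_chrom` (named list of per-chromosome feature tables,
#'   ascending in `first`), and `rejected`.
#' @export
build_genome <- function(chromosomes, genes) {
  stopifnot(inherits(chromosomes, "chromosome_set"))
  known <- genes$chrom %in% chromosomes$id
  rejected <- genes[!known, , drop = FALSE]
  if (nrow(rejected) > 0L) {
    warning(nrow(rejected), " feature(s) reference unknown chromosome(s) (",
            paste(unique(rejected$chrom), collapse = ", "),
            ") and were set aside")
  }
  kept <- genes[known, , drop = FALSE]
  by_chrom <- lapply(chromosomes$id, function(cid) {
    sub <- kept[kept$chrom == cid, , drop = FALSE]
    sub <- sub[order(sub$first, method = "radix"), , drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
  names(by_chrom) <- chromosomes$id
  n_over <- sum(vapply(chromosomes$id, function(cid) {
    sum(by_chrom[[cid]]$last >
          chromosomes$length[chromosomes$id == cid])
  }, 0))
  if (n_over > 0L) {
    warning(n_over, " feature(s) overhang their chromosome end; they are ",
            "kept and clipped at render time")
  }
  structure(list(chromosomes = chromosomes, genes_by_chrom = by_chrom,
                 rejected = rejected),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", nrow(x$chromosomes), "chromosome(s),",
      sum(vapply(x$genes_by_chrom, nrow, 0L)), "gene(s)")
  if (nrow(x$rejected)) cat(",", nrow(x$rejected), "rejected")
  cat("\n")
  invisible(x)
}

# Total placed genes.
genome_gene_count <- function(genome) {
  sum(vapply(genome$genes_by_chrom, nrow, 0L))
}

#' Per-chromosome genome statistics
#'
#' For each chromosome: its length, the number of genes on it, the average
#' number of base pairs per gene (chromosome length divided by gene count;
#' `NA` for a geneless chromosome) and, as an extra clearly-labelled column,
#' the mean gene length. When `dir` is given the table is written to
#' `dir/stats` (tab-separated) and the genes of each chromosome to
#' `dir/<id>.genes.txt`, the layout kept under a project's `_stats` folder.
#'
#' @param genome a [build_genome()] result.
#' @param dir optional directory to write `stats` and the per-chromosome
#'   `id.genes.txt` files into (created if absent).
#' @return A data frame of class `genome_stats` with columns `chrom_id`,
#'   `length`, `gene_count`, `bp_per_gene`, `mean_gene_length`.
#' @export
compute_stats <- function(genome, dir = NULL) {
  stopifnot(inherits(genome, "genome"))
  cs <- genome$chromosomes
  gene_count <- vapply(cs$id, function(cid) nrow(genome$genes_by_chrom[[cid]]),
                       0L)
  bp_per_gene <- ifelse(gene_count > 0, cs$length / gene_count, NA_real_)
  mean_len <- vapply(cs$id, function(cid) {
    g <- genome$genes_by_chrom[[cid]]
    if (nrow(g) == 0L) NA_real_ else mean(g$last - g$first + 1)
  }, 0)
  stats <- data.frame(chrom_id = cs$id, length = cs$length,
                      gene_count = as.integer(gene_count),
                      bp_per_gene = bp_per_gene,
                      mean_gene_length = mean_len,
                      stringsAsFactors = FALSE)
  class(stats) <- c("genome_stats", "data.frame")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out <- stats
    out$length <- fmt_coord(out$length)
    num <- function(x) ifelse(is.na(x), "NA", fmt_value(round(x, 1)))
    out$bp_per_gene <- num(stats$bp_per_gene)
    out$mean_gene_length <- num(stats$mean_gene_length)
    utils::write.table(out, file.path(dir, "stats"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (cid in cs$id) {
      write_genes(genome$genes_by_chrom[[cid]],
                  file.path(dir, paste0(cid, ".genes.txt")))
    }
  }
  stats
}

SPECIAL_FOLDERS <- c("_data", "_seqs", "_stats")

#' Scan a map project directory
#'
#' A project is a directory tree: the special underscore folders `_data`
#' (chromosomes, genes, colors, credits and optional per-chromosome
#' `id.fasta` files), `_seqs` (saved region sequences) and `_stats`
#' (derived statistics) -- created automatically when absent -- plus any
#' number of menu folders whose nested structure and track files
#' (`.posn`/`.blast`/`.expr`/`.freq`/`.graph`) define the catalogue, exactly
#' as the folder tree would populate a menu bar. Folders beginning with an
#' underscore never become menu nodes. If `_data/chromosomes` and
#' `_data/genes` are present the genome is loaded and `_stats` regenerated.
#'
#' @param root project root directory (must exist).
#' @return An object of class `project_catalogue`: `root`, `leaves` (a data
#'   frame with columns `menu`, `name`, `kind`, `path`, `broken`),
#'   `credits`, and when `_data` is populated `genome`, `colours` and
#'   `stats`.
#' @export
scan_project <- function(root) {
  if (!dir.exists(root)) stop("project root does not exist: ", root)
  for (f in SPECIAL_FOLDERS) {
    d <- file.path(root, f)
    if (!dir.exists(d)) dir.create(d)
  }

  files <- list.files(root, recursive = TRUE, full.names = FALSE)
  rel_dirs <- dirname(files)
  top <- vapply(strsplit(files, "/", fixed = TRUE), `[[`, "", 1L)
  in_menu <- !startsWith(top, "_") & rel_dirs != "." &
    !vapply(strsplit(rel_dirs, "/", fixed = TRUE),
            function(p) any(startsWith(p, "_")), TRUE)
  ext <- tolower(tools::file_ext(files))
  is_track <- in_menu & ext %in% TRACK_EXTENSIONS
  leaves <- data.frame(
    menu = rel_dirs[is_track],
    name = tools::file_path_sans_ext(basename(files[is_track])),
    kind = ext[is_track],
    path = file.path(root, files[is_track]),
    broken = rep(FALSE, sum(is_track)),
    stringsAsFactors = FALSE
  )
  leaves <- leaves[order(leaves$menu, leaves$name, method = "radix"), ,
                   drop = FALSE]
  rownames(leaves) <- NULL
  for (i in seq_len(nrow(leaves))) {
    ok <- tryCatch({ readLines(leaves$path[i], n = 1L, warn = FALSE); TRUE },
                   error = function(e) FALSE)
    if (!ok) {
      leaves$broken[i] <- TRUE
      warning("track file unreadable, leaf marked broken: ", leaves$path[i])
    }
  }

  credits_path <- file.path(root, "_data", "credits")
  credits <- if (file.exists(credits_path)) {
    paste(readLines(credits_path, warn = FALSE), collapse = "\n")
  } else ""

  colours_path <- file.path(root, "_data", "colors")
  colours <- if (file.exists(colours_path)) {
    parse_colors(readLines(colours_path, warn = FALSE))
  } else default_colours()

  cat_obj <- structure(
    list(root = normalizePath(root), leaves = leaves, credits = credits,
         colours = colours, genome = NULL, stats = NULL,
         cache = new.env(parent = emptyenv())),
    class = "project_catalogue")

  chrom_path <- file.path(root, "_data", "chromosomes")
  genes_path <- file.path(root, "_data", "genes")
  if (file.exists(chrom_path) && file.exists(genes_path)) {
    chroms <- parse_chromosomes(readLines(chrom_path, warn = FALSE))
    genes <- parse_genes(readLines(genes_path, warn = FALSE))
    cat_obj$genome <- build_genome(chroms, genes)
    # _stats is cheap to derive, so it is regenerated on every scan.
    cat_obj$stats <- compute_stats(cat_obj$genome, file.path(root, "_stats"))
  }
  cat_obj
}

#' @export
print.project_catalogue <- function(x, ...) {
  cat("map project at", x$root, "\n")
  cat(" ", nrow(x$leaves), "track leaf/leaves under",
      length(unique(x$leaves$menu)), "menu node(s)\n")
  if (!is.null(x$genome)) print(x$genome)
  invisible(x)
}

#' Menu nodes of a catalogue
#'
#' @param catalogue a [scan_project()] result.
#' @return Character vector of menu node paths (e.g. `"A"`, `"A/B"`), the
#'   directory tree minus underscore folders.
#' @export
catalogue_nodes <- function(catalogue) {
  menus <- unique(catalogue$leaves$menu)
  nodes <- unique(unlist(lapply(strsplit(menus, "/", fixed = TRUE),
                                function(p) {
                                  vapply(seq_along(p), function(k) {
                                    paste(p[1:k], collapse = "/")
                                  }, "")
                                })))
  sort(nodes)
}

#' Load a track by its catalogue path
#'
#' Dispatches to the parser selected by the leaf's file extension and caches
#' the result per path, so loading the same leaf twice returns the identical
#' object.
#'
#' @param catalogue a [scan_project()] result.
#' @param node_path leaf path as `"menu/sub/name"` (no extension), or just
#'   `"name"` when unambiguous.
#' @return A [track()].
#' @export
load_track <- function(catalogue, node_path) {
  stopifnot(inherits(catalogue, "project_catalogue"))
  lv <- catalogue$leaves
  full <- file.path(lv$menu, lv$name)
  hit <- which(full == node_path | lv$name == node_path)
  if (length(hit) == 0L) stop("no track leaf '", node_path, "' in catalogue")
  if (length(hit) > 1L) {
    stop("ambiguous track name '", node_path, "'; use the full menu path (",
         paste(full[hit], collapse = ", "), ")")
  }
  if (lv$broken[hit]) stop("track leaf '", node_path, "' is marked broken")
  key <- lv$path[hit]
  if (!is.null(catalogue$cache[[key]])) {
    message("cache hit: ", node_path)
    return(catalogue$cache[[key]])
  }
  tr <- read_track(key, name = lv$name[hit], colours = catalogue$colours)
  assign(key, tr, envir = catalogue$cache)
  tr
}
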