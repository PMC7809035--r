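#' Read / write an expression TSV (genes in rows, samples in columns)
#'
#' @param path file path.
#' @param unit unit tag for the returned matrix.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, unit = "fpkm") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, unit)
}

#' @rdname read_expression_tsv
#' @param m an [expression_matrix()].
#' @export
write_expression_tsv <- function(m, path) {
  df <- dplyr::bind_cols(tibble(gene = rownames(m)),
                         as_tibble(unclass(m)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read / write a gene-module assignment TSV (columns gene, module)
#' @param path file path.
#' @param ... passed to [module_assignment()].
#' @return A [module_assignment()].
#' @export
read_modules_tsv <- function(path, ...) {
  module_assignment(readr::read_tsv(path, show_col_types = FALSE), ...)
}

#' @rdname read_modules_tsv
#' @param a a [module_assignment()].
#' @export
write_modules_tsv <- function(a, path) {
  readr::write_tsv(as_tibble(a), path)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab separated.
#'
#' @param path file path.
#' @param provenance provenance tag applied to every set read.
#' @return A named list of [gene_set()] objects.
#' @export
read_gmt <- function(path, provenance = "pathway") {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    stop("package 'fgsea' is required to read GMT files", call. = FALSE)
  }
  sets <- fgsea::gmtPathways(path)
  purrr::imap(sets, function(g, nm) gene_set(nm, g, provenance))
}

#' @rdname read_gmt
#' @param sets list of [gene_set()] objects.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$provenance, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a single-nucleus count matrix as MTX plus metadata
#'
#' MatrixMarket sparse counts with genes and cells sidecar TSVs and a cell
#' metadata CSV (`cell_id`, `subject_id`, `cluster`).
#'
#' @param sn a `mglia_sn` object (or list with `counts` and `meta`).
#' @param dir output directory.
#' @export
write_sn_mtx <- function(sn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(methods::as(sn$counts, "dMatrix"), "generalMatrix"),
                  file.path(dir, "counts.mtx"))
  writeLines(rownames(sn$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(sn$counts), file.path(dir, "cells.tsv"))
  readr::write_csv(sn$meta, file.path(dir, "cell_metadata.csv"))
  invisible(dir)
}

#' @rdname write_sn_mtx
#' @return `read_sn_mtx`: a list with `counts` (sparse genes x cells) and
#'   `meta`.
#' @export
read_sn_mtx <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "counts.mtx"))
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "cells.tsv"))
  meta <- readr::read_csv(file.path(dir, "cell_metadata.csv"),
                          show_col_types = FALSE)
  list(counts = counts, meta = meta)
}

#' Write / read a 16-bit grayscale TIFF image
#'
#' Values are clipped to `[0, 1]` and stored with 16 bits per sample.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path file path.
#' @export
write_image_tiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required for TIFF output", call. = FALSE)
  }
  tiff::writeTIFF(pmin(pmax(img, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @return `read_image_tiff`: a numeric matrix in `[0, 1]`.
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required for TIFF input", call. = FALSE)
  }
  tiff::readTIFF(path)
}

#' Export a network edge list
#'
#' @param net a `mglia_network`.
#' @param path output path; `.csv` writes the tidy edge table, `.graphml`
#'   writes GraphML via igraph.
#' @export
write_network <- function(net, path) {
  if (grepl("\\.graphml$", path)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = data.frame(name = net$visible))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    readr::write_csv(net$edges, path)
  }
  invisible(path)
}
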