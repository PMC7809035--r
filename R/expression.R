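#' Expression matrix container
#'
#' A genes-by-samples numeric matrix with a unit tag. FPKM matrices must be
#' nonnegative; gene and sample identifiers must be unique.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param unit one of `"fpkm"`, `"log2"`, `"residual"`, `"zscore"`.
#' @return The matrix with class `mglia_expr` and a `unit` attribute.
#' @export
expression_matrix <- function(values, unit = c("fpkm", "log2", "residual", "zscore")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values)))) {
    stop("`values` must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicated gene ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids", call. = FALSE)
  if (anyNA(values)) stop("missing values are not supported", call. = FALSE)
  if (unit == "fpkm" && any(values < 0)) {
    stop("fpkm values must be nonnegative", call. = FALSE)
  }
  structure(values, unit = unit, class = c("mglia_expr", "matrix", "array"))
}

#' @export
print.mglia_expr <- function(x, ...) {
  cat(sprintf("<mglia_expr> %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), expr_unit(x)))
  print(utils::head(unclass(x)[, seq_len(min(5L, ncol(x))), drop = FALSE]))
  invisible(x)
}

#' Unit tag of an expression matrix
#' @param m an [expression_matrix()].
#' @return A string.
#' @export
expr_unit <- function(m) attr(m, "unit") %||% "fpkm"

`%||%` <- function(a, b) if (is.null(a)) b else a

# rebuild container after a transform, keeping dimnames
as_expr <- function(values, template, unit) {
  dimnames(values) <- dimnames(template)
  expression_matrix(values, unit)
}

#' Module assignment container
#'
#' A partition of genes into named modules. Each gene belongs to at most one
#' module; modules entering the analysis must reach the minimum size (20
#' genes by default, matching the module-size floor used for cortical
#' co-expression modules).
#'
#' @param df data frame with columns `gene` and `module`.
#' @param min_size minimum module size for the analysis catalog.
#' @return A tibble with class `mglia_modules`; the catalog of analysis
#'   modules (those meeting `min_size`) is in `attr(, "catalog")`.
#' @export
module_assignment <- function(df, min_size = 20L) {
  df <- as_tibble(df)
  if (!all(c("gene", "module") %in% names(df))) {
    stop("`df` needs columns `gene` and `module`", call. = FALSE)
  }
  if (anyDuplicated(df$gene)) {
    stop("a gene may belong to at most one module", call. = FALSE)
  }
  catalog <- df |>
    dplyr::count(.data$module, name = "size") |>
    dplyr::filter(.data$size >= min_size)
  structure(df, catalog = catalog, min_size = min_size,
            class = c("mglia_modules", class(df)))
}

#' Genes of one module
#' @param a a [module_assignment()].
#' @param module_id module name.
#' @return Character vector of gene ids.
#' @export
module_genes <- function(a, module_id) {
  g <- a$gene[a$module == module_id]
  if (length(g) == 0L) stop(sprintf("module '%s' not found", module_id), call. = FALSE)
  g
}

#' Analysis module catalog
#' @param a a [module_assignment()].
#' @return Tibble with columns `module`, `size`.
#' @export
module_catalog <- function(a) attr(a, "catalog")
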