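#' Quantile normalization
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' across-sample mean of the column-sorted values. Ties within a column
#' receive the mean of the reference values at their tied ranks, so the
#' transform is well defined and idempotent.
#'
#' @param m an [expression_matrix()] without missing values, >= 2 samples.
#' @return An [expression_matrix()] with the same unit.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (anyNA(m)) stop("missing values are not supported", call. = FALSE)
  x <- unclass(m)
  ref <- rowMeans(apply(x, 2L, sort))
  out <- apply(x, 2L, function(col) {
    v <- numeric(length(col))
    v[order(col)] <- ref
    # average the reference values over tied ranks
    stats::ave(v, factor(col), FUN = mean)
  })
  as_expr(out, m, expr_unit(m))
}

#' Per-gene location-scale batch adjustment
#'
#' Re-centers and re-scales every batch of each gene to the pooled gene mean
#' and pooled within-batch standard deviation. This is the location-scale
#' core of batch correction without empirical-Bayes shrinkage of the batch
#' parameters.
#'
#' @param m an [expression_matrix()].
#' @param batch vector of batch labels, one per sample; at least 2 batches
#'   with >= 3 samples each.
#' @return An adjusted [expression_matrix()], same unit.
#' @export
adjust_batch <- function(m, batch) {
  batch <- as.factor(batch)
  if (length(batch) != ncol(m)) stop("one batch label per sample", call. = FALSE)
  if (nlevels(batch) < 2L) stop("need at least 2 batches", call. = FALSE)
  small <- table(batch) < 3L
  if (any(small)) {
    stop(sprintf("batches with fewer than 3 samples: %s",
                 paste(names(which(small)), collapse = ", ")), call. = FALSE)
  }
  x <- unclass(m)
  out <- x
  nb <- tabulate(batch)
  for (g in seq_len(nrow(x))) {
    v <- x[g, ]
    mb <- tapply(v, batch, mean)
    sb <- tapply(v, batch, sd)
    # pooled: grand mean; within-batch pooled sd (shift-invariant)
    mu <- sum(nb * mb) / sum(nb)
    sigma <- sqrt(sum((nb - 1L) * sb^2) / sum(nb - 1L))
    z <- (v - mb[batch]) / ifelse(sb[batch] > 0, sb[batch], 1)
    out[g, ] <- z * sigma + mu
  }
  as_expr(out, m, expr_unit(m))
}

#' Filter genes on mean FPKM
#'
#' Retains genes whose mean FPKM strictly exceeds `min_mean` (default 1),
#' the expression floor applied before module analyses.
#'
#' @param m an [expression_matrix()] in fpkm units.
#' @param min_mean threshold on the per-gene mean (strict inequality).
#' @return The filtered [expression_matrix()]; gene order is preserved.
#' @export
filter_genes <- function(m, min_mean = 1.0) {
  if (expr_unit(m) != "fpkm") stop("filter_genes expects fpkm units", call. = FALSE)
  keep <- rowMeans(m) > min_mean
  if (!any(keep)) warning("no gene passes the expression filter")
  out <- unclass(m)[keep, , drop = FALSE]
  if (nrow(out) == 0L) dimnames(out) <- list(character(0), colnames(m))
  expression_matrix(out, "fpkm")
}

#' Log2 transform of FPKM
#'
#' `log2(fpkm + 1)`; the offset of 1 keeps zeros finite.
#'
#' @param m an [expression_matrix()] in fpkm units.
#' @param offset pseudo-count added before the log.
#' @return An [expression_matrix()] in log2 units.
#' @export
log2_fpkm <- function(m, offset = 1) {
  if (expr_unit(m) != "fpkm") stop("log2_fpkm expects fpkm units", call. = FALSE)
  as_expr(log2(unclass(m) + offset), m, "log2")
}

#' Remove covariate effects per gene
#'
#' Ordinary least squares of each gene on the covariates (intercept always
#' included); returns the residuals. Categorical covariates are expanded to
#' indicator columns with the first level as reference.
#'
#' @param m an [expression_matrix()] in log2 units.
#' @param covariates data frame, one row per sample, aligned with the
#'   columns of `m`.
#' @return An [expression_matrix()] with unit `"residual"`.
#' @export
residualize <- function(m, covariates) {
  if (expr_unit(m) != "log2") stop("residualize expects log2 units", call. = FALSE)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != ncol(m)) {
    stop("covariate rows must align with samples", call. = FALSE)
  }
  X <- if (ncol(covariates) == 0L) {
    matrix(1, nrow(covariates), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    model.matrix(~ ., data = covariates)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop(sprintf("rank-deficient design; collinear columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  res <- t(qr.resid(qx, t(unclass(m))))
  as_expr(res, m, "residual")
}

#' Module meta-feature
#'
#' The per-sample activity proxy of a module: each member gene is z-scored
#' across samples (denominator n-1) and the z-scores are averaged,
#' unweighted, over the module's genes present in the matrix.
#'
#' @param m an [expression_matrix()].
#' @param a a [module_assignment()].
#' @param module_id module name.
#' @return Named numeric vector, one score per sample (mean 0).
#' @export
meta_feature <- function(m, a, module_id) {
  genes <- intersect(module_genes(a, module_id), rownames(m))
  if (length(genes) == 0L) {
    stop(sprintf("module '%s' has no genes in the matrix", module_id), call. = FALSE)
  }
  x <- unclass(m)[genes, , drop = FALSE]
  sds <- apply(x, 1L, sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d zero-variance gene(s) from module '%s'",
                    sum(sds == 0), module_id))
    x <- x[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (nrow(x) == 0L) stop("all module genes have zero variance", call. = FALSE)
  }
  z <- (x - rowMeans(x)) / sds
  colMeans(z)
}

#' Meta-features for every analysis module
#'
#' @param m an [expression_matrix()].
#' @param a a [module_assignment()].
#' @param modules module names; defaults to the full analysis catalog.
#' @return Tibble with `sample_id` and one column per module.
#' @export
module_scores <- function(m, a, modules = module_catalog(a)$module) {
  scores <- purrr::map(setNames(modules, modules),
                       function(k) meta_feature(m, a, k))
  dplyr::bind_cols(tibble(sample_id = colnames(m)), as_tibble(scores))
}
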