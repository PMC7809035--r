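#' Graphical lasso: sparse precision matrix estimation
#'
#' Maximizes `log det(Omega) - tr(S Omega) - lambda * sum_{i != j}
#' |Omega_ij|` by block coordinate descent (diagonal unpenalized). Partial
#' correlations follow as `rho_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`;
#' their zero pattern equals the off-diagonal zero pattern of `Omega`.
#'
#' @param S symmetric sample covariance/correlation matrix (standardize
#'   features first so `S` has unit diagonal).
#' @param lambda penalty, `>= 0`. At 0 the solution is `solve(S)`; above
#'   the largest off-diagonal `|S_ij|` the precision is diagonal.
#' @param tol convergence tolerance on the working covariance (relative to
#'   the mean absolute off-diagonal of `S`).
#' @param maxit maximum outer sweeps.
#' @return Object of class `mglia_glasso`: `Omega`, `W` (its inverse),
#'   `rho`, `lambda`, `kkt`, `iterations`, `converged`.
#' @export
graphical_lasso <- function(S, lambda, tol = 1e-4, maxit = 500L) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8) {
    stop("S must be symmetric (within 1e-8)", call. = FALSE)
  }
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  S <- (S + t(S)) / 2
  fit <- glasso_cd(S, lambda, tol, as.integer(maxit))
  if (!fit$converged) {
    stop(sprintf("graphical lasso did not converge in %d sweeps (kkt residual %.3g)",
                 maxit, fit$kkt), call. = FALSE)
  }
  Omega <- fit$Omega
  dimnames(Omega) <- dimnames(S)
  d <- sqrt(diag(Omega))
  rho <- -Omega / outer(d, d)
  diag(rho) <- 1
  structure(list(Omega = Omega, W = fit$W, rho = rho, lambda = lambda,
                 kkt = fit$kkt, iterations = fit$iterations,
                 converged = fit$converged),
            class = "mglia_glasso")
}

#' @export
print.mglia_glasso <- function(x, ...) {
  p <- nrow(x$Omega)
  ne <- sum(x$Omega[upper.tri(x$Omega)] != 0)
  cat(sprintf("<mglia_glasso> %d nodes, %d edges, lambda = %.4g, kkt = %.2g\n",
              p, ne, x$lambda, x$kkt))
  invisible(x)
}

#' Penalized log-likelihood objective
#'
#' `log det(Omega) - tr(S Omega) - lambda * sum_{i != j} |Omega_ij|`;
#' the quantity [graphical_lasso()] maximizes.
#'
#' @param Omega precision matrix.
#' @param S covariance matrix.
#' @param lambda penalty.
#' @return Scalar objective value.
#' @export
glasso_objective <- function(Omega, S, lambda) {
  off <- sum(abs(Omega)) - sum(abs(diag(Omega)))
  determinant(Omega, logarithm = TRUE)$modulus[1] - sum(S * Omega) - lambda * off
}

#' Default penalty grid
#'
#' 25 log-spaced values in `[0.01, 1]` on the correlation scale.
#' @param n grid size.
#' @param range grid range.
#' @return Decreasing numeric vector (warm-start order).
#' @export
lambda_grid <- function(n = 25L, range = c(0.01, 1)) {
  sort(exp(seq(log(range[1]), log(range[2]), length.out = n)), decreasing = TRUE)
}

# Fit the whole lambda path with warm starts; returns list of fits.
glasso_path <- function(S, lambdas, tol = 1e-4, maxit = 500L) {
  W0 <- NULL; B0 <- NULL
  out <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    fit <- glasso_cd(S, lambdas[i], tol, as.integer(maxit), W0, B0)
    W0 <- fit$W; B0 <- fit$B
    out[[i]] <- fit
  }
  out
}

#' Select the graphical-lasso penalty by repeated cross-validation
#'
#' Repeated k-fold cross-validation of the held-out Gaussian
#' log-likelihood `log det(Omega) - tr(S_test Omega)`. Within each
#' training fold the features are standardized, the penalty path is fitted
#' with warm starts, and each fit is scored on the held-out covariance
#' (computed with the training centering/scaling). The returned penalty is
#' the largest (sparsest) lambda whose mean score is within one standard
#' error of the best mean score; ties break toward larger lambda.
#'
#' @param x numeric matrix or data frame, samples in rows.
#' @param folds number of folds (default 10); `n >= folds` required.
#' @param repeats number of repeats (default 10).
#' @param lambdas penalty grid, default [lambda_grid()].
#' @param one_se apply the one-standard-error rule (default TRUE);
#'   otherwise the mean-optimal lambda is returned.
#' @param tol,maxit passed to the solver.
#' @return List of class `mglia_cv`: `lambda` (selected), `lambda_best`
#'   (mean-optimal), `cv` (tibble lambda, mean, se).
#' @export
select_penalty <- function(x, folds = 10L, repeats = 10L,
                           lambdas = lambda_grid(), one_se = TRUE,
                           tol = 1e-4, maxit = 500L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(lambdas) == 0L) stop("empty lambda grid", call. = FALSE)
  if (n < folds) stop("fewer samples than folds", call. = FALSE)
  lambdas <- sort(lambdas, decreasing = TRUE)
  scores <- matrix(NA_real_, nrow = folds * repeats, ncol = length(lambdas))
  row <- 0L
  for (r in seq_len(repeats)) {
    fold_id <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      test <- fold_id == f
      xtr <- x[!test, , drop = FALSE]
      ctr <- colMeans(xtr)
      str_ <- apply(xtr, 2L, sd)
      if (any(str_ == 0)) stop("a feature is constant within a training fold", call. = FALSE)
      ztr <- scale(xtr, ctr, str_)
      zte <- scale(x[test, , drop = FALSE], ctr, str_)
      Str <- crossprod(ztr) / (nrow(ztr) - 1L)
      Ste <- crossprod(zte) / max(1L, nrow(zte))
      path <- glasso_path(Str, lambdas, tol, maxit)
      row <- row + 1L
      scores[row, ] <- vapply(path, function(fit) {
        determinant(fit$Omega, logarithm = TRUE)$modulus[1] -
          sum(Ste * fit$Omega)
      }, numeric(1))
    }
  }
  mean_s <- colMeans(scores)
  # one-SE band: fold-level spread over sqrt(folds) (the cross-validation
  # convention); fold x repeat scores are dependent, so sqrt(folds*repeats)
  # would understate the uncertainty of the CV estimate
  se_s <- apply(scores, 2L, sd) / sqrt(folds)
  best <- which.max(mean_s)
  lambda_best <- lambdas[best]
  sel <- if (one_se) {
    ok <- mean_s >= mean_s[best] - se_s[best]
    lambdas[which(ok)[1]]     # grid is decreasing: first ok = largest lambda
  } else lambda_best
  structure(list(lambda = sel, lambda_best = lambda_best,
                 cv = tibble(lambda = lambdas, mean = mean_s, se = se_s)),
            class = "mglia_cv")
}

#' Build the module-trait partial-correlation network
#'
#' Assembles module meta-features, visible traits and hidden technical
#' covariates into one feature matrix (complete cases only), standardizes
#' every column, tunes the penalty by repeated tenfold cross-validation,
#' runs the graphical lasso on the full variable set, and reports edges
#' (nonzero partial correlations) among visible nodes only. Hidden
#' covariates condition the network but are suppressed from the edge list.
#'
#' @param scores wide tibble from [module_scores()].
#' @param phen phenotype tibble (`subject_id` matching `sample_id`).
#' @param traits visible trait columns.
#' @param hidden hidden covariate columns (default RIN and PMI).
#' @param folds,repeats,lambdas,one_se passed to [select_penalty()].
#' @param tol,maxit solver controls.
#' @return Object of class `mglia_network`: `edges` (tibble `node_a`,
#'   `node_b`, `partial_correlation`), `rho`, `Omega`, `lambda`, `cv`,
#'   `nodes`, `visible`, `n`, `n_dropped`.
#' @export
build_network <- function(scores, phen,
                          traits = c("amyloid_sqrt", "tau_sqrt",
                                     "decline_slope", "sex", "age_death"),
                          hidden = c("rin", "pmi"),
                          folds = 10L, repeats = 10L,
                          lambdas = lambda_grid(), one_se = TRUE,
                          tol = 1e-4, maxit = 500L) {
  dat <- dplyr::inner_join(as_tibble(phen), scores,
                           by = c(subject_id = "sample_id"))
  mods <- setdiff(names(scores), "sample_id")
  visible <- c(mods, traits)
  if (length(visible) < 3L) stop("need at least 3 visible nodes", call. = FALSE)
  cols <- c(visible, hidden)
  x <- as.matrix(dat[, cols, drop = FALSE])
  cc_ <- complete.cases(x)
  n_dropped <- sum(!cc_)
  if (n_dropped > 0) message(sprintf("dropped %d incomplete row(s)", n_dropped))
  x <- x[cc_, , drop = FALSE]
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    stop(sprintf("constant column(s): %s", paste(cols[sds == 0], collapse = ", ")),
         call. = FALSE)
  }
  z <- scale(x)
  S <- crossprod(z) / (nrow(z) - 1L)
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-10) {
    stop("singular correlation matrix (duplicated node?)", call. = FALSE)
  }
  cv <- select_penalty(x, folds = folds, repeats = repeats, lambdas = lambdas,
                       one_se = one_se, tol = tol, maxit = maxit)
  fit <- graphical_lasso(S, cv$lambda, tol = tol, maxit = maxit)
  rho <- fit$rho
  edges <- which(upper.tri(rho) & rho != 0, arr.ind = TRUE)
  edge_tbl <- tibble(node_a = cols[edges[, 1]], node_b = cols[edges[, 2]],
                     partial_correlation = rho[edges]) |>
    dplyr::filter(.data$node_a %in% visible, .data$node_b %in% visible) |>
    dplyr::arrange(dplyr::desc(abs(.data$partial_correlation)))
  structure(list(edges = edge_tbl, rho = rho, Omega = fit$Omega,
                 lambda = cv$lambda, cv = cv$cv, nodes = cols,
                 visible = visible, n = nrow(x), n_dropped = n_dropped),
            class = "mglia_network")
}

#' @export
print.mglia_network <- function(x, ...) {
  cat(sprintf("<mglia_network> %d visible nodes (%d total), %d edges, lambda = %.4g, n = %d\n",
              length(x$visible), length(x$nodes), nrow(x$edges), x$lambda, x$n))
  print(x$edges, n = 10)
  invisible(x)
}

#' Does the network contain an edge?
#' @param net a `mglia_network`.
#' @param a,b node names.
#' @return TRUE if a nonzero partial correlation links `a` and `b`.
#' @export
has_edge <- function(net, a, b) {
  any((net$edges$node_a == a & net$edges$node_b == b) |
        (net$edges$node_a == b & net$edges$node_b == a))
}

#' @method tidy mglia_network
#' @export
tidy.mglia_network <- function(x, ...) x$edges

#' @method glance mglia_network
#' @export
glance.mglia_network <- function(x, ...) {
  tibble(n_nodes = length(x$visible), n_edges = nrow(x$edges),
         lambda = x$lambda, n_samples = x$n, n_dropped = x$n_dropped)
}

#' @method tidy mglia_glasso
#' @export
tidy.mglia_glasso <- function(x, ...) {
  rho <- x$rho
  idx <- which(upper.tri(rho) & rho != 0, arr.ind = TRUE)
  nm <- rownames(rho) %||% as.character(seq_len(nrow(rho)))
  tibble(node_a = nm[idx[, 1]], node_b = nm[idx[, 2]],
         partial_correlation = rho[idx])
}

#' Plot a partial-correlation network
#'
#' Circle-layout diagram of the visible nodes; edge width scales with the
#' absolute partial correlation, color with its sign.
#'
#' @param object a `mglia_network`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mglia_network
#' @export
autoplot.mglia_network <- function(object, ...) {
  nodes <- object$visible
  k <- length(nodes)
  ang <- seq(0, 2 * pi, length.out = k + 1L)[seq_len(k)]
  pos <- tibble(node = nodes, px = cos(ang), py = sin(ang))
  ed <- object$edges |>
    dplyr::left_join(pos, by = c(node_a = "node")) |>
    dplyr::rename(xa = "px", ya = "py") |>
    dplyr::left_join(pos, by = c(node_b = "node")) |>
    dplyr::rename(xb = "px", yb = "py")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
                   linewidth = abs(.data$partial_correlation),
                   color = .data$partial_correlation > 0)) +
    ggplot2::geom_point(data = pos, ggplot2::aes(.data$px, .data$py), size = 3) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(.data$px * 1.12, .data$py * 1.12,
                                    label = .data$node), size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 2), guide = "none") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
                                labels = c(`TRUE` = "positive", `FALSE` = "negative"),
                                name = "partial corr.") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
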