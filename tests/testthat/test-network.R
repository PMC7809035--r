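test_that("graphical lasso hits its analytic limits", {
  set.seed(1)
  A <- matrix(rnorm(200), 40, 5)
  S <- cor(A)
  # unpenalized limit equals the matrix inverse
  f0 <- graphical_lasso(S, 0, tol = 1e-9)
  expect_lt(max(abs(f0$Omega - solve(S))), 1e-6)
  # full-shrinkage limit is diagonal
  lam_max <- max(abs(S[upper.tri(S)]))
  fmax <- graphical_lasso(S, lam_max + 1e-6)
  expect_true(all(fmax$Omega[upper.tri(fmax$Omega)] == 0))
  expect_equal(diag(fmax$Omega), 1 / diag(S), tolerance = 1e-8)
  # KKT residual small at interior lambda
  fmid <- graphical_lasso(S, 0.1, tol = 1e-6)
  expect_lt(fmid$kkt, 1e-4)
  expect_error(graphical_lasso(S + matrix(rnorm(25, 0, 1e-3), 5), 0.1),
               "symmetric")
  expect_error(graphical_lasso(S, -0.1), ">= 0")
})

test_that("objective matches an independent slow optimizer on 5x5 problems", {
  set.seed(2)
  for (rep in 1:3) {
    A <- matrix(rnorm(40 * 5), 40, 5)
    S <- cor(A)
    for (lambda in c(0.1, 0.3)) {
      fit <- graphical_lasso(S, lambda, tol = 1e-7)
      ref <- pg_glasso(S, lambda, iters = 4000)
      obj_cd <- glasso_objective(fit$Omega, S, lambda)
      obj_pg <- glasso_objective(ref, S, lambda)
      expect_gte(obj_cd, obj_pg - 1e-5)
      expect_lt(abs(obj_cd - obj_pg), 1e-4)
    }
  }
})

test_that("partial correlations respect sign, bound and zero pattern", {
  set.seed(3)
  A <- matrix(rnorm(60 * 6), 60, 6)
  fit <- graphical_lasso(cor(A), 0.05)
  off <- upper.tri(fit$rho)
  expect_true(all(abs(fit$rho) <= 1 + 1e-12))
  expect_equal(diag(fit$rho), rep(1, 6))
  expect_true(all(sign(fit$rho[off]) == -sign(fit$Omega[off])))
  expect_identical(fit$rho[off] == 0, fit$Omega[off] == 0)
})

test_that("edge count is non-increasing in lambda", {
  set.seed(4)
  A <- matrix(rnorm(80 * 7), 80, 7)
  S <- cor(A)
  counts <- vapply(sort(lambda_grid(12)), function(l) {
    O <- graphical_lasso(S, l)$Omega
    sum(O[upper.tri(O)] != 0)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("block-diagonal input gives block-diagonal precision at any lambda", {
  set.seed(5)
  S1 <- cor(matrix(rnorm(50 * 3), 50, 3))
  S2 <- cor(matrix(rnorm(50 * 4), 50, 4))
  S <- as.matrix(Matrix::bdiag(S1, S2))
  for (l in c(0, 0.05, 0.3)) {
    O <- graphical_lasso(S, l, tol = 1e-8)$Omega
    expect_true(all(O[1:3, 4:7] == 0))
    expect_lt(max(abs(O[1:3, 1:3] -
                        graphical_lasso(S1, l, tol = 1e-8)$Omega)), 1e-5)
  }
})

test_that("cross-validated penalty selection behaves at the null and in recovery", {
  # independent features: near-maximal lambda, near-empty graph
  set.seed(6)
  x0 <- matrix(rnorm(200 * 6), 200, 6)
  cv0 <- select_penalty(x0, folds = 5, repeats = 2)
  expect_gte(cv0$lambda, 0.2)
  net0 <- graphical_lasso(cor(x0), cv0$lambda)
  expect_lte(sum(net0$Omega[upper.tri(net0$Omega)] != 0), 2)

  # leave-one-out degenerate config runs
  x_small <- matrix(rnorm(30 * 3), 30, 3)
  expect_s3_class(select_penalty(x_small, folds = 30, repeats = 1,
                                 lambdas = lambda_grid(5)), "mglia_cv")
  expect_error(select_penalty(x_small, folds = 31), "fewer samples")
  expect_error(select_penalty(x_small, lambdas = numeric(0)), "empty lambda")
})

test_that("edges of a sparse 8-node precision are recovered with F1 >= 0.8", {
  # chain-structured truth: partial correlations ~ 0.4 along a path
  p <- 8
  Omega_true <- diag(p)
  for (i in 1:(p - 1)) Omega_true[i, i + 1] <- Omega_true[i + 1, i] <- -0.4
  Sigma <- solve(Omega_true)
  R <- chol(Sigma)
  f1s <- vapply(1:10, function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(400 * p), 400, p) %*% R
    cv <- select_penalty(x, folds = 10, repeats = 3)
    O <- graphical_lasso(cor(x), cv$lambda)$Omega
    est <- O[upper.tri(O)] != 0
    tru <- Omega_true[upper.tri(Omega_true)] != 0
    tp <- sum(est & tru)
    if (tp == 0) return(0)
    prec <- tp / sum(est); rec <- tp / sum(tru)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  expect_gte(mean(f1s), 0.8)
})

test_that("build_network reports visible edges only and rejects bad input", {
  cs <- cohort_scores(3)
  micro <- cs$scores[, c("sample_id", "m5", "m113", "m114", "m115", "m116")]
  set.seed(8)
  net <- build_network(micro, cs$phen, folds = 5, repeats = 2)
  expect_s3_class(net, "mglia_network")
  nodes_in_edges <- unique(c(net$edges$node_a, net$edges$node_b))
  expect_true(all(nodes_in_edges %in% net$visible))
  expect_false(any(c("rin", "pmi") %in% nodes_in_edges))
  expect_true(all(abs(net$edges$partial_correlation) <= 1))

  # tidy/glance interface
  expect_identical(tidy(net), net$edges)
  expect_equal(glance(net)$n_edges, nrow(net$edges))
  expect_s3_class(autoplot(net), "ggplot")

  # duplicated node -> singular correlation matrix
  dup <- dplyr::mutate(micro, m5b = m5)
  expect_error(suppressMessages(build_network(dup, cs$phen, folds = 5,
                                              repeats = 1)),
               "singular|constant")

  # empty hidden set runs the same estimation path
  set.seed(8)
  net2 <- build_network(micro, cs$phen, hidden = character(0),
                        folds = 5, repeats = 2)
  expect_false(any(c("rin", "pmi") %in% net2$nodes))
})
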