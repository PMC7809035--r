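test_that("quantile normalization maps columns to the reference distribution", {
  # hand enumeration: columns (1,2) and (3,4) -> reference (2,3)
  m <- toy_expr(c(1, 2, 3, 4))
  out <- quantile_normalize(m)
  expect_equal(unname(unclass(out)), matrix(c(2, 3, 2, 3), 2),
               ignore_attr = TRUE)

  # identical columns are a fixed point
  m2 <- expression_matrix(matrix(rep(c(5, 1, 3, 2), 3), 4,
                                 dimnames = list(paste0("g", 1:4),
                                                 paste0("s", 1:3))), "fpkm")
  expect_equal(unclass(quantile_normalize(m2)), unclass(m2))

  # row-permutation equivariance
  set.seed(42)
  x <- matrix(runif(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  m3 <- expression_matrix(x, "fpkm")
  perm <- sample(10)
  m3p <- expression_matrix(x[perm, ], "fpkm")
  expect_equal(unclass(quantile_normalize(m3))[perm, ],
               unclass(quantile_normalize(m3p)), ignore_attr = TRUE)

  # idempotence
  q1 <- quantile_normalize(m3)
  expect_equal(unclass(quantile_normalize(q1)), unclass(q1), tolerance = 1e-12)

  # ties get the mean of the reference values at the tied ranks
  mt <- expression_matrix(matrix(c(1, 1, 4, 2, 3, 9), 3,
                                 dimnames = list(c("g1", "g2", "g3"),
                                                 c("s1", "s2"))), "fpkm")
  ref <- rowMeans(apply(unclass(mt), 2, sort)) # (1.5, 2, 6.5)
  out_t <- quantile_normalize(mt)
  expect_equal(unname(unclass(out_t)[, 1]),
               unname(c(mean(ref[1:2]), mean(ref[1:2]), ref[3])))

  expect_error(quantile_normalize(toy_expr(c(1, 2))[, 1, drop = FALSE]),
               "2 samples")
})

test_that("batch adjustment removes location and scale differences", {
  set.seed(7)
  x <- matrix(rnorm(9 * 20, 5), 9, 20,
              dimnames = list(paste0("g", 1:9), paste0("s", 1:20)))
  batch <- rep(c("a", "b"), each = 10)
  shifted <- x
  shifted[, batch == "b"] <- shifted[, batch == "b"] + 3       # shift
  shifted[, batch == "b"] <- (shifted[, batch == "b"] - 8) * 2 + 8  # double spread
  out <- unclass(adjust_batch(expression_matrix(shifted, "log2"), batch))
  for (g in 1:9) {
    ma <- mean(out[g, batch == "a"]); mb <- mean(out[g, batch == "b"])
    expect_equal(ma, mb, tolerance = 1e-10)
    expect_equal(sd(out[g, batch == "a"]), sd(out[g, batch == "b"]),
                 tolerance = 1e-8)
  }
  expect_error(adjust_batch(expression_matrix(x, "log2"), rep("a", 20)),
               "2 batches")
  expect_error(adjust_batch(expression_matrix(x, "log2"),
                            c(rep("a", 18), "b", "b")),
               "fewer than 3")
})

test_that("gene filter uses a strict mean threshold", {
  m <- toy_expr(c(1, 1, 1, 1))            # gene means exactly 1
  expect_warning(out <- filter_genes(m), "no gene")
  expect_equal(nrow(out), 0L)

  m2 <- toy_expr(c(0, 1.5, 2.5, 1.5))     # means 1.25 and 1.5
  expect_equal(rownames(filter_genes(m2)), c("g1", "g2"))

  expect_warning(out0 <- filter_genes(toy_expr(rep(0, 4))), "no gene")
  expect_equal(nrow(out0), 0L)
})

test_that("residualization is an exact projection orthogonal to the design", {
  set.seed(11)
  n <- 30
  cov <- data.frame(age = rnorm(n, 85, 5), sex = rbinom(n, 1, 0.5))
  x <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
  x[1, ] <- 2 * cov$age                       # exactly explained gene
  m <- expression_matrix(x, "log2")
  res <- residualize(m, cov)
  expect_lt(max(abs(unclass(res)[1, ])), 1e-10)
  for (g in 2:5) {
    expect_lt(abs(cor(unclass(res)[g, ], cov$age)), 1e-8)
    expect_lt(abs(cor(unclass(res)[g, ], cov$sex)), 1e-8)
  }
  # intercept only -> centered input
  res0 <- residualize(m, data.frame(row.names = seq_len(n))[, FALSE, drop = FALSE])
  expect_equal(unname(unclass(res0)), unname(x - rowMeans(x)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # projection: applying twice changes nothing
  res2 <- residualize(expression_matrix(unclass(res), "log2"), cov)
  expect_equal(unclass(res2), unclass(res), tolerance = 1e-10)
  # rank-deficient design errors and names the collinear column
  cov_bad <- cbind(cov, age2 = 2 * cov$age)
  expect_error(residualize(m, cov_bad), "age2")
})

test_that("meta-feature is the mean of per-gene z-scores", {
  x <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8,
                5, 1, 4, 2), 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  m <- expression_matrix(x, "residual")
  a <- module_assignment(tibble::tibble(gene = c("g1", "g2", "g3"),
                                        module = c("mA", "mA", "mA")),
                         min_size = 1)
  zs <- t(apply(x, 1, function(v) (v - mean(v)) / sd(v)))
  expect_equal(unname(meta_feature(m, a, "mA")), unname(colMeans(zs)))

  # single-gene module equals that gene's z-score
  a1 <- module_assignment(tibble::tibble(gene = "g3", module = "m1"), min_size = 1)
  expect_equal(unname(meta_feature(m, a1, "m1")), unname(zs[3, ]))

  # two perfectly correlated genes equal either z-score (g2 = 2 * g1)
  a2 <- module_assignment(tibble::tibble(gene = c("g1", "g2"), module = "m2"),
                          min_size = 1)
  expect_equal(unname(meta_feature(m, a2, "m2")), unname(zs[1, ]))

  # invariant to per-gene affine rescaling
  x2 <- x * c(3, 0.5, 10) + c(-2, 7, 100)
  m2 <- expression_matrix(x2, "residual")
  expect_equal(meta_feature(m2, a, "mA"), meta_feature(m, a, "mA"),
               tolerance = 1e-12)

  # zero-variance gene excluded with warning
  x3 <- x; x3[2, ] <- 5
  expect_warning(mf <- meta_feature(expression_matrix(x3, "residual"), a, "mA"),
                 "zero-variance")
  expect_equal(unname(mf), unname(colMeans(zs[c(1, 3), ])))

  expect_error(meta_feature(m, a, "missing_module"), "not found")
})
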