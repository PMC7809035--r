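test_that("cpm rescales every cell to one million", {
  counts <- Matrix::Matrix(matrix(c(1, 1, 2,
                                    0, 0, 0,
                                    10, 0, 30), 3, byrow = FALSE,
                                  dimnames = list(paste0("g", 1:3),
                                                  paste0("c", 1:3))),
                           sparse = TRUE)
  # note: columns are cells; cell 2 here is all zero
  expect_warning(out <- cpm(counts), "zero total")
  expect_equal(ncol(out), 2L)
  expect_equal(as.numeric(Matrix::colSums(out)), rep(1e6, 2), tolerance = 1e-6)
  # cell (1, 1, 2) -> (250000, 250000, 500000)
  expect_equal(as.numeric(out[, "c1"]), c(250000, 250000, 500000))

  # doubling a cell's counts leaves its cpm unchanged
  expect_equal(as.numeric(cpm(counts[, c(1, 3)] * 2)[, 1]),
               as.numeric(out[, 1]))
  expect_error(cpm(counts - 1), "nonnegative")
})

test_that("cell module scores average detected module genes only", {
  cpm_mat <- matrix(c(10, 20, 30,
                      40, 50, 60,
                      0, 1, 2), 3, byrow = TRUE,
                    dimnames = list(c("g1", "g2", "g3"), paste0("c", 1:3)))
  a <- module_assignment(tibble::tibble(gene = c("g1", "g2", "gX"),
                                        module = c("m1", "m2", "m2")),
                         min_size = 1)
  # single-gene module equals that gene's cpm
  expect_equal(unname(cell_module_score(cpm_mat, a, "m1")), c(10, 20, 30))
  # gX is not detected: m2 score is just g2
  expect_equal(unname(cell_module_score(cpm_mat, a, "m2")), c(40, 50, 60))
  # adding an unrelated gene to the matrix changes nothing
  bigger <- rbind(cpm_mat, gZ = c(99, 99, 99))
  expect_equal(cell_module_score(bigger, a, "m1"),
               cell_module_score(cpm_mat, a, "m1"))
  a_absent <- module_assignment(tibble::tibble(gene = "gQ", module = "mq"),
                                min_size = 1)
  expect_error(cell_module_score(cpm_mat, a_absent, "mq"), "present")
})

test_that("cluster proportions sum to one and handle empty subjects", {
  meta <- tibble::tibble(
    cell_id = paste0("c", 1:25),
    subject_id = c(rep("s1", 20), rep("s2", 4), "s3"),
    cluster = c(rep("Mic1", 10), rep("Mic4", 10),
                "Mic1", "Mic2", "Mic3", "Mic4",
                "Oligo"))
  expect_warning(props <- cluster_proportions(meta), "no cell")
  expect_equal(nrow(props), 2L)                       # s3 has no Mic cell
  s1 <- props[props$subject_id == "s1", -1]
  expect_equal(unlist(s1), c(Mic1 = 0.5, Mic2 = 0, Mic3 = 0, Mic4 = 0.5))
  expect_equal(rowSums(props[, -1]), rep(1, 2), tolerance = 1e-12)

  # duplicating every cell of a subject changes nothing
  dup <- dplyr::bind_rows(meta, dplyr::mutate(meta[meta$subject_id == "s1", ],
                                              cell_id = paste0(cell_id, "b")))
  expect_warning(props_dup <- cluster_proportions(dup), "no cell")
  expect_equal(props_dup, props)

  # relabeling cluster order permutes columns identically
  relab <- dplyr::mutate(meta, cluster = dplyr::recode(cluster,
                                                       Mic1 = "Mic4", Mic4 = "Mic1"))
  expect_warning(props_r <- cluster_proportions(relab), "no cell")
  expect_equal(props_r$Mic4, props$Mic1)
})

test_that("module scores are invariant to per-cell sequencing depth", {
  tr <- synthetic_truth(n_subjects = 30, seed = 3)
  sn <- generate_sn_counts(tr, cells = 200)
  a <- module_assignment(purrr::map_dfr(names(tr$module_defs), function(k) {
    tibble::tibble(gene = tr$module_defs[[k]]$genes, module = k)
  }))
  base <- cell_module_score(cpm(sn$counts), a, "m5")
  depth <- sample(c(1, 2, 5), ncol(sn$counts), replace = TRUE)
  rescaled <- sn$counts %*% Matrix::Diagonal(x = depth)
  colnames(rescaled) <- colnames(sn$counts)
  expect_equal(cell_module_score(cpm(rescaled), a, "m5"), base,
               tolerance = 1e-10)
})

test_that("robust proportion-trait association resists an outlier subject", {
  set.seed(19)
  n <- 48
  tau <- rnorm(n, 1.8, 0.7)
  prop <- 0.25 + 0.08 * scale(tau)[, 1] + rnorm(n, 0, 0.03)
  phen <- tibble::tibble(subject_id = paste0("s", 1:n), tau_sqrt = tau,
                         sex = rbinom(n, 1, 0.5), pmi = rnorm(n, 7, 2))
  props <- tibble::tibble(subject_id = phen$subject_id, Mic1 = prop)
  clean <- proportion_trait_assoc(props, "Mic1", phen)
  expect_gt(clean$beta, 0)
  expect_lt(clean$p, 0.05)

  # contaminate one subject with an extreme proportion
  dirty <- props
  dirty$Mic1[which.min(tau)] <- 0.95
  rob <- proportion_trait_assoc(dirty, "Mic1", phen)
  ols <- summary(lm(tau_sqrt ~ Mic1 + sex + pmi,
                    data = dplyr::inner_join(dirty, phen, by = "subject_id")))
  beta_ols <- ols$coefficients["Mic1", 1]
  expect_lt(abs(rob$beta - clean$beta), abs(beta_ols - clean$beta))

  expect_error(proportion_trait_assoc(dplyr::mutate(props, Mic1 = 0.3),
                                      "Mic1", phen), "constant")
  expect_error(proportion_trait_assoc(props[1:5, ], "Mic1", phen[1:5, ]),
               "10 subjects")
})

test_that("a zero tau effect leaves cluster proportions unassociated", {
  ps <- vapply(1:20, function(seed) {
    tr <- synthetic_truth(n_subjects = 30, seed = seed + 900)
    sn <- generate_sn_counts(tr, cells = 30 * 60, tau_effect = 0)
    suppressWarnings(
      proportion_trait_assoc(cluster_proportions(sn$meta), "Mic1",
                             sn$phenotypes)$p)
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.2)
  expect_gte(stats::ks.test(ps, "punif")$p.value, 0.01)
})
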