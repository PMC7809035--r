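test_that("cohort generation is deterministic and validates its config", {
  tr <- synthetic_truth(n_subjects = 40, seed = 5)
  c1 <- generate_cohort(tr)
  c2 <- generate_cohort(tr)
  expect_identical(unclass(c1$expression), unclass(c2$expression))
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_true(all(unclass(c1$expression) > 0))
  expect_true(all(c1$phenotypes$sex %in% 0:1))
  expect_true(all(c1$phenotypes$amyloid_sqrt >= 0))
  # sqrt-scale and raw scale stored consistently
  expect_equal(c1$phenotypes$amyloid, c1$phenotypes$amyloid_sqrt^2)

  expect_error(generate_cohort(synthetic_truth(n_subjects = 40,
                                               genes_per_module = 10)),
               "smaller than 20")
  expect_error(generate_cohort(synthetic_truth(n_subjects = 10)), ">= 30")
  tr_bad <- synthetic_truth(n_subjects = 40)
  tr_bad$noise_sds["gene"] <- 0
  expect_error(generate_cohort(tr_bad), "non-positive")
})

test_that("a named stream is insensitive to other outputs being generated", {
  tr <- synthetic_truth(n_subjects = 40, seed = 9)
  lc_alone <- generate_longitudinal(tr, visits = 4, resid_sd = 0.2)
  invisible(generate_cohort(tr))  # draws from other streams
  lc_after <- generate_longitudinal(tr, visits = 4, resid_sd = 0.2)
  expect_identical(lc_alone$score, lc_after$score)
})

test_that("reference profiles plant recoverable fold-change signatures", {
  tr <- synthetic_truth(n_subjects = 40, seed = 5)
  prof <- generate_reference_profiles(tr)
  bulk <- rowMeans(prof$bulk)
  mic <- rowMeans(prof$microglia)
  planted <- tr$signature_spec$microglia
  # planted genes: mic mean >= 4x bulk and > 1
  expect_true(all(mic[planted] >= 4 * bulk[planted]))
  expect_true(all(mic[planted] > 1))
  # exact round-trip through the derivation rule, vs bulk
  rec <- derive_enriched_set(mic, list(bulk), name = "mic")
  expect_setequal(rec$genes, planted)
  # and vs the other cell-type profiles
  rec2 <- derive_enriched_set(mic, list(rowMeans(prof$astrocyte),
                                        rowMeans(prof$neuron)), name = "mic2")
  expect_setequal(rec2$genes, planted)
  # a gene planted in no signature is excluded from every recovered set
  free <- setdiff(tr$gene_ids, unlist(tr$signature_spec))[1]
  for (ct in c("microglia", "astrocyte", "neuron")) {
    r <- derive_enriched_set(rowMeans(prof[[ct]]), list(bulk))
    expect_false(free %in% r$genes)
  }
  tr_empty <- tr
  tr_empty$signature_spec$microglia <- character(0)
  expect_error(generate_reference_profiles(tr_empty), "empty signature")
})

test_that("longitudinal generator stores true slopes and rejects short designs", {
  tr <- synthetic_truth(n_subjects = 40, seed = 5)
  lc <- generate_longitudinal(tr, visits = 5, resid_sd = 0.1)
  expect_equal(nrow(lc), 40 * 5)
  ts <- attr(lc, "true_slopes")
  expect_equal(ts$slope, generate_cohort(tr)$phenotypes$decline_slope)
  expect_error(generate_longitudinal(tr, visits = 2), "3 visits")
})

test_that("GWAS generator plants recoverable AD genes", {
  tr <- synthetic_truth(n_subjects = 40, seed = 5)
  gw <- generate_gwas_summary(tr)
  fl <- gwas_gene_flags(gw$intervals, gw$probes)
  expect_true(all(gw$ad_genes %in% fl$genes))   # recovery is a superset
  expect_error(generate_gwas_summary(tr, probes_per_gene = 0), ">= 1")
})

test_that("cell-image generator builds one component per planted cell", {
  tr <- synthetic_truth(n_subjects = 40, seed = 5)
  img <- generate_cell_images(tr, cells_per_subject = 12, n_subjects = 2)
  for (mask in img$masks) {
    expect_true(all(mask %in% c(0L, 1L)))
    lab <- mglianet:::label_components8(mask)
    expect_equal(max(lab), 12)
  }
  for (ch in img$channels) {
    expect_true(all(ch$pan >= 0 & ch$pan <= 1))
    expect_true(all(ch$marker >= 0 & ch$marker <= 1))
  }
  expect_error(generate_cell_images(tr, cells_per_subject = 5), ">= 10")
  expect_error(generate_cell_images(tr, cells_per_subject = 20000,
                                    max_dim = 512),
               "packing")
})

test_that("single-nucleus generator produces integer counts in 4 clusters", {
  tr <- synthetic_truth(n_subjects = 30, seed = 3)
  sn <- generate_sn_counts(tr, cells = 30 * 40)
  expect_true(all(sn$counts@x >= 0))
  expect_true(all(sn$counts@x == round(sn$counts@x)))
  expect_setequal(unique(sn$meta$cluster), paste0("Mic", 1:4))
  expect_equal(ncol(sn$counts), nrow(sn$meta))
  # cluster 1 cells carry the elevated m5 program (construction check)
  cp <- cpm(sn$counts)
  ma <- module_assignment(purrr::map_dfr(names(tr$module_defs), function(k) {
    tibble::tibble(gene = tr$module_defs[[k]]$genes, module = k)
  }))
  s5 <- cell_module_score(cp, ma, "m5")
  means <- tapply(s5[sn$meta$cell_id], sn$meta$cluster, mean)
  expect_equal(names(which.max(means)), "Mic1")
  expect_error(generate_sn_counts(tr, cells = 10), "4 x n_subjects")
  expect_error(generate_sn_counts(tr, n_clusters = 3), "at least 4")
})
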