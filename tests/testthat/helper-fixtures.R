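# Shared fixtures; heavyweight cohorts are cached so several test files can
# reuse the same simulated data.

.fixture_cache <- new.env(parent = emptyenv())

# Cohort processed to module meta-features (technical-covariate
# residualization; age/sex remain in downstream models).
cohort_scores <- function(seed, n_subjects = 400L, genes_per_module = 30L,
                          causal_coeffs = NULL) {
  key <- paste("cs", seed, n_subjects, genes_per_module,
               paste(causal_coeffs, collapse = "_"), sep = "|")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  tr <- synthetic_truth(n_subjects = n_subjects,
                        genes_per_module = genes_per_module,
                        causal_coeffs = causal_coeffs, seed = seed)
  co <- generate_cohort(tr)
  resid <- residualize(log2_fpkm(filter_genes(quantile_normalize(co$expression))),
                       co$phenotypes[, c("study", "rin", "pmi")])
  out <- list(truth = tr,
              phen = co$phenotypes,
              latents = co$latents,
              modules = co$modules,
              scores = module_scores(resid, co$modules))
  .fixture_cache[[key]] <- out
  out
}

null_coeffs <- function() {
  c(sex_m114 = 0, m114_amyloid = 0, m113_amyloid = 0, m5_tau = 0,
    tau_cogdec = 0, amyloid_cogdec = 0, age_m116 = 0)
}

# tiny deterministic expression matrix for preprocessing tests
toy_expr <- function(values, unit = "fpkm") {
  m <- matrix(values, nrow = length(values) / 2)
  dimnames(m) <- list(paste0("g", seq_len(nrow(m))),
                      paste0("s", seq_len(ncol(m))))
  expression_matrix(m, unit)
}

# mask with blobs at given pixel coordinate sets (1-based rows/cols)
toy_mask <- function(nr, nc, blobs) {
  m <- matrix(0L, nr, nc)
  for (b in blobs) m[b] <- 1L
  m
}

# pixel index matrix of a filled rectangle (1-based)
rect_px <- function(r0, r1, c0, c1) {
  as.matrix(expand.grid(row = r0:r1, col = c0:c1))
}
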