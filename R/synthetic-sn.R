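#' Generate a synthetic single-nucleus count matrix
#'
#' Emulates microglial nuclei from the cohort's subjects falling into four
#' transcriptional clusters. Cluster 1 cells have the means of all m5
#' genes multiplied by `m5_factor` (an activated-microglia state), and a
#' subject's probability of contributing cluster-1 cells rises with that
#' subject's latent tau (logistic link, slope `tau_effect`). Counts follow
#' a Poisson-lognormal scheme: per-cell lognormal depth jitter on top of
#' lognormal gene baselines, then Poisson sampling.
#'
#' @param truth a [synthetic_truth()].
#' @param cells total number of cells (>= 4 x n_subjects).
#' @param n_clusters number of microglial clusters (must be >= 4; cluster
#'   1 is the activated state).
#' @param m5_factor mean multiplier of m5 genes in cluster 1 (default 2).
#' @param tau_effect logit-scale slope of cluster-1 membership on latent
#'   tau; 0 gives the null generator.
#' @return List of class `mglia_sn`: `counts` (sparse genes x cells
#'   integer matrix), `meta` (cell_id, subject_id, cluster), `phenotypes`
#'   (the cohort phenotype table for the same truth).
#' @export
generate_sn_counts <- function(truth, cells = NULL, n_clusters = 4L,
                               m5_factor = 2, tau_effect = 0.6) {
  validate_truth(truth)
  if (n_clusters < 4L) stop("need at least 4 microglial clusters", call. = FALSE)
  n <- truth$n_subjects
  if (is.null(cells)) cells <- 150L * n
  if (cells < 4L * n) stop("need cells >= 4 x n_subjects", call. = FALSE)
  subj <- gen_subjects(truth)
  tau_lat <- subj$latents$tau
  genes <- truth$gene_ids
  m5_genes <- truth$module_defs$m5$genes
  marker_sets <- list(NULL, truth$module_defs$m1$genes,
                      truth$module_defs$m2$genes, truth$module_defs$m3$genes)
  out <- with_stream(truth$seed, "snrna", {
    base <- setNames(exp(rnorm(length(genes), log(0.3), 1)), genes)
    cell_subject <- sample.int(n, cells, replace = TRUE)
    p1 <- plogis(qlogis(1 / n_clusters) + tau_effect * tau_lat)
    cl <- integer(cells)
    for (i in seq_len(cells)) {
      s <- cell_subject[i]
      probs <- c(p1[s], rep((1 - p1[s]) / (n_clusters - 1), n_clusters - 1L))
      cl[i] <- sample.int(n_clusters, 1L, prob = probs)
    }
    depth <- exp(rnorm(cells, 0, 0.3))
    lam <- matrix(base, nrow = length(genes), ncol = cells,
                  dimnames = list(genes, sprintf("c%05d", seq_len(cells))))
    lam <- sweep(lam, 2L, depth, "*")
    lam[m5_genes, cl == 1L] <- lam[m5_genes, cl == 1L] * m5_factor
    for (j in 2:min(n_clusters, 4L)) {
      mk <- marker_sets[[j]]
      if (!is.null(mk)) lam[mk, cl == j] <- lam[mk, cl == j] * 1.8
    }
    counts <- matrix(rpois(length(lam), lam), nrow = nrow(lam),
                     dimnames = dimnames(lam))
    list(counts = counts, cl = cl, cell_subject = cell_subject)
  })
  meta <- tibble(cell_id = colnames(out$counts),
                 subject_id = subj$phenotypes$subject_id[out$cell_subject],
                 cluster = paste0("Mic", out$cl))
  structure(list(counts = Matrix::Matrix(out$counts, sparse = TRUE),
                 meta = meta,
                 phenotypes = subj$phenotypes),
            class = "mglia_sn")
}
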