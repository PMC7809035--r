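#' Counts-per-million normalization of single-nucleus counts
#'
#' Scales every cell (column) so its values sum to one million. Cells with
#' zero total counts are dropped with a warning.
#'
#' @param counts genes x cells matrix (dense or sparse) of nonnegative
#'   integer counts.
#' @return A genes x cells matrix of CPM values; every retained column
#'   sums to 1e6.
#' @export
cpm <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  tot <- Matrix::colSums(counts)
  drop <- tot == 0
  if (any(drop)) {
    warning(sprintf("dropping %d cell(s) with zero total counts", sum(drop)))
    counts <- counts[, !drop, drop = FALSE]
    tot <- tot[!drop]
  }
  out <- counts %*% Matrix::Diagonal(x = 1e6 / tot)
  colnames(out) <- colnames(counts)
  if (!isS4(out)) attr(out, "n_dropped") <- sum(drop)
  out
}

#' Per-cell module score
#'
#' Unweighted mean CPM over the module's genes present in the matrix.
#' Unlike the bulk meta-feature, no z-scoring is applied: CPM values are
#' already on a per-cell relative scale, and z-scoring across sparse
#' single-nucleus profiles would be dominated by dropout. Only detected
#' (present) module genes enter the mean.
#'
#' @param cpm_mat genes x cells CPM matrix from [cpm()].
#' @param a a [module_assignment()].
#' @param module_id module name.
#' @return Named numeric vector, one score per cell.
#' @export
cell_module_score <- function(cpm_mat, a, module_id) {
  genes <- intersect(module_genes(a, module_id), rownames(cpm_mat))
  if (length(genes) == 0L) {
    stop(sprintf("no gene of module '%s' is present in the matrix", module_id),
         call. = FALSE)
  }
  setNames(as.numeric(Matrix::colMeans(cpm_mat[genes, , drop = FALSE])),
           colnames(cpm_mat))
}

#' Per-subject cluster proportions
#'
#' Restricts the cell metadata to the given cluster labels (the four
#' microglial clusters) and computes, per subject, the proportion of cells
#' in each cluster relative to the sum over those clusters. Subjects
#' without any cell in the subset are excluded with a warning.
#'
#' @param meta tibble with columns `cell_id`, `subject_id`, `cluster`.
#' @param clusters cluster labels to keep (default the four `Mic`
#'   clusters).
#' @return Wide tibble: `subject_id` plus one proportion column per
#'   cluster (rows sum to 1).
#' @export
cluster_proportions <- function(meta,
                                clusters = c("Mic1", "Mic2", "Mic3", "Mic4")) {
  meta <- as_tibble(meta)
  sub <- meta[meta$cluster %in% clusters, , drop = FALSE]
  lost <- setdiff(unique(meta$subject_id), unique(sub$subject_id))
  if (length(lost) > 0L) {
    warning(sprintf("excluding %d subject(s) with no cell in the cluster subset",
                    length(lost)))
  }
  sub |>
    dplyr::count(.data$subject_id, .data$cluster) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("subject_id", "cluster", "prop") |>
    tidyr::pivot_wider(names_from = "cluster", values_from = "prop",
                       values_fill = 0) |>
    dplyr::select(dplyr::all_of(c("subject_id",
                                  intersect(clusters, unique(sub$cluster)))))
}

#' Associate a cluster proportion with a trait by robust regression
#'
#' Huber M-estimated linear model (tuning constant 1.345, 95% Gaussian
#' efficiency) of the trait on one cluster's per-subject proportion with
#' sex and PMI as default covariates; robust standard errors from the
#' M-estimator, two-sided p from the t distribution.
#'
#' @param props wide tibble from [cluster_proportions()].
#' @param cluster which cluster's proportion to test (e.g. `"Mic1"`).
#' @param phen phenotype tibble with `subject_id`.
#' @param trait outcome column (default `"tau_sqrt"`).
#' @param covariates adjustment columns (default sex and PMI).
#' @return One-row tibble: `predictor`, `trait`, `beta`, `se`, `t`, `p`,
#'   `n`, `covariates`, `model`.
#' @export
proportion_trait_assoc <- function(props, cluster, phen, trait = "tau_sqrt",
                                   covariates = c("sex", "pmi")) {
  dat <- dplyr::inner_join(props, as_tibble(phen), by = "subject_id")
  if (nrow(dat) < 10L) stop("need >= 10 subjects", call. = FALSE)
  x <- dat[[cluster]]
  if (sd(x) == 0) stop("constant cluster proportions", call. = FALSE)
  df_ <- dplyr::bind_cols(tibble(.y = dat[[trait]], .x = x),
                          dat[, covariates, drop = FALSE])
  df_ <- df_[complete.cases(df_), , drop = FALSE]
  fit <- MASS::rlm(.y ~ ., data = df_, k = 1.345, maxit = 100)
  cf <- summary(fit)$coefficients[".x", ]
  df_res <- nrow(df_) - length(coef(fit))
  tibble(predictor = paste0("prop_", cluster), trait = trait,
         beta = cf[["Value"]], se = cf[["Std. Error"]],
         t = cf[["t value"]],
         p = 2 * pt(-abs(cf[["t value"]]), df_res),
         n = nrow(df_),
         covariates = paste(covariates, collapse = "+"),
         model = "rlm_huber")
}
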