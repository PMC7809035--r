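#' Ground truth for a synthetic aging-cohort simulation
#'
#' Defines every knob of the synthetic cohort: the gene-to-module partition
#' with per-gene loadings, the standardized causal path coefficients of the
#' two pathology chains (sex -> m114 -> amyloid -> cognitive decline and
#' m5 -> tau -> cognitive decline, plus age -> m116), per-gene noise, the
#' cell-type signature plan, and the root seed. All downstream generators
#' derive named child RNG streams from the root seed, so adding an output
#' never perturbs existing ones.
#'
#' Default path coefficients (standardized scale): sex->m114 = 0.30,
#' m114->amyloid = 0.30, m113->amyloid = 0.25, m5->tau = 0.30,
#' tau->cogdec = -0.35, amyloid->cogdec = -0.25, age->m116 = 0.30. Sex is
#' coded 0 = male, 1 = female, and women have higher m5/m114 activity.
#'
#' @param n_subjects number of subjects (>= 30 for cohort generation).
#' @param genes_per_module genes in each module (>= 20).
#' @param n_genes total genes; genes beyond the module partition stay
#'   unassigned.
#' @param causal_coeffs named numeric vector of standardized path
#'   coefficients; defaults above. Setting all to zero gives the null
#'   generator.
#' @param noise_sds named numeric: `gene` is the per-gene log2 residual sd.
#' @param seed integer root seed.
#' @return A `synthetic_truth` object (list).
#' @export
synthetic_truth <- function(n_subjects = 400L,
                            genes_per_module = 30L,
                            n_genes = NULL,
                            causal_coeffs = NULL,
                            noise_sds = c(gene = 0.6),
                            seed = 1L) {
  default_coeffs <- c(sex_m114 = 0.30, m114_amyloid = 0.30,
                      m113_amyloid = 0.25, m5_tau = 0.30,
                      tau_cogdec = -0.35, amyloid_cogdec = -0.25,
                      age_m116 = 0.30)
  if (is.null(causal_coeffs)) {
    causal_coeffs <- default_coeffs
  } else {
    stopifnot(!is.null(names(causal_coeffs)))
    cc <- default_coeffs
    cc[names(causal_coeffs)] <- causal_coeffs
    causal_coeffs <- cc
  }
  if (any(noise_sds < 0)) stop("noise sds must be >= 0", call. = FALSE)
  modules <- c("m5", "m113", "m114", "m115", "m116",   # microglial
               "m21", "m107", "m110", "m112",          # neuron/astro/oligo/endo
               "m1", "m2", "m3")                       # background
  n_assigned <- length(modules) * genes_per_module
  if (is.null(n_genes)) n_genes <- n_assigned + 40L
  if (n_genes < n_assigned) stop("n_genes smaller than the module partition", call. = FALSE)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  idx <- split(gene_ids[seq_len(n_assigned)],
               rep(modules, each = genes_per_module))
  loadings <- with_stream(seed, "loadings", {
    lapply(idx, function(g) setNames(runif(length(g), 0.5, 1), g))
  })
  module_defs <- lapply(setNames(modules, modules), function(k) {
    list(genes = idx[[k]], loadings = loadings[[k]])
  })
  gm <- function(k, i) module_defs[[k]]$genes[i]
  # half of each microglial module is planted in the microglia signature
  # (all of m116, the canonical pan-microglial module); m113/m115 share
  # further genes with the astrocyte signature, mirroring their mixed
  # astro/myeloid character
  half <- seq_len(ceiling(genes_per_module / 2))
  shared <- seq(max(half) + 1L, min(genes_per_module, max(half) + 12L))
  signature_spec <- list(
    microglia = c(module_defs$m116$genes, gm("m5", half), gm("m114", half),
                  gm("m113", half), gm("m115", half)),
    astrocyte = c(module_defs$m107$genes, gm("m113", shared),
                  gm("m115", shared)),
    neuron = module_defs$m21$genes)
  structure(list(
    module_defs = module_defs,
    causal_coeffs = causal_coeffs,
    noise_sds = noise_sds,
    n_subjects = as.integer(n_subjects),
    n_genes = as.integer(n_genes),
    gene_ids = gene_ids,
    signature_spec = signature_spec,
    ad_genes = c(gm("m116", 1:8), gm("m5", 1:4)),
    seed = as.integer(seed)
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_truth> %d subjects, %d genes, %d modules, ",
                     "seed %d\n"),
              x$n_subjects, x$n_genes, length(x$module_defs), x$seed))
  invisible(x)
}

validate_truth <- function(truth, min_module = 20L) {
  if (!inherits(truth, "synthetic_truth")) stop("not a synthetic_truth", call. = FALSE)
  sizes <- vapply(truth$module_defs, function(m) length(m$genes), integer(1))
  if (any(sizes < min_module)) {
    stop(sprintf("invalid config: module(s) smaller than %d genes: %s",
                 min_module,
                 paste(names(sizes)[sizes < min_module], collapse = ", ")),
         call. = FALSE)
  }
  allg <- unlist(lapply(truth$module_defs, function(m) m$genes))
  if (anyDuplicated(allg)) stop("invalid config: module gene lists overlap", call. = FALSE)
  sig <- unlist(truth$signature_spec)
  if (anyDuplicated(sig)) {
    stop("invalid config: a signature gene belongs to more than one cell type",
         call. = FALSE)
  }
  if (!is.numeric(truth$noise_sds["gene"]) || truth$noise_sds[["gene"]] <= 0) {
    stop("invalid config: non-positive gene noise variance", call. = FALSE)
  }
  invisible(truth)
}

# population-scale standardization used throughout the generator
zs_age <- function(age) (age - 88) / 6
zs_sex <- function(sex) (sex - 0.5) / 0.5
zs_edu <- function(edu) (edu - 16) / 3

# Shared subject-level draws: covariates, latent module activities and
# latent traits. Used by generate_cohort, generate_longitudinal and
# generate_sn_counts so their ground truths agree for identical `truth`.
gen_subjects <- function(truth) {
  n <- truth$n_subjects
  cc <- truth$causal_coeffs
  cov <- with_stream(truth$seed, "subjects", {
    tibble(
      subject_id = sprintf("s%03d", seq_len(n)),
      age_death = pmin(pmax(rnorm(n, 88, 6), 70), 105),
      sex = rbinom(n, 1L, 0.5),
      study = rbinom(n, 1L, 0.5),
      rin = pmin(pmax(rnorm(n, 7, 1), 4), 10),
      pmi = pmax(rnorm(n, 7, 3), 1),
      education = round(pmin(pmax(rnorm(n, 16, 3), 8), 25))
    )
  })
  resid_sd <- function(...) sqrt(max(0, 1 - sum(c(...)^2)))
  lat <- with_stream(truth$seed, "latents", {
    e <- function() rnorm(n)
    act <- list(
      m114 = cc["sex_m114"] * zs_sex(cov$sex) + resid_sd(cc["sex_m114"]) * e(),
      m116 = cc["age_m116"] * zs_age(cov$age_death) + resid_sd(cc["age_m116"]) * e()
    )
    for (k in setdiff(names(truth$module_defs), names(act))) act[[k]] <- e()
    amyloid <- cc["m114_amyloid"] * act$m114 + cc["m113_amyloid"] * act$m113 +
      resid_sd(cc["m114_amyloid"], cc["m113_amyloid"]) * e()
    tau <- cc["m5_tau"] * act$m5 + resid_sd(cc["m5_tau"]) * e()
    cogdec <- cc["tau_cogdec"] * tau + cc["amyloid_cogdec"] * amyloid +
      resid_sd(cc["tau_cogdec"], cc["amyloid_cogdec"]) * e()
    np <- 0.6 * amyloid + 0.3 * tau + resid_sd(0.6, 0.3) * e()
    nft <- 0.6 * tau + 0.3 * amyloid + resid_sd(0.6, 0.3) * e()
    dp <- 0.5 * amyloid + resid_sd(0.5) * e()
    c(act, list(amyloid = amyloid, tau = tau, cogdec = cogdec,
                np = np, nft = nft, dp = dp))
  })
  amyloid_sqrt <- pmax(0, 2.0 + 0.8 * lat$amyloid)
  tau_sqrt <- pmax(0, 1.8 + 0.7 * lat$tau)
  phen <- cov |>
    dplyr::mutate(
      amyloid_sqrt = amyloid_sqrt,
      tau_sqrt = tau_sqrt,
      amyloid = amyloid_sqrt^2,
      tau = tau_sqrt^2,
      np = 0.7 + 0.5 * lat$np,
      nft = 0.7 + 0.5 * lat$nft,
      dp = 0.7 + 0.5 * lat$dp,
      decline_slope = -0.05 + 0.10 * lat$cogdec,
      braak = pmin(6L, pmax(0L, as.integer(round(3 + 1.4 * lat$tau)))),
      cerad = pmin(4L, pmax(1L, as.integer(round(2.5 + lat$amyloid)))),
      niareagan = pmin(4L, pmax(1L, as.integer(round(2.5 + 0.7 * lat$amyloid +
                                                       0.5 * lat$tau))))
    )
  list(phenotypes = phen,
       latents = dplyr::bind_cols(tibble(subject_id = cov$subject_id),
                                  as_tibble(lat)))
}

#' Generate a synthetic cohort: expression, modules, phenotypes
#'
#' Draws latent module activities per the truth's causal paths, builds
#' traits as linear combinations plus Gaussian noise, and generates FPKM as
#' the exponential of (baseline + loading x module activity + technical RIN
#' effect + noise), so all FPKM are positive. One bulk sample per subject.
#'
#' @param truth a [synthetic_truth()] with `n_subjects >= 30` and every
#'   module of at least 20 genes.
#' @return A list of class `mglia_cohort`: `expression` (fpkm
#'   [expression_matrix()]), `modules` ([module_assignment()]),
#'   `phenotypes`, `latents` (tibbles) and `truth`.
#' @export
generate_cohort <- function(truth) {
  validate_truth(truth)
  if (truth$n_subjects < 30L) stop("need n_subjects >= 30", call. = FALSE)
  subj <- gen_subjects(truth)
  n <- truth$n_subjects
  sd_g <- truth$noise_sds[["gene"]]
  assigned <- unlist(lapply(truth$module_defs, function(m) m$genes),
                     use.names = FALSE)
  expr <- with_stream(truth$seed, "expression", {
    # module genes stay clear of the FPKM>1 floor so planted signature
    # overlap counts are deterministic; unassigned genes span the floor
    # and exercise the expression filter
    baseline <- rnorm(truth$n_genes, 3, 1.5)
    names(baseline) <- truth$gene_ids
    baseline[assigned] <- pmax(baseline[assigned], 1.5)
    baseline[setdiff(truth$gene_ids, assigned)] <-
      rnorm(truth$n_genes - length(assigned), 0, 1.5)
    log2e <- matrix(rnorm(truth$n_genes * n, 0, sd_g),
                    nrow = truth$n_genes,
                    dimnames = list(truth$gene_ids, subj$phenotypes$subject_id))
    log2e <- log2e + baseline
    rin_s <- (subj$phenotypes$rin - 7) / 1
    log2e <- log2e + matrix(0.15 * rin_s, nrow = truth$n_genes,
                            ncol = n, byrow = TRUE)
    for (k in names(truth$module_defs)) {
      md <- truth$module_defs[[k]]
      act <- subj$latents[[k]]
      log2e[md$genes, ] <- log2e[md$genes, ] + outer(md$loadings, act)
    }
    2^log2e
  })
  assignment <- module_assignment(
    purrr::map_dfr(names(truth$module_defs), function(k) {
      tibble(gene = truth$module_defs[[k]]$genes, module = k)
    }))
  structure(list(expression = expression_matrix(expr, "fpkm"),
                 modules = assignment,
                 phenotypes = subj$phenotypes,
                 latents = subj$latents,
                 truth = truth),
            class = "mglia_cohort")
}

#' @export
print.mglia_cohort <- function(x, ...) {
  cat(sprintf("<mglia_cohort> %d genes x %d subjects, %d modules\n",
              nrow(x$expression), ncol(x$expression),
              nrow(module_catalog(x$modules))))
  invisible(x)
}

#' Generate cell-type reference expression profiles
#'
#' Emits a bulk-tissue profile plus one profile per cell type in the
#' truth's signature plan. Each planted signature gene has mean FPKM in its
#' own cell type at least fourfold the bulk mean (and > 1); every other
#' gene violates the fold rule, so [derive_enriched_set()] recovers the
#' planted signatures exactly. Each profile carries 3 replicate columns
#' whose row means equal the designed target exactly.
#'
#' @param truth a [synthetic_truth()].
#' @param replicates columns per profile.
#' @return Named list of fpkm [expression_matrix()] objects, including
#'   `bulk`.
#' @export
generate_reference_profiles <- function(truth, replicates = 3L) {
  validate_truth(truth)
  if (length(truth$signature_spec) == 0L) {
    stop("signature plan is empty", call. = FALSE)
  }
  if (any(lengths(truth$signature_spec) == 0L)) {
    stop("empty signature for a requested cell type", call. = FALSE)
  }
  genes <- truth$gene_ids
  with_stream(truth$seed, "profiles", {
    bulk <- setNames(2^rnorm(length(genes), 3, 1.2), genes)
    make_mat <- function(target, label) {
      eps <- matrix(exp(rnorm(length(genes) * replicates, 0, 0.1)),
                    nrow = length(genes))
      eps <- eps / rowMeans(eps)           # row means exactly 1
      vals <- target * eps
      dimnames(vals) <- list(genes, sprintf("%s_r%d", label, seq_len(replicates)))
      expression_matrix(vals, "fpkm")
    }
    out <- list(bulk = make_mat(bulk, "bulk"))
    for (ct in names(truth$signature_spec)) {
      sig <- truth$signature_spec[[ct]]
      target <- bulk * runif(length(genes), 0.3, 0.9)
      target[sig] <- pmax(4 * bulk[sig] * runif(length(sig), 1.1, 2.5), 1.1)
      names(target) <- genes
      out[[ct]] <- make_mat(target, ct)
    }
    out
  })
}

#' Generate longitudinal cognition trajectories
#'
#' Observed global cognition = person intercept + true slope x year +
#' age/sex/education effects + Gaussian residual. True slopes equal the
#' cohort's `decline_slope` for the same truth, so mixed-model slope
#' extraction can be validated against ground truth.
#'
#' @param truth a [synthetic_truth()].
#' @param visits annual visits per subject (>= 3).
#' @param resid_sd residual sd of the observed score.
#' @return Tibble (`subject_id`, `year`, `score`, `age`, `sex`,
#'   `education`) with the true slopes in `attr(, "true_slopes")`.
#' @export
generate_longitudinal <- function(truth, visits = 8L, resid_sd = 0.25) {
  validate_truth(truth)
  if (visits < 3L) {
    stop("need >= 3 visits to identify per-subject slopes", call. = FALSE)
  }
  if (resid_sd < 0) stop("resid_sd must be >= 0", call. = FALSE)
  subj <- gen_subjects(truth)
  ph <- subj$phenotypes
  n <- nrow(ph)
  lc <- with_stream(truth$seed, "longitudinal", {
    intercept <- rnorm(n, 0, 0.4)
    purrr::map_dfr(seq_len(n), function(i) {
      year <- 0:(visits - 1L)
      mu <- intercept[i] + ph$decline_slope[i] * year -
        0.02 * zs_age(ph$age_death[i]) + 0.03 * ph$sex[i] +
        0.05 * zs_edu(ph$education[i])
      tibble(subject_id = ph$subject_id[i], year = year,
             score = mu + rnorm(visits, 0, resid_sd),
             age = ph$age_death[i], sex = ph$sex[i],
             education = ph$education[i])
    })
  })
  attr(lc, "true_slopes") <- tibble(subject_id = ph$subject_id,
                                    slope = ph$decline_slope)
  lc
}

#' Generate a GWAS-style probe table and gene intervals
#'
#' Genes are laid out along one chromosome; every designated AD gene
#' receives at least one probe with p < 0.05 within 50 kb of the gene,
#' while all other probes carry uniform p-values.
#'
#' @param truth a [synthetic_truth()].
#' @param probes_per_gene probes per gene (>= 1).
#' @param window flanking window in bp used for probe placement.
#' @return List: `intervals` (gene, chrom, start, end; 1-based inclusive),
#'   `probes` (chrom, pos, p), `ad_genes`.
#' @export
generate_gwas_summary <- function(truth, probes_per_gene = 3L, window = 50000L) {
  validate_truth(truth)
  if (probes_per_gene < 1L) stop("probes_per_gene must be >= 1", call. = FALSE)
  genes <- truth$gene_ids
  if (length(genes) == 0L) stop("empty gene interval table", call. = FALSE)
  start <- 1L + (seq_along(genes) - 1L) * 200000L
  intervals <- tibble(gene = genes, chrom = "chr1",
                      start = start, end = start + 9999L)
  probes <- with_stream(truth$seed, "gwas", {
    tab <- purrr::map_dfr(seq_along(genes), function(i) {
      lo <- max(1L, intervals$start[i] - window)
      hi <- intervals$end[i] + window
      tibble(chrom = "chr1",
             pos = as.integer(floor(runif(probes_per_gene, lo, hi + 1))),
             p = runif(probes_per_gene))
    })
    is_ad <- rep(genes %in% truth$ad_genes, each = probes_per_gene)
    first_of_gene <- !duplicated(rep(seq_along(genes), each = probes_per_gene))
    force_sig <- is_ad & first_of_gene
    tab$p[force_sig] <- runif(sum(force_sig), 0, 0.049)
    tab
  })
  list(intervals = intervals, probes = probes, ad_genes = truth$ad_genes)
}
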