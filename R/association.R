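#' Default covariate set for trait associations
#'
#' Age at death, sex, study indicator, RNA integrity number and
#' postmortem interval — the adjustment set used in every bulk
#' module/gene-trait model.
#' @export
default_covariates <- function() c("age_death", "sex", "study", "rin", "pmi")

#' Extract person-specific cognitive-decline slopes
#'
#' Fits the longitudinal global-cognition scores with a linear mixed model
#' (fixed effects: visit year, age, sex, education; correlated random
#' intercept and slope per subject) and returns each subject's conditional
#' -mode (shrunken) slope: fixed-year effect plus the subject's random
#' slope. Subjects with fewer than 2 visits get a missing slope.
#'
#' @param lc tibble with columns `subject_id`, `year`, `score`, `age`,
#'   `sex`, `education` (one row per visit).
#' @return Tibble: `subject_id`, `slope`, `n_visits`. The fitted lme4
#'   model is attached as `attr(, "fit")`.
#' @export
fit_decline_slopes <- function(lc) {
  lc <- as_tibble(lc)
  nv <- dplyr::count(lc, .data$subject_id, name = "n_visits")
  usable <- nv$subject_id[nv$n_visits >= 2L]
  if (sum(nv$n_visits >= 3L) < 30L) {
    stop("need at least 30 subjects with >= 3 visits", call. = FALSE)
  }
  dat <- lc[lc$subject_id %in% usable, , drop = FALSE]
  # exactly-linear trajectories (zero residual) make the mixed model
  # degenerate; per-subject OLS slopes are then exact and unshrunken
  per_subj <- dat |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      slope = coef(lm(score ~ year, data = dplyr::pick(dplyr::everything())))[["year"]],
      rss = sum(residuals(lm(score ~ year,
                             data = dplyr::pick(dplyr::everything())))^2))
  if (max(per_subj$rss) < 1e-16) {
    out <- nv |>
      dplyr::left_join(per_subj[, c("subject_id", "slope")], by = "subject_id") |>
      dplyr::select("subject_id", "slope", "n_visits")
    return(out)
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(score ~ year + age + sex + education + (1 + year | subject_id),
                 data = dat,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)))),
    error = function(e) stop("mixed model failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  re <- lme4::ranef(fit)$subject_id
  slopes <- lme4::fixef(fit)[["year"]] + re[usable, "year"]
  out <- nv |>
    dplyr::left_join(tibble(subject_id = usable, slope = slopes),
                     by = "subject_id") |>
    dplyr::select("subject_id", "slope", "n_visits")
  attr(out, "fit") <- fit
  out
}

#' Associate a predictor with a trait
#'
#' Covariate-adjusted ordinary least squares of the trait on the
#' predictor: `trait ~ predictor + covariates` with an intercept. The
#' default covariates are age, sex, study, RIN and PMI; the
#' cell-type-adjusted variant is obtained by passing other module
#' meta-features through `extra`.
#'
#' @param phen phenotype tibble, one row per subject.
#' @param predictor numeric vector aligned with `phen` rows (e.g. a module
#'   meta-feature), or the name of a `phen` column.
#' @param trait name of the outcome column in `phen`.
#' @param covariates character vector of adjustment columns in `phen`.
#' @param extra named list of additional numeric covariate vectors (e.g.
#'   cell-type module meta-features).
#' @param predictor_id label for the predictor in the result.
#' @return One-row tibble: `predictor`, `trait`, `beta`, `se`, `t`, `p`
#'   (two-sided), `n`, `covariates`, `model`.
#' @export
associate <- function(phen, predictor, trait,
                      covariates = default_covariates(),
                      extra = list(), predictor_id = "predictor") {
  phen <- as_tibble(phen)
  if (is.character(predictor) && length(predictor) == 1L) {
    predictor_id <- predictor
    predictor <- phen[[predictor]]
    covariates <- setdiff(covariates, predictor_id)
  }
  if (length(predictor) != nrow(phen)) {
    stop("predictor must align with the phenotype rows", call. = FALSE)
  }
  if (predictor_id %in% c(trait, covariates, names(extra))) {
    stop(sprintf("predictor id '%s' clashes with a model term", predictor_id),
         call. = FALSE)
  }
  if (trait %in% covariates) stop("trait cannot be a covariate", call. = FALSE)
  dat <- dplyr::bind_cols(
    tibble(.y = phen[[trait]], .x = predictor),
    phen[, covariates, drop = FALSE])
  if (length(extra) > 0L) dat <- dplyr::bind_cols(dat, as_tibble(extra))
  dat <- dat[complete.cases(dat), , drop = FALSE]
  p_terms <- 2L + length(covariates) + length(extra)
  if (nrow(dat) < p_terms + 2L) stop("too few complete cases", call. = FALSE)
  fit <- lm(.y ~ ., data = dat)
  cf <- summary(fit)$coefficients
  tibble(predictor = predictor_id, trait = trait,
         beta = cf[".x", 1], se = cf[".x", 2],
         t = cf[".x", 3], p = cf[".x", 4],
         n = nrow(dat),
         covariates = paste(c(covariates, names(extra)), collapse = "+"),
         model = "ols")
}

#' Module-by-trait association grid
#'
#' Runs [associate()] for every module meta-feature against every trait, a
#' tidy version of the module-trait association table.
#'
#' @param scores wide tibble from [module_scores()] (`sample_id` + one
#'   column per module).
#' @param phen phenotype tibble whose `subject_id` matches `sample_id`.
#' @param traits trait column names.
#' @param ... passed to [associate()].
#' @return Tidy tibble, one row per module x trait.
#' @export
associate_modules <- function(scores, phen,
                              traits = c("amyloid_sqrt", "tau_sqrt",
                                         "decline_slope", "np", "nft", "dp"),
                              ...) {
  phen <- dplyr::inner_join(as_tibble(phen), scores,
                            by = c(subject_id = "sample_id"))
  mods <- setdiff(names(scores), "sample_id")
  purrr::map_dfr(mods, function(m) {
    purrr::map_dfr(traits, function(tr) {
      associate(phen, phen[[m]], tr, predictor_id = m, ...)
    })
  })
}

#' Multiplicity adjustment with a reported threshold
#'
#' Bonferroni rejects `p < alpha / m` and reports that fixed threshold;
#' Benjamini-Hochberg runs the standard step-up and reports the largest
#' rejected p-value as the data-dependent threshold.
#'
#' @param p vector of p-values in (0, 1].
#' @param method `"bonferroni"` or `"bh"`.
#' @param alpha family-wise / FDR level.
#' @return List: `reject` (logical), `threshold`, `method`, `alpha`.
#' @export
adjust_multiplicity <- function(p, method = c("bonferroni", "bh"), alpha = 0.05) {
  method <- match.arg(method)
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  if (method == "bonferroni") {
    thr <- alpha / length(p)
    reject <- p < thr
  } else {
    reject <- p.adjust(p, "BH") <= alpha
    thr <- if (any(reject)) max(p[reject]) else NA_real_
  }
  list(reject = reject, threshold = thr, method = method, alpha = alpha)
}

#' Fraction of an exposure effect explained by a mediator
#'
#' Quantifies how much of an exposure's effect on a trait runs through a
#' mediator, under the shared covariate set (minus the exposure). Two
#' labeled definitions are returned: `attenuation` = 1 - beta_adjusted /
#' beta_unadjusted, and `variance_ratio` = 1 - (incremental R^2 of the
#' exposure with the mediator in the model) / (incremental R^2 without).
#' If the unadjusted exposure effect is indistinguishable from zero
#' (|t| < 1) the fractions are undefined and returned as NA with
#' `defined = FALSE`.
#'
#' @param phen phenotype tibble.
#' @param trait outcome column name.
#' @param exposure exposure column name (e.g. `"sex"`).
#' @param mediator numeric vector aligned with `phen` (e.g. a module
#'   meta-feature).
#' @param covariates adjustment columns; the exposure is removed from this
#'   set automatically.
#' @return One-row tibble: `trait`, `exposure`, `attenuation`,
#'   `variance_ratio`, `beta_unadjusted`, `beta_adjusted`, `defined`.
#' @export
mediated_variance_fraction <- function(phen, trait, exposure, mediator,
                                       covariates = default_covariates()) {
  phen <- as_tibble(phen)
  covariates <- setdiff(covariates, c(exposure, trait))
  if (!exposure %in% names(phen)) stop("exposure not in phenotype table", call. = FALSE)
  dat <- dplyr::bind_cols(
    tibble(.y = phen[[trait]], .e = phen[[exposure]], .m = mediator),
    phen[, covariates, drop = FALSE])
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (abs(cor(dat$.e, dat$.m)) > 0.999) {
    stop("mediator is collinear with the exposure", call. = FALSE)
  }
  f0 <- lm(.y ~ . - .m, data = dat)           # exposure, no mediator
  f1 <- lm(.y ~ ., data = dat)                # exposure + mediator
  b0 <- summary(f0)$coefficients[".e", ]
  b1 <- summary(f1)$coefficients[".e", ]
  r2 <- function(fit) summary(fit)$r.squared
  f0_base <- lm(.y ~ . - .m - .e, data = dat) # covariates only
  f1_base <- lm(.y ~ . - .e, data = dat)      # covariates + mediator
  d_r2_without <- r2(f0) - r2(f0_base)
  d_r2_with <- r2(f1) - r2(f1_base)
  defined <- abs(b0[["t value"]]) >= 1
  tibble(trait = trait, exposure = exposure,
         attenuation = if (defined) 1 - b1[["Estimate"]] / b0[["Estimate"]] else NA_real_,
         variance_ratio = if (defined) 1 - d_r2_with / d_r2_without else NA_real_,
         beta_unadjusted = b0[["Estimate"]], beta_adjusted = b1[["Estimate"]],
         defined = defined)
}
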