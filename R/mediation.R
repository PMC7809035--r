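#' Attenuation-based mediation test for one triple
#'
#' Implements the two-threshold decision rule: if the coefficient of A in
#' the regression of B on A (plus covariates) has p < alpha, and that
#' p-value rises to >= alpha once C enters the model, the A-B relationship
#' is called mediated through C. If the direct A-B association is not
#' significant the verdict is `no_association`; if it survives adjustment
#' for C it is `not_mediated`. Verdicts order events; they are
#' "consistent with the data", not proofs of causality.
#'
#' @param a,b,c_ numeric vectors: exposure A, outcome B, candidate
#'   mediator C (aligned; complete cases used).
#' @param covariates optional data frame of additional covariates (e.g.
#'   RIN and PMI), aligned with the vectors.
#' @param alpha decision threshold (default 0.05).
#' @param labels character(3): names for A, B, C in the output.
#' @return One-row tibble: the triple, `beta_direct`, `p_direct`,
#'   `beta_conditional`, `p_conditional`, `attenuation`, `verdict`.
#' @export
mediation_test <- function(a, b, c_, covariates = NULL, alpha = 0.05,
                           labels = c("A", "B", "C")) {
  dat <- tibble(.a = a, .b = b, .c = c_)
  if (!is.null(covariates)) dat <- dplyr::bind_cols(dat, as_tibble(covariates))
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (abs(cor(dat$.a, dat$.c)) > 0.999) {
    stop("A and C are collinear (|corr| > 0.999)", call. = FALSE)
  }
  f_direct <- lm(.b ~ . - .c, data = dat)
  f_cond <- lm(.b ~ ., data = dat)
  cd <- summary(f_direct)$coefficients[".a", ]
  cc <- summary(f_cond)$coefficients[".a", ]
  p_direct <- cd[["Pr(>|t|)"]]
  p_cond <- cc[["Pr(>|t|)"]]
  verdict <- mediation_verdict(p_direct, p_cond, alpha)
  tibble(a = labels[1], b = labels[2], c = labels[3],
         beta_direct = cd[["Estimate"]], p_direct = p_direct,
         beta_conditional = cc[["Estimate"]], p_conditional = p_cond,
         attenuation = if (p_direct < alpha) 1 - cc[["Estimate"]] / cd[["Estimate"]]
                       else NA_real_,
         verdict = verdict, alpha = alpha)
}

#' Exhaustive mediation ordering of a variable triple
#'
#' Runs [mediation_test()] for all six directed orderings of three
#' variables. An ordering `X -> Z -> Y` is *supported* when the X-Y
#' association is mediated by Z while the X-Z and Z-Y links stay
#' significant given the remaining variable. The supported set may be
#' empty or contain several orderings; ties are reported, not resolved.
#'
#' @param x,y,z numeric vectors (aligned).
#' @param covariates optional data frame of extra covariates.
#' @param alpha decision threshold.
#' @param labels character(3): names of `x`, `y`, `z`.
#' @return Tibble, one row per ordering: `upstream`, `mediator`,
#'   `downstream`, the mediation-test columns, `edge_up_p` (upstream-
#'   mediator link given the third), `edge_down_p` (mediator-downstream
#'   link given the third), and `supported`.
#' @export
order_triple <- function(x, y, z, covariates = NULL, alpha = 0.05,
                         labels = c("x", "y", "z")) {
  vars <- list(x, y, z)
  names(vars) <- labels
  n_min <- 3L + if (is.null(covariates)) 0L else ncol(covariates)
  if (length(x) < n_min + 3L) stop("too few observations for the triple", call. = FALSE)
  ords <- list(c(1, 3, 2), c(2, 3, 1), c(1, 2, 3),
               c(3, 2, 1), c(2, 1, 3), c(3, 1, 2))
  purrr::map_dfr(ords, function(o) {
    up <- vars[[o[1]]]; mid <- vars[[o[2]]]; down <- vars[[o[3]]]
    med <- mediation_test(up, down, mid, covariates = covariates, alpha = alpha,
                          labels = labels[o])
    # upstream-mediator link given the downstream variable
    p_up <- partial_coef_p(mid, up, down, covariates)
    # mediator-downstream link given the upstream variable
    p_down <- partial_coef_p(down, mid, up, covariates)
    tibble(upstream = labels[o[1]], mediator = labels[o[2]],
           downstream = labels[o[3]],
           beta_direct = med$beta_direct, p_direct = med$p_direct,
           beta_conditional = med$beta_conditional,
           p_conditional = med$p_conditional,
           attenuation = med$attenuation, verdict = med$verdict,
           edge_up_p = p_up, edge_down_p = p_down,
           supported = med$verdict == "mediated" &&
             p_up < alpha && p_down < alpha)
  })
}

#' The two-threshold mediation verdict rule
#'
#' `no_association` iff the direct p-value is `>= alpha`; `mediated` iff
#' the direct p-value is `< alpha` while the conditional one is
#' `>= alpha`; `not_mediated` otherwise.
#'
#' @param p_direct p-value of A in B ~ A (+ covariates).
#' @param p_conditional p-value of A in B ~ A + C (+ covariates).
#' @param alpha decision threshold.
#' @return One of `"no_association"`, `"mediated"`, `"not_mediated"`.
#' @export
mediation_verdict <- function(p_direct, p_conditional, alpha = 0.05) {
  if (p_direct >= alpha) "no_association"
  else if (p_conditional >= alpha) "mediated"
  else "not_mediated"
}

# p-value of `pred` in lm(outcome ~ pred + other + covariates)
partial_coef_p <- function(outcome, pred, other, covariates) {
  dat <- tibble(.y = outcome, .x = pred, .o = other)
  if (!is.null(covariates)) dat <- dplyr::bind_cols(dat, as_tibble(covariates))
  dat <- dat[complete.cases(dat), , drop = FALSE]
  summary(lm(.y ~ ., data = dat))$coefficients[".x", "Pr(>|t|)"]
}
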