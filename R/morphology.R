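#' Segment cells from a mask image
#'
#' Connected-component labeling of a binary (or labeled) image under
#' 8-connectivity: diagonally touching pixels join one cell. Components
#' below `min_area` pixels are discarded (count reported via message).
#' Pixel coordinates are 0-based (row, col); centroids sit at pixel
#' centers.
#'
#' @param mask 2D numeric/integer matrix; nonzero = foreground.
#' @param min_area minimum component area in pixels (default 5).
#' @return Tibble, one row per cell: `cell_id`, `area`, `centroid_row`,
#'   `centroid_col`, `compactness`, and `pixels` (list column of 0-based
#'   coordinate matrices).
#' @export
segment_cells <- function(mask, min_area = 5L) {
  if (length(dim(mask)) != 2L) stop("mask must be a 2D image", call. = FALSE)
  lab <- label_components8(matrix(as.integer(mask != 0), nrow(mask)))
  ncomp <- max(lab)
  if (ncomp == 0L) {
    return(tibble(cell_id = integer(), area = integer(),
                  centroid_row = numeric(), centroid_col = numeric(),
                  compactness = numeric(), pixels = list()))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  px_by_comp <- split.data.frame(idx - 1L, comp)   # 0-based coords
  areas <- vapply(px_by_comp, nrow, integer(1))
  small <- areas < min_area
  if (any(small)) {
    message(sprintf("discarded %d component(s) below %d px", sum(small), min_area))
  }
  px_by_comp <- px_by_comp[!small]
  if (length(px_by_comp) == 0L) {
    return(tibble(cell_id = integer(), area = integer(),
                  centroid_row = numeric(), centroid_col = numeric(),
                  compactness = numeric(), pixels = list()))
  }
  rows <- purrr::imap(px_by_comp, function(px, id) {
    px <- as.matrix(px)
    tibble(cell_id = as.integer(id), area = nrow(px),
           centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]),
           compactness = compactness(px), pixels = list(px))
  })
  out <- dplyr::bind_rows(rows)
  out$cell_id <- seq_len(nrow(out))
  out
}

#' Radial-variance compactness of a pixel set
#'
#' The population variance of the pixel-to-centroid Euclidean distances
#' divided by the area (pixel count). Zero for a single pixel; a filled
#' disk scores lower than a thin ramified shape of equal area, so larger
#' values mean more spread/ramification.
#'
#' @param pixels matrix with two columns (row, col), one pixel per row.
#' @return Nonnegative scalar.
#' @export
compactness <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) stop("empty pixel set", call. = FALSE)
  ctr <- colMeans(pixels)
  r <- sqrt((pixels[, 1] - ctr[1])^2 + (pixels[, 2] - ctr[2])^2)
  mean((r - mean(r))^2) / nrow(pixels)
}

#' Call marker positivity per cell
#'
#' Thresholds the channel image globally with Otsu's method, then flags a
#' cell as marker-positive when at least `positive_fraction` of its pixels
#' exceed the threshold. Raising `positive_fraction` never creates new
#' positives.
#'
#' @param cells tibble from [segment_cells()].
#' @param channel intensity image aligned with the mask geometry, values
#'   in `[0, 1]`.
#' @param marker marker name; the flag column is `positive_<marker>`.
#' @param positive_fraction fraction of cell pixels that must exceed the
#'   threshold (default 0.10).
#' @return `cells` with the added logical flag column and a
#'   `threshold_<marker>` attribute.
#' @export
call_positivity <- function(cells, channel, marker, positive_fraction = 0.10) {
  if (length(dim(channel)) != 2L) stop("channel must be a 2D image", call. = FALSE)
  rng <- range(channel)
  if (diff(rng) == 0) {
    stop("constant-intensity channel: threshold undefined", call. = FALSE)
  }
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("package 'EBImage' is required for Otsu thresholding", call. = FALSE)
  }
  thr <- EBImage::otsu(EBImage::Image(channel), range = rng)
  flag <- purrr::map_lgl(cells$pixels, function(px) {
    v <- channel[cbind(px[, 1] + 1L, px[, 2] + 1L)]
    mean(v > thr) >= positive_fraction
  })
  cells[[paste0("positive_", marker)]] <- flag
  attr(cells, paste0("threshold_", marker)) <- thr
  cells
}

#' Compare compactness between marker groups across subjects
#'
#' Random-intercept linear mixed model `compactness ~ group +
#' (1 | subject)`; the group coefficient measures the compactness shift of
#' marker-positive cells after accounting for between-subject variability.
#' With a single subject the model degrades to OLS with a warning.
#'
#' @param cells tibble with one row per cell.
#' @param group name of the logical/binary group column (e.g. a
#'   `positive_<marker>` flag).
#' @param subject name of the subject id column.
#' @param response name of the response column (default `"compactness"`).
#' @return One-row tibble: `beta`, `se`, `t`, `p`, `n_cells`,
#'   `n_subjects`, `model`.
#' @export
compare_compactness <- function(cells, group = "positive_marker",
                                subject = "subject_id",
                                response = "compactness") {
  dat <- tibble(y = cells[[response]],
                g = as.numeric(cells[[group]]),
                s = cells[[subject]])
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (length(unique(dat$g)) < 2L) {
    stop("both marker groups must be present", call. = FALSE)
  }
  ns <- length(unique(dat$s))
  if (ns >= 2L) {
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(y ~ g + (1 | s), data = dat,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))))
    cf <- summary(fit)$coefficients["g", ]
    tibble(beta = cf[["Estimate"]], se = cf[["Std. Error"]],
           t = cf[["t value"]], p = cf[["Pr(>|t|)"]],
           n_cells = nrow(dat), n_subjects = ns, model = "lmm")
  } else {
    warning("single subject: falling back to ordinary least squares")
    cf <- summary(lm(y ~ g, data = dat))$coefficients["g", ]
    tibble(beta = cf[["Estimate"]], se = cf[["Std. Error"]],
           t = cf[["t value"]], p = cf[["Pr(>|t|)"]],
           n_cells = nrow(dat), n_subjects = ns, model = "ols")
  }
}

#' Positive fraction versus ordinal stage score
#'
#' OLS of the per-subject marker-positive fraction on an ordinal stage
#' score treated as numeric (e.g. Braak 0-6).
#'
#' @param fractions numeric vector of per-subject positive fractions.
#' @param stage ordinal stage scores, same length.
#' @return One-row tibble: `beta`, `se`, `t`, `p`, `n`.
#' @export
positivity_vs_stage <- function(fractions, stage) {
  ok <- complete.cases(fractions, stage)
  fractions <- fractions[ok]; stage <- as.numeric(stage[ok])
  if (length(fractions) < 4L) stop("need >= 4 subjects with a stage score", call. = FALSE)
  if (sd(stage) == 0) stop("constant stage score", call. = FALSE)
  cf <- summary(lm(fractions ~ stage))$coefficients["stage", ]
  tibble(beta = cf[["Estimate"]], se = cf[["Std. Error"]],
         t = cf[["t value"]], p = cf[["Pr(>|t|)"]], n = length(fractions))
}
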