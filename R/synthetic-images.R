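#' Generate synthetic microglia mask and channel images
#'
#' Each subject gets one mask image containing `cells_per_subject`
#' connected blobs laid out on a non-overlapping tile grid, plus a
#' pan-marker channel (positive on every cell) and a marker channel
#' (positive only on marker-positive cells). Marker-positive cells are
#' drawn from a compact shape family (short processes), marker-negative
#' cells from a ramified family (long processes); `effect` scales the
#' process length of positive cells (`effect = -0.3` shortens them by
#' 30%, `effect = 0` makes the two families identical). The per-subject
#' fraction of positive cells increases with the subject's tau stage
#' score, emulating more activated microglia at higher Braak stages.
#'
#' @param truth a [synthetic_truth()].
#' @param cells_per_subject cells per subject (>= 10).
#' @param n_subjects number of imaged subjects (default 6).
#' @param effect relative change of process length in positive cells.
#' @param pos_base,pos_slope intercept/slope of the positive fraction on
#'   the Braak score.
#' @param tile tile side in pixels; blobs are confined to tile interiors,
#'   so components never touch.
#' @param max_dim packing limit: maximum image side in pixels.
#' @return List of class `mglia_images`: `masks` (binary integer matrices),
#'   `channels` (per subject, `pan` and `marker` matrices in `[0,1]`),
#'   `cells` (tibble with per-cell truth: subject, tile center, planted
#'   positivity), `subjects` (braak score and true positive fraction).
#' @export
generate_cell_images <- function(truth, cells_per_subject = 100L,
                                 n_subjects = 6L, effect = -0.3,
                                 pos_base = 0.15, pos_slope = 0.06,
                                 tile = 36L, max_dim = 4096L) {
  validate_truth(truth)
  if (cells_per_subject < 10L) stop("need >= 10 cells per subject", call. = FALSE)
  ncols <- ceiling(sqrt(cells_per_subject))
  nrows <- ceiling(cells_per_subject / ncols)
  if (max(nrows, ncols) * tile > max_dim) {
    stop("packing limit exceeded: too many cells for the image size", call. = FALSE)
  }
  braak <- rep_len(1:6, n_subjects)
  masks <- list(); channels <- list(); cell_rows <- list()
  pos_frac <- numeric(n_subjects)
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("img%02d", s)
    out <- with_stream(truth$seed, paste0("images.", s), {
      frac <- min(0.95, max(0.05, pos_base + pos_slope * braak[s] +
                              rnorm(1, 0, 0.02)))
      nr <- nrows * tile; nc <- ncols * tile
      mask <- matrix(0L, nr, nc)
      pan <- matrix(pmin(pmax(rnorm(nr * nc, 0.15, 0.03), 0), 1), nr, nc)
      marker <- matrix(pmin(pmax(rnorm(nr * nc, 0.15, 0.03), 0), 1), nr, nc)
      positive <- runif(cells_per_subject) < frac
      info <- vector("list", cells_per_subject)
      for (i in seq_len(cells_per_subject)) {
        tr <- (i - 1L) %/% ncols; tc <- (i - 1L) %% ncols
        r0 <- tr * tile; c0 <- tc * tile  # tile origin (0-based)
        cr <- r0 + tile / 2 + runif(1, -2, 2)
        cc <- c0 + tile / 2 + runif(1, -2, 2)
        core_r <- runif(1, 2, 4)
        k <- sample(3:6, 1)
        ang <- runif(k, 0, 2 * pi)
        arm_len <- runif(k, 7, 13)
        if (positive[i]) arm_len <- arm_len * (1 + effect)
        px <- blob_pixels(cr, cc, core_r, ang, arm_len,
                          rlim = c(r0 + 1, r0 + tile - 2),
                          clim = c(c0 + 1, c0 + tile - 2))
        idx <- cbind(px[, 1] + 1L, px[, 2] + 1L)  # 0-based -> R index
        mask[idx] <- 1L
        pan[idx] <- pmin(pmax(rnorm(nrow(px), 0.75, 0.05), 0), 1)
        if (positive[i]) {
          marker[idx] <- pmin(pmax(rnorm(nrow(px), 0.80, 0.05), 0), 1)
        }
        info[[i]] <- tibble(subject_id = sid, cell = i,
                            center_row = r0 + tile / 2,
                            center_col = c0 + tile / 2,
                            positive = positive[i], braak = braak[s])
      }
      list(mask = mask, pan = pan, marker = marker,
           cells = dplyr::bind_rows(info), frac = mean(positive))
    })
    masks[[sid]] <- out$mask
    channels[[sid]] <- list(pan = out$pan, marker = out$marker)
    cell_rows[[sid]] <- out$cells
    pos_frac[s] <- out$frac
  }
  structure(list(masks = masks, channels = channels,
                 cells = dplyr::bind_rows(cell_rows),
                 subjects = tibble(subject_id = names(masks), braak = braak,
                                   positive_fraction_true = pos_frac)),
            class = "mglia_images")
}

# Pixel set (0-based row/col) of one blob: a filled core disk plus `k`
# 1-px-wide arms; confined to [rlim, clim] so tiles stay disjoint. The
# result is one 8-connected component by construction.
blob_pixels <- function(cr, cc, core_r, ang, arm_len, rlim, clim) {
  rr <- seq(floor(cr - core_r), ceiling(cr + core_r))
  ccs <- seq(floor(cc - core_r), ceiling(cc + core_r))
  grid <- expand.grid(r = rr, c = ccs)
  core <- grid[(grid$r - cr)^2 + (grid$c - cc)^2 <= core_r^2, ]
  arms <- purrr::map2_dfr(ang, arm_len, function(a, L) {
    t <- seq(0, L, by = 0.4)
    data.frame(r = round(cr + t * sin(a)), c = round(cc + t * cos(a)))
  })
  px <- rbind(round(core), arms)
  px$r <- pmin(pmax(px$r, rlim[1]), rlim[2])
  px$c <- pmin(pmax(px$c, clim[1]), clim[2])
  as.matrix(unique(px))
}
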