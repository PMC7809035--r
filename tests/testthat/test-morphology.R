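test_that("segmentation uses 8-connectivity and the area floor", {
  # two disjoint 3x3 squares
  mask <- toy_mask(12, 12, list(rect_px(2, 4, 2, 4), rect_px(8, 10, 8, 10)))
  cells <- segment_cells(mask)
  expect_equal(nrow(cells), 2L)
  expect_equal(cells$area, c(9L, 9L))

  # empty mask -> empty result
  expect_equal(nrow(segment_cells(matrix(0L, 5, 5))), 0L)

  # diagonal touch joins into one cell
  diag_mask <- toy_mask(10, 10, list(rect_px(2, 4, 2, 4), rect_px(5, 7, 5, 7)))
  expect_equal(nrow(segment_cells(diag_mask)), 1L)

  # small components are discarded with a message, and areas add up
  mixed <- toy_mask(12, 12, list(rect_px(2, 4, 2, 4),
                                 rect_px(9, 9, 9, 10)))   # area 2 < 5
  expect_message(kept <- segment_cells(mixed), "discarded 1")
  expect_equal(sum(kept$area), sum(mixed) - 2L)

  expect_error(segment_cells(array(0, c(2, 2, 2))), "2D")
})

test_that("compactness matches hand arithmetic and its invariances", {
  # single pixel
  expect_equal(compactness(matrix(c(0, 0), 1)), 0)

  # 3x3 filled square: radial distances {0, 1 x4, sqrt(2) x4}
  px <- rect_px(0, 2, 0, 2)
  r <- c(0, rep(1, 4), rep(sqrt(2), 4))
  hand <- mean((r - mean(r))^2) / 9
  expect_equal(compactness(px), hand, tolerance = 1e-12)
  expect_equal(hand, 0.020226, tolerance = 1e-4)

  # translation and 90-degree rotation invariance
  set.seed(9)
  blob <- unique(cbind(sample(0:20, 40, TRUE), sample(0:20, 40, TRUE)))
  expect_equal(compactness(blob + 13), compactness(blob), tolerance = 1e-12)
  rot <- cbind(blob[, 2], -blob[, 1])
  expect_equal(compactness(rot), compactness(blob), tolerance = 1e-12)

  # ramified (line) shapes score above compact (disk-like) ones at equal area
  for (side in 3:7) {
    area <- side^2
    square <- rect_px(0, side - 1, 0, side - 1)
    line <- cbind(0:(area - 1), 0)
    expect_lt(compactness(square), compactness(line))
  }

  expect_error(compactness(matrix(numeric(0), ncol = 2)), "empty")
})

test_that("positivity calling thresholds per image and is monotone", {
  mask <- toy_mask(20, 20, list(rect_px(2, 5, 2, 5), rect_px(10, 13, 10, 13)))
  cells <- segment_cells(mask)
  channel <- matrix(0.1, 20, 20) + matrix(rnorm(400, 0, 0.01), 20)
  channel[rect_px(2, 5, 2, 5)] <- 0.9   # first cell fully bright
  out <- call_positivity(cells, channel, "vasp")
  # discovery order is column-major: the (2:5, 2:5) block is cell 1
  expect_true(out$positive_vasp[1])
  expect_false(out$positive_vasp[2])

  # raising positive_fraction never creates new positives
  half <- channel
  half[rect_px(10, 11, 10, 13)] <- 0.9  # half of the second cell bright
  flags <- vapply(c(0.1, 0.4, 0.6, 0.9), function(f) {
    sum(call_positivity(cells, half, "m", positive_fraction = f)$positive_m)
  }, numeric(1))
  expect_true(all(diff(flags) <= 0))

  expect_error(call_positivity(cells, matrix(0.5, 20, 20), "m"), "constant")
})

test_that("compactness comparison recovers a planted negative effect", {
  tr <- synthetic_truth(n_subjects = 30, seed = 11)
  img <- generate_cell_images(tr, cells_per_subject = 40, n_subjects = 6,
                              effect = -0.3)
  cells <- purrr::imap_dfr(img$masks, function(mask, sid) {
    seg <- segment_cells(mask)
    seg <- call_positivity(seg, img$channels[[sid]]$marker, "marker")
    dplyr::mutate(seg, subject_id = sid)
  })
  # planted positivity recovered nearly perfectly (match truth by tile)
  tile <- 36
  cells$tile <- paste(cells$subject_id, floor(cells$centroid_row / tile),
                      floor(cells$centroid_col / tile))
  truthm <- img$cells
  truthm$tile <- paste(truthm$subject_id, floor(truthm$center_row / tile),
                       floor(truthm$center_col / tile))
  m <- dplyr::inner_join(cells, truthm[, c("tile", "positive")], by = "tile")
  expect_equal(nrow(m), nrow(cells))
  expect_gte(mean(m$positive[m$positive_marker]), 0.95)   # precision
  expect_gte(mean(m$positive_marker[m$positive]), 0.95)   # recall
  # marker+ cells are less ramified
  cmp <- compare_compactness(cells, "positive_marker")
  expect_lt(cmp$beta, 0)
  expect_lt(cmp$p, 0.01)
  expect_identical(cmp$model, "lmm")

  # single subject falls back to OLS with a warning
  one <- cells[cells$subject_id == cells$subject_id[1], ]
  expect_warning(cmp1 <- compare_compactness(one, "positive_marker"), "single")
  expect_identical(cmp1$model, "ols")

  # a group absent everywhere errors
  allneg <- dplyr::mutate(cells, positive_marker = FALSE)
  expect_error(compare_compactness(allneg, "positive_marker"), "both")
})

test_that("positive fraction vs stage is exact on linear input", {
  stage <- 1:6
  frac <- 0.1 + 0.05 * stage
  res <- positivity_vs_stage(frac, stage)
  expect_equal(res$beta, 0.05, tolerance = 1e-12)
  expect_lt(res$p, 1e-10)
  expect_error(positivity_vs_stage(frac[1:3], stage[1:3]), "4 subjects")
  expect_error(positivity_vs_stage(frac, rep(3, 6)), "constant")
})
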