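test_that("median filter matches the sort-and-pick oracle", {
  # constant image unchanged
  flat <- matrix(7, 9, 9)
  expect_equal(median_filter(flat, 3), flat)
  # isolated impulse removed
  hot <- matrix(0, 9, 9); hot[5, 5] <- 255
  expect_equal(median_filter(hot, 3), matrix(0, 9, 9))
  # random images, both window sizes, exhaustive oracle
  for (seed in 1:5) {
    set.seed(seed)
    img <- matrix(sample(0:255, 49, replace = TRUE), 7, 7)
    expect_equal(median_filter(img, 3), oracle_median_filter(img, 3))
    expect_equal(median_filter(img, 5), oracle_median_filter(img, 5))
  }
  expect_error(median_filter(matrix(0, 5, 5), 4), "odd")
})

test_that("rolling-ball background equals the erosion-dilation oracle", {
  # flat image: background is the image itself, subtraction all-zero
  flat <- matrix(10, 16, 16)
  expect_equal(rolling_ball_background(flat, 5), flat)
  expect_equal(subtract_background(flat, 5), matrix(0, 16, 16))
  # compact bright spot on flat background: spot excluded from background
  spot <- matrix(10, 24, 24); spot[12:13, 12:13] <- 110
  bg <- rolling_ball_background(spot, 5)
  expect_equal(bg, oracle_opening(spot, 5))
  sub <- subtract_background(spot, 5)
  expect_true(all(sub[12:13, 12:13] >= 99))
  expect_true(all(sub[1:8, 1:8] == 0))
  # random images against the oracle
  for (seed in 1:3) {
    set.seed(seed)
    img <- matrix(runif(20 * 18, 0, 100), 20, 18)
    expect_equal(rolling_ball_background(img, 3), oracle_opening(img, 3),
                 tolerance = 1e-12)
  }
  expect_error(rolling_ball_background(flat, 0), "positive")
})

test_that("background never exceeds the image (anti-extensivity)", {
  for (seed in 1:20) {
    set.seed(100 + seed)
    img <- matrix(runif(15 * 15, 0, 255), 15, 15)
    expect_true(all(rolling_ball_background(img, 4) <= img + 1e-9))
  }
})

test_that("component labeling matches the flood-fill oracle", {
  for (seed in 1:10) {
    set.seed(200 + seed)
    mask <- matrix(runif(32 * 32) < 0.35, 32, 32)
    expect_identical(label_components(mask, 8), oracle_flood_fill(mask, 8))
    expect_identical(label_components(mask, 4), oracle_flood_fill(mask, 4))
  }
  # diagonal pair: one component at 8-connectivity, two at 4
  diagm <- matrix(FALSE, 4, 4); diagm[1, 1] <- TRUE; diagm[2, 2] <- TRUE
  expect_equal(max(label_components(diagm, 8)), 1L)
  expect_equal(max(label_components(diagm, 4)), 2L)
})

test_that("detect_cells handles the canonical single-square example", {
  expect_equal(nrow(detect_cells(section_image(matrix(0, 16, 16)))), 0)
  # 3x3 square of 100 at 0-based rows/cols 10-12
  img <- matrix(0, 32, 32); img[11:13, 11:13] <- 100
  cells <- detect_cells(section_image(img), detection_params())
  expect_equal(nrow(cells), 1)
  expect_equal(cells$x_px, 11)
  expect_equal(cells$y_px, 11)
  # the 3x3 median filter erodes the square's corners to a 5-px plus;
  # confirm the frozen size against the brute-force chain
  filt <- oracle_median_filter(img, 3)
  sub <- pmax(filt - oracle_opening(filt, 5), 0)
  expect_equal(cells$size_px, sum(sub >= 20))
  expect_equal(cells$size_px, 5L)
})

test_that("detection recovers all ground-truth spots on a clean scene", {
  s <- make_test_scene(rate = 2, noise_sd = 0, seed = 41)
  det <- detect_cells_stack(s$scene$images)
  truth <- s$scene$truth$cells
  expect_equal(nrow(det), nrow(truth))
  matched <- dplyr::inner_join(
    det, truth, by = "section_index", relationship = "many-to-many",
    suffix = c("", "_t")
  ) |>
    dplyr::filter(abs(.data$x_px - .data$x_px_t) <= 1,
                  abs(.data$y_px - .data$y_px_t) <= 1)
  # 100% recall and precision: every truth cell matched exactly once
  expect_equal(nrow(matched), nrow(truth))
})

test_that("raising thresholds never increases detections", {
  s <- make_test_scene(rate = 2, noise_sd = 2, seed = 43)
  img <- s$scene$images[[1]]
  n_at <- function(thr, msize) nrow(detect_cells(
    img, detection_params(intensity_threshold = thr,
                          min_component_px = msize)))
  counts_thr <- vapply(c(10, 20, 40, 80, 119), n_at, numeric(1), msize = 2)
  expect_true(all(diff(counts_thr) <= 0))
  counts_size <- vapply(c(1, 2, 5, 9, 13), function(m) n_at(20, m),
                        numeric(1))
  expect_true(all(diff(counts_size) <= 0))
})

test_that("thresholding is idempotent on its own binary output", {
  s <- make_test_scene(rate = 2, noise_sd = 0, seed = 47)
  img <- s$scene$images[[2]]
  p <- detection_params()
  sub <- subtract_background(median_filter(img, 3), 5)
  mask <- sub >= p$intensity_threshold
  relabeled <- label_components((mask * 100) >= p$intensity_threshold,
                                p$connectivity)
  expect_identical(label_components(mask, p$connectivity), relabeled)
})

test_that("images smaller than the median window are rejected", {
  expect_error(detect_cells(section_image(matrix(0, 3, 3)),
                            detection_params(median_window = 5)),
               "smaller")
  expect_error(detection_params(median_window = 2), "odd")
  expect_error(detection_params(connectivity = 6), "4 or 8")
})
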