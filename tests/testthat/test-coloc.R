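test_that("pearson coefficient matches hand computation and its invariances", {
  a <- matrix(c(1, 2, 3, 4), 2, 2)
  b <- matrix(c(2, 4, 6, 9), 2, 2)
  # by-hand product-moment value: 11.5 / sqrt(5 * 26.75)
  expect_equal(pearson_coefficient(a, b), 11.5 / sqrt(5 * 26.75),
               tolerance = 1e-12)
  expect_equal(pearson_coefficient(a, a), 1)
  expect_equal(pearson_coefficient(a, max(a) - a), -1)
  # positive affine invariance
  expect_equal(pearson_coefficient(a, 3 * b + 7),
               pearson_coefficient(a, b), tolerance = 1e-12)
  expect_error(pearson_coefficient(a, matrix(1, 2, 2)),
               class = "gtpasekin_input_error")
})

test_that("overlap coefficient matches its formula and bounds", {
  a <- matrix(c(1, 1, 0, 0), 1)
  b <- matrix(c(1, 0, 0, 0), 1)
  expect_equal(overlap_coefficient(a, b), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(overlap_coefficient(a, 5 * a), 1, tolerance = 1e-12)
  disjoint <- matrix(c(0, 0, 1, 1), 1)
  expect_equal(overlap_coefficient(a, disjoint), 0)
  expect_error(overlap_coefficient(a, matrix(0, 1, 4)),
               class = "gtpasekin_input_error")
  pair <- generate_image_pair(15, 0.3, seed = 4)
  o <- overlap_coefficient(pair$channel_a, pair$channel_b)
  expect_true(o >= 0 && o <= 1)
  expect_equal(overlap_coefficient(pair$channel_a, 2.5 * pair$channel_b), o,
               tolerance = 1e-12)
})

test_that("pearson of independent noise images is near zero", {
  set.seed(11)
  a <- matrix(rnorm(256 * 256), 256)
  b <- matrix(rnorm(256 * 256), 256)
  expect_lt(abs(pearson_coefficient(a, b)), 0.1)
})

test_that("segmentation recovers ground-truth objects and centroids", {
  pair <- generate_image_pair(12, 0.5, background_sd = 0, seed = 3)
  for (side in c("a", "b")) {
    obj <- segment_objects(pair[[paste0("channel_", side)]])
    truth <- pair[[paste0("truth_centroids_", side)]]
    expect_equal(nrow(obj), nrow(truth))
    # each truth centroid has a segmented centroid within 0.5 px
    d <- sqrt(outer(truth$row, obj$row, `-`)^2 +
                outer(truth$col, obj$col, `-`)^2)
    expect_lt(max(apply(d, 1, min)), 0.5)
    expect_true(all(obj$area >= 4))
  }
  # blank image: empty set, no error
  empty <- segment_objects(matrix(0, 32, 32))
  expect_equal(nrow(empty), 0)
  # two spots separated by more than the PSF width resolve as two objects
  two <- generate_image_pair(2, 1, grid_shape = c(64, 64), background_sd = 0,
                             min_separation = 20, seed = 9)
  expect_equal(nrow(segment_objects(two$channel_a)), 2)
})

test_that("segmentation merges diagonally connected pixels (8-connectivity)", {
  img <- matrix(0, 16, 16)
  img[5, 5] <- 10; img[6, 6] <- 10; img[7, 7] <- 10; img[8, 8] <- 10
  obj <- segment_objects(img, rel_threshold = 1, min_area = 4)
  expect_equal(nrow(obj), 1)
  expect_equal(obj$area, 4L)
})

test_that("object matching is one-to-one, symmetric under channel swap, and bounded", {
  set.seed(5)
  a <- tibble::tibble(row = runif(8, 5, 60), col = runif(8, 5, 60))
  b <- dplyr::bind_rows(a[1:5, ],
                        tibble::tibble(row = runif(4, 70, 120),
                                       col = runif(4, 70, 120)))
  res <- object_based_colocalization(a, b, max_dist = 1)
  expect_equal(res$n_matched, 5)
  expect_lte(res$n_matched, min(res$n_a, res$n_b))
  expect_equal(res$pct_a_in_b, 100 * 5 / 8)
  expect_equal(res$pct_b_in_a, 100 * 5 / 9)
  swapped <- object_based_colocalization(b, a, max_dist = 1)
  expect_equal(swapped$n_matched, res$n_matched)
  expect_equal(swapped$pct_a_in_b, res$pct_b_in_a)
  expect_equal(swapped$pct_b_in_a, res$pct_a_in_b)
  # identical sets match fully; far sets not at all
  full <- object_based_colocalization(a, a, max_dist = 3)
  expect_equal(c(full$pct_a_in_b, full$pct_b_in_a), c(100, 100))
  far <- object_based_colocalization(
    a, dplyr::mutate(a, row = row + 500), max_dist = 3)
  expect_equal(far$n_matched, 0)
  expect_equal(far$pct_a_in_b, 0)
  expect_error(object_based_colocalization(a, b, max_dist = -1),
               class = "gtpasekin_input_error")
})

test_that("image-pair ground truth is constructed as requested", {
  pair <- generate_image_pair(20, 0.5, jitter_px = 0, seed = 2)
  expect_equal(pair$n_coloc, 10)
  # co-placed centroid pairs coincide exactly at zero jitter
  expect_equal(pair$truth_centroids_a[1:10, ], pair$truth_centroids_b[1:10, ])
  full <- generate_image_pair(8, 1, jitter_px = 0, seed = 2)
  expect_equal(full$truth_centroids_a, full$truth_centroids_b)
  # zero coloc with wide separation: nothing matches at tolerance 3
  none <- generate_image_pair(10, 0, min_separation = 10, seed = 2)
  res <- object_based_colocalization(
    segment_objects(none$channel_a), segment_objects(none$channel_b),
    max_dist = 3)
  expect_equal(res$n_matched, 0)
  # impossible placement errors out
  expect_error(generate_image_pair(500, 0, grid_shape = c(32, 32),
                                   min_separation = 10, seed = 1,
                                   max_tries = 50),
               class = "gtpasekin_placement_error")
})

test_that("recovered colocalization tracks the true fraction across seeds", {
  errs <- vapply(1:20, function(s) {
    pair <- generate_image_pair(20, 0.5, seed = s)
    res <- coloc_analyze(pair$channel_a, pair$channel_b)
    abs(res$pct_a_in_b - 50)
  }, numeric(1))
  # within one object (100/20 = 5 percentage points) on every clean fixture
  expect_true(all(errs <= 5))
})
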