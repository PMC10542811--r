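test_that("mask area converts pixel counts with the squared scale", {
  m <- matrix(0, 20, 20); m[1:10, 1:10] <- 1          # 100 pixels
  expect_equal(mask_area(m, 0.05), 0.25)
  expect_equal(mask_area(matrix(0, 5, 5), 0.05), 0)
  expect_equal(mask_area(m, 0.10), 4 * mask_area(m, 0.05))  # scaling law
  expect_error(mask_area(m, 0), "positive")
  expect_error(mask_area(m, -1), "positive")
  expect_error(mask_area(m * 0.5, 0.05), "binary")
})

test_that("double-area formula reproduces direct evaluation", {
  v <- double_area_volume(1, 1)
  expect_equal(v$volume_ml, exp(0.8304), tolerance = 1e-12)
  v10 <- double_area_volume(10, 10)
  expect_equal(v10$volume_ml, exp(0.8304 + (0.5625 + 0.7211) * log(10)),
               tolerance = 1e-12)
  expect_equal(v10$volume_ml, 44.1, tolerance = 0.01)
})

test_that("volume is zero and flagged for empty segmentations", {
  expect_warning(v <- double_area_volume(0, 3), "empty")
  expect_equal(v$volume_ml, 0)
  expect_true(v$flagged)
  expect_error(double_area_volume(-1, 1), "nonnegative")
})

test_that("volume is strictly increasing in each area", {
  set.seed(41)
  for (rep in 1:20) {
    a1 <- runif(1, 0.5, 40); a2 <- runif(1, 0.5, 40)
    v <- double_area_volume(a1, a2)$volume_ml
    expect_gt(double_area_volume(a1 * 1.01, a2)$volume_ml, v)
    expect_gt(double_area_volume(a1, a2 * 1.01)$volume_ml, v)
  }
})

test_that("the power-law scaling identity holds exactly", {
  set.seed(42)
  for (rep in 1:20) {
    a1 <- runif(1, 0.5, 30); a2 <- runif(1, 0.5, 30); k <- runif(1, 0.1, 5)
    lhs <- double_area_volume(k * a1, k * a2)$volume_ml
    rhs <- k^(0.5625 + 0.7211) * double_area_volume(a1, a2)$volume_ml
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("estimate_from_pair composes areas and formula", {
  s <- tiny_phantoms()[[1]]
  v <- s$views
  est <- estimate_from_pair(v$sagittal$inner, v$transverse$inner,
                            v$sagittal$cm_per_pixel,
                            v$transverse$cm_per_pixel)
  direct <- double_area_volume(
    mask_area(v$sagittal$inner, v$sagittal$cm_per_pixel),
    mask_area(v$transverse$inner, v$transverse$cm_per_pixel))
  expect_equal(est$volume_ml, direct$volume_ml)
  expect_equal(est$source, "clinician_mask")
  e <- matrix(0, 4, 4)
  expect_warning(z <- estimate_from_pair(e, e, 0.05, 0.05), "empty")
  expect_equal(z$volume_ml, 0)
  # model-mask and clinician-mask paths share the computation
  em <- estimate_from_pair(v$sagittal$inner, v$transverse$inner,
                           v$sagittal$cm_per_pixel,
                           v$transverse$cm_per_pixel, source = "model_mask")
  expect_equal(em$volume_ml, est$volume_ml)
  expect_equal(em$source, "model_mask")
})

test_that("estimated volume is strictly monotone in true volume on spheres", {
  # noise-free concentric geometry: rank correlation must be exactly 1
  radii <- seq(1, 4, length.out = 8)
  vols <- vapply(radii, function(r) {
    cfg <- phantom_config(img_size = 64, axes_range_cm = c(r, r))
    s <- generate_phantoms(1, cfg, seed = 5)[[1]]
    estimate_from_pair(s$views$sagittal$inner, s$views$transverse$inner,
                       s$views$sagittal$cm_per_pixel,
                       s$views$transverse$cm_per_pixel)$volume_ml
  }, 0)
  true_v <- 4 / 3 * pi * radii^3
  expect_equal(cor(vols, true_v, method = "spearman"), 1)
})
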