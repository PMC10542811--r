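test_that("true volume is the exact ellipsoid volume", {
  # sphere of radius 2 cm: (4/3) * pi * 8
  cfg <- phantom_config(img_size = 64, axes_range_cm = c(2, 2))
  s <- generate_phantoms(1, cfg, seed = 7)[[1]]
  expect_equal(s$true_volume_ml, 4 / 3 * pi * 8, tolerance = 1e-12)
})

test_that("generation is bit-reproducible from the seed", {
  cfg <- phantom_config(img_size = 64)
  a <- generate_phantoms(5, cfg, seed = 9)
  b <- generate_phantoms(5, cfg, seed = 9)
  expect_identical(a, b)
  c <- generate_phantoms(5, cfg, seed = 10)
  expect_false(identical(a, c))
})

test_that("masks are consistent: inner inside outer, drawn before noise", {
  for (s in tiny_phantoms()) for (v in s$views) {
    expect_true(all(v$inner <= v$outer))
    expect_true(all(v$inner %in% c(0, 1)) && all(v$outer %in% c(0, 1)))
  }
})

test_that("inner mask area matches the analytic ellipse area", {
  # discretization error at the default scale stays below 2%
  for (size in c(64L, 224L)) {
    cfg <- phantom_config(img_size = size)
    ph <- generate_phantoms(3, cfg, seed = 11)
    for (s in ph) for (v in s$views) {
      measured <- mask_area(v$inner, v$cm_per_pixel)
      analytic <- pi * v$geom$rh * v$geom$rv
      expect_lt(abs(measured / analytic - 1), 0.02)
    }
  }
})

test_that("sagittal and transverse views share the ellipsoid's a axis", {
  for (s in tiny_phantoms()) {
    a <- s$semi_axes_cm[["a"]]
    expect_equal(s$views$sagittal$geom$rh, a)
    expect_equal(s$views$transverse$geom$rh, a)
    expect_equal(s$views$sagittal$geom$rv, s$semi_axes_cm[["c"]])
    expect_equal(s$views$transverse$geom$rv, s$semi_axes_cm[["b"]])
  }
})

test_that("speckle field has unit mean within 1% at full resolution", {
  # 224^2 pixels: the sample mean of unit-mean Rayleigh speckle is within
  # 1% with large margin (sd of the mean ~ 0.0023)
  for (s in generate_phantoms(3, phantom_config(img_size = 224), seed = 13))
    for (v in s$views)
      expect_lt(abs(mean(v$speckle) - 1), 0.01)
})

test_that("an anatomy too large for the field of view errors out", {
  cfg <- phantom_config(img_size = 64, axes_range_cm = c(20, 20))
  expect_error(generate_phantoms(1, cfg, seed = 1), "cannot fit")
})

test_that("degradation erases the wall sector but not the annotations", {
  cfg <- phantom_config(img_size = 64)
  s <- generate_phantoms(1, cfg, seed = 12)[[1]]
  expect_identical(degrade_phantom(s, 0, cfg), s)
  d <- degrade_phantom(s, 1, cfg)
  for (vn in names(s$views)) {
    v0 <- s$views[[vn]]; v1 <- d$views[[vn]]
    wall <- v0$outer > 0 & v0$inner == 0
    expect_true(all(v1$anatomy[wall] == cfg$background))
    expect_identical(v1$inner, v0$inner)          # masks stay ground truth
    expect_identical(v1$outer, v0$outer)
  }
  # partial degradation touches a strict subset of the wall
  dh <- degrade_phantom(s, 0.5, cfg)
  v <- dh$views$sagittal
  wall <- s$views$sagittal$outer > 0 & s$views$sagittal$inner == 0
  changed <- v$anatomy[wall] != s$views$sagittal$anatomy[wall]
  expect_gt(sum(changed), 0)
  expect_lt(sum(changed), sum(wall))
})

test_that("splits are disjoint by phantom instance and reproducible", {
  ph <- tiny_phantoms()
  sp1 <- split_phantoms(ph, seed = 3)
  sp2 <- split_phantoms(ph, seed = 3)
  ids <- lapply(sp1, function(g) vapply(g, function(s) s$id, 0L))
  expect_equal(length(unlist(ids)), length(ph))
  expect_equal(anyDuplicated(unlist(ids)), 0L)
  expect_identical(lapply(sp2, function(g) vapply(g, function(s) s$id, 0L)),
                   ids)
})

test_that("phantoms round-trip through PNG + JSON sidecars", {
  dir <- tempfile()
  ph <- tiny_phantoms()[1:2]
  write_phantoms(ph, dir)
  back <- read_phantoms(dir)
  expect_length(back, 2L)
  for (k in 1:2) {
    expect_identical(back[[k]]$views$sagittal$inner,
                     ph[[k]]$views$sagittal$inner)   # masks exact
    expect_equal(back[[k]]$true_volume_ml, ph[[k]]$true_volume_ml)
    expect_equal(back[[k]]$views$transverse$cm_per_pixel,
                 ph[[k]]$views$transverse$cm_per_pixel)
    expect_lt(max(abs(back[[k]]$views$sagittal$image -
                      ph[[k]]$views$sagittal$image)), 1 / 255)
  }
  unlink(dir, recursive = TRUE)
})
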