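test_that("configuration constraints are enforced", {
  expect_error(unet_config(100), "divisible")
  expect_error(unet_config(64, variant = "bq", skip_bits = 5), "3, 4, 6")
  expect_error(unet_config(64, out_channels = 3), "1 or 2")
  cfg <- unet_config(64, base_channels = 8, variant = "bq")
  expect_equal(cfg$skip_bits, 6L)                 # quantized default
  expect_equal(unet_config(64)$skip_bits, 32L)    # full-precision skips
})

test_that("layer precision follows the variant", {
  mk <- function(v) build_model(unet_config(64, 4, 8, variant = v), seed = 1)
  sfp <- model_layer_summary(mk("fp"))
  expect_equal(sum(sfp$binary), 0L)
  for (v in c("bfp", "bq")) {
    s <- model_layer_summary(mk(v))
    expect_equal(sum(!s$binary), 1L)              # only the first layer
    expect_identical(s$name[!s$binary], "stem")
  }
  sbq <- model_layer_summary(mk("bq"))
  expect_equal(sbq$weight_bits[sbq$name == "stem"], 4L)
})

test_that("fp and bfp variants have identical parameter tensor shapes", {
  m1 <- build_model(unet_config(64, 4, 8, variant = "fp"), seed = 1)
  m2 <- build_model(unet_config(64, 4, 8, variant = "bfp"), seed = 1)
  w1 <- m1$params[grep("\\.w$", names(m1$params))]
  w2 <- m2$params[grep("\\.w$", names(m2$params))]
  expect_identical(names(w1), names(w2))
  expect_identical(lapply(w1, dim), lapply(w2, dim))
})

test_that("forward produces full-size probability maps and depth skip stores", {
  set.seed(31)
  m <- build_model(unet_config(64, 4, 8, out_channels = 2, variant = "bfp"),
                   seed = 2)
  img <- matrix(runif(64 * 64), 64, 64)
  fw <- model_forward(m, img, collect_skips = TRUE)
  expect_equal(dim(fw$probs[[1]]), c(64L, 64L, 2L))
  expect_true(all(fw$probs[[1]] >= 0 & fw$probs[[1]] <= 1))
  expect_length(fw$skips, 4L)
  sides <- vapply(fw$skips, function(s) dim(s[[1]])[1], 0L)
  expect_equal(sides, c(32L, 16L, 8L, 4L))        # halving spatial sizes
  expect_error(model_forward(m, matrix(0, 32, 32)), "64x64")
})

test_that("predict_mask thresholds elementwise", {
  expect_true(all(predict_mask(array(0.9, c(4, 4, 1))) == 1))
  expect_true(all(predict_mask(array(0.1, c(4, 4, 1))) == 0))
  set.seed(32)
  p <- array(runif(5 * 5 * 2), c(5, 5, 2))
  m <- predict_mask(p, 0.4)
  for (i in seq_along(p)) expect_equal(m[i], as.numeric(p[i] > 0.4))
})

test_that("quantized outputs approach binarized outputs as skip bits grow", {
  set.seed(33)
  mb <- build_model(unet_config(64, 4, 8, variant = "bfp"), seed = 3)
  imgs <- lapply(1:4, function(i) matrix(runif(64 * 64), 64, 64))
  m6 <- convert_bfp_to_bq(mb, 6L, imgs)
  m4 <- convert_bfp_to_bq(mb, 4L, imgs)
  pb <- model_forward(mb, imgs)$probs
  p6 <- model_forward(m6, imgs)$probs
  p4 <- model_forward(m4, imgs)$probs
  d6 <- mean(mapply(function(a, b) mean(abs(a - b)), pb, p6))
  d4 <- mean(mapply(function(a, b) mean(abs(a - b)), pb, p4))
  expect_lt(d6, d4)
})

test_that("quantization plan serializes through YAML and JSON", {
  plan <- quant_plan(unet_config(64, variant = "bq", skip_bits = 4))
  expect_match(plan$bq[plan$component == "skip connections"], "4-bit")
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_quant_plan(plan, f)
    back <- read_quant_plan(f)
    expect_equal(as.data.frame(lapply(back, as.character)),
                 as.data.frame(lapply(plan, as.character)))
    unlink(f)
  }
})

test_that("checkpoints reload bit-exactly, storing codes for bq", {
  set.seed(34)
  img <- matrix(runif(64 * 64), 64, 64)
  mb <- build_model(unet_config(64, 4, 8, variant = "bfp"), seed = 4)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(mb, f)
  mb2 <- load_checkpoint(f)
  expect_identical(model_forward(mb2, img)$probs, model_forward(mb, img)$probs)

  mq <- convert_bfp_to_bq(mb, 6L, list(img))
  save_checkpoint(mq, f)
  ck <- readRDS(f)
  expect_equal(ck$kind, "bq_codes")
  expect_true(all(vapply(ck$codes, is.integer, TRUE)))   # codes, not reals
  mq2 <- load_checkpoint(f)
  expect_identical(model_forward(mq2, img)$probs, model_forward(mq, img)$probs)
  unlink(f)
})

test_that("binary +-1 convolution equals the XNOR/popcount formulation", {
  set.seed(35)
  for (rep in 1:25) {
    cin <- sample(1:4, 1); cout <- sample(1:4, 1)
    H <- sample(4:9, 1); k <- sample(c(1L, 3L), 1)
    stride <- sample(1:2, 1)
    x <- array(sign(rnorm(H * H * cin)), c(H, H, cin))
    w <- array(sign(rnorm(k * k * cin * cout)), c(k, k, cin, cout))
    expect_identical(binary_conv2d(x, w, stride),
                     xnor_popcount_conv2d(x, w, stride))
  }
})

test_that("guarded fixed-point inference agrees exactly with the engine", {
  set.seed(36)
  m <- build_model(unet_config(64, 4, 8, variant = "bq", skip_bits = 6),
                   seed = 5)
  img <- matrix(runif(64 * 64), 64, 64)
  g <- guarded_forward(m, img)
  expect_true(g$all_ok)
  expect_true(all(g$guard$grid_exact))
  expect_true(all(g$guard$scales_fixed_point))
  fw <- model_forward(m, img)
  expect_equal(max(abs(fw$probs[[1]] - g$probs)), 0)
  expect_error(guarded_forward(build_model(unet_config(64, 4, 8), seed = 1),
                               img), "quantized")
})
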