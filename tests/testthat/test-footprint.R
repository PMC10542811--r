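test_that("parameter memory counts single layers by hand", {
  # depthwise 3x3 over 128 channels: 9 * 128 weights
  m <- build_model(unet_config(224, 4, 16, variant = "bfp"), seed = 1)
  pm <- param_memory(m)$per_layer
  expect_equal(pm$bits[pm$name == "e4.dw"], 9 * 128 * 1)      # 1152 binary
  mfp <- build_model(unet_config(224, 4, 16, variant = "fp"), seed = 1)
  pf <- param_memory(mfp)$per_layer
  expect_equal(pf$bits[pf$name == "e4.dw"], 9 * 128 * 32)     # 36864 FP
  # pointwise 16 -> 32 binary: one bit per weight
  expect_equal(pm$bits[pm$name == "e1.pw"], 16 * 32)
  # totals are the sums of the parts
  expect_equal(param_memory(m)$total_bits, sum(pm$bits))
})

test_that("quantized parameters always undercut full precision", {
  for (bc in c(8L, 16L)) {
    fp <- param_memory(build_model(unet_config(64, 4, bc, variant = "fp"),
                                   seed = 1))$total_bits
    bq <- param_memory(build_model(unet_config(64, 4, bc, variant = "bq"),
                                   seed = 1))$total_bits
    expect_lt(bq, fp)
  }
})

test_that("inference memory counts skip values at their bitwidths", {
  m6 <- build_model(unet_config(224, 4, 16, variant = "bq", skip_bits = 6),
                    seed = 1)
  im <- inference_memory(m6)
  # connection 1: 112 x 112 x 16 values at 6 bits + 1-bit binarized store
  expect_equal(im$per_connection$stored_bits[1], 112^2 * 16 * 6)
  expect_equal(im$per_connection$binarized_bits[1], 112^2 * 16)
  expect_equal(im$total_bits,
               sum(im$per_connection$stored_bits) +
                 sum(im$per_connection$binarized_bits))
  # full-precision skips are 32/q times the raw q-bit payload
  mfp <- build_model(unet_config(224, 4, 16, variant = "fp"), seed = 1)
  imf <- inference_memory(mfp)
  expect_equal(imf$per_connection$stored_bits[1],
               im$per_connection$stored_bits[1] * 32 / 6)
  expect_equal(imf$binarized_store_bits, 0)
})

test_that("MAC counting follows the a-bit x b-bit rule", {
  m <- build_model(unet_config(64, 4, 8, variant = "bq", skip_bits = 6),
                   seed = 1)
  mc <- mac_count(m)
  pl <- mc$per_layer
  # stem: 4-bit x 4-bit = 16 equivalent binary MACs each, at 32x32 positions
  stem <- pl[pl$name == "stem", ]
  expect_equal(stem$macs, 32^2 * 9 * 8)
  expect_equal(stem$equivalent_binary_macs, 16 * stem$macs)
  # binary depthwise conv at 16x16 on 8 channels
  e1 <- pl[pl$name == "e1.dw", ]
  expect_equal(e1$macs, 16^2 * 9 * 8)
  expect_equal(e1$equivalent_binary_macs, e1$macs)
  # binary pointwise 16 -> 8 at 32x32 (decoder level 1, after upsample)
  d1 <- pl[pl$name == "d1.pw1", ]
  expect_equal(d1$macs, 32^2 * 16 * 8)
  expect_equal(mc$fp_macs, 0)                      # no FP MACs in bq
  expect_equal(mc$equivalent_binary_macs, sum(pl$equivalent_binary_macs))

  mfp <- build_model(unet_config(64, 4, 8, variant = "fp"), seed = 1)
  mcf <- mac_count(mfp)
  expect_equal(mcf$equivalent_binary_macs, 0)      # FP model: no binary MACs
  expect_equal(mcf$fp_macs, sum(mcf$per_layer$macs))
})

test_that("accounting is structure-only (weight values are irrelevant)", {
  cfg <- unet_config(64, 4, 8, variant = "bq")
  a <- build_model(cfg, seed = 1); b <- build_model(cfg, seed = 99)
  expect_identical(param_memory(a), param_memory(b))
  expect_identical(mac_count(a)$per_layer, mac_count(b)$per_layer)
  expect_identical(inference_memory(a), inference_memory(b))
})

test_that("full-precision to quantized memory reduction exceeds 8x", {
  r <- memory_reduction_ratio(skip_bits = 4L)      # default architecture
  expect_gt(r$ratio, 8)
  # binarization alone leaves the skip memory dominant
  mb <- build_model(unet_config(224, 4, 16, variant = "bfp"), seed = 1)
  expect_gt(inference_memory(mb)$total_bits / param_memory(mb)$total_bits, 1)
})

test_that("compressed skip sizing equals a brute-force worst case", {
  set.seed(61)
  m <- build_model(unet_config(64, 4, 8, variant = "bq", skip_bits = 6),
                   seed = 2)
  imgs <- lapply(tiny_phantoms(n = 4, size = 64), function(s)
    s$views$sagittal$image)
  comp <- inference_memory(m, codec = "zvc", dataset = imgs)
  fw <- model_forward(m, imgs, collect_skips = TRUE)
  for (i in 1:4) {
    sh <- m$buffers[[paste0("skip", i, ".shift")]]
    brute <- max(vapply(fw$skips[[i]], function(v) {
      codes <- array(as.integer(round(v / 2^sh)), dim = dim(v))
      codec_size_bits(codec_encode(codes, "zvc", bits = 6))
    }, 0))
    expect_equal(comp$per_connection$stored_bits[i], brute)
  }
  expect_error(inference_memory(m, codec = "zvc"), "dataset")
})
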