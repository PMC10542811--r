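test_that("rsign binarizes with the strict-greater tie rule", {
  expect_equal(rsign(c(0.3, -0.1, 0.2), 0.2), c(1, -1, -1))
  x <- matrix(rnorm(16), 4, 4)
  expect_true(all(rsign(x, min(x) - 1) == 1))   # threshold below the minimum
  expect_true(all(rsign(x, max(x)) == -1))      # x == alpha maps to -1
})

test_that("rsign matches a scalar loop oracle on multi-channel input", {
  set.seed(11)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  alpha <- rnorm(3)
  got <- rsign(x, alpha)
  for (c in 1:3) for (i in 1:8) for (j in 1:8)
    expect_identical(got[i, j, c], if (x[i, j, c] > alpha[c]) 1 else -1)
})

test_that("rsign rejects channel mismatch", {
  expect_error(rsign(array(0, c(4, 4, 3)), c(0, 0)), "channel mismatch")
})

test_that("binarize_weights thresholds each channel at its mean", {
  expect_equal(as.numeric(binarize_weights(matrix(c(0.5, -0.5, 1), 1, 3))),
               c(1, -1, 1))
  # a constant channel sits on the threshold and maps to all -1
  expect_true(all(binarize_weights(matrix(2, 3, 5)) == -1))
  expect_error(binarize_weights(matrix(numeric(0), 0, 0)), "empty")
})

test_that("binarize_weights matches a per-channel loop oracle", {
  set.seed(12)
  W <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  got <- binarize_weights(W, channel_dim = 1L)
  for (ch in 1:4) {
    mu <- mean(W[ch, , ])
    expect_identical(got[ch, , ], ifelse(W[ch, , ] > mu, 1, -1))
  }
})

test_that("prelu is continuous at the knee and matches hand evaluation", {
  for (beta in c(0, 0.25, 0.7)) {
    expect_equal(prelu(1.5, beta, gamma = 1.5, eta = -0.3), -0.3)
  }
  x <- seq(-2, 2, by = 0.25)
  expect_equal(prelu(x, beta = 1, gamma = 0, eta = 0), x)   # identity case
  expect_equal(prelu(c(0, 3), beta = 0.5, gamma = 1, eta = 2), c(1.5, 4.0))
  # piecewise linear with exactly two slopes {1, beta}
  f <- function(v) prelu(v, 0.25, 0.5, 1)
  eps <- 1e-6
  expect_equal((f(2 + eps) - f(2)) / eps, 1, tolerance = 1e-4)
  expect_equal((f(-1 + eps) - f(-1)) / eps, 0.25, tolerance = 1e-4)
  # continuity at the knee from both sides
  expect_equal(f(0.5 + 1e-12), f(0.5), tolerance = 1e-9)
})

test_that("bn_to_shiftnorm rounds log2 of the scale and absorbs the sign", {
  expect_equal(bn_to_shiftnorm(4)$shift, 2L)
  expect_equal(bn_to_shiftnorm(0.3)$shift, -2L)   # log2(0.3) = -1.737 -> -2
  sn <- bn_to_shiftnorm(-3)
  expect_equal(sn$shift, 2L)                      # round(log2(3)) = round(1.585)
  expect_equal(sn$sign, -1)
  expect_error(bn_to_shiftnorm(0), "nonzero")
})

test_that("shift-norm scale is within sqrt(2) of the source scale", {
  set.seed(13)
  w <- exp(runif(500, log(2^-7.4), log(2^6.4)))   # inside the clamp range
  s <- bn_to_shiftnorm(w)$shift
  ratio <- 2^s / w
  expect_true(all(ratio >= 1 / sqrt(2) & ratio <= sqrt(2)))
})

test_that("quantize_skip round-trips grid-aligned values and clamps", {
  x <- c(0, 1, 2, 5, 15) * 2^-3
  fp <- quantize_skip(x, bits = 4, shift = -3L)
  expect_equal(fp_decode(fp), x)
  # repeated quantization of a decoded tensor is the identity on codes
  fp2 <- quantize_skip(fp_decode(fp), bits = 4, shift = fp$shift)
  expect_identical(fp2$codes, fp$codes)
  expect_identical(quantize_skip(c(15.4, 16.2), 4, shift = 0L)$codes,
                   c(15L, 15L))
})

test_that("quantize_skip calibration bounds the error by half a step", {
  set.seed(14)
  x <- abs(rnorm(200))
  fp <- quantize_skip(x, bits = 6)
  dec <- fp_decode(fp)
  unclamped <- fp$codes > 0 & fp$codes < 63
  expect_true(all(abs(dec - x)[unclamped] <= 2^(fp$shift - 1) + 1e-12))
  expect_true(max(x) <= (2^6 - 1) * 2^fp$shift)   # max decodes w/o overflow
  expect_warning(quantize_skip(rep(0, 5), 4), "all-zero")
})

test_that("separately stored binarized skip equals rsign of the decode", {
  set.seed(15)
  x <- array(abs(rnorm(6 * 6 * 2)), c(6, 6, 2))
  fp <- quantize_skip(x, bits = 4)
  alpha <- c(0.3, 0.8)
  expect_identical(binarize_skip_separately(fp, alpha),
                   rsign(fp_decode(fp), alpha))
  expect_true(all(binarize_skip_separately(fp, c(-10, -10)) == 1))
})

test_that("sign surrogates match their definitions", {
  expect_equal(ste_surrogate_grad(0, "tanh2x"), 2)
  expect_equal(ste_surrogate_grad(c(0.5, 2), "ste"), c(1, 0))
  expect_error(ste_surrogate_grad(0, "nope"))
  # numeric differentiation of tanh(2x)
  set.seed(16)
  x <- rnorm(50)
  h <- 1e-6
  fd <- (tanh(2 * (x + h)) - tanh(2 * (x - h))) / (2 * h)
  expect_equal(ste_surrogate_grad(x, "tanh2x"), fd, tolerance = 1e-5)
})
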