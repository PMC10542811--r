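test_that("ZVC matches the hand-computed example and its size formula", {
  st <- codec_encode(c(0L, 5L, 0L, 3L, 0L), "zvc", bits = 4)
  expect_equal(codec_size_bits(st), 13)            # 5 flags + 2 * 4
  expect_identical(codec_decode(st), c(0L, 5L, 0L, 3L, 0L))
  # all-zero input costs exactly one flag bit per value
  st0 <- codec_encode(rep(0L, 37), "zvc", bits = 6)
  expect_equal(codec_size_bits(st0), 37)
  expect_identical(codec_decode(st0), rep(0L, 37))
})

test_that("DZVC matches the hand-computed example and its size formula", {
  st <- codec_encode(c(7L, 7L, 7L, 0L, 2L), "dzvc", bits = 4)
  expect_equal(codec_size_bits(st), 17)            # 5 flags + 3 new * 4
  expect_identical(codec_decode(st), c(7L, 7L, 7L, 0L, 2L))
  # constant tensor: one transmitted value
  stc <- codec_encode(rep(9L, 50), "dzvc", bits = 4)
  expect_equal(codec_size_bits(stc), 50 + 4)
})

test_that("all codecs round-trip across value regimes and bitwidths", {
  set.seed(21)
  for (q in c(3L, 4L, 6L)) for (regime in c("uniform", "sparse", "plateau")) {
    for (rep in 1:4) {
      n <- sample(40:400, 1)
      x <- random_codes(n, q, regime)
      for (cd in c("zvc", "dzvc", "bpc8", "bpc16", "ebpc")) {
        st <- codec_encode(x, cd, bits = q)
        expect_identical(codec_decode(st), as.integer(x),
                         info = sprintf("%s q=%d %s n=%d", cd, q, regime, n))
      }
    }
  }
})

test_that("codecs round-trip 3-d tensors with shape restored", {
  set.seed(22)
  x <- array(random_codes(8 * 8 * 3, 4L, "sparse"), c(8, 8, 3))
  for (cd in c("zvc", "dzvc", "bpc16", "ebpc")) {
    y <- codec_decode(codec_encode(x, cd, bits = 4))
    expect_identical(y, array(as.integer(x), dim(x)))
  }
})

test_that("ZVC/DZVC sizes equal their closed forms on random tensors", {
  set.seed(23)
  for (rep in 1:20) {
    q <- sample(c(3L, 4L, 6L), 1)
    n <- sample(30:300, 1)
    x <- random_codes(n, q, sample(c("uniform", "sparse", "plateau"), 1))
    expect_equal(codec_size_bits(codec_encode(x, "zvc", bits = q)),
                 n + q * sum(x != 0))
    nnew <- 1 + sum(x[-1] != x[-n])
    expect_equal(codec_size_bits(codec_encode(x, "dzvc", bits = q)),
                 n + q * nnew)
  }
})

test_that("sparser input never increases the ZVC size", {
  set.seed(24)
  x <- random_codes(256, 4L, "uniform")
  sizes <- vapply(c(0, 0.3, 0.6, 0.9), function(f) {
    y <- x
    y[seq_len(round(f * length(y)))] <- 0L
    codec_size_bits(codec_encode(y, "zvc", bits = 4))
  }, 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("DZVC beats ZVC when nonzero plateaus dominate", {
  set.seed(25)
  for (rep in 1:5) {
    x <- integer(0)
    while (length(x) < 300)                        # long nonzero plateaus
      x <- c(x, rep(sample(1:15, 1), sample(10:25, 1)))
    x <- x[1:300]
    expect_lt(codec_size_bits(codec_encode(x, "dzvc", bits = 4)),
              codec_size_bits(codec_encode(x, "zvc", bits = 4)))
  }
})

test_that("BPC compresses all-zero blocks below raw size", {
  for (block in c("bpc8", "bpc16")) for (q in c(3L, 6L)) {
    n <- 64L
    st <- codec_encode(rep(0L, n), block, bits = q)
    expect_lt(codec_size_bits(st), n * q)
    expect_identical(codec_decode(st), rep(0L, n))
  }
})

test_that("BPC worst-case expansion is bounded per block", {
  set.seed(26)
  # incompressible full-width uniform data: per plane at most 1 extra bit,
  # q+1 planes per block, base value always raw
  for (rep in 1:10) {
    q <- sample(c(3L, 4L, 6L), 1)
    block <- sample(c(8L, 16L), 1)
    n <- block * sample(3:10, 1)
    x <- random_codes(n, q, "uniform")
    cd <- if (block == 8L) "bpc8" else "bpc16"
    size <- codec_size_bits(codec_encode(x, cd, bits = q))
    nblocks <- n / block
    # per block at worst: raw base (q bits) + q+1 planes at 1 + (block-1) bits
    bound <- nblocks * (q + (q + 1) * block)
    expect_lte(size, bound)
  }
})

test_that("EBPC equals flags-only on zeros and beats ZVC on sparse-smooth data", {
  st <- codec_encode(rep(0L, 100), "ebpc", bits = 6)
  expect_equal(codec_size_bits(st), 100)
  set.seed(27)
  for (rep in 1:5) {
    # sparse with smooth (plateau-valued) nonzero runs
    x <- integer(0)
    while (length(x) < 400) {
      x <- c(x, rep(0L, sample(5:30, 1)),
             rep(sample(1:40, 1), sample(8:20, 1)))
    }
    x <- pmin(x[1:400], 63L)
    expect_lte(codec_size_bits(codec_encode(x, "ebpc", bits = 6)),
               codec_size_bits(codec_encode(x, "zvc", bits = 6)))
  }
})

test_that("worst_case_size equals exhaustive per-sample recomputation", {
  set.seed(28)
  tensors <- lapply(1:7, function(i) random_codes(96, 4L, "sparse"))
  got <- worst_case_size(tensors, "zvc", 4L)
  brute <- max(vapply(tensors, function(x)
    codec_size_bits(codec_encode(x, "zvc", bits = 4)), 0))
  expect_equal(got, ceiling(brute / 8))
  expect_equal(worst_case_size(tensors[3], "zvc", 4L),
               ceiling(codec_size_bits(codec_encode(tensors[[3]], "zvc",
                                                    bits = 4)) / 8))
  # grouped samples: totals are summed before the max
  grouped <- list(tensors[1:2], tensors[3:4])
  gsize <- worst_case_size(grouped, "zvc", 4L)
  s12 <- sum(vapply(tensors[1:2], function(x)
    codec_size_bits(codec_encode(x, "zvc", bits = 4)), 0))
  s34 <- sum(vapply(tensors[3:4], function(x)
    codec_size_bits(codec_encode(x, "zvc", bits = 4)), 0))
  expect_equal(gsize, ceiling(max(s12, s34) / 8))
})

test_that("corrupt streams fail loudly instead of decoding silently", {
  st <- codec_encode(c(1L, 2L, 3L, 0L, 5L), "zvc", bits = 4)
  st$nbits <- st$nbits - 4
  expect_error(codec_decode(st), "corrupt|past end")
})
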