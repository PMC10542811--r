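# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# a small phantom cohort at reduced resolution
tiny_phantoms <- function(n = 12L, size = 64L, seed = 42L) {
  cached(sprintf("ph_%d_%d_%d", n, size, seed),
         generate_phantoms(n, phantom_config(img_size = size), seed = seed))
}

# random unsigned q-bit code tensors in the three regimes the codecs target
random_codes <- function(n, q, regime = c("uniform", "sparse", "plateau")) {
  regime <- match.arg(regime)
  switch(regime,
    uniform = sample(0:(2^q - 1), n, replace = TRUE),
    sparse = {
      v <- sample(0:(2^q - 1), n, replace = TRUE)
      v[stats::runif(n) < stats::runif(1, 0.7, 0.95)] <- 0L
      v
    },
    plateau = {
      v <- integer(0)
      while (length(v) < n)
        v <- c(v, rep(sample(0:(2^q - 1), 1L), sample(1:20, 1L)))
      v[seq_len(n)]
    })
}

# the scaled-down precision-ladder experiment, run once per test session
ladder_experiment <- function() {
  cached("ladder", run_scaled_experiment(seed = 1L))
}
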