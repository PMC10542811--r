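#' Thresholded sign binarization (RSign)
#'
#' Binarizes activations against a learned per-channel threshold
#' \eqn{\alpha}: values strictly greater than the threshold map to +1,
#' values less than or equal to it map to -1.
#'
#' @param x Numeric vector, matrix or array. If `x` has three dimensions the
#'   last dimension is the channel dimension; otherwise a single channel is
#'   assumed and `alpha` must have length 1.
#' @param alpha Per-channel threshold(s). Length must equal the channel count
#'   of `x`.
#' @param quantized If `TRUE`, thresholds are first snapped to the 4-bit
#'   signed fixed-point grid used by the fully quantized model (step
#'   \eqn{2^{-2}}, codes in \eqn{[-8, 7]}, i.e. values in \eqn{[-2, 1.75]}).
#' @return An object shaped like `x` with entries in `{-1, +1}`.
#' @export
rsign <- function(x, alpha, quantized = FALSE) {
  nc <- n_channels(x)
  if (length(alpha) == 1L) alpha <- rep(alpha, nc)
  if (length(alpha) != nc)
    stop("channel mismatch: x has ", nc, " channels, alpha has length ",
         length(alpha))
  if (quantized) alpha <- quantize_grid(alpha, 2^-2, -8, 7)
  out <- sweep_channels(x, alpha, function(v, a) ifelse(v > a, 1, -1))
  out
}

#' Per-channel mean-threshold weight binarization
#'
#' Each output channel of a weight tensor is binarized against the mean of
#' that channel's weights: weights strictly above the mean map to +1, weights
#' less than or equal to the mean map to -1 (so a constant channel maps to
#' all -1).
#'
#' @param W Numeric array; `channel_dim` indexes output channels (default:
#'   leading dimension).
#' @param channel_dim Which dimension of `W` is the output-channel dimension.
#' @return A `{-1, +1}` tensor of the same shape as `W`.
#' @export
binarize_weights <- function(W, channel_dim = 1L) {
  if (is.null(dim(W))) W <- matrix(W, nrow = 1L)
  d <- dim(W)
  if (channel_dim < 1L || channel_dim > length(d)) stop("bad channel_dim")
  if (any(d == 0L)) stop("empty channel")
  mu <- apply(W, channel_dim, mean)
  sw <- sweep(W, channel_dim, mu, FUN = function(w, m) ifelse(w > m, 1, -1))
  sw
}

#' Parametrized ReLU with knee and offset
#'
#' Piecewise-linear activation with per-channel slope `beta` below the knee
#' `gamma`, unit slope above it, and offset `eta`:
#' \deqn{f(x) = (x-\gamma)+\eta \ \mathrm{if}\ x > \gamma; \quad
#'       \beta(x-\gamma)+\eta \ \mathrm{if}\ x \le \gamma.}
#' The two branches agree at \eqn{x=\gamma} (both evaluate to \eqn{\eta}), so
#' the function is continuous with exactly two slopes.
#'
#' @param x Numeric vector/matrix/array (last dimension = channels for 3-d).
#' @param beta,gamma,eta Per-channel parameters (scalars are recycled).
#' @param quantized If `TRUE`, parameters are snapped to the quantized grids:
#'   `beta` to the 2-bit grid `{0, 0.25, 0.5, 0.75}`, `gamma` and `eta` to
#'   4-bit signed codes times `2^gamma_step` / `2^eta_step`.
#' @param gamma_step,eta_step Per-layer power-of-two step exponents for the
#'   quantized `gamma`/`eta` grids.
#' @return Activated tensor of the same shape as `x`.
#' @export
prelu <- function(x, beta, gamma, eta, quantized = FALSE,
                  gamma_step = 0L, eta_step = 0L) {
  nc <- n_channels(x)
  beta <- rep_len(beta, nc); gamma <- rep_len(gamma, nc); eta <- rep_len(eta, nc)
  if (quantized) {
    beta <- quantize_grid(beta, 2^-2, 0, 3)
    gamma <- quantize_grid(gamma, 2^gamma_step, -8, 7)
    eta <- quantize_grid(eta, 2^eta_step, -8, 7)
  }
  sweep_channels3(x, beta, gamma, eta, function(v, b, g, e)
    ifelse(v > g, (v - g) + e, b * (v - g) + e))
}

#' Convert BatchNorm scale/bias to a binary-shift normalization
#'
#' Replaces the per-channel BatchNorm multiplication by `w` with a bit shift
#' \eqn{s = \mathrm{clamp}(\mathrm{round}(\log_2 |w|), -8, 7)} and quantizes
#' the bias to a 4-bit signed code times a per-layer power-of-two step. The
#' sign of `w` is returned as a per-channel flag for the caller to fold into
#' the preceding binary convolution's weights.
#'
#' @param w Per-channel scale (finite, nonzero).
#' @param b Per-channel bias.
#' @param bias_step Power-of-two exponent of the bias grid; if `NULL` it is
#'   calibrated as the smallest step whose 4-bit code range covers
#'   `max(abs(b))`.
#' @param clamp Two-element integer range for the shift exponent.
#' @return A list with `shift` (integer exponents), `sign` (per-channel
#'   `+-1`), `bias_code` (integer codes in `[-8, 7]`), `bias_step` and the
#'   decoded `bias` values.
#' @export
bn_to_shiftnorm <- function(w, b = rep(0, length(w)), bias_step = NULL,
                            clamp = c(-8L, 7L)) {
  if (any(!is.finite(w)) || any(w == 0))
    stop("shift norm undefined: scale must be finite and nonzero")
  s <- pmin(pmax(round_q(log2(abs(w))), clamp[1]), clamp[2])
  if (is.null(bias_step)) bias_step <- calibrate_step(b, 7)
  code <- pmin(pmax(round_q(b / 2^bias_step), -8), 7)
  list(shift = as.integer(s), sign = ifelse(w > 0, 1, -1),
       bias_code = as.integer(code), bias_step = as.integer(bias_step),
       bias = code * 2^bias_step)
}

#' Quantize a post-activation feature map to unsigned fixed point
#'
#' Skip-connection values are stored as unsigned q-bit codes with one
#' power-of-two scale (`shift`) per connection:
#' `code = clamp(round(x / 2^shift), 0, 2^q - 1)`. When `shift` is not
#' supplied it is calibrated so the observed maximum decodes without
#' overflow: `shift = ceiling(log2(max(x) / (2^q - 1)))`.
#'
#' @param x Numeric array of post-activation values.
#' @param bits Code bitwidth q (>= 1).
#' @param shift Optional fixed scale exponent; calibrated from `x` if `NULL`.
#' @return A `fp_tensor`: list of integer `codes`, `bits`, `signed = FALSE`
#'   and `shift`, with the original shape retained.
#' @export
quantize_skip <- function(x, bits, shift = NULL) {
  stopifnot(bits >= 1)
  if (is.null(shift)) {
    mx <- max(x)
    if (mx <= 0) {
      warning("all-zero (or non-positive) calibration input; shift set to 0")
      shift <- 0L
    } else shift <- as.integer(ceiling(log2(mx / (2^bits - 1))))
  }
  codes <- as.integer(pmin(pmax(round_q(x / 2^shift), 0), 2^bits - 1))
  dim(codes) <- dim(x)
  structure(list(codes = codes, bits = as.integer(bits), signed = FALSE,
                 shift = as.integer(shift)),
            class = "fp_tensor")
}

#' Decode a fixed-point tensor to real values
#'
#' @param fp An `fp_tensor` from [quantize_skip()].
#' @return Numeric array `codes * 2^shift` (exact).
#' @export
fp_decode <- function(fp) {
  stopifnot(inherits(fp, "fp_tensor"))
  out <- fp$codes * 2^fp$shift
  dim(out) <- dim(fp$codes)
  out
}

#' @export
print.fp_tensor <- function(x, ...) {
  cat(sprintf("<fp_tensor> %s-bit %s, shift 2^%d, %s values\n", x$bits,
              if (x$signed) "signed" else "unsigned", x$shift,
              length(x$codes)))
  invisible(x)
}

#' Separately stored binarized skip connection
#'
#' The decoder consumes an RSign of each skip connection, but the 4-bit
#' threshold grid is incompatible with the skip connection's own scale, so
#' the 1-bit binarized version is computed once at encode time and stored
#' alongside the quantized skip (one extra bit per value).
#'
#' @param fp Quantized skip connection (`fp_tensor`).
#' @param alpha RSign threshold(s), one per channel of the decoded tensor.
#' @param quantized Snap `alpha` to the 4-bit threshold grid first.
#' @return `{-1, +1}` array equal to `rsign(fp_decode(fp), alpha)`.
#' @export
binarize_skip_separately <- function(fp, alpha, quantized = FALSE) {
  rsign(fp_decode(fp), alpha, quantized = quantized)
}

#' Backward-pass surrogate for the sign nonlinearity
#'
#' The sign function has zero derivative almost everywhere, so training uses
#' a surrogate gradient: the straight-through estimator (pass-through,
#' clipped to `|x| <= 1`) or the derivative of `tanh(2x)`,
#' `2 (1 - tanh(2x)^2)`.
#'
#' @param x Pre-binarization values.
#' @param mode `"ste"` or `"tanh2x"`.
#' @return Elementwise surrogate derivative, same shape as `x`.
#' @export
ste_surrogate_grad <- function(x, mode = c("ste", "tanh2x")) {
  mode <- match.arg(mode)
  if (mode == "ste") {
    out <- as.numeric(abs(x) <= 1)
  } else {
    th <- tanh(2 * x)
    out <- 2 * (1 - th^2)
  }
  dim(out) <- dim(x)
  out
}

# ---- internal helpers -------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

# round half away from zero (the hardware convention used by all quantizers
# here; base R's round() rounds half to even)
round_q <- function(x) sign(x) * floor(abs(x) + 0.5)

n_channels <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) < 3L) 1L else d[length(d)]
}

# snap values to code * step with integer codes clamped to [lo, hi]
quantize_grid <- function(x, step, lo, hi) {
  pmin(pmax(round_q(x / step), lo), hi) * step
}

# smallest power-of-two step exponent whose [-(maxcode+1), maxcode] code range
# covers max(abs(v))
calibrate_step <- function(v, maxcode) {
  mx <- max(abs(v))
  if (mx == 0) return(0L)
  as.integer(ceiling(log2(mx / maxcode)))
}

# apply f(values, par) channelwise; x is vector/matrix (1 channel) or 3-d array
sweep_channels <- function(x, par, f) {
  d <- dim(x)
  if (is.null(d) || length(d) < 3L) return(f(x, par[1L]))
  out <- x
  for (c in seq_len(d[3])) out[, , c] <- f(x[, , c], par[c])
  out
}

sweep_channels3 <- function(x, p1, p2, p3, f) {
  d <- dim(x)
  if (is.null(d) || length(d) < 3L) return(f(x, p1[1L], p2[1L], p3[1L]))
  out <- x
  for (c in seq_len(d[3])) out[, , c] <- f(x[, , c], p1[c], p2[c], p3[c])
  out
}
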