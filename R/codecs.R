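#' Lossless compression of quantized feature maps
#'
#' Encodes unsigned q-bit integer codes with one of the skip-connection
#' compression schemes:
#' \describe{
#'   \item{`zvc`}{zero-value compression: one flag bit per value (1 =
#'     nonzero) followed by the q-bit codes of the nonzero values. Payload
#'     size is exactly `n + q * nnz` bits.}
#'   \item{`dzvc`}{differential ZVC: the flag marks whether the value differs
#'     from its predecessor in scan order (each channel's first value is
#'     always transmitted); only new values are stored. Payload size is
#'     exactly `n + q * n_new` bits.}
#'   \item{`bpc8`, `bpc16`}{bit-plane compression with block size 8 or 16:
#'     per block, the first value is sent raw and the successive deltas are
#'     bit-plane transposed, XORed between adjacent planes and coded with a
#'     prefix-free symbol table (documented in the package vignette).}
#'   \item{`ebpc`}{extended BPC: ZVC first, then BPC (block 16) on the
#'     nonzero payload.}
#' }
#' Scan order is channel-major, then row-major within each channel. Sizes
#' are payload bits; the descriptive header is kept in R and excluded from
#' size accounting (buffer provisioning is payload-oriented).
#'
#' @param x Integer vector/matrix/array of unsigned codes, or an
#'   `fp_tensor` from [quantize_skip()] (its `bits` then provides `bits`).
#' @param codec One of `"zvc"`, `"dzvc"`, `"bpc8"`, `"bpc16"`, `"ebpc"`.
#' @param bits Code bitwidth q (required unless `x` is an `fp_tensor`).
#' @return A `bitstream` object: raw `bytes`, payload `nbits` and a header.
#' @export
codec_encode <- function(x, codec = c("zvc", "dzvc", "bpc8", "bpc16", "ebpc"),
                         bits = NULL) {
  codec <- match.arg(codec)
  if (inherits(x, "fp_tensor")) {
    bits <- bits %||% x$bits
    x <- x$codes
  }
  if (is.null(bits)) stop("bits (code bitwidth) is required")
  shape <- dim(x) %||% length(x)
  sc <- flatten_scan(x)
  enc <- switch(codec,
    zvc = .cx_zvc_encode(sc$codes, bits),
    dzvc = .cx_dzvc_encode(sc$codes, bits, sc$chan_sizes),
    bpc8 = .cx_bpc_encode(sc$codes, bits, 8L),
    bpc16 = .cx_bpc_encode(sc$codes, bits, 16L),
    ebpc = .cx_ebpc_encode(sc$codes, bits, 16L))
  structure(list(bytes = enc$bytes, nbits = enc$nbits,
                 header = list(codec = codec, bits = as.integer(bits),
                               shape = shape, n = length(sc$codes),
                               chan_sizes = sc$chan_sizes,
                               scan = "channel-row-major")),
            class = "bitstream")
}

#' Decode a compressed bitstream
#'
#' Exact inverse of [codec_encode()]; restores the original shape.
#'
#' @param stream A `bitstream` object.
#' @return Integer array of codes identical to the encoder input.
#' @export
codec_decode <- function(stream) {
  stopifnot(inherits(stream, "bitstream"))
  h <- stream$header
  codes <- switch(h$codec,
    zvc = .cx_zvc_decode(stream$bytes, stream$nbits, h$n, h$bits),
    dzvc = .cx_dzvc_decode(stream$bytes, stream$nbits, h$bits, h$chan_sizes),
    bpc8 = .cx_bpc_decode(stream$bytes, stream$nbits, h$n, h$bits, 8L),
    bpc16 = .cx_bpc_decode(stream$bytes, stream$nbits, h$n, h$bits, 16L),
    ebpc = .cx_ebpc_decode(stream$bytes, stream$nbits, h$n, h$bits, 16L))
  unflatten_scan(codes, h$shape)
}

#' @export
print.bitstream <- function(x, ...) {
  cat(sprintf("<bitstream> %s, q=%d, %d values, %.0f payload bits (%.2f bits/value)\n",
              x$header$codec, x$header$bits, x$header$n, x$nbits,
              x$nbits / x$header$n))
  invisible(x)
}

#' Payload size of a bitstream, in bits
#'
#' @param stream A `bitstream`.
#' @return Number of payload bits (numeric).
#' @export
codec_size_bits <- function(stream) stream$nbits

#' Worst-case compressed size over a collection
#'
#' The on-chip buffer for compressed skip connections must be provisioned
#' for the worst case, so the relevant statistic is the maximum over samples
#' of the total compressed size.
#'
#' @param tensors A list; each element is either a single code tensor or a
#'   list of code tensors (e.g. one sample's skip connections, summed).
#' @param codec Codec id as in [codec_encode()].
#' @param bits Code bitwidth q.
#' @return Worst-case size in bytes (bits rounded up to whole bytes).
#' @export
worst_case_size <- function(tensors, codec, bits) {
  stopifnot(length(tensors) > 0)
  per_sample <- vapply(tensors, function(tt) {
    if (is.list(tt) && !inherits(tt, "fp_tensor"))
      sum(vapply(tt, function(x) codec_size_bits(codec_encode(x, codec, bits = bits)), 0))
    else codec_size_bits(codec_encode(tt, codec, bits = bits))
  }, 0)
  ceiling(max(per_sample) / 8)
}

# scan order: channel-major, row-major within channel
flatten_scan <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 1L)
    return(list(codes = as.integer(x), chan_sizes = length(x)))
  if (length(d) == 2L)
    return(list(codes = as.integer(t(x)), chan_sizes = length(x)))
  stopifnot(length(d) == 3L)
  codes <- integer(0)
  for (c in seq_len(d[3])) codes <- c(codes, as.integer(t(x[, , c])))
  list(codes = codes, chan_sizes = rep(d[1] * d[2], d[3]))
}

unflatten_scan <- function(codes, shape) {
  if (length(shape) == 1L) return(as.integer(codes))
  if (length(shape) == 2L)
    return(t(matrix(as.integer(codes), shape[2], shape[1])))
  out <- array(0L, shape)
  per <- shape[1] * shape[2]
  for (c in seq_len(shape[3]))
    out[, , c] <- t(matrix(codes[(c - 1L) * per + seq_len(per)],
                           shape[2], shape[1]))
  out
}
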