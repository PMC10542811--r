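#' Permanent parameter memory of a model
#'
#' Counts every stored parameter at its configured precision: binary
#' convolution weights at 1 bit, 4-bit codes at 4 bits, full-precision
#' values at 32 bits, shift exponents at 4 bits. This is the memory that
#' must be permanently kept on-chip.
#'
#' @param model A `qnn_model`.
#' @return A list with `per_layer` (data frame: name, kind, bits) and
#'   `total_bits`.
#' @export
param_memory <- function(model) {
  bq <- model$cfg$variant == "bq"
  binary <- model$cfg$variant != "fp"
  rows <- list()
  add <- function(name, kind, bits)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, kind = kind,
                                             bits = bits)
  for (op in model$tape) {
    nm <- op$name
    switch(op$op,
      conv_stem = {
        add(nm, "conv", 9 * op$cout * (if (op$kind == "q4") 4 else 32) +
              (if (op$kind == "q4") 4 else 0))
      },
      dw = add(nm, "conv", 9 * op$channels * (if (op$binary) 1 else 32)),
      pw = add(nm, "conv", op$cin * op$cout * (if (op$binary) 1 else 32)),
      bn = add(nm, "norm", 2 * op$channels * 32),
      affine = add(nm, "norm", op$channels * (4 + 4) + 4),
      act = {
        if (op$kind == "prelu") add(nm, "act", 3 * op$channels * 32)
        else if (op$kind == "prelu_q") add(nm, "act",
                                           op$channels * (2 + 4 + 4) + 8)
      },
      rsign = add(nm, "rsign", op$channels * (if (op$quantized) 4 else 32)),
      skip_save = if (op$quantized) add(nm, "skip_shift", 4),
      NULL)
  }
  per_layer <- do.call(rbind, rows)
  list(per_layer = per_layer, total_bits = sum(per_layer$bits))
}

# spatial side length and channel count of each stored skip connection
skip_geometry <- function(cfg) {
  ch <- level_channels(cfg)
  data.frame(connection = seq_len(cfg$depth),
             side = cfg$input_size / 2^seq_len(cfg$depth),
             channels = ch[seq_len(cfg$depth)])
}

#' Inference-time skip-connection memory
#'
#' The skip connections between encoder and decoder must be buffered during
#' inference; this is the memory cost that occurs only at inference time.
#' For the quantized variant each value is stored at `skip_bits` plus one
#' bit for the separately stored binarized version (the decoder's RSign of
#' the skip, precomputed because the 4-bit threshold grid is incompatible
#' with the skip scale). With a codec, the value payload is replaced by the
#' worst-case compressed size over `dataset`; the 1-bit binarized store is
#' kept uncompressed.
#'
#' @param model A `qnn_model`.
#' @param codec `"none"` or a codec id from [codec_encode()].
#' @param dataset List of input images (required when `codec != "none"`).
#' @return A list with `per_connection` (data frame), `total_bits`, and
#'   `binarized_store_bits` (included in the total for the quantized
#'   variant, reported separately).
#' @export
inference_memory <- function(model, codec = "none", dataset = NULL) {
  cfg <- model$cfg
  geom <- skip_geometry(cfg)
  values <- geom$side^2 * geom$channels
  bq <- cfg$variant == "bq"
  q <- if (bq) cfg$skip_bits else 32L
  raw_bits <- values * q
  bin_bits <- if (bq) values else 0 * values
  if (codec == "none") {
    stored <- raw_bits
  } else {
    if (!bq) stop("compression applies to the quantized variant")
    if (is.null(dataset)) stop("dataset required for compressed sizes")
    fw <- model_forward(model, dataset, mode = "eval", collect_skips = TRUE)
    stored <- vapply(seq_len(cfg$depth), function(i) {
      sh <- model$buffers[[paste0("skip", i, ".shift")]]
      sizes <- vapply(fw$skips[[i]], function(v) {
        codes <- array(as.integer(round_q(v / 2^sh)), dim = dim(v))
        codec_size_bits(codec_encode(codes, codec, bits = q))
      }, 0)
      max(sizes)  # worst case over the dataset
    }, 0)
  }
  per <- data.frame(geom, values = values, stored_bits = stored,
                    binarized_bits = bin_bits)
  list(per_connection = per, total_bits = sum(stored) + sum(bin_bits),
       binarized_store_bits = sum(bin_bits), codec = codec)
}

#' Multiply-accumulate counts
#'
#' Counts one MAC per kernel element per output position per channel pair.
#' A binary MAC (sign activations times sign weights) is a single
#' XNOR-plus-count and counts as 1 equivalent binary MAC; a MAC between an
#' a-bit and a b-bit operand counts as `a * b` equivalent binary MACs (the
#' 4-bit first layer of the quantized model thus contributes 16 per MAC);
#' full-precision MACs are reported separately. Per-element normalization,
#' activation and comparison work (adds, shifts, compares) is tabulated in
#' an auxiliary table, not in the MAC totals.
#'
#' @param model A `qnn_model`.
#' @return A list with `per_layer`, `fp_macs`, `equivalent_binary_macs` and
#'   `aux_ops`.
#' @export
mac_count <- function(model) {
  cfg <- model$cfg
  side <- cfg$input_size
  rows <- list(); aux <- list()
  addc <- function(name, macs, class) {
    eb <- switch(class, binary = macs, q4 = 16 * macs, fp = 0)
    fp <- if (class == "fp") macs else 0
    rows[[length(rows) + 1L]] <<- data.frame(name = name, macs = macs,
                                             class = class,
                                             equivalent_binary_macs = eb,
                                             fp_macs = fp)
  }
  adda <- function(name, kind, nops)
    aux[[length(aux) + 1L]] <<- data.frame(name = name, kind = kind,
                                           ops = nops)
  for (op in model$tape) {
    nm <- op$name
    switch(op$op,
      conv_stem = {
        side <- side / op$stride
        addc(nm, side^2 * 9 * op$cout,
             if (op$kind == "q4") "q4" else "fp")
      },
      dw = {
        side <- side / op$stride
        addc(nm, side^2 * 9 * op$channels,
             if (op$binary) "binary" else "fp")
      },
      pw = addc(nm, side^2 * op$cin * op$cout,
                if (op$binary) "binary" else "fp"),
      bn = adda(nm, "norm_mul_add", side^2 * op$channels),
      affine = adda(nm, "norm_shift_add", side^2 * op$channels),
      act = adda(nm, op$kind, side^2 * op$channels),
      rsign = adda(nm, "compare", side^2 * op$channels),
      upsample = { side <- side * 2 },
      NULL)
  }
  per_layer <- do.call(rbind, rows)
  list(per_layer = per_layer,
       fp_macs = sum(per_layer$fp_macs),
       equivalent_binary_macs = sum(per_layer$equivalent_binary_macs),
       aux_ops = do.call(rbind, aux))
}

#' Full memory / computation footprint report
#'
#' Combines [param_memory()], [inference_memory()] and [mac_count()] into
#' one report, with totals in kB (1 kB = 1024 bytes).
#'
#' @param model A `qnn_model`.
#' @param codec Codec id or `"none"` for the skip-connection payload.
#' @param dataset Images for worst-case compressed sizing (if `codec` set).
#' @return A `footprint_report` list.
#' @export
footprint_report <- function(model, codec = "none", dataset = NULL) {
  pm <- param_memory(model)
  im <- inference_memory(model, codec = codec, dataset = dataset)
  mc <- mac_count(model)
  structure(list(variant = model$cfg$variant,
                 skip_bits = model$cfg$skip_bits,
                 param = pm, skip = im, macs = mc,
                 param_kb = pm$total_bits / 8 / 1024,
                 skip_kb = im$total_bits / 8 / 1024,
                 total_kb = (pm$total_bits + im$total_bits) / 8 / 1024),
            class = "footprint_report")
}

#' @export
print.footprint_report <- function(x, ...) {
  cat(sprintf("Footprint (%s, skip %d-bit):\n", x$variant, x$skip_bits))
  cat(sprintf("  parameters (permanent): %8.1f kB\n", x$param_kb))
  cat(sprintf("  skip buffers (inference): %6.1f kB (codec: %s%s)\n",
              x$skip_kb, x$skip$codec,
              if (x$skip$binarized_store_bits > 0)
                sprintf(", incl. %.1f kB 1-bit binarized store",
                        x$skip$binarized_store_bits / 8 / 1024) else ""))
  cat(sprintf("  total: %21.1f kB\n", x$total_kb))
  cat(sprintf("  MACs: fp %.2fM, equivalent binary %.2fM\n",
              x$macs$fp_macs / 1e6, x$macs$equivalent_binary_macs / 1e6))
  invisible(x)
}

#' Total-memory reduction of the quantized model over full precision
#'
#' Structure-only accounting: builds the full-precision and fully quantized
#' variants of the same architecture and compares total (parameter + skip)
#' memory.
#'
#' @param input_size,depth,base_channels,channel_growth,out_channels
#'   Architecture, as in [unet_config()].
#' @param skip_bits Skip bitwidth of the quantized model.
#' @return A list with both totals (bits) and their `ratio`.
#' @export
memory_reduction_ratio <- function(input_size = 224L, depth = 4L,
                                   base_channels = 16L, channel_growth = 2L,
                                   out_channels = 2L, skip_bits = 4L) {
  mk <- function(variant, sb) {
    cfg <- unet_config(input_size, depth, base_channels, channel_growth,
                       out_channels, variant = variant, skip_bits = sb)
    m <- build_model(cfg, seed = 1L)
    param_memory(m)$total_bits + inference_memory(m)$total_bits
  }
  fp <- mk("fp", NULL)
  bq <- mk("bq", skip_bits)
  list(fp_bits = fp, bq_bits = bq, ratio = fp / bq)
}
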