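#' U-Net configuration
#'
#' Describes the lightweight encoder-decoder segmentation network in one of
#' three precision variants:
#' \describe{
#'   \item{`"fp"`}{full precision: plain convolutions, BatchNorm, ReLU.}
#'   \item{`"bfp"`}{binarized: every convolution except the first uses RSign
#'     activations and mean-thresholded sign weights; BatchNorm and PReLU
#'     parameters stay real-valued.}
#'   \item{`"bq"`}{fully quantized: additionally, the first layer uses 4-bit
#'     input and 4-bit weights, BatchNorm becomes a power-of-two shift with a
#'     4-bit bias, PReLU parameters use 2/4-bit codes, RSign thresholds use
#'     4-bit codes, and skip connections are stored as unsigned q-bit codes
#'     with one power-of-two scale per connection.}
#' }
#' The stem convolution has stride 2, each of the `depth` encoder levels
#' halves the resolution once more, and one skip connection is stored per
#' level ("the horizontal arrows"); the decoder mirrors the encoder with
#' nearest-neighbour upsampling, and a final upsample restores the input
#' resolution.
#'
#' @param input_size Input image side length in pixels (square input); must
#'   be divisible by `2^(depth + 1)` because of the stride-2 stem.
#' @param depth Number of encoder levels / skip connections.
#' @param base_channels Channel count after the stem.
#' @param channel_growth Per-level channel multiplier.
#' @param out_channels 1 (inner wall only) or 2 (inner + outer wall).
#' @param variant `"fp"`, `"bfp"` or `"bq"`.
#' @param skip_bits Skip-connection bitwidth; 32 for `"fp"`/`"bfp"`, one of
#'   3, 4, 6 for `"bq"`.
#' @param surrogate Backward surrogate for the sign nonlinearity: `"ste"` or
#'   `"tanh2x"`.
#' @return A `unet_config` list.
#' @export
unet_config <- function(input_size = 224L, depth = 4L, base_channels = 16L,
                        channel_growth = 2L, out_channels = 2L,
                        variant = c("fp", "bfp", "bq"), skip_bits = NULL,
                        surrogate = c("ste", "tanh2x")) {
  variant <- match.arg(variant)
  surrogate <- match.arg(surrogate)
  if (input_size %% 2^(depth + 1L) != 0L)
    stop("input_size must be divisible by 2^(depth + 1)")
  if (!out_channels %in% 1:2) stop("out_channels must be 1 or 2")
  if (is.null(skip_bits)) skip_bits <- if (variant == "bq") 6L else 32L
  if (variant == "bq" && !skip_bits %in% c(3L, 4L, 6L))
    stop("bq variant requires skip_bits in {3, 4, 6}")
  if (variant != "bq") skip_bits <- 32L
  structure(list(input_size = as.integer(input_size), depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 channel_growth = as.integer(channel_growth),
                 out_channels = as.integer(out_channels), variant = variant,
                 skip_bits = as.integer(skip_bits), surrogate = surrogate),
            class = "unet_config")
}

# channel width at level i = 0..depth
level_channels <- function(cfg) {
  cfg$base_channels * cfg$channel_growth^(0:cfg$depth)
}

# ---- tape construction ------------------------------------------------------

# The network is represented as a linear tape of ops executed by the C++
# engine (and by the R fixed-point interpreter in guard mode).
build_tape <- function(cfg) {
  ch <- level_channels(cfg)
  binary <- cfg$variant != "fp"
  bq <- cfg$variant == "bq"
  tape <- list()
  add <- function(...) tape[[length(tape) + 1L]] <<- list(...)
  norm <- function(name, C) {
    if (bq) add(op = "affine", name = name, channels = C)
    else add(op = "bn", name = name, channels = C)
  }
  act <- function(name, C) {
    kind <- if (!binary) "relu" else if (bq) "prelu_q" else "prelu"
    add(op = "act", name = name, kind = kind, channels = C)
  }
  rs <- function(name, C) {
    if (binary) add(op = "rsign", name = name, channels = C, quantized = bq)
  }

  if (bq) add(op = "quant_input")
  add(op = "conv_stem", name = "stem", stride = 2L,
      kind = if (bq) "q4" else "fp", cin = 1L, cout = ch[1])
  norm("n0", ch[1]); act("a0", ch[1])
  for (i in seq_len(cfg$depth)) {
    cin <- ch[i]; cout <- ch[i + 1]
    add(op = "skip_save", name = paste0("skip", i), slot = i,
        quantized = bq, bits = cfg$skip_bits, channels = cin)
    p <- function(s) paste0("e", i, ".", s)
    rs(p("rs1"), cin)
    add(op = "dw", name = p("dw"), stride = 2L, binary = binary,
        channels = cin)
    norm(p("n1"), cin); act(p("a1"), cin)
    rs(p("rs2"), cin)
    add(op = "pw", name = p("pw"), binary = binary, cin = cin, cout = cout)
    norm(p("n2"), cout); act(p("a2"), cout)
  }
  cb <- ch[cfg$depth + 1]
  rs("b.rs1", cb)
  add(op = "dw", name = "b.dw", stride = 1L, binary = binary, channels = cb)
  norm("b.n1", cb); act("b.a1", cb)
  rs("b.rs2", cb)
  add(op = "pw", name = "b.pw", binary = binary, cin = cb, cout = cb)
  norm("b.n2", cb); act("b.a2", cb)
  for (i in rev(seq_len(cfg$depth))) {
    ci <- ch[i + 1]; co <- ch[i]
    p <- function(s) paste0("d", i, ".", s)
    add(op = "upsample")
    rs(p("rs1"), ci)
    add(op = "pw", name = p("pw1"), binary = binary, cin = ci, cout = co)
    norm(p("n1"), co); act(p("a1"), co)
    add(op = "skip_cat", slot = i)
    rs(p("rs2"), 2L * co)
    add(op = "dw", name = p("dw"), stride = 1L, binary = binary,
        channels = 2L * co)
    norm(p("n2"), 2L * co); act(p("a2"), 2L * co)
    rs(p("rs3"), 2L * co)
    add(op = "pw", name = p("pw2"), binary = binary, cin = 2L * co, cout = co)
    norm(p("n3"), co); act(p("a3"), co)
  }
  add(op = "upsample")
  rs("head.rs", ch[1])
  add(op = "pw", name = "head", binary = binary, cin = ch[1],
      cout = cfg$out_channels)
  norm("head.n", cfg$out_channels)
  add(op = "sigmoid")
  tape
}

# ---- parameter initialization ----------------------------------------------

init_model_state <- function(tape, cfg) {
  params <- list(); buffers <- list()
  bq <- cfg$variant == "bq"
  for (op in tape) {
    nm <- op$name
    switch(op$op,
      conv_stem = {
        params[[paste0(nm, ".w")]] <- array(stats::rnorm(9 * op$cout,
                                                         sd = sqrt(2 / 9)),
                                            dim = c(3L, 3L, op$cout))
        if (op$kind == "q4")
          buffers[[paste0(nm, ".wshift")]] <-
            calibrate_step(params[[paste0(nm, ".w")]], 7)
      },
      dw = {
        params[[paste0(nm, ".w")]] <- array(stats::rnorm(9 * op$channels,
                                                         sd = sqrt(2 / 9)),
                                            dim = c(3L, 3L, op$channels))
      },
      pw = {
        params[[paste0(nm, ".w")]] <- matrix(stats::rnorm(op$cin * op$cout,
                                                          sd = sqrt(2 / op$cin)),
                                             op$cin, op$cout)
      },
      bn = {
        params[[paste0(nm, ".gamma")]] <- rep(1, op$channels)
        params[[paste0(nm, ".beta")]] <- rep(0, op$channels)
        buffers[[paste0(nm, ".mean")]] <- rep(0, op$channels)
        buffers[[paste0(nm, ".var")]] <- rep(1, op$channels)
      },
      affine = {
        params[[paste0(nm, ".w")]] <- rep(1, op$channels)
        params[[paste0(nm, ".b")]] <- rep(0, op$channels)
        buffers[[paste0(nm, ".bstep")]] <- -2L
      },
      act = {
        if (op$kind != "relu") {
          params[[paste0(nm, ".beta")]] <- rep(0.25, op$channels)
          params[[paste0(nm, ".gamma")]] <- rep(0, op$channels)
          params[[paste0(nm, ".eta")]] <- rep(0, op$channels)
          if (op$kind == "prelu_q") {
            buffers[[paste0(nm, ".gstep")]] <- -2L
            buffers[[paste0(nm, ".estep")]] <- -2L
          }
        }
      },
      rsign = {
        params[[paste0(nm, ".alpha")]] <- rep(0, op$channels)
      },
      skip_save = {
        if (op$quantized) buffers[[paste0(nm, ".shift")]] <- 0L
      },
      NULL)
  }
  list(params = params, buffers = buffers)
}

#' Build a segmentation model
#'
#' Instantiates the network described by a [unet_config()] with randomly
#' initialized parameters (He-style normal weights, identity normalization,
#' PReLU slope 0.25, zero thresholds).
#'
#' @param cfg A [unet_config()].
#' @param seed Integer seed for the weight initialization.
#' @return A `qnn_model` object (config, op tape, parameters, buffers).
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "unet_config"))
  tape <- build_tape(cfg)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  st <- init_model_state(tape, cfg)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(cfg = cfg, tape = tape, params = st$params,
                 buffers = st$buffers), class = "qnn_model")
}

#' @export
print.qnn_model <- function(x, ...) {
  s <- model_layer_summary(x)
  cat(sprintf("<qnn_model> variant %s, %dx%d input, depth %d, %s conv layers (%d binary), %d parameters\n",
              x$cfg$variant, x$cfg$input_size, x$cfg$input_size, x$cfg$depth,
              nrow(s), sum(s$binary), sum(vapply(x$params, length, 1L))))
  invisible(x)
}

#' Summarize the convolution layers of a model
#'
#' @param model A `qnn_model`.
#' @return A data frame with one row per convolution layer: name, type
#'   (`stem`/`dw`/`pw`), input/output channels, kernel size, weight precision
#'   and whether the layer is binary.
#' @export
model_layer_summary <- function(model) {
  rows <- list()
  for (op in model$tape) {
    if (op$op == "conv_stem") {
      rows[[length(rows) + 1L]] <- data.frame(
        name = op$name, type = "stem", cin = 1L, cout = op$cout, kernel = 9L,
        weight_bits = if (op$kind == "q4") 4L else 32L, binary = FALSE)
    } else if (op$op == "dw") {
      rows[[length(rows) + 1L]] <- data.frame(
        name = op$name, type = "dw", cin = op$channels, cout = op$channels,
        kernel = 9L, weight_bits = if (op$binary) 1L else 32L,
        binary = op$binary)
    } else if (op$op == "pw") {
      rows[[length(rows) + 1L]] <- data.frame(
        name = op$name, type = "pw", cin = op$cin, cout = op$cout, kernel = 1L,
        weight_bits = if (op$binary) 1L else 32L, binary = op$binary)
    }
  }
  do.call(rbind, rows)
}

# coerce an image (matrix or HxWx1 array) to the engine's input format
as_input_array <- function(img) {
  if (is.matrix(img)) dim(img) <- c(nrow(img), ncol(img), 1L)
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 1L)
  img
}

#' Run the network forward
#'
#' @param model A `qnn_model`.
#' @param images A single image matrix or a list of image matrices (values in
#'   `[0, 1]`, side length `cfg$input_size`).
#' @param mode `"eval"` uses stored normalization statistics; `"train"` uses
#'   batch statistics and updates the stored ones.
#' @param collect_skips Also return the stored skip-connection tensors.
#' @return A list with `probs` (per-sample `H x W x out_channels` probability
#'   arrays) and optionally `skips` (per-connection list of per-sample
#'   arrays, quantized values for the `bq` variant).
#' @export
model_forward <- function(model, images, mode = c("eval", "train"),
                          collect_skips = FALSE) {
  mode <- match.arg(mode)
  single <- !is.list(images)
  if (single) images <- list(images)
  images <- lapply(images, as_input_array)
  sz <- model$cfg$input_size
  for (im in images)
    if (dim(im)[1] != sz || dim(im)[2] != sz)
      stop("input image must be ", sz, "x", sz)
  out <- .cx_qnn_forward(model$params, model$buffers, model$tape, images,
                         if (mode == "train") 1L else 0L, collect_skips)
  out
}

#' Threshold probability maps into binary masks
#'
#' Channel 1 is the inner bladder wall and is the only channel used for
#' volume estimation downstream.
#'
#' @param probs Probability array (`H x W x C`) or a list of them.
#' @param threshold Decision threshold in (0, 1).
#' @return Binary (0/1) array(s) of the same shape.
#' @export
predict_mask <- function(probs, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  f <- function(p) {
    m <- (p > threshold) + 0
    dim(m) <- dim(p)
    m
  }
  if (is.list(probs)) lapply(probs, f) else f(probs)
}

# ---- quantization plan ------------------------------------------------------

#' Per-layer precision plan
#'
#' Tabulates the precision of each model component in the three variants
#' (full precision, binarized, fully quantized), mirroring the model-version
#' layer-precision table.
#'
#' @param cfg A [unet_config()] (its `skip_bits` fills the quantized skip
#'   column).
#' @return A data frame with columns `component`, `fp`, `bfp`, `bq`.
#' @export
quant_plan <- function(cfg = unet_config()) {
  data.frame(
    component = c("most conv layers", "first layer", "skip connections",
                  "normalization", "activation", "rsign threshold"),
    fp = c("FP", "FP", "FP", "BatchNorm (FP)", "ReLU", "-"),
    bfp = c("binary", "FP", "FP", "BatchNorm (FP)",
            "PReLU (FP beta/gamma/eta)", "FP alpha"),
    bq = c("binary", "4-bit input + 4-bit weight",
           sprintf("%d-bit unsigned + per-connection shift", cfg$skip_bits),
           "binary shift + 4-bit bias",
           "PReLU (2-bit beta, 4-bit gamma/eta)", "4-bit alpha"))
}

#' Write / read a quantization plan
#'
#' @param plan A data frame from [quant_plan()].
#' @param path Output file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_quant_plan` returns the plan data frame.
#' @export
write_quant_plan <- function(plan, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(lapply(plan, as.character), path)
  else jsonlite::write_json(plan, path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_quant_plan
#' @export
read_quant_plan <- function(path) {
  if (grepl("\\.ya?ml$", path)) as.data.frame(yaml::read_yaml(path))
  else as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

# ---- stage-2 conversion -----------------------------------------------------

#' Convert a trained binarized model to the fully quantized variant
#'
#' Stage-2 initialization: BatchNorm layers are folded into per-channel
#' affine scale/bias (the scale is then constrained to a power of two in the
#' forward pass), per-layer power-of-two steps for the 4-bit bias and PReLU
#' gamma/eta grids are calibrated from the trained parameter ranges, the
#' first-layer weight scale is calibrated from the trained weights, and each
#' skip connection's shift is calibrated so the maximum activation observed
#' on `calib_images` decodes without overflow.
#'
#' @param model A trained `"bfp"` model.
#' @param skip_bits Skip bitwidth for the quantized model (3, 4 or 6).
#' @param calib_images List of images used to calibrate skip shifts.
#' @return A `"bq"` `qnn_model` ready for quantization-aware fine-tuning.
#' @export
convert_bfp_to_bq <- function(model, skip_bits = 6L, calib_images) {
  stopifnot(model$cfg$variant == "bfp")
  cfg <- model$cfg
  cfg$variant <- "bq"
  cfg$skip_bits <- as.integer(skip_bits)
  if (!cfg$skip_bits %in% c(3L, 4L, 6L)) stop("skip_bits must be 3, 4 or 6")
  tape <- build_tape(cfg)
  params <- list(); buffers <- list()
  old <- model$params; oldb <- model$buffers
  for (op in tape) {
    nm <- op$name
    switch(op$op,
      conv_stem = {
        params[[paste0(nm, ".w")]] <- old[[paste0(nm, ".w")]]
        buffers[[paste0(nm, ".wshift")]] <-
          calibrate_step(old[[paste0(nm, ".w")]], 7)
      },
      dw = , pw = {
        params[[paste0(nm, ".w")]] <- old[[paste0(nm, ".w")]]
      },
      rsign = {
        params[[paste0(nm, ".alpha")]] <- old[[paste0(nm, ".alpha")]]
      },
      act = {
        for (f in c("beta", "gamma", "eta"))
          params[[paste0(nm, ".", f)]] <- old[[paste0(nm, ".", f)]]
        buffers[[paste0(nm, ".gstep")]] <-
          min(-2L, calibrate_step(old[[paste0(nm, ".gamma")]], 7))
        buffers[[paste0(nm, ".estep")]] <-
          min(-2L, calibrate_step(old[[paste0(nm, ".eta")]], 7))
      },
      affine = {
        g <- old[[paste0(nm, ".gamma")]]
        be <- old[[paste0(nm, ".beta")]]
        mu <- oldb[[paste0(nm, ".mean")]]
        v <- oldb[[paste0(nm, ".var")]]
        w <- g / sqrt(v + 1e-5)
        if (any(w == 0)) stop("cannot fold BatchNorm with zero scale")
        b <- be - w * mu
        params[[paste0(nm, ".w")]] <- w
        params[[paste0(nm, ".b")]] <- b
        buffers[[paste0(nm, ".bstep")]] <- calibrate_step(b, 7)
      },
      skip_save = {
        buffers[[paste0(nm, ".shift")]] <- 0L   # calibrated below
      },
      NULL)
  }
  out <- structure(list(cfg = cfg, tape = tape, params = params,
                        buffers = buffers), class = "qnn_model")
  # calibrate skip shifts from the trained bfp model's skip activations
  fw <- model_forward(model, calib_images, mode = "eval", collect_skips = TRUE)
  for (i in seq_len(cfg$depth)) {
    mx <- max(vapply(fw$skips[[i]], max, 0))
    if (mx <= 0) {
      warning("skip connection ", i,
              " saw no positive activations during calibration; shift 0")
      sh <- 0L
    } else sh <- as.integer(ceiling(log2(mx / (2^cfg$skip_bits - 1))))
    out$buffers[[paste0("skip", i, ".shift")]] <- sh
  }
  out
}

# ---- checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Full-precision and binarized models store their real-valued parameters.
#' Fully quantized (`bq`) models store integer codes and shift exponents
#' only (weight signs, 4-bit threshold/bias/knee codes, power-of-two scale
#' exponents); loading decodes them back onto the quantization grids, which
#' reproduces the inference function bit-exactly.
#'
#' @param model A `qnn_model`.
#' @param path File path (`.rds`).
#' @return `load_checkpoint` returns the `qnn_model`.
#' @export
save_checkpoint <- function(model, path) {
  if (model$cfg$variant == "bq") {
    saveRDS(list(kind = "bq_codes", cfg = model$cfg,
                 codes = export_bq_codes(model), buffers = model$buffers),
            path)
  } else {
    saveRDS(list(kind = "raw", cfg = model$cfg, params = model$params,
                 buffers = model$buffers), path)
  }
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  tape <- build_tape(x$cfg)
  if (x$kind == "raw") {
    return(structure(list(cfg = x$cfg, tape = tape, params = x$params,
                          buffers = x$buffers), class = "qnn_model"))
  }
  params <- decode_bq_codes(x$codes, tape, x$buffers)
  structure(list(cfg = x$cfg, tape = tape, params = params,
                 buffers = x$buffers), class = "qnn_model")
}

# integer-code export for the fully quantized model
export_bq_codes <- function(model) {
  stopifnot(model$cfg$variant == "bq")
  p <- model$params; b <- model$buffers
  codes <- list()
  for (op in model$tape) {
    nm <- op$name
    switch(op$op,
      conv_stem = {
        ws <- b[[paste0(nm, ".wshift")]]
        codes[[paste0(nm, ".w")]] <-
          array(as.integer(pmin(pmax(round_q(p[[paste0(nm, ".w")]] / 2^ws), -8), 7)),
                dim = dim(p[[paste0(nm, ".w")]]))
      },
      dw = , pw = {
        w <- p[[paste0(nm, ".w")]]
        sgn <- if (op$op == "dw") binarize_weights(w, channel_dim = 3L)
               else binarize_weights(w, channel_dim = 2L)
        codes[[paste0(nm, ".w")]] <- array(as.integer(sgn), dim = dim(w))
      },
      rsign = {
        codes[[paste0(nm, ".alpha")]] <-
          as.integer(pmin(pmax(round_q(p[[paste0(nm, ".alpha")]] / 0.25), -8), 7))
      },
      act = {
        codes[[paste0(nm, ".beta")]] <-
          as.integer(pmin(pmax(round_q(p[[paste0(nm, ".beta")]] / 0.25), 0), 3))
        codes[[paste0(nm, ".gamma")]] <-
          as.integer(pmin(pmax(round_q(p[[paste0(nm, ".gamma")]] /
                                     2^b[[paste0(nm, ".gstep")]]), -8), 7))
        codes[[paste0(nm, ".eta")]] <-
          as.integer(pmin(pmax(round_q(p[[paste0(nm, ".eta")]] /
                                     2^b[[paste0(nm, ".estep")]]), -8), 7))
      },
      affine = {
        sn <- bn_to_shiftnorm(p[[paste0(nm, ".w")]], p[[paste0(nm, ".b")]],
                              bias_step = b[[paste0(nm, ".bstep")]])
        codes[[paste0(nm, ".shift")]] <- sn$shift
        codes[[paste0(nm, ".sign")]] <- as.integer(sn$sign)
        codes[[paste0(nm, ".b")]] <- sn$bias_code
      },
      NULL)
  }
  codes
}

decode_bq_codes <- function(codes, tape, buffers) {
  params <- list()
  for (op in tape) {
    nm <- op$name
    switch(op$op,
      conv_stem = {
        ws <- buffers[[paste0(nm, ".wshift")]]
        params[[paste0(nm, ".w")]] <- codes[[paste0(nm, ".w")]] * 2^ws
      },
      dw = , pw = {
        params[[paste0(nm, ".w")]] <- codes[[paste0(nm, ".w")]] * 1.0
      },
      rsign = {
        params[[paste0(nm, ".alpha")]] <- codes[[paste0(nm, ".alpha")]] * 0.25
      },
      act = {
        params[[paste0(nm, ".beta")]] <- codes[[paste0(nm, ".beta")]] * 0.25
        params[[paste0(nm, ".gamma")]] <-
          codes[[paste0(nm, ".gamma")]] * 2^buffers[[paste0(nm, ".gstep")]]
        params[[paste0(nm, ".eta")]] <-
          codes[[paste0(nm, ".eta")]] * 2^buffers[[paste0(nm, ".estep")]]
      },
      affine = {
        params[[paste0(nm, ".w")]] <-
          codes[[paste0(nm, ".sign")]] * 2^codes[[paste0(nm, ".shift")]]
        params[[paste0(nm, ".b")]] <-
          codes[[paste0(nm, ".b")]] * 2^buffers[[paste0(nm, ".bstep")]]
      },
      NULL)
  }
  params
}
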