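#' Training configuration
#'
#' Defaults follow the study training recipe: Dice loss, cosine annealing
#' with warm restarts from an initial learning rate of 0.005, weight decay
#' 4e-5 for the full-precision model only (none for the binarized /
#' quantized variants), straight-through estimator surrogate, two stages of
#' 150 epochs, and model selection by the highest validation metric (mean
#' inner-wall Dice) across epochs.
#'
#' @param epochs Integer vector of length 2: epochs for stage 1 (binarized)
#'   and stage 2 (quantized fine-tuning). Single-stage training uses the
#'   first element.
#' @param lr Initial learning rate.
#' @param t0,t_mult Warm-restart schedule: first cycle length (epochs) and
#'   cycle-length multiplier.
#' @param weight_decay L2 penalty, applied to convolution weights of the
#'   full-precision variant only.
#' @param batch_size Minibatch size.
#' @param augment Apply random flips/shear/rotation each epoch.
#' @param threshold Mask decision threshold for the validation metric.
#' @param seed Integer seed controlling shuffling and augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = c(150L, 150L), lr = 0.005, t0 = 10L,
                         t_mult = 2L, weight_decay = 4e-5, batch_size = 16L,
                         augment = TRUE, threshold = 0.5, seed = 1L) {
  if (length(epochs) == 1L) epochs <- rep(epochs, 2L)
  structure(list(epochs = as.integer(epochs), lr = lr, t0 = as.integer(t0),
                 t_mult = as.integer(t_mult), weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), augment = augment,
                 threshold = threshold, seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealed learning rate with warm restarts
#'
#' Cycle lengths are `t0, t0*t_mult, t0*t_mult^2, ...`; within a cycle of
#' length T at position t (0-based) the rate is
#' `eta_min + (lr0 - eta_min) * (1 + cos(pi * t / T)) / 2`, so each cycle
#' restarts at `lr0`.
#'
#' @param epoch 1-based epoch number.
#' @param lr0 Initial (restart) learning rate.
#' @param t0,t_mult Schedule parameters.
#' @param eta_min Floor learning rate.
#' @return Learning rate for that epoch.
#' @export
cosine_lr <- function(epoch, lr0 = 0.005, t0 = 10L, t_mult = 2L,
                      eta_min = 0) {
  t <- epoch - 1L
  ti <- t0
  while (t >= ti) {
    t <- t - ti
    ti <- ti * t_mult
  }
  eta_min + (lr0 - eta_min) * (1 + cos(pi * t / ti)) / 2
}

#' Soft Dice loss
#'
#' `1 - Dice` for one output channel, or one minus the mean of the
#' inner-wall and outer-wall Dice scores for two channels, with smoothing
#' `eps` on numerator and denominator. Targets must be binary.
#'
#' @param pred Predicted probability array (`H x W x C`).
#' @param target Binary target array of the same shape.
#' @param eps Smoothing constant.
#' @return Scalar loss in `[0, 1)`.
#' @export
dice_loss <- function(pred, target, eps = 1) {
  if (is.matrix(pred)) dim(pred) <- c(dim(pred), 1L)
  if (is.matrix(target)) dim(target) <- c(dim(target), 1L)
  stopifnot(identical(dim(pred), dim(target)))
  if (!all(target %in% c(0, 1))) stop("targets must be binary (0/1)")
  ds <- vapply(seq_len(dim(pred)[3]), function(c) {
    p <- pred[, , c]; t <- target[, , c]
    (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  }, 0)
  1 - mean(ds)
}

#' Random affine augmentation of an image/mask pair
#'
#' Draws a horizontal flip, a shear and a rotation by a random angle and
#' applies the identical transform to the image (bilinear) and to the masks
#' (nearest neighbour, so masks stay binary). A fresh transform is drawn at
#' every call (i.e. each epoch) unless `params` is supplied.
#'
#' @param image Image matrix.
#' @param masks `H x W x C` binary mask array.
#' @param params Optional transform list (`flip`, `angle_deg`, `shear`) to
#'   re-apply a known transform.
#' @param max_angle_deg,max_shear Draw ranges.
#' @return A list: transformed `image`, `masks` and the sampled `params`.
#' @export
augment_pair <- function(image, masks, params = NULL, max_angle_deg = 25,
                         max_shear = 0.1) {
  if (is.null(params))
    params <- list(flip = stats::runif(1) < 0.5,
                   angle_deg = stats::runif(1, -max_angle_deg, max_angle_deg),
                   shear = stats::runif(1, -max_shear, max_shear))
  if (params$flip) {
    image <- image[, rev(seq_len(ncol(image)))]
    masks <- masks[, rev(seq_len(ncol(masks))), , drop = FALSE]
  }
  if (params$angle_deg != 0 || params$shear != 0) {
    m <- affine_about_center(nrow(image), params$angle_deg, params$shear)
    image <- as.matrix(EBImage::affine(image, m, filter = "bilinear",
                                       output.dim = dim(image), bg.col = 0))
    for (c in seq_len(dim(masks)[3]))
      masks[, , c] <- as.matrix(EBImage::affine(masks[, , c], m,
                                                filter = "none",
                                                output.dim = dim(masks)[1:2],
                                                bg.col = 0))
  }
  list(image = image, masks = masks, params = params)
}

# 3x2 affine matrix (EBImage convention) rotating by `angle` and shearing,
# both about the image center
affine_about_center <- function(size, angle_deg, shear) {
  th <- angle_deg * pi / 180
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  shm <- matrix(c(1, shear, 0, 1), 2, 2)
  lin <- rot %*% shm
  ctr <- c((size + 1) / 2, (size + 1) / 2)
  off <- ctr - lin %*% ctr
  rbind(t(lin), as.numeric(off))
}

# force a deep copy: the engine updates normalization statistics in place,
# so snapshots (and the caller's model) must own their memory
deep_copy <- function(x) unserialize(serialize(x, NULL))

# ---- optimizer --------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- training loop ----------------------------------------------------------

#' Mean per-channel Dice of a model on a dataset
#'
#' @param model A `qnn_model`.
#' @param data Dataset from [phantoms_to_dataset()].
#' @param threshold Mask decision threshold.
#' @return Named numeric: mean Dice per output channel (`inner`, and
#'   `outer` for two-channel models).
#' @export
evaluate_model <- function(model, data, threshold = 0.5) {
  fw <- model_forward(model, data$images, mode = "eval")
  nch <- model$cfg$out_channels
  acc <- matrix(0, length(data$images), nch)
  for (s in seq_along(data$images)) {
    pm <- predict_mask(fw$probs[[s]], threshold)
    for (c in seq_len(nch))
      acc[s, c] <- dice_score(pm[, , c], data$masks[[s]][, , c])
  }
  out <- colMeans(acc)
  names(out) <- c("inner", "outer")[seq_len(nch)]
  out
}

#' Train a model on a dataset
#'
#' Minibatch Adam with the cosine warm-restart schedule, Dice loss, fresh
#' augmentation draws each epoch, and model selection by the highest mean
#' inner-wall validation Dice across epochs. Fully deterministic given
#' `cfg$seed`.
#'
#' @param model A `qnn_model` (any variant).
#' @param data Training dataset from [phantoms_to_dataset()].
#' @param val Validation dataset (same format); if `NULL`, the final epoch's
#'   parameters are returned.
#' @param cfg A [train_config()].
#' @param epochs Number of epochs (defaults to `cfg$epochs[1]`).
#' @param verbose Print a line per epoch.
#' @return A list: `model` (best checkpoint), `history` (data frame with
#'   epoch, lr, loss, val_dice), `best_epoch`.
#' @export
train_model <- function(model, data, val = NULL, cfg = train_config(),
                        epochs = NULL, verbose = FALSE) {
  epochs <- epochs %||% cfg$epochs[1]
  n <- length(data$images)
  surr <- if (model$cfg$surrogate == "tanh2x") 1L else 0L
  wd <- if (model$cfg$variant == "fp") cfg$weight_decay else 0
  opt <- adam_init(model$params)
  model$buffers <- deep_copy(model$buffers)
  set.seed(cfg$seed)
  best <- list(dice = -Inf, params = model$params,
               buffers = deep_copy(model$buffers), epoch = 0L)
  hist <- vector("list", epochs)
  wnames <- grep("\\.w$", names(model$params), value = TRUE)
  for (ep in seq_len(epochs)) {
    lr <- cosine_lr(ep, cfg$lr, cfg$t0, cfg$t_mult)
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      imgs <- vector("list", length(idx))
      msks <- vector("list", length(idx))
      for (k in seq_along(idx)) {
        if (cfg$augment) {
          au <- augment_pair(data$images[[idx[k]]], data$masks[[idx[k]]])
          imgs[[k]] <- as_input_array(au$image)
          msks[[k]] <- au$masks
        } else {
          imgs[[k]] <- as_input_array(data$images[[idx[k]]])
          msks[[k]] <- data$masks[[idx[k]]]
        }
      }
      res <- .cx_qnn_loss_grad(model$params, model$buffers, model$tape,
                               imgs, msks, surr)
      if (!is.finite(res$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      grads <- res$grads
      if (wd > 0)
        for (nm in wnames) grads[[nm]] <- grads[[nm]] + wd * model$params[[nm]]
      st <- adam_step(model$params, grads, opt, lr)
      model$params <- st$params
      opt <- st$state
      model$buffers <- res$buffers
      ep_loss <- ep_loss + res$loss; nb <- nb + 1L
    }
    vd <- NA_real_
    if (!is.null(val)) {
      vd <- evaluate_model(model, val, cfg$threshold)[["inner"]]
      if (vd > best$dice)
        best <- list(dice = vd, params = model$params,
                     buffers = deep_copy(model$buffers), epoch = ep)
    }
    hist[[ep]] <- data.frame(epoch = ep, lr = lr, loss = ep_loss / nb,
                             val_dice = vd)
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  loss %.4f  val dice %s", ep, lr,
                      ep_loss / nb,
                      if (is.na(vd)) "-" else sprintf("%.4f", vd)))
  }
  if (!is.null(val) && best$epoch > 0L) {
    model$params <- best$params
    model$buffers <- best$buffers
  }
  list(model = model, history = do.call(rbind, hist),
       best_epoch = if (is.null(val)) epochs else best$epoch)
}

#' Two-stage training: binarized model, then quantized fine-tuning
#'
#' Stage 1 trains the binarized (`bfp`) model from scratch. Stage 2
#' initializes the fully quantized (`bq`) model from the best stage-1
#' parameters (folding BatchNorm, calibrating quantization steps and skip
#' shifts on the training images) and fine-tunes all layers with
#' quantization-aware updates (round-to-grid forward, straight-through
#' backward).
#'
#' @param data Training dataset ([phantoms_to_dataset()]).
#' @param val Validation dataset for model selection.
#' @param model_cfg A `"bfp"` [unet_config()] (stage 2 derives the `bq`
#'   config from it).
#' @param cfg A [train_config()].
#' @param skip_bits Skip bitwidth for stage 2.
#' @param init_seed Weight-initialization seed for stage 1.
#' @param verbose Print progress.
#' @return A list: `bfp` (stage-1 best model), `bq` (stage-2 best model),
#'   `history` (list of both stage histories).
#' @export
train_two_stage <- function(data, val, model_cfg, cfg = train_config(),
                            skip_bits = 6L, init_seed = 1L, verbose = FALSE) {
  stopifnot(model_cfg$variant == "bfp")
  m1 <- build_model(model_cfg, seed = init_seed)
  s1 <- train_model(m1, data, val, cfg, epochs = cfg$epochs[1],
                    verbose = verbose)
  m2 <- convert_bfp_to_bq(s1$model, skip_bits = skip_bits,
                          calib_images = data$images)
  cfg2 <- cfg
  cfg2$seed <- cfg$seed + 1L
  s2 <- train_model(m2, data, val, cfg2, epochs = cfg$epochs[2],
                    verbose = verbose)
  list(bfp = s1$model, bq = s2$model,
       history = list(stage1 = s1$history, stage2 = s2$history))
}
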