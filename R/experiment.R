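#' Scaled-down end-to-end precision-ladder experiment
#'
#' Runs the precision-ladder study at desk scale: a cohort of synthetic
#' phantoms is split by instance into train/validation/test; the
#' full-precision model is trained directly, the binarized model is trained
#' from scratch, and the fully quantized models (6/4/3-bit skips) are
#' fine-tuned from the binarized checkpoint (two-stage training). All
#' variants share the splits, augmentation seeds and initialization seed,
#' and each is selected by its best validation Dice. Held-out inner-wall
#' Dice is reported per variant, together with the trained models and test
#' data for downstream analyses (skip sparsity, compression, volumetry).
#'
#' The default problem size (200 phantoms at 64 pixels, base width 8,
#' 30 + 30 epochs) is chosen so the whole ladder trains in a few minutes on
#' one CPU; the methods vignette discusses what this scale does and does
#' not probe.
#'
#' @param n_phantoms Number of phantoms in the cohort.
#' @param img_size Phantom image / network input side length (pixels).
#' @param base_channels Network width.
#' @param epochs Two-element vector: stage-1 and stage-2 epochs.
#' @param skip_bits_set Quantized skip bitwidths to fine-tune.
#' @param batch_size Minibatch size. The default of 8 keeps the number of
#'   optimizer steps per epoch high enough for the binarized stage to
#'   converge within the reduced epoch budget of this cohort size.
#' @param seed Master seed (phantoms, splits, initialization, shuffling).
#' @param verbose Print per-epoch progress.
#' @return A list: `dice` (named held-out inner-wall Dice per variant),
#'   `models` (per variant), `test` (test dataset), `phantom_test` (test
#'   phantoms), `history`.
#' @export
run_scaled_experiment <- function(n_phantoms = 200L, img_size = 64L,
                                  base_channels = 8L, epochs = c(30L, 30L),
                                  skip_bits_set = c(6L, 4L, 3L),
                                  batch_size = 8L, seed = 1L,
                                  verbose = FALSE) {
  ph <- generate_phantoms(n_phantoms, phantom_config(img_size = img_size),
                          seed = seed)
  sp <- split_phantoms(ph, seed = seed + 1L)
  tr <- phantoms_to_dataset(sp$train)
  va <- phantoms_to_dataset(sp$val)
  te <- phantoms_to_dataset(sp$test)
  tcfg <- train_config(epochs = epochs, batch_size = batch_size,
                       seed = seed + 2L)

  models <- list(); history <- list()

  fp_cfg <- unet_config(img_size, 4L, base_channels, variant = "fp")
  fit <- train_model(build_model(fp_cfg, seed = seed + 3L), tr, va, tcfg,
                     epochs = epochs[1], verbose = verbose)
  models$fp <- fit$model; history$fp <- fit$history

  bfp_cfg <- unet_config(img_size, 4L, base_channels, variant = "bfp")
  fit <- train_model(build_model(bfp_cfg, seed = seed + 3L), tr, va, tcfg,
                     epochs = epochs[1], verbose = verbose)
  models$bfp <- fit$model; history$bfp <- fit$history

  for (sb in skip_bits_set) {
    m2 <- convert_bfp_to_bq(models$bfp, skip_bits = sb,
                            calib_images = tr$images)
    tcfg2 <- tcfg; tcfg2$seed <- tcfg$seed + 1L
    fit <- train_model(m2, tr, va, tcfg2, epochs = epochs[2],
                       verbose = verbose)
    models[[paste0("bq", sb)]] <- fit$model
    history[[paste0("bq", sb)]] <- fit$history
  }

  dice <- vapply(models, function(m) evaluate_model(m, te)[["inner"]], 0)
  list(dice = dice, models = models, test = te, phantom_test = sp$test,
       history = history)
}

#' Skip-connection sparsity and compressibility of a trained model pair
#'
#' Compares the zero fraction of the binarized model's real-valued skip
#' activations with that of the quantized model's skip codes on the same
#' images, and measures the storage reduction the best codec achieves on
#' the quantized codes relative to raw q-bit storage (worst case over
#' images, as an on-chip buffer would be provisioned).
#'
#' @param bfp_model,bq_model Trained `"bfp"` and `"bq"` models.
#' @param images List of input images.
#' @param codecs Codec ids to try.
#' @return A list: `fp_zero_fraction`, `q_zero_fraction`, `raw_bits`,
#'   `best_codec`, `best_bits`, `reduction` (fraction of raw storage saved).
#' @export
skip_sparsity_report <- function(bfp_model, bq_model, images,
                                 codecs = c("zvc", "dzvc", "bpc8", "bpc16",
                                            "ebpc")) {
  q <- bq_model$cfg$skip_bits
  fw_fp <- model_forward(bfp_model, images, collect_skips = TRUE)
  fw_q <- model_forward(bq_model, images, collect_skips = TRUE)
  nz <- function(skips) {
    tot <- 0; zero <- 0
    for (sl in skips) for (v in sl) { tot <- tot + length(v); zero <- zero + sum(v == 0) }
    zero / tot
  }
  # per-sample lists of per-connection code tensors
  code_samples <- lapply(seq_along(images), function(s) {
    lapply(seq_len(bq_model$cfg$depth), function(i) {
      sh <- bq_model$buffers[[paste0("skip", i, ".shift")]]
      v <- fw_q$skips[[i]][[s]]
      array(as.integer(round_q(v / 2^sh)), dim = dim(v))
    })
  })
  raw_bits <- sum(vapply(code_samples[[1]], length, 0L)) * q
  sizes <- vapply(codecs, function(cd)
    8 * worst_case_size(code_samples, cd, q), 0)
  best <- which.min(sizes)
  list(fp_zero_fraction = nz(fw_fp$skips), q_zero_fraction = nz(fw_q$skips),
       raw_bits = raw_bits, codec_bits = sizes,
       best_codec = codecs[best], best_bits = unname(sizes[best]),
       reduction = unname(1 - sizes[best] / raw_bits))
}

#' Volume-agreement evaluation of a segmentation model on phantoms
#'
#' Segments both views of each phantom, estimates volumes with the
#' double-area method from the predicted and the reference (ground-truth)
#' inner masks, and summarizes agreement (Bland-Altman bias and limits,
#' concordance correlation) of model-derived against reference-derived
#' volumes.
#'
#' @param model A trained `qnn_model`.
#' @param phantoms List of `phantom_sample`s (e.g. the held-out test set).
#' @param threshold Mask decision threshold.
#' @return A list: `per_case` data frame, `agreement` (`agreement_stats`),
#'   `ccc`, `mean_dice`.
#' @export
volume_agreement <- function(model, phantoms, threshold = 0.5) {
  rows <- list(); mv <- c(); cv <- c()
  for (s in phantoms) {
    masks <- list(); dices <- c()
    for (vn in c("sagittal", "transverse")) {
      fw <- model_forward(model, s$views[[vn]]$image)
      pm <- predict_mask(fw$probs[[1]], threshold)
      masks[[vn]] <- pm[, , 1]
      dices[vn] <- dice_score(pm[, , 1], s$views[[vn]]$inner)
    }
    pred <- suppressWarnings(estimate_from_pair(
      masks$sagittal, masks$transverse,
      s$views$sagittal$cm_per_pixel, s$views$transverse$cm_per_pixel,
      source = "model_mask"))
    ref <- estimate_from_pair(
      s$views$sagittal$inner, s$views$transverse$inner,
      s$views$sagittal$cm_per_pixel, s$views$transverse$cm_per_pixel,
      source = "clinician_mask")
    mv <- c(mv, pred$volume_ml); cv <- c(cv, ref$volume_ml)
    rows[[length(rows) + 1L]] <- data.frame(
      id = s$id, dice_sag = dices[["sagittal"]],
      dice_trans = dices[["transverse"]], model_volume_ml = pred$volume_ml,
      reference_volume_ml = ref$volume_ml,
      true_volume_ml = s$true_volume_ml)
  }
  per_case <- do.call(rbind, rows)
  ba <- bland_altman(mv, cv)
  list(per_case = per_case, agreement = ba, ccc = concordance_cc(mv, cv),
       mean_dice = mean(c(per_case$dice_sag, per_case$dice_trans)))
}
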