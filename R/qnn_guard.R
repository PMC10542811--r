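# Fixed-point guarded inference for the fully quantized variant, plus the
# XNOR/popcount formulation of binary convolution.
#
# The guarded interpreter executes the same op tape as the C++ engine but
# tracks, for every intermediate tensor, a per-channel power-of-two grid
# exponent g such that every value must equal an integer times 2^g.  After
# each op it verifies (exactly, in double arithmetic, which is lossless for
# these magnitudes) that all values sit on their grid and that every
# multiplicative constant in the path is +-1, a power of two, or a small
# integer code times a power-of-two step -- i.e. that the inference pass
# involves no general real-valued multiplication.

# 3x3 convolution, padding 1, single channel, vectorized over shifts
r_conv3 <- function(x, w9, stride = 1L) {
  H <- nrow(x); W <- ncol(x)
  Ho <- (H - 1L) %/% stride + 1L; Wo <- (W - 1L) %/% stride + 1L
  P <- matrix(0, H + 2L, W + 2L)
  P[2:(H + 1L), 2:(W + 1L)] <- x
  out <- matrix(0, Ho, Wo)
  for (dj in 0:2) for (di in 0:2) {
    out <- out + w9[di + 1L, dj + 1L] *
      P[(0:(Ho - 1L)) * stride + di + 1L, (0:(Wo - 1L)) * stride + dj + 1L,
        drop = FALSE]
  }
  out
}

is_pow2 <- function(v) {
  v <- abs(v)
  v > 0 & log2(v) == round(log2(v))
}

on_grid <- function(cur, gexp) {
  for (c in seq_len(dim(cur)[3])) {
    v <- cur[, , c] / 2^gexp[c]
    if (any(v != round(v))) return(FALSE)
  }
  TRUE
}

#' Guarded fixed-point inference for the fully quantized model
#'
#' Runs a `bq` model forward in a reference R interpreter that represents
#' every intermediate tensor as integer codes on a power-of-two grid and
#' asserts, op by op, that (a) all values remain exactly on their grid and
#' (b) every multiplicative constant is `+-1`, a power of two, or a <= 4-bit
#' integer code times a power-of-two step -- i.e. the inference path performs
#' no general floating-point multiplication. The segmentation decision is
#' taken on the integer logits (`logit > 0` is equivalent to a probability
#' above 0.5), so the sigmoid is outside the guarded region and only computed
#' for reporting.
#'
#' @param model A `"bq"` `qnn_model`.
#' @param image Input image matrix (values in `[0, 1]`).
#' @return A list: `logits`, `probs`, `mask`, `guard` (per-op check table)
#'   and `all_ok`.
#' @export
guarded_forward <- function(model, image) {
  stopifnot(inherits(model, "qnn_model"))
  if (model$cfg$variant != "bq")
    stop("guard mode applies to the fully quantized (bq) variant")
  p <- model$params; b <- model$buffers
  cur <- as_input_array(image)
  gexp <- 0
  skips <- list(); skip_g <- list()
  checks <- list()
  note <- function(opname, grid, scales)
    checks[[length(checks) + 1L]] <<- data.frame(op = opname,
                                                 grid_exact = grid,
                                                 scales_fixed_point = scales)
  for (op in model$tape) {
    nm <- op$name %||% op$op
    switch(op$op,
      quant_input = {
        cur[] <- pmin(pmax(round_q(cur * 16), 0), 15) / 16
        gexp <- -4
        note("quant_input", on_grid(cur, gexp), TRUE)
      },
      conv_stem = {
        ws <- b[[paste0(nm, ".wshift")]]
        wcode <- pmin(pmax(round_q(p[[paste0(nm, ".w")]] / 2^ws), -8), 7)
        wq <- wcode * 2^ws
        Cout <- dim(wq)[3]
        Ho <- (dim(cur)[1] - 1L) %/% op$stride + 1L
        y <- array(0, c(Ho, Ho, Cout))
        for (c in seq_len(Cout))
          y[, , c] <- r_conv3(cur[, , 1], wq[, , c], op$stride)
        cur <- y
        gexp <- rep(gexp[1] + ws, Cout)
        note(nm, on_grid(cur, gexp),
             all(wcode == round(wcode)) && all(abs(wcode) <= 8))
      },
      rsign = {
        a <- pmin(pmax(round_q(p[[paste0(nm, ".alpha")]] / 0.25), -8), 7) * 0.25
        for (c in seq_len(dim(cur)[3]))
          cur[, , c] <- ifelse(cur[, , c] > a[c], 1, -1)
        gexp <- rep(0, dim(cur)[3])
        note(nm, on_grid(cur, gexp), TRUE)
      },
      dw = {
        wb <- binarize_weights(p[[paste0(nm, ".w")]], channel_dim = 3L)
        y <- NULL
        for (c in seq_len(dim(cur)[3])) {
          o <- r_conv3(cur[, , c], wb[, , c], op$stride)
          if (is.null(y)) y <- array(0, c(nrow(o), ncol(o), dim(cur)[3]))
          y[, , c] <- o
        }
        cur <- y
        note(nm, on_grid(cur, gexp), all(abs(wb) == 1))
      },
      pw = {
        wb <- binarize_weights(p[[paste0(nm, ".w")]], channel_dim = 2L)
        d <- dim(cur)
        m <- matrix(cur, d[1] * d[2], d[3]) %*% wb
        cur <- array(m, c(d[1], d[2], ncol(wb)))
        gexp <- rep(gexp[1], ncol(wb))  # inputs are +-1 on the integer grid
        note(nm, on_grid(cur, gexp), all(abs(wb) == 1))
      },
      affine = {
        w <- p[[paste0(nm, ".w")]]
        sn <- bn_to_shiftnorm(w, p[[paste0(nm, ".b")]],
                              bias_step = b[[paste0(nm, ".bstep")]])
        scale <- sn$sign * 2^sn$shift
        for (c in seq_along(scale))
          cur[, , c] <- scale[c] * cur[, , c] + sn$bias[c]
        gexp <- pmin(gexp + sn$shift, sn$bias_step)
        note(nm, on_grid(cur, gexp), all(is_pow2(scale)))
      },
      act = {
        be <- pmin(pmax(round_q(p[[paste0(nm, ".beta")]] / 0.25), 0), 3) * 0.25
        gs <- b[[paste0(nm, ".gstep")]]; es <- b[[paste0(nm, ".estep")]]
        ga <- pmin(pmax(round_q(p[[paste0(nm, ".gamma")]] / 2^gs), -8), 7) * 2^gs
        et <- pmin(pmax(round_q(p[[paste0(nm, ".eta")]] / 2^es), -8), 7) * 2^es
        for (c in seq_along(be)) {
          v <- cur[, , c]
          cur[, , c] <- ifelse(v > ga[c], (v - ga[c]) + et[c],
                               be[c] * (v - ga[c]) + et[c])
        }
        gexp <- pmin(pmin(gexp, gs) - 2, es)
        note(nm, on_grid(cur, gexp), all(be %in% c(0, 0.25, 0.5, 0.75)))
      },
      skip_save = {
        sh <- b[[paste0(nm, ".shift")]]
        codes <- pmin(pmax(round_q(cur / 2^sh), 0), 2^op$bits - 1)
        cur <- codes * 2^sh
        gexp <- rep(sh, dim(cur)[3])
        skips[[op$slot]] <- cur
        skip_g[[op$slot]] <- gexp
        note(nm, on_grid(cur, gexp), TRUE)
      },
      skip_cat = {
        s <- skips[[op$slot]]
        d <- dim(cur)
        cur <- array(c(cur, s), c(d[1], d[2], d[3] + dim(s)[3]))
        gexp <- c(gexp, skip_g[[op$slot]])
        note(paste0("cat", op$slot), on_grid(cur, gexp), TRUE)
      },
      upsample = {
        d <- dim(cur)
        y <- array(0, c(2L * d[1], 2L * d[2], d[3]))
        for (c in seq_len(d[3]))
          y[, , c] <- kronecker(cur[, , c], matrix(1, 2, 2))
        cur <- y
        note("upsample", on_grid(cur, gexp), TRUE)
      },
      sigmoid = {
        # end of the guarded integer path; logits already in `cur`
      })
  }
  guard <- do.call(rbind, checks)
  logits <- cur
  probs <- 1 / (1 + exp(-logits))
  mask <- (logits > 0) + 0
  dim(mask) <- dim(logits)
  list(logits = logits, probs = probs, mask = mask, guard = guard,
       all_ok = all(guard$grid_exact) && all(guard$scales_fixed_point))
}

#' Binary convolution in +-1 arithmetic and XNOR/popcount form
#'
#' Reference implementations (direct loops, "valid" padding) of the same
#' binary convolution computed two ways: as an ordinary dot product of
#' `{-1, +1}` tensors, and as hardware would compute it -- XNOR of the sign
#' bits followed by a population count, mapped back via
#' `2 * popcount - n`. The two agree exactly.
#'
#' @param x `H x W x Cin` array with entries in `{-1, +1}`.
#' @param w `kh x kw x Cin x Cout` weight array with entries in `{-1, +1}`.
#' @param stride Convolution stride.
#' @return `Ho x Wo x Cout` integer-valued array.
#' @export
binary_conv2d <- function(x, w, stride = 1L) {
  stopifnot(all(abs(x) == 1), all(abs(w) == 1))
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  stopifnot(dim(x)[3] == cin)
  Ho <- (dim(x)[1] - kh) %/% stride + 1L
  Wo <- (dim(x)[2] - kw) %/% stride + 1L
  out <- array(0, c(Ho, Wo, cout))
  for (co in seq_len(cout)) {
    wc <- array(w[, , , co], c(kh, kw, cin))
    for (jo in seq_len(Wo)) for (io in seq_len(Ho)) {
      i0 <- (io - 1L) * stride; j0 <- (jo - 1L) * stride
      patch <- x[i0 + seq_len(kh), j0 + seq_len(kw), , drop = FALSE]
      out[io, jo, co] <- sum(patch * wc)
    }
  }
  out
}

#' @rdname binary_conv2d
#' @export
xnor_popcount_conv2d <- function(x, w, stride = 1L) {
  stopifnot(all(abs(x) == 1), all(abs(w) == 1))
  xb <- x > 0; wb <- w > 0
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  n <- kh * kw * cin
  Ho <- (dim(x)[1] - kh) %/% stride + 1L
  Wo <- (dim(x)[2] - kw) %/% stride + 1L
  out <- array(0, c(Ho, Wo, cout))
  for (co in seq_len(cout)) {
    wc <- array(wb[, , , co], c(kh, kw, cin))
    for (jo in seq_len(Wo)) for (io in seq_len(Ho)) {
      i0 <- (io - 1L) * stride; j0 <- (jo - 1L) * stride
      patch <- xb[i0 + seq_len(kh), j0 + seq_len(kw), , drop = FALSE]
      popcount <- sum(patch == wc)          # XNOR then count
      out[io, jo, co] <- 2L * popcount - n
    }
  }
  out
}
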