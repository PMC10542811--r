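#' Dice overlap score of two binary masks
#'
#' \eqn{\mathrm{Dice} = 2|A \cap B| / (|A| + |B|)}, with an additive
#' smoothing `eps` on numerator and denominator so that two empty masks
#' score 1 rather than 0/0.
#'
#' @param a,b Binary (0/1) masks of equal shape.
#' @param eps Smoothing constant.
#' @return Dice score in `[0, 1]`.
#' @export
dice_score <- function(a, b, eps = 1) {
  stopifnot(identical(dim(a), dim(b)))
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("masks must be binary (0/1)")
  (2 * sum(a * b) + eps) / (sum(a) + sum(b) + eps)
}

#' Bland-Altman agreement between model and clinician volumes
#'
#' Differences are taken as model minus clinician; the bias is their mean
#' and the 95% limits of agreement are bias +- 1.96 standard deviations
#' (sample SD, n-1). Because the clinician estimate is treated as the
#' reference, plots put the clinician volume on the x-axis rather than the
#' pair mean.
#'
#' @param model_vols,clinician_vols Paired volume series (ml), length >= 2.
#' @return An `agreement_stats` list: `bias`, `loa_low`, `loa_high`, `sd`,
#'   `n` and the per-pair `differences`.
#' @export
bland_altman <- function(model_vols, clinician_vols) {
  stopifnot(length(model_vols) == length(clinician_vols),
            length(model_vols) >= 2)
  d <- model_vols - clinician_vols
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d), differences = d,
                 clinician = clinician_vols, model = model_vols),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> n=%d, bias %.2f ml, 95%% LoA [%.2f, %.2f] ml\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{\rho_c = \frac{2\,\mathrm{cov}(x,y)}{\mathrm{var}(x) +
#'   \mathrm{var}(y) + (\bar{x} - \bar{y})^2}}
#' using population (1/n) moments, per Lin's original definition. Penalizes
#' both decorrelation and mean/scale shifts; `|ccc| <= |pearson|`.
#'
#' @param x,y Paired numeric series, length >= 2, not both constant.
#' @return CCC in `[-1, 1]`.
#' @export
concordance_cc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  if (vx == 0 && vy == 0) stop("CCC undefined: both series are constant")
  cxy <- mean((x - mx) * (y - my))
  2 * cxy / (vx + vy + (mx - my)^2)
}

#' Bland-Altman plot with the clinician volume on the x-axis
#'
#' @param stats An `agreement_stats` from [bland_altman()].
#' @return A ggplot object: differences against clinician volume, with the
#'   bias and the 95% limits of agreement drawn as horizontal lines.
#' @export
plot_bland_altman <- function(stats) {
  stopifnot(inherits(stats, "agreement_stats"))
  df <- data.frame(clinician = stats$clinician, difference = stats$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = clinician, y = difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = stats$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(stats$loa_low, stats$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Clinician volume (ml)",
                  y = "Model - clinician (ml)",
                  title = sprintf("Bias %.1f ml, 95%% LoA [%.1f, %.1f] ml",
                                  stats$bias, stats$loa_low, stats$loa_high)) +
    ggplot2::theme_minimal()
}
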