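#' Synthetic B-mode bladder phantom configuration
#'
#' The generator emulates paired sagittal/transverse B-mode views of one
#' underlying ellipsoidal bladder: a hypoechoic (dark) lumen bounded by an
#' echogenic (bright) wall annulus on a mid-gray background, smoothed by a
#' Gaussian point-spread proxy, modulated by a mild depth-dependent
#' attenuation gradient and multiplicative Rayleigh speckle of unit mean.
#' The sagittal section shows semi-axes (a, c) and the transverse section
#' (a, b) of the same ellipsoid, so the true volume
#' \eqn{V = \frac{4}{3}\pi a b c} is known exactly.
#'
#' @param img_size Image side length in pixels.
#' @param axes_range_cm Range of the ellipsoid semi-axes (cm).
#' @param wall_range_cm Range of the bladder wall thickness (cm).
#' @param scale_range_cmpx Range of the physical pixel scale (cm/pixel).
#'   The default keeps the physical field of view of a 224-pixel image
#'   (0.03-0.06 cm/px at 224) for any `img_size`.
#' @param center_jitter Maximum center offset as a fraction of the field of
#'   view (further limited by what keeps the bladder inside the image).
#' @param max_rotation_deg In-plane pose rotation range (+-).
#' @param background,wall_intensity,lumen_intensity Tissue gray levels.
#' @param blur_sigma Gaussian point-spread proxy, in pixels.
#' @param attenuation Fractional intensity drop from the top to the bottom
#'   row (depth-dependent attenuation).
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(img_size = 224L,
                           axes_range_cm = c(1, 6),
                           wall_range_cm = c(0.2, 0.5),
                           scale_range_cmpx = c(0.03, 0.06) * 224 / img_size,
                           center_jitter = 0.08,
                           max_rotation_deg = 20,
                           background = 0.35, wall_intensity = 0.75,
                           lumen_intensity = 0.08,
                           blur_sigma = 1.5, attenuation = 0.25) {
  stopifnot(img_size >= 16, all(axes_range_cm > 0), all(wall_range_cm > 0),
            all(scale_range_cmpx > 0))
  structure(as.list(environment()), class = "phantom_config")
}

# rasterize one view; returns the view component list
render_view <- function(rh, rv, t, cfg, margin = 0.97, max_retry = 100L) {
  S <- cfg$img_size
  # a pixel scale large enough that the outer ellipse fits the field of view
  need <- 2 * (max(rh, rv) + t) / (margin * S)
  lo <- max(cfg$scale_range_cmpx[1], need)
  if (lo > cfg$scale_range_cmpx[2])
    stop("bladder (", round(max(rh, rv) + t, 2),
         " cm semi-axis) cannot fit the field of view at any allowed scale")
  for (retry in seq_len(max_retry)) {
    scale <- stats::runif(1, lo, cfg$scale_range_cmpx[2])
    fov <- S * scale
    theta <- stats::runif(1, -cfg$max_rotation_deg, cfg$max_rotation_deg) * pi / 180
    # bounding half-extents of the rotated outer ellipse
    bx <- sqrt(((rh + t) * cos(theta))^2 + ((rv + t) * sin(theta))^2)
    by <- sqrt(((rh + t) * sin(theta))^2 + ((rv + t) * cos(theta))^2)
    slack_x <- margin * fov / 2 - bx
    slack_y <- margin * fov / 2 - by
    if (slack_x < 0 || slack_y < 0) next   # re-draw pose
    cx <- stats::runif(1, -1, 1) * min(slack_x, cfg$center_jitter * fov)
    cy <- stats::runif(1, -1, 1) * min(slack_y, cfg$center_jitter * fov)
    # pixel-center coordinates (cm), image centered on the probe axis
    ax <- (seq_len(S) - 0.5) * scale - fov / 2
    X <- matrix(ax, S, S, byrow = TRUE)   # columns = lateral
    Y <- matrix(ax, S, S)                 # rows = depth
    dx <- X - cx; dy <- Y - cy
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    inner <- (u / rh)^2 + (v / rv)^2 <= 1
    outer <- (u / (rh + t))^2 + (v / (rv + t))^2 <= 1
    anatomy <- matrix(cfg$background, S, S)
    anatomy[outer] <- cfg$wall_intensity
    anatomy[inner] <- cfg$lumen_intensity
    if (cfg$blur_sigma > 0)
      anatomy <- as.matrix(EBImage::gblur(anatomy, sigma = cfg$blur_sigma))
    atten <- seq(1, 1 - cfg$attenuation, length.out = S)
    # Rayleigh speckle with unit mean: sigma = sqrt(2/pi)
    speckle <- matrix(sqrt(2 / pi) * sqrt(-2 * log(stats::runif(S * S))), S, S)
    view <- list(anatomy = anatomy, atten = atten, speckle = speckle,
                 inner = inner + 0, outer = outer + 0,
                 cm_per_pixel = scale,
                 geom = list(rh = rh, rv = rv, wall = t, cx = cx, cy = cy,
                             theta = theta, u = NULL))
    view$image <- compose_view(view)
    return(view)
  }
  stop("could not place the bladder inside the field of view after ",
       max_retry, " pose draws")
}

compose_view <- function(view) {
  img <- view$anatomy * view$atten * view$speckle
  pmin(pmax(img, 0), 1)
}

#' Generate synthetic bladder phantoms
#'
#' Draws `n` independent phantoms (ellipsoid semi-axes, wall thickness,
#' per-view pixel scale and pose) and renders the paired sagittal and
#' transverse views with their inner/outer wall masks. Masks are rasterized
#' from the exact geometry before any blur or noise is applied. Generation
#' is fully reproducible from `seed`.
#'
#' @param n Number of phantoms.
#' @param cfg A [phantom_config()].
#' @param seed Integer seed.
#' @return A list of `phantom_sample` objects; each has `views$sagittal` and
#'   `views$transverse` (image, masks, cm/pixel, noise components),
#'   `semi_axes_cm`, `wall_cm`, `true_volume_ml` and `id`.
#' @export
generate_phantoms <- function(n, cfg = phantom_config(), seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    ax <- stats::runif(3, cfg$axes_range_cm[1], cfg$axes_range_cm[2])
    a <- ax[1]; b <- ax[2]; cc <- ax[3]
    t <- stats::runif(1, cfg$wall_range_cm[1], cfg$wall_range_cm[2])
    sag <- render_view(a, cc, t, cfg)     # sagittal: semi-axes (a, c)
    tra <- render_view(a, b, t, cfg)      # transverse: semi-axes (a, b)
    structure(list(views = list(sagittal = sag, transverse = tra),
                   semi_axes_cm = c(a = a, b = b, c = cc), wall_cm = t,
                   true_volume_ml = 4 / 3 * pi * a * b * cc,
                   id = k, seed = seed),
              class = "phantom_sample")
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample #%d> semi-axes %.2f/%.2f/%.2f cm, wall %.2f cm, true volume %.1f ml\n",
              x$id, x$semi_axes_cm[1], x$semi_axes_cm[2], x$semi_axes_cm[3],
              x$wall_cm, x$true_volume_ml))
  invisible(x)
}

#' Degrade the bladder wall of a phantom
#'
#' Locally erases the wall contrast over an angular sector whose width is
#' proportional to `level` (`level = 1` erases the full annulus), crudely
#' emulating a poorly defined bladder wall. The ground-truth masks are kept
#' unchanged, as the annotation remains the reference.
#'
#' @param sample A `phantom_sample`.
#' @param level Degradation level in `[0, 1]`.
#' @param cfg The [phantom_config()] used to generate the sample (for the
#'   background gray level).
#' @return The degraded `phantom_sample`.
#' @export
degrade_phantom <- function(sample, level, cfg = phantom_config()) {
  stopifnot(level >= 0, level <= 1)
  if (level == 0) return(sample)
  for (vn in names(sample$views)) {
    view <- sample$views[[vn]]
    S <- nrow(view$anatomy)
    g <- view$geom
    scale <- view$cm_per_pixel
    ax <- (seq_len(S) - 0.5) * scale - S * scale / 2
    X <- matrix(ax, S, S, byrow = TRUE); Y <- matrix(ax, S, S)
    dx <- X - g$cx; dy <- Y - g$cy
    u <- dx * cos(g$theta) + dy * sin(g$theta)
    v <- -dx * sin(g$theta) + dy * cos(g$theta)
    phi <- atan2(v, u)
    wall <- view$outer > 0 & view$inner == 0
    sector <- abs(phi) <= level * pi     # width level * 2*pi, level 1 = all
    view$anatomy[wall & sector] <- cfg$background
    view$image <- compose_view(view)
    sample$views[[vn]] <- view
  }
  sample
}

#' Split phantoms into disjoint train/validation/test sets
#'
#' Splitting is by phantom instance (both views of a phantom stay in the
#' same subset) and reproducible from `seed`.
#'
#' @param samples List of `phantom_sample`s.
#' @param frac Named fractions `c(train=, val=, test=)`; must sum to 1.
#' @param seed Integer seed.
#' @return A list with `train`, `val` and `test` sample lists.
#' @export
split_phantoms <- function(samples, frac = c(train = 0.7, val = 0.15,
                                             test = 0.15), seed = 1L) {
  stopifnot(abs(sum(frac) - 1) < 1e-8)
  n <- length(samples)
  set.seed(seed)
  idx <- sample.int(n)
  ntr <- round(frac[["train"]] * n)
  nva <- round(frac[["val"]] * n)
  list(train = samples[idx[seq_len(ntr)]],
       val = samples[idx[ntr + seq_len(nva)]],
       test = samples[idx[setdiff(seq_len(n), seq_len(ntr + nva))]])
}

#' Convert phantoms to a training dataset
#'
#' Both views of each phantom become independent training images (the
#' clinical workflow mixes sagittal and transverse images at training time).
#'
#' @param samples List of `phantom_sample`s.
#' @param out_channels 1 (inner mask only) or 2 (inner + outer masks).
#' @return A list with `images` (list of matrices), `masks` (list of
#'   `H x W x out_channels` arrays) and `meta` (data frame: phantom id,
#'   view, cm/pixel, true volume).
#' @export
phantoms_to_dataset <- function(samples, out_channels = 2L) {
  images <- list(); masks <- list(); meta <- list()
  for (s in samples) for (vn in names(s$views)) {
    v <- s$views[[vn]]
    images[[length(images) + 1L]] <- v$image
    m <- if (out_channels == 2L) {
      array(c(v$inner, v$outer), dim = c(dim(v$inner), 2L))
    } else array(v$inner, dim = c(dim(v$inner), 1L))
    masks[[length(masks) + 1L]] <- m
    meta[[length(meta) + 1L]] <- data.frame(id = s$id, view = vn,
                                            cm_per_pixel = v$cm_per_pixel,
                                            true_volume_ml = s$true_volume_ml)
  }
  list(images = images, masks = masks, meta = do.call(rbind, meta))
}

#' Write / read phantoms as PNG images with JSON sidecars
#'
#' Each phantom writes `sNNN_{sag,trans}.png`, the corresponding
#' `*_inner.png` / `*_outer.png` masks and one `sNNN.json` sidecar with the
#' pixel scales, true volume, semi-axes and seed. Images are stored as
#' 8-bit grayscale PNG; masks are binary PNG and round-trip exactly.
#'
#' @param samples List of `phantom_sample`s.
#' @param dir Output directory (created if needed).
#' @return `read_phantoms` returns a list of samples (images and masks only;
#'   the noise decomposition is not persisted).
#' @export
write_phantoms <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in samples) {
    base <- file.path(dir, sprintf("s%03d", s$id))
    for (vn in c("sagittal", "transverse")) {
      tag <- if (vn == "sagittal") "sag" else "trans"
      v <- s$views[[vn]]
      png::writePNG(v$image, paste0(base, "_", tag, ".png"), dpi = NULL)
      png::writePNG(v$inner, paste0(base, "_", tag, "_inner.png"))
      png::writePNG(v$outer, paste0(base, "_", tag, "_outer.png"))
    }
    jsonlite::write_json(
      list(id = s$id,
           cm_per_pixel = list(sagittal = s$views$sagittal$cm_per_pixel,
                               transverse = s$views$transverse$cm_per_pixel),
           true_volume_ml = s$true_volume_ml,
           semi_axes_cm = as.list(s$semi_axes_cm), wall_cm = s$wall_cm,
           seed = s$seed),
      paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_phantoms
#' @export
read_phantoms <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "^s[0-9]+\\.json$",
                              full.names = TRUE))
  lapply(sidecars, function(f) {
    meta <- jsonlite::read_json(f, simplifyVector = TRUE)
    base <- sub("\\.json$", "", f)
    views <- list()
    for (vn in c("sagittal", "transverse")) {
      tag <- if (vn == "sagittal") "sag" else "trans"
      views[[vn]] <- list(
        image = png::readPNG(paste0(base, "_", tag, ".png")),
        inner = round(png::readPNG(paste0(base, "_", tag, "_inner.png"))),
        outer = round(png::readPNG(paste0(base, "_", tag, "_outer.png"))),
        cm_per_pixel = meta$cm_per_pixel[[vn]])
    }
    structure(list(views = views,
                   semi_axes_cm = unlist(meta$semi_axes_cm),
                   wall_cm = meta$wall_cm,
                   true_volume_ml = meta$true_volume_ml,
                   id = meta$id, seed = meta$seed),
              class = "phantom_sample")
  })
}
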