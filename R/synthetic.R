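# Seeded synthetic dermoscopy-like image generator. Each image is a skin-tone
# background carrying one elliptical lesion whose color/texture parameters are
# class-specific, with optional hair-stroke and droplet artifacts drawn over
# the image (never into the mask). The generator exists so that segmentation,
# classification, uncertainty gating and saliency can all be exercised
# end-to-end without external data, with pixel-exact ground truth.

#' Default class palette
#'
#' One row per class: lesion base color (RGB in \[0, 1\]) plus a sinusoidal
#' texture amplitude and spatial frequency. Colors are pairwise separated by
#' more than three times the default pixel noise so classes remain learnable,
#' while two pairs (4/5 and 6/7) are deliberately close in color — emulating
#' visually confusable diagnostic categories — so that referral gating has
#' genuine borderline cases to act on.
#'
#' @param n_classes number of classes (1..7 rows of the built-in table)
#' @return data.frame with columns `r`, `g`, `b`, `texture_amp`, `texture_freq`
#' @export
default_class_palette <- function(n_classes = 7) {
  pal <- data.frame(
    r = c(0.15, 0.45, 0.85, 0.72, 0.62, 0.38, 0.52),
    g = c(0.10, 0.28, 0.55, 0.34, 0.46, 0.24, 0.20),
    b = c(0.08, 0.18, 0.55, 0.28, 0.26, 0.34, 0.42),
    texture_amp = c(0.03, 0.05, 0.02, 0.06, 0.08, 0.04, 0.03),
    texture_freq = c(4, 6, 3, 8, 10, 5, 7)
  )
  if (n_classes > nrow(pal)) stop("built-in palette supports at most 7 classes")
  pal[seq_len(n_classes), , drop = FALSE]
}

#' Configuration of the synthetic image generator
#'
#' @param image_height,image_width image size in pixels
#' @param n_classes number of lesion classes
#' @param lesion_radius_range lesion radius as a fraction of `min(H, W)`,
#'   length-2 numeric in (0, 0.5]
#' @param class_palette per-class color/texture table
#'   (see [default_class_palette()])
#' @param artifact_rate probability in \[0, 1\] of drawing each artifact type
#'   (hair strokes, droplets) on an image
#' @param noise_sd standard deviation of additive pixel noise
#' @param seed integer seed controlling dataset generation
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(image_height = 224, image_width = 224,
                             n_classes = 7,
                             lesion_radius_range = c(0.15, 0.30),
                             class_palette = default_class_palette(n_classes),
                             artifact_rate = 0.3,
                             noise_sd = 0.05,
                             seed = 1L) {
  stopifnot(image_height >= 8, image_width >= 8, n_classes >= 1)
  if (any(lesion_radius_range <= 0) || any(lesion_radius_range > 0.5)) {
    stop("lesion_radius_range values must lie in (0, 0.5]")
  }
  if (artifact_rate < 0 || artifact_rate > 1) stop("artifact_rate must be in [0, 1]")
  if (nrow(class_palette) != n_classes) {
    stop("class_palette must have exactly n_classes rows")
  }
  pm <- as.matrix(class_palette)
  if (anyDuplicated(pm)) stop("class_palette rows must be pairwise distinct")
  structure(list(image_height = image_height, image_width = image_width,
                 n_classes = n_classes,
                 lesion_radius_range = sort(lesion_radius_range),
                 class_palette = class_palette,
                 artifact_rate = artifact_rate,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' A single sample: image, optional mask, optional label
#'
#' @param image (H, W, 3) array with values in \[0, 1\]
#' @param mask optional (H, W) binary matrix (exact lesion support)
#' @param label optional integer class label in `1..n_classes`
#' @param sample_id identifier string
#' @param ... additional metadata fields kept on the object
#' @return a `lesion_sample` list
#' @export
lesion_sample <- function(image, mask = NULL, label = NULL,
                          sample_id = "sample", ...) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  if (min(image) < 0 || max(image) > 1) stop("image values must lie in [0, 1]")
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(image)[1:2]))
    if (!all(mask %in% c(0, 1))) stop("mask values must be binary")
  }
  structure(c(list(image = image, mask = mask, label = label,
                   sample_id = sample_id), list(...)),
            class = "lesion_sample")
}

paint_hair <- function(img, rng_dummy = NULL) {
  H <- dim(img)[1]; W <- dim(img)[2]
  n_strokes <- sample(1:3, 1)
  hair_col <- c(0.08, 0.06, 0.05)
  tk <- max(0L, round(min(H, W) / 120))
  painted <- integer(0)
  for (s in seq_len(n_strokes)) {
    p0 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
    p2 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
    p1 <- (p0 + p2) / 2 + stats::rnorm(2, 0, 0.3 * min(H, W))
    t <- seq(0, 1, length.out = 3L * (H + W))
    py <- (1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1]
    px <- (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2]
    for (dy in -tk:tk) for (dx in -tk:tk) {
      yi <- round(py) + dy; xi <- round(px) + dx
      ok <- yi >= 1 & yi <= H & xi >= 1 & xi <= W
      idx <- unique(yi[ok] + (xi[ok] - 1L) * H)
      painted <- c(painted, idx)
      for (c in 1:3) {
        ch <- img[, , c]
        ch[idx] <- 0.25 * ch[idx] + 0.75 * hair_col[c]
        img[, , c] <- ch
      }
    }
  }
  list(img = img, idx = unique(painted))
}

paint_droplets <- function(img) {
  H <- dim(img)[1]; W <- dim(img)[2]
  n_drops <- sample(1:3, 1)
  gy <- rep(seq_len(H), times = W)
  gx <- rep(seq_len(W), each = H)
  painted <- integer(0)
  for (s in seq_len(n_drops)) {
    cy <- stats::runif(1, 0.2 * H, 0.8 * H)
    cx <- stats::runif(1, 0.2 * W, 0.8 * W)
    r <- stats::runif(1, 0.04, 0.09) * min(H, W)
    d <- sqrt((gy - cy)^2 + (gx - cx)^2)
    alpha <- 0.55 * exp(-2 * (d / r)^2)
    alpha[d > 1.3 * r] <- 0
    alpha[d < 0.35 * r] <- 0.85
    idx <- which(alpha > 0)
    painted <- c(painted, idx)
    bright <- c(0.96, 0.96, 0.98)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[idx] <- (1 - alpha[idx]) * ch[idx] + alpha[idx] * bright[c]
      img[, , c] <- ch
    }
  }
  list(img = img, idx = unique(painted))
}

#' Generate one synthetic lesion image
#'
#' Renders a skin-tone background, one elliptical lesion drawn from the
#' class palette (its exact pixel support returned as the mask), additive
#' Gaussian pixel noise, and — each with probability `artifact_rate` — dark
#' curved hair strokes and bright circular droplets painted over the image.
#' Artifacts never alter the mask; the linear indices of artifact pixels are
#' kept in `$artifact_idx`.
#'
#' @param config a [synthetic_config()]
#' @param class_index class label in `1..n_classes`
#' @param seed optional integer seed; when `NULL` the current RNG stream is used
#' @param sample_id identifier for the sample
#' @return a [lesion_sample()] with fields `bg_tone`, `has_hair`,
#'   `has_droplet`, `artifact_idx` in addition to image/mask/label
#' @export
generate_sample <- function(config, class_index, seed = NULL,
                            sample_id = sprintf("c%d_s", class_index)) {
  stopifnot(inherits(config, "synthetic_config"))
  if (class_index < 1 || class_index > config$n_classes) {
    stop(sprintf("class_index %d out of range 1..%d", class_index, config$n_classes))
  }
  if (!is.null(seed)) set.seed(seed)
  H <- config$image_height; W <- config$image_width
  gy <- rep(seq_len(H), times = W)
  gx <- rep(seq_len(W), each = H)

  # skin background: warm tone with a mild smooth gradient
  bg_tone <- pmin(pmax(c(0.87, 0.72, 0.62) + stats::rnorm(3, 0, 0.025), 0), 1)
  gdir <- stats::runif(1, 0, 2 * pi)
  grad <- ((gy - H / 2) * sin(gdir) + (gx - W / 2) * cos(gdir)) / max(H, W)
  img <- array(0, c(H, W, 3))
  for (c in 1:3) img[, , c] <- bg_tone[c] + 0.05 * grad

  # elliptical lesion; axes r*s and r/s keep area pi*r^2 independent of
  # eccentricity, so pixel counts track the analytic area
  rr <- stats::runif(1, config$lesion_radius_range[1], config$lesion_radius_range[2])
  r <- rr * min(H, W)
  s <- stats::runif(1, 1, 1.15)
  a_ax <- r * s; b_ax <- r / s
  th <- stats::runif(1, 0, pi)
  cy <- H / 2 + stats::runif(1, -0.08, 0.08) * H
  cx <- W / 2 + stats::runif(1, -0.08, 0.08) * W
  u <- (gy - cy) * cos(th) + (gx - cx) * sin(th)
  v <- -(gy - cy) * sin(th) + (gx - cx) * cos(th)
  rho2 <- (u / a_ax)^2 + (v / b_ax)^2
  inside <- rho2 <= 1
  mask <- matrix(0, H, W)
  mask[inside] <- 1

  pal <- config$class_palette[class_index, ]
  col <- pmin(pmax(c(pal$r, pal$g, pal$b) + stats::rnorm(3, 0, 0.02), 0), 1)
  phi0 <- stats::runif(1, 0, pi)
  tex <- pal$texture_amp *
    sin(2 * pi * pal$texture_freq * (u * cos(phi0) + v * sin(phi0)) / (2 * r))
  shade <- 0.85 + 0.3 * sqrt(pmin(rho2, 1)) # darker core, lighter rim
  for (c in 1:3) {
    ch <- img[, , c]
    ch[inside] <- col[c] * shade[inside] + tex[inside]
    img[, , c] <- ch
  }

  if (config$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, config$noise_sd)
  }
  img <- pmin(pmax(img, 0), 1)

  has_hair <- stats::runif(1) < config$artifact_rate
  has_droplet <- stats::runif(1) < config$artifact_rate
  artifact_idx <- integer(0)
  if (has_hair) {
    res <- paint_hair(img)
    img <- res$img
    artifact_idx <- c(artifact_idx, res$idx)
  }
  if (has_droplet) {
    res <- paint_droplets(img)
    img <- res$img
    artifact_idx <- c(artifact_idx, res$idx)
  }
  img <- pmin(pmax(img, 0), 1)

  lesion_sample(img, mask = mask, label = class_index, sample_id = sample_id,
                bg_tone = bg_tone, has_hair = has_hair,
                has_droplet = has_droplet,
                artifact_idx = sort(unique(artifact_idx)))
}

#' Generate a balanced synthetic dataset
#'
#' `n_per_class` samples for each of the configured classes, deterministic
#' given `config$seed` (per-sample seeds are drawn once from the dataset
#' seed).
#'
#' @param config a [synthetic_config()]
#' @param n_per_class samples per class (>= 1)
#' @return a `lesion_dataset`: list with `samples` (list of
#'   [lesion_sample()]), `manifest` (data.frame `sample_id`, `label`) and
#'   `config`
#' @export
generate_dataset <- function(config, n_per_class) {
  stopifnot(inherits(config, "synthetic_config"), n_per_class >= 1)
  set.seed(config$seed)
  n_total <- config$n_classes * n_per_class
  seeds <- sample.int(2147483646L, n_total)
  samples <- vector("list", n_total)
  k <- 0L
  for (ci in seq_len(config$n_classes)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      samples[[k]] <- generate_sample(config, ci, seed = seeds[k],
                                      sample_id = sprintf("c%d_s%03d", ci, i))
    }
  }
  manifest <- data.frame(
    sample_id = vapply(samples, `[[`, "", "sample_id"),
    label = vapply(samples, `[[`, 0L, "label")
  )
  structure(list(samples = samples, manifest = manifest, config = config),
            class = "lesion_dataset")
}

sample_list <- function(x) {
  if (inherits(x, "lesion_dataset")) x$samples else x
}

# background tone of a sample or raw image: stored tone if present, else
# the per-channel median of the border pixels (used as rotation fill)
estimate_bg_tone <- function(sample) {
  if (inherits(sample, "lesion_sample")) {
    if (!is.null(sample$bg_tone)) return(sample$bg_tone)
    img <- sample$image
  } else {
    img <- sample
  }
  border <- rbind(img[1, , ], img[dim(img)[1], , ], img[, 1, ], img[, dim(img)[2], ])
  apply(border, 2, stats::median)
}

#' Offline augmentation: flips and random rotations
#'
#' Each input contributes itself plus `copies_per_sample` randomly flipped
#' and rotated copies. Masks are transformed identically to images but with
#' nearest-neighbour resampling (so they stay binary); rotation fill is the
#' sample's background skin tone for images and 0 for masks; labels are
#' preserved.
#'
#' @param samples list of [lesion_sample()] or a `lesion_dataset`
#' @param rotation_range_deg length-2 range of rotation angles in degrees
#'   (default the training range `c(-65, 65)`)
#' @param flip_horizontal,flip_vertical allow the respective random flip
#' @param copies_per_sample augmented copies generated per input
#' @param seed optional RNG seed
#' @return list of `lesion_sample`, length `n * (1 + copies_per_sample)`
#' @export
offline_augment <- function(samples, rotation_range_deg = c(-65, 65),
                            flip_horizontal = TRUE, flip_vertical = TRUE,
                            copies_per_sample = 1, seed = NULL) {
  samples <- sample_list(samples)
  if (any(abs(rotation_range_deg) > 180)) {
    stop("rotation_range_deg must lie within [-180, 180]")
  }
  if (length(samples) == 0) return(list())
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", length(samples) * (1 + copies_per_sample))
  k <- 0L
  for (sm in samples) {
    k <- k + 1L
    out[[k]] <- sm
    for (j in seq_len(copies_per_sample)) {
      hf <- flip_horizontal && stats::runif(1) < 0.5
      vf <- flip_vertical && stats::runif(1) < 0.5
      ang <- stats::runif(1, rotation_range_deg[1], rotation_range_deg[2])
      img <- flip_image(sm$image, horizontal = hf, vertical = vf)
      msk <- if (!is.null(sm$mask)) flip_image(sm$mask, horizontal = hf, vertical = vf)
      if (ang != 0) {
        img <- pmin(pmax(rotate_image(img, ang, fill = estimate_bg_tone(sm)), 0), 1)
        if (!is.null(msk)) msk <- rotate_image(msk, ang, fill = 0, method = "nearest")
      }
      k <- k + 1L
      out[[k]] <- lesion_sample(img, mask = msk, label = sm$label,
                                sample_id = paste0(sm$sample_id, "_aug", j),
                                bg_tone = sm$bg_tone)
    }
  }
  out
}

#' Write a dataset to disk as PNG images plus a CSV manifest
#'
#' @param dataset a `lesion_dataset` or list of samples
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest data.frame with columns
#'   `sample_id`, `label`, `image_path`, `mask_path`
#' @export
write_dataset <- function(dataset, dir) {
  samples <- sample_list(dataset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(sm) {
    ip <- file.path(dir, paste0(sm$sample_id, ".png"))
    png::writePNG(sm$image, ip)
    mp <- NA_character_
    if (!is.null(sm$mask)) {
      mp <- file.path(dir, paste0(sm$sample_id, "_mask.png"))
      png::writePNG(sm$mask, mp)
    }
    data.frame(sample_id = sm$sample_id,
               label = if (is.null(sm$label)) NA_integer_ else sm$label,
               image_path = ip, mask_path = mp)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `manifest.csv`
#' @return list of [lesion_sample()]
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- png::readPNG(manifest$image_path[i])
    msk <- NULL
    if (!is.na(manifest$mask_path[i])) {
      msk <- round(png::readPNG(manifest$mask_path[i]))
    }
    lb <- manifest$label[i]
    lesion_sample(img, mask = msk, label = if (is.na(lb)) NULL else lb,
                  sample_id = manifest$sample_id[i])
  })
}
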