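# Image resampling utilities: separable resize (bicubic Catmull-Rom,
# bilinear, nearest) and center rotation with configurable fill. Images are
# (H, W) matrices or (H, W, C) arrays with values in [0, 1]; masks use
# nearest-neighbour resampling so they stay binary.

cubic_kernel <- function(t, a = -0.5) {
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  i2 <- at > 1 & at < 2
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

# Sample a single-channel image at fractional (row, col) positions.
# Positions outside the source raster return `fill`.
sample_channel <- function(ch, ys, xs, method, fill) {
  H <- nrow(ch); W <- ncol(ch)
  out <- numeric(length(ys))
  # the image occupies the pixel-area extent [0.5, H + 0.5]; positions
  # beyond it take the fill value, positions within clamp to edge pixels
  inside <- ys >= 0.5 - 1e-9 & ys <= H + 0.5 + 1e-9 &
    xs >= 0.5 - 1e-9 & xs <= W + 0.5 + 1e-9
  if (method == "nearest") {
    yi <- pmin(pmax(round(ys), 1L), H)
    xi <- pmin(pmax(round(xs), 1L), W)
    out <- ch[cbind(yi, xi)]
  } else if (method == "bilinear") {
    y0 <- pmin(pmax(floor(ys), 1L), H); y1 <- pmin(y0 + 1L, H)
    x0 <- pmin(pmax(floor(xs), 1L), W); x1 <- pmin(x0 + 1L, W)
    fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
    out <- ch[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
      ch[cbind(y1, x0)] * fy * (1 - fx) +
      ch[cbind(y0, x1)] * (1 - fy) * fx +
      ch[cbind(y1, x1)] * fy * fx
  } else { # bicubic
    y0 <- floor(ys); x0 <- floor(xs)
    out <- numeric(length(ys))
    wsum <- numeric(length(ys))
    for (dy in -1:2) for (dx in -1:2) {
      yi <- pmin(pmax(y0 + dy, 1L), H)
      xi <- pmin(pmax(x0 + dx, 1L), W)
      w <- cubic_kernel(ys - (y0 + dy)) * cubic_kernel(xs - (x0 + dx))
      out <- out + w * ch[cbind(yi, xi)]
      wsum <- wsum + w
    }
    out <- out / pmax(wsum, 1e-12)
  }
  out[!inside] <- fill
  out
}

warp_image <- function(img, ys, xs, out_h, out_w, method, fill) {
  if (is.matrix(img)) {
    return(matrix(sample_channel(img, ys, xs, method, fill), out_h, out_w))
  }
  C <- dim(img)[3]
  fill <- rep(fill, length.out = C)
  out <- array(0, c(out_h, out_w, C))
  for (c in seq_len(C)) {
    out[, , c] <- sample_channel(img[, , c], ys, xs, method, fill[c])
  }
  out
}

#' Resize an image
#'
#' Separable resampling with pixel-center alignment. Bicubic (Catmull-Rom)
#' interpolation is the default, matching common dermoscopy preprocessing;
#' use `"nearest"` for binary masks.
#'
#' @param img (H, W) matrix or (H, W, C) array
#' @param out_h,out_w target size in pixels
#' @param method one of `"bicubic"`, `"bilinear"`, `"nearest"`
#' @param clamp clip the result into `[0, 1]` (bicubic can overshoot)
#' @return resized image with the same number of channels
#' @export
resize_image <- function(img, out_h, out_w,
                         method = c("bicubic", "bilinear", "nearest"),
                         clamp = TRUE) {
  method <- match.arg(method)
  H <- dim(img)[1]; W <- dim(img)[2]
  if (H == out_h && W == out_w) return(img)
  # pixel-center mapping: dst index i (1-based) -> src coordinate
  ys <- ((seq_len(out_h) - 0.5) * H / out_h) + 0.5
  xs <- ((seq_len(out_w) - 0.5) * W / out_w) + 0.5
  grid_y <- rep(ys, times = out_w)
  grid_x <- rep(xs, each = out_h)
  out <- warp_image(img, grid_y, grid_x, out_h, out_w, method, fill = 0)
  if (clamp) out <- pmin(pmax(out, 0), 1)
  out
}

#' Rotate an image about its center
#'
#' @param img (H, W) matrix or (H, W, C) array
#' @param angle_deg counter-clockwise rotation in degrees
#' @param fill value(s) used outside the source raster (per channel)
#' @param method interpolation; masks should use `"nearest"`
#' @return rotated image of identical size
#' @export
rotate_image <- function(img, angle_deg, fill = 0,
                         method = c("bilinear", "nearest", "bicubic")) {
  method <- match.arg(method)
  if (angle_deg %% 360 == 0) return(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  a <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- rep(seq_len(H), times = W) - cy
  gx <- rep(seq_len(W), each = H) - cx
  # inverse mapping of a CCW rotation
  ys <- cos(a) * gy + sin(a) * gx + cy
  xs <- -sin(a) * gy + cos(a) * gx + cx
  out <- warp_image(img, ys, xs, H, W, method, fill)
  if (method == "bicubic") out <- pmin(pmax(out, 0), 1)
  out
}

#' Flip an image
#'
#' @param img (H, W) matrix or (H, W, C) array
#' @param horizontal mirror left-right
#' @param vertical mirror top-bottom
#' @export
flip_image <- function(img, horizontal = FALSE, vertical = FALSE) {
  if (is.matrix(img)) {
    if (vertical) img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
    if (horizontal) img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    return(img)
  }
  if (vertical) img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  if (horizontal) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  img
}

#' Gaussian blur
#'
#' Isotropic Gaussian smoothing (via EBImage) applied per channel.
#'
#' @param img (H, W) matrix or (H, W, C) array
#' @param sigma kernel standard deviation in pixels
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) stop("blur sigma must be positive")
  if (is.matrix(img)) return(as.matrix(EBImage::gblur(img, sigma = sigma)))
  out <- img
  for (c in seq_len(dim(img)[3])) {
    out[, , c] <- as.matrix(EBImage::gblur(img[, , c], sigma = sigma))
  }
  out
}
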