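# Saliency attribution for the classifier: pixel-gradient methods (Guided
# Backpropagation), class-activation mapping (Grad-CAM, Guided Grad-CAM),
# path-integral attribution (integrated gradients) and region-based
# attribution (XRAI over a Felzenszwalb graph over-segmentation), plus the
# bokeh-effect benchmark that scores saliency maps by the classifier's
# accuracy on blur-then-restore reconstructions.

new_attribution <- function(values, method, target_class, input_id) {
  stopifnot(all(is.finite(values)))
  structure(list(values = values, method = method,
                 target_class = target_class, input_id = input_id),
            class = "attribution_map")
}

# Differentiable class-score node. `model` is a classifier bayes_net or a
# `score_model` (list with $score: function(tape, x_node, classes) -> node).
score_model <- function(score) structure(list(score = score), class = "score_model")

forward_score <- function(model, tape_unused, x, classes, guided_relu = FALSE) {
  if (inherits(model, "score_model")) {
    if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
    tape <- ad_tape(guided_relu = guided_relu)
    xn <- ad_leaf(tape, x)
    list(tape = tape, input = xn, score = model$score(tape, xn, classes),
         acts = list(input = xn))
  } else {
    stopifnot(inherits(model, "bayes_net"), model$spec$kind == "classifier")
    res <- net_forward(model, x, training = FALSE, stochastic = FALSE,
                       guided_relu = guided_relu)
    acts <- res$fw$acts
    acts$input <- res$input
    list(tape = res$tape, input = res$input,
         score = ad_select_score(res$tape, res$logits, classes),
         acts = acts, probs = res$probs)
  }
}

predicted_class_of <- function(model, img) {
  which.max(predict_one(model, img, stochastic = FALSE))
}

#' Guided Backpropagation attribution
#'
#' Input-gradient of the class score where, at every ReLU, the backward
#' signal is zeroed wherever either the incoming gradient or the forward
#' input was negative. Channels are reduced by the sum of absolute values.
#'
#' @param model classifier `bayes_net`
#' @param input a [lesion_sample()] or (H, W, 3) image
#' @param target_class class whose score is explained; defaults to the
#'   model's prediction
#' @return an `attribution_map`
#' @export
guided_backprop <- function(model, input, target_class = NULL) {
  img <- as_input_image(input)
  if (is.null(target_class)) target_class <- predicted_class_of(model, img)
  fs <- forward_score(model, NULL, img, target_class, guided_relu = TRUE)
  ad_backward(fs$tape, fs$score)
  g <- node_grad(fs$input)[, , , 1]
  new_attribution(apply(abs(g), c(1, 2), sum), "guided_backprop",
                  target_class, input_id(input))
}

#' Grad-CAM attribution
#'
#' Neuron-importance weights are the globally average-pooled gradients of
#' the pre-softmax class score with respect to the target conv layer's
#' activation maps; the weighted activation sum is rectified and bilinearly
#' upsampled to the input resolution.
#'
#' @inheritParams guided_backprop
#' @param target_layer activation name (default the last conv stage,
#'   `"stage4_relu"`; `"input"` treats the input pixels as the activations)
#' @return an `attribution_map` (non-negative everywhere)
#' @export
grad_cam <- function(model, input, target_class = NULL,
                     target_layer = "stage4_relu") {
  img <- as_input_image(input)
  if (is.null(target_class)) target_class <- predicted_class_of(model, img)
  fs <- forward_score(model, NULL, img, target_class, guided_relu = FALSE)
  act <- fs$acts[[target_layer]]
  if (is.null(act)) stop(sprintf("no activation named '%s'", target_layer))
  ad_backward(fs$tape, fs$score)
  Fv <- act$value[, , , 1, drop = FALSE]
  dF <- node_grad(act)[, , , 1, drop = FALSE]
  C <- dim(Fv)[3]
  beta <- vapply(seq_len(C), function(a) mean(dF[, , a, 1]), 0)
  cam <- matrix(0, dim(Fv)[1], dim(Fv)[2])
  for (a in seq_len(C)) cam <- cam + beta[a] * Fv[, , a, 1]
  cam[cam < 0] <- 0
  up <- resize_image(cam, dim(img)[1], dim(img)[2], method = "bilinear",
                     clamp = FALSE)
  up[up < 0] <- 0
  new_attribution(up, "grad_cam", target_class, input_id(input))
}

#' Guided Grad-CAM attribution
#'
#' Elementwise product of the upsampled Grad-CAM map with the Guided
#' Backpropagation map: class-discriminative and fine-grained.
#'
#' @inheritParams grad_cam
#' @return an `attribution_map`
#' @export
guided_grad_cam <- function(model, input, target_class = NULL,
                            target_layer = "stage4_relu") {
  img <- as_input_image(input)
  if (is.null(target_class)) target_class <- predicted_class_of(model, img)
  gc <- grad_cam(model, input, target_class, target_layer)
  gb <- guided_backprop(model, input, target_class)
  new_attribution(gc$values * gb$values, "guided_grad_cam",
                  target_class, input_id(input))
}

ig_mean_gradient <- function(model, x, baseline, target_class, steps) {
  d <- dim(x)
  acc <- array(0, d)
  chunk <- max(1L, min(steps, floor(2^21 / prod(d[1:2]))))
  alphas <- (seq_len(steps) - 0.5) / steps # midpoint rule
  for (start in seq(1L, steps, chunk)) {
    idx <- start:min(start + chunk - 1L, steps)
    nb <- length(idx)
    xb <- array(0, c(d, nb))
    for (j in seq_len(nb)) xb[, , , j] <- baseline + alphas[idx[j]] * (x - baseline)
    fs <- forward_score(model, NULL, xb, rep(target_class, nb))
    ad_backward(fs$tape, fs$score)
    g <- node_grad(fs$input)
    acc <- acc + apply(g, c(1, 2, 3), sum)
  }
  acc / steps
}

#' Integrated gradients attribution
#'
#' Midpoint Riemann approximation of the path integral of score gradients
#' from `baseline` to the input, scaled by `(input - baseline)` and summed
#' (signed) over channels, so the completeness axiom
#' `sum(attributions) = score(input) - score(baseline)` holds up to the
#' discretization error of the path integral.
#'
#' @inheritParams guided_backprop
#' @param baseline baseline image (same shape as the input, or a scalar)
#' @param steps number of integration steps (>= 2)
#' @return an `attribution_map`
#' @export
integrated_gradients <- function(model, input, target_class = NULL,
                                 baseline = 0, steps = 64) {
  stopifnot(steps >= 2)
  img <- as_input_image(input)
  if (length(baseline) == 1) baseline <- array(baseline, dim(img))
  if (!all(dim(baseline) == dim(img))) stop("baseline shape mismatch")
  if (is.null(target_class)) target_class <- predicted_class_of(model, img)
  mg <- ig_mean_gradient(model, img, baseline, target_class, steps)
  attr <- apply((img - baseline) * mg, c(1, 2), sum)
  new_attribution(attr, "integrated_gradients", target_class, input_id(input))
}

#' Felzenszwalb graph-based over-segmentation
#'
#' Efficient graph segmentation on the 8-connected pixel lattice with
#' Euclidean color edge weights; a component pair merges while the joining
#' edge is no heavier than each side's internal difference plus `k / size`.
#' Larger `k` yields coarser segments.
#'
#' @param img (H, W, 3) array or (H, W) matrix in \[0, 1\]
#' @param k scale parameter (on the \[0, 1\] color-distance scale)
#' @param sigma Gaussian pre-smoothing in pixels (0 disables)
#' @param min_size minimum component size; smaller components are merged
#'   into a neighbour
#' @return integer label matrix with labels `1..n_segments`
#' @export
felzenszwalb_segment <- function(img, k = 0.3, sigma = 0.6, min_size = NULL) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1))
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  if (is.null(min_size)) min_size <- max(4L, round(0.002 * H * W))
  if (sigma > 0) for (c in seq_len(C)) {
    img[, , c] <- as.matrix(EBImage::gblur(img[, , c], sigma = sigma))
  }
  id <- matrix(seq_len(H * W), H, W)
  ia <- c(as.vector(id[-H, ]), as.vector(id[, -W]),
          as.vector(id[-H, -W]), as.vector(id[-1, -W]))
  ib <- c(as.vector(id[-1, ]), as.vector(id[, -1]),
          as.vector(id[-1, -1]), as.vector(id[-H, -1]))
  d2 <- 0
  for (c in seq_len(C)) d2 <- d2 + (img[, , c][ia] - img[, , c][ib])^2
  ew <- sqrt(d2)
  ord <- order(ew)
  ia <- ia[ord]; ib <- ib[ord]; ew <- ew[ord]
  n <- H * W
  parent <- seq_len(n)
  csize <- rep(1L, n)
  internal <- numeric(n)
  uf_find <- function(i) { # path-halving union-find
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_along(ew)) {
    a <- uf_find(ia[r]); b <- uf_find(ib[r])
    if (a == b) next
    w <- ew[r]
    if (w <= min(internal[a] + k / csize[a], internal[b] + k / csize[b])) {
      parent[b] <- a
      csize[a] <- csize[a] + csize[b]
      internal[a] <- w
    }
  }
  # absorb undersized components
  for (r in seq_along(ew)) {
    a <- uf_find(ia[r]); b <- uf_find(ib[r])
    if (a != b && (csize[a] < min_size || csize[b] < min_size)) {
      parent[b] <- a
      csize[a] <- csize[a] + csize[b]
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(i), 0L)
  matrix(match(roots, unique(roots)), H, W)
}

# pixel-index region list from label matrices at several scales
regions_from_labels <- function(label_mats) {
  regs <- list()
  for (lm in label_mats) {
    regs <- c(regs, split(seq_along(lm), as.vector(lm)))
  }
  unname(regs)
}

#' Greedy XRAI region ranking
#'
#' Regions are added in decreasing order of summed attribution gain per
#' newly covered pixel until the whole image is covered or regions run out.
#' Ties break on the lower region index. Returned saliency values decrease
#' strictly with addition rank (pixels never covered get 0), so top-k
#' selection follows the ranking.
#'
#' @param values attribution matrix (H, W)
#' @param regions list of pixel-index vectors (overlaps across scales
#'   allowed)
#' @return list with `order` (region indices in addition order), `scores`
#'   (gain densities), and `saliency` (H, W matrix)
#' @export
xrai_ranking <- function(values, regions) {
  if (length(regions) == 1) warning("degenerate segmentation: single region")
  npix <- length(values)
  covered <- logical(npix)
  remaining <- seq_along(regions)
  ord <- integer(0); scores <- numeric(0)
  sal <- matrix(0, nrow(values), ncol(values))
  rank_val <- length(regions)
  while (length(remaining) > 0 && !all(covered)) {
    gains <- vapply(remaining, function(ri) {
      new <- regions[[ri]][!covered[regions[[ri]]]]
      if (length(new) == 0) return(-Inf)
      sum(values[new]) / length(new)
    }, 0)
    if (all(!is.finite(gains))) break
    best <- remaining[which.max(gains)] # ties -> lowest region index
    new <- regions[[best]][!covered[regions[[best]]]]
    sal[new] <- rank_val / length(regions)
    rank_val <- rank_val - 1L
    covered[regions[[best]]] <- TRUE
    ord <- c(ord, best)
    scores <- c(scores, max(gains[is.finite(gains)]))
    remaining <- setdiff(remaining, best)
  }
  list(order = ord, scores = scores, saliency = sal)
}

#' XRAI region-based attribution
#'
#' Integrated-gradients attributions with black and white baselines are
#' averaged, the image is over-segmented at several Felzenszwalb scales,
#' and regions are greedily ranked by attribution gain density.
#'
#' @inheritParams guided_backprop
#' @param segmentation_scales Felzenszwalb `k` values (coarse to fine mix)
#' @param steps integration steps per baseline
#' @return list with `map` (an `attribution_map` of rank-derived saliency)
#'   and `ranking` (see [xrai_ranking()]); the raw averaged
#'   integrated-gradients attribution is attached as `attr_values`
#' @export
xrai <- function(model, input, target_class = NULL,
                 segmentation_scales = c(0.1, 0.3, 0.9), steps = 64) {
  img <- as_input_image(input)
  if (is.null(target_class)) target_class <- predicted_class_of(model, img)
  ig_black <- integrated_gradients(model, img, target_class,
                                   baseline = 0, steps = steps)
  ig_white <- integrated_gradients(model, img, target_class,
                                   baseline = 1, steps = steps)
  values <- (ig_black$values + ig_white$values) / 2
  labels <- lapply(segmentation_scales, function(k) felzenszwalb_segment(img, k = k))
  ranking <- xrai_ranking(values, regions_from_labels(labels))
  map <- new_attribution(ranking$saliency, "xrai", target_class, input_id(input))
  list(map = map, ranking = ranking, attr_values = values)
}

#' Bokeh-effect reconstruction
#'
#' Blurs the whole image with an isotropic Gaussian of scale `blur_sigma`
#' and restores the original pixel values at the `top_fraction` most
#' salient pixels (ties broken by pixel index).
#'
#' @param image (H, W, 3) array
#' @param saliency an `attribution_map` or (H, W) matrix of saliency values
#' @param top_fraction fraction of pixels restored, in (0, 1]
#' @param blur_sigma Gaussian scale in pixels (> 0)
#' @return reconstructed (H, W, 3) image
#' @export
bokeh_reconstruct <- function(image, saliency, top_fraction, blur_sigma) {
  if (top_fraction <= 0 || top_fraction > 1) stop("top_fraction must be in (0, 1]")
  if (blur_sigma <= 0) stop("blur_sigma must be positive")
  v <- if (inherits(saliency, "attribution_map")) saliency$values else saliency
  stopifnot(all(dim(v) == dim(image)[1:2]))
  if (top_fraction == 1) return(image)
  out <- gaussian_blur(image, blur_sigma)
  npix <- length(v)
  keep <- utils::head(order(-as.vector(v), seq_len(npix)),
                      ceiling(top_fraction * npix))
  for (c in seq_len(dim(image)[3])) {
    ch <- out[, , c]; och <- image[, , c]
    ch[keep] <- och[keep]
    out[, , c] <- ch
  }
  out
}

saliency_methods <- c("guided_backprop", "grad_cam", "guided_grad_cam",
                      "integrated_gradients", "xrai")

#' Compute a saliency map by method name
#'
#' @inheritParams guided_backprop
#' @param method one of `"guided_backprop"`, `"grad_cam"`,
#'   `"guided_grad_cam"`, `"integrated_gradients"`, `"xrai"`, or a function
#'   `f(model, input, target_class)` returning an `attribution_map`
#' @param ... passed to the method
#' @return an `attribution_map`
#' @export
compute_saliency <- function(model, input, method = "xrai",
                             target_class = NULL, ...) {
  if (is.function(method)) return(method(model, input, target_class))
  method <- match.arg(method, saliency_methods)
  switch(method,
         guided_backprop = guided_backprop(model, input, target_class),
         grad_cam = grad_cam(model, input, target_class, ...),
         guided_grad_cam = guided_grad_cam(model, input, target_class, ...),
         integrated_gradients = integrated_gradients(model, input, target_class, ...),
         xrai = xrai(model, input, target_class, ...)$map)
}

#' Bokeh-effect evaluation of saliency quality
#'
#' For every labeled sample: compute the saliency of the model's predicted
#' class, reconstruct the image by blur-then-restore, classify the
#' reconstruction, and report the fraction of reconstructions classified
#' as the ground-truth label. Faithful saliency maps preserve the pixels
#' the model relies on, so better methods score higher.
#'
#' @param model classifier `bayes_net`
#' @param samples labeled [lesion_sample()] list or `lesion_dataset`
#' @param method saliency method name or function (see [compute_saliency()])
#' @param top_fraction fraction of pixels restored
#' @param blur_sigma Gaussian blur scale; default 5% of the smaller image
#'   side
#' @param seed optional RNG seed (methods themselves are deterministic)
#' @return accuracy in \[0, 1\]
#' @export
evaluate_saliency_bokeh <- function(model, samples, method = "xrai",
                                    top_fraction = 0.10, blur_sigma = NULL,
                                    seed = NULL) {
  samples <- sample_list(samples)
  if (length(samples) == 0) stop("bokeh evaluation undefined on empty dataset")
  if (!is.null(seed)) set.seed(seed)
  d <- dim(samples[[1]]$image)
  if (is.null(blur_sigma)) blur_sigma <- 0.05 * min(d[1], d[2])
  hits <- vapply(samples, function(sm) {
    pred <- predicted_class_of(model, sm$image)
    if (top_fraction == 1) {
      recon <- sm$image
    } else {
      sal <- compute_saliency(model, sm, method, target_class = pred)
      recon <- bokeh_reconstruct(sm$image, sal, top_fraction, blur_sigma)
    }
    predicted_class_of(model, recon) == sm$label
  }, NA)
  mean(hits)
}

#' Write an attribution map as an 8-bit PNG heatmap
#'
#' Values are min-max scaled; the raw values can be kept alongside as a
#' plain-text RDS-free CSV for reproducibility.
#'
#' @param map an `attribution_map`
#' @param path output PNG path
#' @param values_csv optional path for the raw values as CSV
#' @export
write_attribution_png <- function(map, path, values_csv = NULL) {
  v <- map$values
  rng <- range(v)
  vn <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  png::writePNG(vn, path)
  if (!is.null(values_csv)) {
    utils::write.table(v, values_csv, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
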