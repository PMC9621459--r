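# score_model helpers built directly on the autodiff tape
linear_score <- function(w) {
  skinet:::score_model(function(tape, xn, classes) {
    wrep <- array(w, dim(xn$value))
    out <- skinet:::ad_node(tape, sum(wrep * xn$value), list(xn))
    out$backward <- function(nd) skinet:::ad_accum(xn, nd$grad * wrep)
    out
  })
}

constant_score <- function(const = 2) {
  skinet:::score_model(function(tape, xn, classes) {
    skinet:::ad_node(tape, const, list(xn))
  })
}

# score = sum(relu(w * x)): a single-ReLU toy with analytic guided gradients
relu_gate_score <- function(w) {
  skinet:::score_model(function(tape, xn, classes) {
    wrep <- array(w, dim(xn$value))
    prod_nd <- skinet:::ad_node(tape, wrep * xn$value, list(xn))
    prod_nd$backward <- function(nd) skinet:::ad_accum(xn, nd$grad * wrep)
    r <- skinet:::ad_relu(tape, prod_nd)
    out <- skinet:::ad_node(tape, sum(r$value), list(r))
    out$backward <- function(nd) {
      g <- r$value; g[] <- nd$grad
      skinet:::ad_accum(r, g)
    }
    out
  })
}

test_that("guided backpropagation matches the hand-derived masked gradient", {
  set.seed(41)
  x <- array(runif(2 * 2 * 3), c(2, 2, 3))
  w <- array(rnorm(12), c(2, 2, 3))
  map <- guided_backprop(relu_gate_score(w), x, target_class = 1)
  # gradient w * 1{w x > 0}; incoming gradient is +1 so the guided rule
  # only suppresses the negative-forward branch here
  expected <- apply(abs(w * (w * x > 0)), c(1, 2), sum)
  expect_equal(map$values, expected, tolerance = 1e-12)
  # constant score: zero gradient everywhere
  z <- guided_backprop(constant_score(), x, target_class = 1)
  expect_equal(z$values, matrix(0, 2, 2))
})

test_that("guided backprop on the CNN is invariant to a constant score shift", {
  cls <- tiny_classifier(seed = 42)
  x <- rand_image(16, 16, seed = 43)
  m1 <- guided_backprop(cls, x, target_class = 2)
  cls$params[["fc.b"]] <- cls$params[["fc.b"]] + 5
  m2 <- guided_backprop(cls, x, target_class = 2)
  expect_equal(m1$values, m2$values, tolerance = 1e-9)
})

test_that("Grad-CAM is non-negative and matches a finite-difference oracle", {
  cls <- tiny_classifier(seed = 44)
  x <- rand_image(16, 16, seed = 45)
  map <- grad_cam(cls, x, target_class = 1)
  expect_true(all(map$values >= 0))
  expect_equal(dim(map$values), c(16, 16))

  # with the input pixels as the target activations, the neuron-importance
  # weights are channel means of dscore/dx, measurable by central
  # differences on whole-channel perturbations
  cam <- grad_cam(cls, x, target_class = 2, target_layer = "input")
  score_of <- function(img) {
    res <- skinet:::net_forward(cls, img)
    res$logits$value[1, 2]
  }
  eps <- 1e-4
  beta_fd <- vapply(1:3, function(a) {
    xp <- x; xp[, , a] <- xp[, , a] + eps
    xm <- x; xm[, , a] <- xm[, , a] - eps
    (score_of(xp) - score_of(xm)) / (2 * eps * 16 * 16)
  }, 0)
  cam_fd <- matrix(0, 16, 16)
  for (a in 1:3) cam_fd <- cam_fd + beta_fd[a] * x[, , a]
  cam_fd[cam_fd < 0] <- 0
  expect_equal(cam$values, cam_fd, tolerance = 1e-4)
})

test_that("a score equal to one activation map's mean yields beta = 1/G", {
  # score = mean of input channel 2
  m <- skinet:::score_model(function(tape, xn, classes) {
    G <- prod(dim(xn$value)[1:2]) * dim(xn$value)[4]
    out <- skinet:::ad_node(tape, sum(xn$value[, , 2, ]) / G, list(xn))
    out$backward <- function(nd) {
      g <- array(0, dim(xn$value))
      g[, , 2, ] <- nd$grad / G
      skinet:::ad_accum(xn, g)
    }
    out
  })
  x <- rand_image(8, 8, seed = 46)
  cam <- grad_cam(m, x, target_class = 1, target_layer = "input")
  G <- 64
  expect_equal(cam$values, pmax(x[, , 2] / G, 0), tolerance = 1e-12)
})

test_that("guided Grad-CAM is the elementwise product of its parents", {
  cls <- tiny_classifier(seed = 47)
  x <- rand_image(16, 16, seed = 48)
  gg <- guided_grad_cam(cls, x, target_class = 3)
  gc <- grad_cam(cls, x, target_class = 3)
  gb <- guided_backprop(cls, x, target_class = 3)
  expect_equal(gg$values, gc$values * gb$values, tolerance = 1e-12)
  # zero Grad-CAM annihilates; unit Grad-CAM is the identity element
  expect_equal(matrix(0, 16, 16) * gb$values, matrix(0, 16, 16))
})

test_that("integrated gradients is exact for linear scores at any step count", {
  set.seed(49)
  x <- array(runif(4 * 4 * 3), c(4, 4, 3))
  w <- array(rnorm(48), c(4, 4, 3))
  for (steps in c(2, 7, 64)) {
    ig <- integrated_gradients(linear_score(w), x, target_class = 1,
                               baseline = 0, steps = steps)
    expect_equal(ig$values, apply(w * x, c(1, 2), sum), tolerance = 1e-10)
  }
  # input equal to baseline: all-zero attributions
  ig0 <- integrated_gradients(linear_score(w), x, target_class = 1,
                              baseline = x, steps = 8)
  expect_equal(ig0$values, matrix(0, 4, 4))
  expect_error(integrated_gradients(linear_score(w), x, 1,
                                    baseline = array(0, c(2, 2, 3))),
               "shape")
})

test_that("integrated-gradients completeness error shrinks with more steps", {
  cls <- tiny_classifier(seed = 50)
  x <- rand_image(16, 16, seed = 51)
  e <- predicted_class_of(cls, x)
  score_of <- function(img) skinet:::net_forward(cls, img)$logits$value[1, e]
  target <- score_of(x) - score_of(array(0, dim(x)))
  err <- vapply(c(16, 64, 256), function(st) {
    ig <- integrated_gradients(cls, x, target_class = e, baseline = 0,
                               steps = st)
    abs(sum(ig$values) - target)
  }, 0)
  expect_lt(err[3], err[1] + 1e-9)
  expect_lt(err[2] / max(abs(target), 1e-6), 0.02)
  # the headline completeness check at 128 steps
  ig128 <- integrated_gradients(cls, x, target_class = e, baseline = 0,
                                steps = 128)
  expect_lt(abs(sum(ig128$values) - target) / max(abs(target), 1e-6), 0.01)
})

test_that("Felzenszwalb segmentation separates clearly distinct regions", {
  img <- array(0.2, c(16, 16, 3))
  img[, 9:16, ] <- 0.8
  lab <- felzenszwalb_segment(img, k = 0.1, sigma = 0, min_size = 4)
  expect_gte(max(lab), 2)
  # left and right halves should not share a segment
  expect_length(intersect(unique(as.vector(lab[, 1:8])),
                          unique(as.vector(lab[, 9:16]))), 0)
  # a uniform image collapses to one segment
  flat <- array(0.5, c(8, 8, 3))
  expect_equal(max(felzenszwalb_segment(flat, k = 0.5, sigma = 0)), 1)
})

test_that("XRAI ranking honours region scores, ties, coverage and rescaling", {
  vals <- matrix(0, 6, 6)
  vals[1:3, 1:3] <- 1 # all attribution mass in region 1
  regions <- list(which(row(vals) <= 3 & col(vals) <= 3),
                  which(row(vals) > 3 & col(vals) <= 3),
                  which(col(vals) > 3))
  rk <- xrai_ranking(vals, regions)
  expect_equal(rk$order[1], 1)
  expect_setequal(rk$order, 1:3)
  expect_true(all(rk$saliency[regions[[1]]] > rk$saliency[regions[[2]]][1]))
  # every pixel covered
  expect_true(all(rk$saliency > 0))
  # zero attribution: deterministic tie-break by region index
  rk0 <- xrai_ranking(matrix(0, 6, 6), regions)
  expect_equal(rk0$order, 1:3)
  expect_equal(rk0$scores, c(0, 0, 0))
  # invariance to positive rescaling
  rk2 <- xrai_ranking(vals * 3.7, regions)
  expect_equal(rk2$order, rk$order)
  expect_warning(xrai_ranking(vals, regions[1]), "degenerate")
})

test_that("end-to-end XRAI on a small classifier produces a full covering map", {
  cls <- tiny_classifier(seed = 52)
  cfg <- tiny_config(size = 16, n_classes = 3, seed = 53)
  sm <- generate_sample(cfg, 2, seed = 54)
  res <- xrai(cls, sm, steps = 16)
  expect_s3_class(res$map, "attribution_map")
  expect_true(all(res$map$values >= 0))
  expect_true(all(res$map$values[res$ranking$saliency > 0] > 0))
  expect_equal(dim(res$map$values), c(16, 16))
})

test_that("bokeh reconstruction restores exactly the top-saliency pixels", {
  img <- rand_image(16, 16, seed = 55)
  set.seed(56)
  sal <- matrix(runif(256), 16, 16)
  out <- bokeh_reconstruct(img, sal, top_fraction = 0.25, blur_sigma = 2)
  keep <- head(order(-as.vector(sal), seq_len(256)), 64)
  blur <- gaussian_blur(img, 2)
  for (c in 1:3) {
    expect_equal(out[, , c][keep], img[, , c][keep])
    expect_equal(out[, , c][-keep], blur[, , c][-keep])
  }
  # full restoration is the identity
  expect_identical(bokeh_reconstruct(img, sal, 1, 2), img)
  expect_error(bokeh_reconstruct(img, sal, 0, 2), "top_fraction")
  expect_error(bokeh_reconstruct(img, sal, 0.5, -1), "blur_sigma")
})

test_that("mask-oracle saliency beats noise saliency on lesion-driven labels", {
  art <- e2e_artifacts()
  samples <- art$split$validation[1:50]
  mask_method <- function(model, input, target_class) {
    skinet:::new_attribution(input$mask, "mask_oracle", target_class,
                             input$sample_id)
  }
  noise_method <- function(model, input, target_class) {
    skinet:::new_attribution(matrix(stats::runif(32 * 32), 32, 32),
                             "noise", target_class, input$sample_id)
  }
  set.seed(57)
  acc_mask <- evaluate_saliency_bokeh(art$classifier, samples,
                                      method = mask_method,
                                      top_fraction = 0.2, seed = 58)
  acc_noise <- evaluate_saliency_bokeh(art$classifier, samples,
                                       method = noise_method,
                                       top_fraction = 0.2, seed = 58)
  expect_gte(acc_mask, acc_noise)
  expect_error(evaluate_saliency_bokeh(art$classifier, list()), "empty")
})
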