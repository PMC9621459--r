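# The autodiff engine underpins every network; these checks compare its
# gradients against central finite differences on small tensors.

test_that("convolution, pooling and dense gradients match finite differences", {
  set.seed(1)
  H <- 4; W <- 4; C <- 2; N <- 2; Co <- 2
  x0 <- array(rnorm(H * W * C * N), c(H, W, C, N))
  w0 <- array(rnorm(3 * 3 * C * Co) * 0.3, c(3, 3, C, Co))
  b0 <- rnorm(Co) * 0.1
  wt <- array(rnorm(H * W * Co * N), c(H, W, Co, N))

  f <- function(xv) {
    tp <- skinet:::ad_tape()
    out <- skinet:::ad_conv2d(tp, skinet:::ad_leaf(tp, xv),
                              skinet:::ad_leaf(tp, w0),
                              skinet:::ad_leaf(tp, b0))
    sum(out$value * wt)
  }
  tp <- skinet:::ad_tape()
  xn <- skinet:::ad_leaf(tp, x0)
  out <- skinet:::ad_conv2d(tp, xn, skinet:::ad_leaf(tp, w0),
                            skinet:::ad_leaf(tp, b0))
  skinet:::ad_backward(tp, out, seed = wt)
  expect_equal(xn$grad, numeric_gradient(f, x0), tolerance = 1e-6)

  # maxpool routes the gradient to the argmax
  fmp <- function(xv) {
    tp <- skinet:::ad_tape()
    sum(skinet:::ad_maxpool2(tp, skinet:::ad_leaf(tp, xv))$value^2)
  }
  tp <- skinet:::ad_tape()
  xn <- skinet:::ad_leaf(tp, x0)
  mp <- skinet:::ad_maxpool2(tp, xn)
  sq <- skinet:::ad_node(tp, sum(mp$value^2), list(mp))
  sq$backward <- function(nd) skinet:::ad_accum(mp, nd$grad * 2 * mp$value)
  skinet:::ad_backward(tp, sq)
  expect_equal(xn$grad, numeric_gradient(fmp, x0), tolerance = 1e-5)
})

test_that("batch-norm gradients are exact in training and evaluation mode", {
  set.seed(2)
  d <- c(3, 4, 2, 2)
  x0 <- array(rnorm(prod(d)), d)
  g0 <- rnorm(2); b0 <- rnorm(2)
  st0 <- list(mean = rnorm(2) * 0.1, var = runif(2, 0.5, 2))
  wt <- array(rnorm(prod(d)), d)
  for (training in c(TRUE, FALSE)) {
    f <- function(xv) {
      st <- new.env(); st$bn <- st0
      tp <- skinet:::ad_tape()
      out <- skinet:::ad_batchnorm(tp, skinet:::ad_leaf(tp, xv),
                                   skinet:::ad_leaf(tp, g0),
                                   skinet:::ad_leaf(tp, b0),
                                   st, "bn", training = training)
      sum(out$value * wt)
    }
    st <- new.env(); st$bn <- st0
    tp <- skinet:::ad_tape()
    xn <- skinet:::ad_leaf(tp, x0)
    out <- skinet:::ad_batchnorm(tp, xn, skinet:::ad_leaf(tp, g0),
                                 skinet:::ad_leaf(tp, b0), st, "bn",
                                 training = training)
    skinet:::ad_backward(tp, out, seed = wt)
    expect_equal(xn$grad, numeric_gradient(f, x0), tolerance = 1e-5)
  }
})

test_that("softmax cross-entropy and sigmoid BCE gradients are exact", {
  set.seed(3)
  z0 <- matrix(rnorm(3 * 4), 3, 4)
  oh <- diag(4)[c(2, 1, 4), ]
  f <- function(z) {
    tp <- skinet:::ad_tape()
    skinet:::ad_softmax_ce(tp, skinet:::ad_leaf(tp, z), oh)$value
  }
  tp <- skinet:::ad_tape()
  zn <- skinet:::ad_leaf(tp, z0)
  skinet:::ad_backward(tp, skinet:::ad_softmax_ce(tp, zn, oh))
  expect_equal(zn$grad, numeric_gradient(f, z0), tolerance = 1e-6)

  y <- array(rbinom(8, 1, 0.5), c(2, 2, 1, 2))
  l0 <- array(rnorm(8), c(2, 2, 1, 2))
  fb <- function(l) {
    tp <- skinet:::ad_tape()
    skinet:::ad_bce_logits(tp, skinet:::ad_leaf(tp, l), y)$value
  }
  tp <- skinet:::ad_tape()
  ln <- skinet:::ad_leaf(tp, l0)
  skinet:::ad_backward(tp, skinet:::ad_bce_logits(tp, ln, y))
  expect_equal(ln$grad, numeric_gradient(fb, l0), tolerance = 1e-6)
})

test_that("guided mode zeroes negative incoming ReLU gradients", {
  x0 <- array(c(1, -1, 2, -2), c(2, 2, 1, 1))
  seed <- array(c(1, 1, -1, -1), c(2, 2, 1, 1))
  # plain relu: grad passes where input > 0
  tp <- skinet:::ad_tape()
  xn <- skinet:::ad_leaf(tp, x0)
  skinet:::ad_backward(tp, skinet:::ad_relu(tp, xn), seed = seed)
  expect_equal(as.vector(xn$grad), c(1, 0, -1, 0))
  # guided: additionally requires positive incoming gradient
  tp <- skinet:::ad_tape(guided_relu = TRUE)
  xn <- skinet:::ad_leaf(tp, x0)
  skinet:::ad_backward(tp, skinet:::ad_relu(tp, xn), seed = seed)
  expect_equal(as.vector(xn$grad), c(1, 0, 0, 0))
})
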