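# Neural-network operations on the autodiff tape.
#
# Convolutions are computed as im2col followed by a single BLAS matrix
# multiplication, which keeps the whole engine in vectorized R.

pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  xp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , ] <- x
  xp
}

# (H*W*N) x (K*K*C) patch matrix; column order (dy fastest, dx, c) matches
# the linearization of a (K, K, C, Co) weight array.
im2col <- function(xp, K, H, W) {
  C <- dim(xp)[3]; N <- dim(xp)[4]
  out <- matrix(0, H * W * N, K * K * C)
  for (c in seq_len(C)) for (dx in seq_len(K)) for (dy in seq_len(K)) {
    col <- dy + (dx - 1L) * K + (c - 1L) * K * K
    out[, col] <- xp[dy:(dy + H - 1L), dx:(dx + W - 1L), c, ]
  }
  out
}

col2im <- function(dXc, dimp, K, H, W) {
  C <- dimp[3]; N <- dimp[4]
  dxp <- array(0, dimp)
  for (c in seq_len(C)) for (dx in seq_len(K)) for (dy in seq_len(K)) {
    col <- dy + (dx - 1L) * K + (c - 1L) * K * K
    dxp[dy:(dy + H - 1L), dx:(dx + W - 1L), c, ] <-
      dxp[dy:(dy + H - 1L), dx:(dx + W - 1L), c, ] + dXc[, col]
  }
  dxp
}

hwcn_to_mat <- function(x) {
  d <- dim(x)
  if (d[4] == 1L) return(matrix(x, d[1] * d[2], d[3]))
  matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
}

mat_to_hwcn <- function(m, H, W, N, C) {
  if (N == 1L) {
    dim(m) <- c(H, W, C, 1L)
    return(m)
  }
  aperm(array(m, c(H, W, N, C)), c(1, 2, 4, 3))
}

# Stride-1 same-padding convolution; kernel size odd (or 1).
ad_conv2d <- function(tape, x, w, b) {
  xv <- x$value
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  wd <- dim(w$value); K <- wd[1]; Co <- wd[4]
  stopifnot(wd[3] == C, K %% 2L == 1L)
  p <- (K - 1L) %/% 2L
  xp <- pad_hw(xv, p)
  Xc <- im2col(xp, K, H, W)
  Wm <- matrix(w$value, K * K * C, Co)
  Y <- Xc %*% Wm
  Y <- Y + rep(b$value, each = nrow(Y))
  out <- ad_node(tape, mat_to_hwcn(Y, H, W, N, Co), list(x, w, b))
  dimp <- dim(xp)
  out$backward <- function(nd) {
    dYm <- hwcn_to_mat(nd$grad)
    ad_accum(w, array(crossprod(Xc, dYm), wd))
    ad_accum(b, colSums(dYm))
    dxp <- col2im(dYm %*% t(Wm), dimp, K, H, W)
    dx <- if (p > 0L) dxp[(p + 1L):(p + H), (p + 1L):(p + W), , , drop = FALSE] else dxp
    ad_accum(x, dx)
  }
  out
}

# 2x2 stride-2 transposed convolution (learned upsampling).
ad_conv_transpose2 <- function(tape, x, w, b) {
  xv <- x$value
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  wd <- dim(w$value); Co <- wd[4]
  stopifnot(wd[1] == 2L, wd[2] == 2L, wd[3] == C)
  Xm <- hwcn_to_mat(xv)
  y <- array(0, c(2L * H, 2L * W, Co, N))
  for (dy in 1:2) for (dx in 1:2) {
    Wm <- matrix(w$value[dy, dx, , ], C, Co)
    y[seq(dy, 2L * H, 2L), seq(dx, 2L * W, 2L), , ] <-
      mat_to_hwcn(Xm %*% Wm, H, W, N, Co)
  }
  out <- ad_node(tape, sweep_channels_add(y, b$value), list(x, w, b))
  out$backward <- function(nd) {
    dY <- nd$grad
    dXm <- matrix(0, nrow(Xm), C)
    dw <- array(0, wd)
    for (dy in 1:2) for (dx in 1:2) {
      dYs <- hwcn_to_mat(dY[seq(dy, 2L * H, 2L), seq(dx, 2L * W, 2L), , , drop = FALSE])
      Wm <- matrix(w$value[dy, dx, , ], C, Co)
      dXm <- dXm + dYs %*% t(Wm)
      dw[dy, dx, , ] <- crossprod(Xm, dYs)
    }
    ad_accum(w, dw)
    ad_accum(b, channel_sums(dY))
    ad_accum(x, mat_to_hwcn(dXm, H, W, N, C))
  }
  out
}

sweep_channels_add <- function(y, b) {
  d <- dim(y)
  y + rep(rep(b, each = d[1] * d[2]), times = d[4])
}

channel_sums <- function(y) {
  d <- dim(y)
  colSums(matrix(aperm(y, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3]))
}

# 2x2 max pooling, stride 2; H and W must be even (callers crop odd edges).
ad_maxpool2 <- function(tape, x) {
  xv <- x$value
  d <- dim(xv); H <- d[1]; W <- d[2]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  a <- xv[i1, j1, , , drop = FALSE]; b <- xv[i1, j2, , , drop = FALSE]
  cc <- xv[i2, j1, , , drop = FALSE]; e <- xv[i2, j2, , , drop = FALSE]
  m <- pmax(a, b, cc, e)
  # route gradient to the first maximal element (deterministic tie-break)
  m1 <- a >= b & a >= cc & a >= e
  m2 <- !m1 & b >= cc & b >= e
  m3 <- !m1 & !m2 & cc >= e
  m4 <- !(m1 | m2 | m3)
  out <- ad_node(tape, m, list(x))
  out$backward <- function(nd) {
    g <- nd$grad
    dx <- array(0, d)
    dx[i1, j1, , ] <- g * m1
    dx[i1, j2, , ] <- g * m2
    dx[i2, j1, , ] <- g * m3
    dx[i2, j2, , ] <- g * m4
    ad_accum(x, dx)
  }
  out
}

# Crop spatial dims to even sizes (used before pooling on odd inputs).
ad_crop_even <- function(tape, x) {
  d <- dim(x$value)
  H <- d[1] - d[1] %% 2L; W <- d[2] - d[2] %% 2L
  if (H == d[1] && W == d[2]) return(x)
  out <- ad_node(tape, x$value[seq_len(H), seq_len(W), , , drop = FALSE], list(x))
  out$backward <- function(nd) {
    dx <- array(0, d)
    dx[seq_len(H), seq_len(W), , ] <- nd$grad
    ad_accum(x, dx)
  }
  out
}

# Batch normalization over (H, W, N) per channel. `state` keeps running
# moments; in evaluation mode (training = FALSE) only the running moments
# are used so that Monte-Carlo dropout sampling perturbs nothing but the
# dropout masks. Works in the native (H, W, C, N) layout: per-(channel,
# sample) column statistics on an (H*W) x (C*N) view are pooled over
# samples, avoiding any transpose of the data.
ad_batchnorm <- function(tape, x, gamma, beta, state, key, training,
                         momentum = 0.9, eps = 1e-5) {
  xv <- x$value
  d <- dim(xv); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- HW * N
  xm <- matrix(xv, HW, C * N)
  if (is.null(state[[key]])) {
    state[[key]] <- list(mean = numeric(C), var = rep(1, C))
  }
  if (training) {
    mu <- rowMeans(matrix(colMeans(xm), C, N))
    va <- rowMeans(matrix(colMeans(xm * xm), C, N)) - mu^2
    va[va < 0] <- 0
    st <- state[[key]]
    state[[key]] <- list(mean = momentum * st$mean + (1 - momentum) * mu,
                         var  = momentum * st$var + (1 - momentum) * va)
  } else {
    st <- state[[key]]
    mu <- st$mean; va <- st$var
  }
  ivar <- 1 / sqrt(va + eps)
  scl <- gamma$value * ivar
  sc_col <- rep(rep(scl, times = N), each = HW)
  sh_col <- rep(rep(beta$value - scl * mu, times = N), each = HW)
  ym <- xm * sc_col + sh_col
  dim(ym) <- d
  out <- ad_node(tape, ym, list(x, gamma, beta))
  chan_sums <- function(v) rowSums(matrix(colSums(matrix(v, HW, C * N)), C, N))
  out$backward <- function(nd) {
    dym <- matrix(nd$grad, HW, C * N)
    xhat <- (xm - rep(rep(mu, times = N), each = HW)) *
      rep(rep(ivar, times = N), each = HW)
    ad_accum(gamma, chan_sums(dym * xhat))
    ad_accum(beta, chan_sums(dym))
    dxhat <- dym * rep(rep(gamma$value, times = N), each = HW)
    if (training) {
      s1 <- chan_sums(dxhat)
      s2 <- chan_sums(dxhat * xhat)
      dxm <- rep(rep(ivar / m, times = N), each = HW) *
        (m * dxhat - rep(rep(s1, times = N), each = HW) -
           xhat * rep(rep(s2, times = N), each = HW))
    } else {
      dxm <- dxhat * rep(rep(ivar, times = N), each = HW)
    }
    dim(dxm) <- d
    ad_accum(x, dxm)
  }
  out
}

ad_relu <- function(tape, x) {
  pos <- x$value > 0
  out <- ad_node(tape, x$value * pos, list(x))
  guided <- isTRUE(tape$guided_relu)
  out$backward <- function(nd) {
    g <- nd$grad * pos
    if (guided) g <- g * (nd$grad > 0)
    ad_accum(x, g)
  }
  out
}

ad_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  out <- ad_node(tape, s, list(x))
  out$backward <- function(nd) ad_accum(x, nd$grad * s * (1 - s))
  out
}

ad_add <- function(tape, a, b) {
  out <- ad_node(tape, a$value + b$value, list(a, b))
  out$backward <- function(nd) {
    ad_accum(a, nd$grad)
    ad_accum(b, nd$grad)
  }
  out
}

# Concatenate along the channel dimension.
ad_concat <- function(tape, xs) {
  dims <- lapply(xs, function(x) dim(x$value))
  C <- vapply(dims, `[`, 0, 3)
  d <- dims[[1]]
  y <- array(0, c(d[1], d[2], sum(C), d[4]))
  off <- 0L
  for (x in xs) {
    ci <- dim(x$value)[3]
    y[, , (off + 1L):(off + ci), ] <- x$value
    off <- off + ci
  }
  out <- ad_node(tape, y, xs)
  out$backward <- function(nd) {
    off <- 0L
    for (x in xs) {
      ci <- dim(x$value)[3]
      ad_accum(x, nd$grad[, , (off + 1L):(off + ci), , drop = FALSE])
      off <- off + ci
    }
  }
  out
}

# Inverted dropout; mask drawn from the R RNG so runs are seedable.
ad_dropout <- function(tape, x, rate) {
  if (rate <= 0) return(x)
  keep <- (array(stats::runif(length(x$value)), dim(x$value)) >= rate) / (1 - rate)
  out <- ad_node(tape, x$value * keep, list(x))
  out$backward <- function(nd) ad_accum(x, nd$grad * keep)
  out
}

# Global average pooling (H, W, C, N) -> (N, C).
ad_gap <- function(tape, x) {
  d <- dim(x$value)
  m <- d[1] * d[2]
  y <- t(matrix(colMeans(matrix(x$value, m, d[3] * d[4])), d[3], d[4]))
  out <- ad_node(tape, y, list(x))
  out$backward <- function(nd) {
    ad_accum(x, array(rep(as.vector(t(nd$grad)) / m, each = m), d))
  }
  out
}

# Dense layer on (N, F) matrices.
ad_dense <- function(tape, x, w, b) {
  y <- x$value %*% w$value + rep(b$value, each = nrow(x$value))
  out <- ad_node(tape, y, list(x, w, b))
  out$backward <- function(nd) {
    ad_accum(w, crossprod(x$value, nd$grad))
    ad_accum(b, colSums(nd$grad))
    ad_accum(x, nd$grad %*% t(w$value))
  }
  out
}

# Row-wise softmax on (N, K).
ad_softmax <- function(tape, x) {
  z <- x$value - apply(x$value, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  out <- ad_node(tape, p, list(x))
  out$backward <- function(nd) {
    dot <- rowSums(nd$grad * p)
    ad_accum(x, p * (nd$grad - dot))
  }
  out
}

# Mean categorical cross-entropy from logits against one-hot targets.
ad_softmax_ce <- function(tape, logits, onehot) {
  z <- logits$value - apply(logits$value, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  n <- nrow(p)
  loss <- -sum(onehot * log(pmax(p, 1e-12))) / n
  out <- ad_node(tape, loss, list(logits))
  out$backward <- function(nd) ad_accum(logits, nd$grad * (p - onehot) / n)
  out
}

# Mean binary cross-entropy from logits (numerically stable softplus form).
ad_bce_logits <- function(tape, logits, target) {
  z <- logits$value
  n <- length(z)
  loss <- sum(pmax(z, 0) - z * target + log1p(exp(-abs(z)))) / n
  s <- 1 / (1 + exp(-z))
  out <- ad_node(tape, loss, list(logits))
  out$backward <- function(nd) ad_accum(logits, nd$grad * (s - target) / n)
  out
}

# Select one pre-softmax score per row: sum_i z[i, class[i]] (scalar node);
# used by the saliency methods.
ad_select_score <- function(tape, logits, class_index) {
  n <- nrow(logits$value)
  idx <- cbind(seq_len(n), class_index)
  out <- ad_node(tape, sum(logits$value[idx]), list(logits))
  out$backward <- function(nd) {
    g <- matrix(0, n, ncol(logits$value))
    g[idx] <- nd$grad
    ad_accum(logits, g)
  }
  out
}
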