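# Network builders with a uniform stochastic-forward contract.
#
# A `bayes_net` holds its weights in an environment and is executed
# define-by-run on a fresh tape each forward pass. Dropout layers are active
# during training and, when stochastic mode is enabled, also at inference
# (Monte-Carlo dropout); batch-norm always uses running statistics outside
# training so dropout is the only source of inference-time stochasticity.

he_init <- function(dimv, fan_in) {
  array(stats::rnorm(prod(dimv), 0, sqrt(2 / fan_in)), dimv)
}

fw_ctx <- function(model, tape, training, stochastic) {
  fw <- new.env(parent = emptyenv())
  fw$tape <- tape
  fw$params <- model$params
  fw$state <- model$state
  fw$pnodes <- new.env(parent = emptyenv())
  fw$acts <- list()
  fw$training <- training
  fw$stochastic <- stochastic
  fw$rate <- model$spec$dropout_rate
  fw
}

fw_param <- function(fw, name, dimv, init) {
  if (is.null(fw$params[[name]])) fw$params[[name]] <- init()
  nd <- fw$pnodes[[name]]
  if (is.null(nd)) {
    nd <- ad_leaf(fw$tape, fw$params[[name]])
    fw$pnodes[[name]] <- nd
  }
  nd
}

bn_layer <- function(fw, x, name) {
  C <- dim(x$value)[3]
  g <- fw_param(fw, paste0(name, ".g"), C, function() rep(1, C))
  b <- fw_param(fw, paste0(name, ".b"), C, function() rep(0, C))
  ad_batchnorm(fw$tape, x, g, b, fw$state, name, fw$training)
}

conv_layer <- function(fw, x, name, K, Co, bn = TRUE, act = c("relu", "none")) {
  act <- match.arg(act)
  Ci <- dim(x$value)[3]
  w <- fw_param(fw, paste0(name, ".w"), c(K, K, Ci, Co),
                function() he_init(c(K, K, Ci, Co), K * K * Ci))
  b <- fw_param(fw, paste0(name, ".b"), Co, function() rep(0, Co))
  y <- ad_conv2d(fw$tape, x, w, b)
  if (bn) y <- bn_layer(fw, y, paste0(name, ".bn"))
  if (act == "relu") y <- ad_relu(fw$tape, y)
  y
}

tconv_layer <- function(fw, x, name, Co) {
  Ci <- dim(x$value)[3]
  w <- fw_param(fw, paste0(name, ".w"), c(2, 2, Ci, Co),
                function() he_init(c(2, 2, Ci, Co), 4 * Ci))
  b <- fw_param(fw, paste0(name, ".b"), Co, function() rep(0, Co))
  ad_conv_transpose2(fw$tape, x, w, b)
}

maybe_dropout <- function(fw, x) {
  if ((fw$training || fw$stochastic) && fw$rate > 0) {
    ad_dropout(fw$tape, x, fw$rate)
  } else x
}

#' Channel splits of a MultiRes block
#'
#' The nominal filter count `U` is scaled by `alpha` and split across the
#' three chained 3x3 convolutions as `floor(alpha * U * fractions)`.
#'
#' @param U nominal filter count
#' @param alpha width scale factor
#' @param fractions split fractions of the scaled width
#' @return integer vector of three channel counts
#' @export
multires_splits <- function(U, alpha = 1.67, fractions = c(1/6, 1/3, 1/2)) {
  Wn <- alpha * U
  if (Wn <= 0) stop("scaled width alpha * U must be positive")
  sp <- floor(Wn * fractions)
  if (any(sp < 1)) stop("MultiRes splits must each be at least one channel; increase U")
  as.integer(sp)
}

# MultiRes block: three chained 3x3 convolutions (multi-scale 3/5/7 receptive
# fields) concatenated, plus a 1x1-convolved residual of the input.
mrb_forward <- function(fw, x, name, U, alpha = 1.67) {
  sp <- multires_splits(U, alpha)
  c1 <- conv_layer(fw, x, paste0(name, ".c1"), 3, sp[1])
  c2 <- conv_layer(fw, c1, paste0(name, ".c2"), 3, sp[2])
  c3 <- conv_layer(fw, c2, paste0(name, ".c3"), 3, sp[3])
  cc <- bn_layer(fw, ad_concat(fw$tape, list(c1, c2, c3)), paste0(name, ".bncat"))
  sc <- conv_layer(fw, x, paste0(name, ".sc"), 1, sum(sp), act = "none")
  y <- ad_relu(fw$tape, ad_add(fw$tape, cc, sc))
  bn_layer(fw, y, paste0(name, ".bnout"))
}

# Res path: a chain of residual conv blocks narrowing the semantic gap
# between encoder and decoder features on a skip connection.
respath_forward <- function(fw, x, name, n_blocks, filters) {
  h <- x
  for (i in seq_len(n_blocks)) {
    nm <- sprintf("%s.b%d", name, i)
    main <- conv_layer(fw, h, paste0(nm, ".m"), 3, filters)
    sc <- conv_layer(fw, h, paste0(nm, ".s"), 1, filters, act = "none")
    h <- bn_layer(fw, ad_relu(fw$tape, ad_add(fw$tape, main, sc)),
                  paste0(nm, ".bnout"))
  }
  h
}

#' Specification of a Bayesian network
#'
#' @param kind `"segmenter"` (Bayesian MultiResUNet) or `"classifier"`
#'   (small Bayesian CNN backbone)
#' @param input_size length-2 `c(H, W)`; the segmenter requires both
#'   divisible by 16 (four 2x poolings)
#' @param n_classes number of classes (classifier; the segmenter emits one map)
#' @param dropout_rate Bernoulli dropout probability (0.5 is the
#'   published operating point for Monte-Carlo uncertainty)
#' @param dropout_positions classifier dropout insertion points: subset of
#'   `"stage1".."stage4"`, `"head"`
#' @param base_filters width scale; 32 is full width, 4-8 is desk scale
#' @param alpha MultiRes width scale factor
#' @return a `bayesian_net_spec` list
#' @export
bayesian_net_spec <- function(kind = c("segmenter", "classifier"),
                              input_size = c(224, 224),
                              n_classes = 7,
                              dropout_rate = 0.5,
                              dropout_positions = c("stage3", "stage4", "head"),
                              base_filters = 8,
                              alpha = 1.67) {
  kind <- match.arg(kind)
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (base_filters < 2) stop("base_filters must be at least 2")
  structure(list(kind = kind, input_size = input_size, n_classes = n_classes,
                 dropout_rate = dropout_rate,
                 dropout_positions = dropout_positions,
                 base_filters = base_filters, alpha = alpha),
            class = "bayesian_net_spec")
}

seg_forward <- function(model, x, fw) {
  tape <- fw$tape
  xn <- ad_leaf(tape, x)
  base <- model$spec$base_filters
  alpha <- model$spec$alpha
  U <- base * c(1, 2, 4, 8, 16)
  enc <- list(); h <- xn
  for (d in 1:4) {
    e <- mrb_forward(fw, h, paste0("enc", d), U[d], alpha)
    enc[[d]] <- e
    h <- maybe_dropout(fw, ad_maxpool2(tape, e))
  }
  h <- mrb_forward(fw, h, "bridge", U[5], alpha)
  rp <- lapply(1:4, function(d) {
    respath_forward(fw, enc[[d]], paste0("rp", d), n_blocks = 5 - d,
                    filters = base * 2^(d - 1))
  })
  for (d in 4:1) {
    up <- maybe_dropout(fw, tconv_layer(fw, h, paste0("up", d), base * 2^(d - 1)))
    h <- mrb_forward(fw, ad_concat(tape, list(up, rp[[d]])), paste0("dec", d),
                     U[d], alpha)
  }
  Ci <- dim(h$value)[3]
  w <- fw_param(fw, "out.w", c(1, 1, Ci, 1), function() he_init(c(1, 1, Ci, 1), Ci))
  b <- fw_param(fw, "out.b", 1, function() 0)
  logits <- ad_conv2d(tape, h, w, b)
  probs <- ad_sigmoid(tape, logits)
  fw$acts <- list(bridge = h)
  list(tape = tape, input = xn, logits = logits, probs = probs, fw = fw)
}

cls_forward <- function(model, x, fw) {
  tape <- fw$tape
  xn <- ad_leaf(tape, x)
  base <- model$spec$base_filters
  f <- base * c(1, 2, 4, 8)
  pos <- model$spec$dropout_positions
  h <- xn
  acts <- list()
  for (s in 1:4) {
    h <- conv_layer(fw, h, paste0("stage", s), 3, f[s])
    acts[[paste0("stage", s, "_relu")]] <- h
    h <- ad_maxpool2(tape, ad_crop_even(tape, h))
    if (paste0("stage", s) %in% pos) h <- maybe_dropout(fw, h)
  }
  g <- ad_gap(tape, h)
  if ("head" %in% pos) g <- maybe_dropout(fw, g)
  K <- model$spec$n_classes
  Cg <- ncol(g$value)
  w <- fw_param(fw, "fc.w", c(Cg, K), function() he_init(c(Cg, K), Cg))
  b <- fw_param(fw, "fc.b", K, function() rep(0, K))
  logits <- ad_dense(tape, g, w, b)
  probs <- ad_softmax(tape, logits)
  fw$acts <- acts
  list(tape = tape, input = xn, logits = logits, probs = probs, fw = fw)
}

# Full forward pass; x is an (H, W, 3, N) array.
net_forward <- function(model, x, training = FALSE,
                        stochastic = isTRUE(model$stochastic),
                        guided_relu = FALSE) {
  stopifnot(inherits(model, "bayes_net"))
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  tape <- ad_tape(guided_relu = guided_relu)
  fw <- fw_ctx(model, tape, training, stochastic)
  if (model$spec$kind == "segmenter") seg_forward(model, x, fw)
  else cls_forward(model, x, fw)
}

new_bayes_net <- function(spec, seed = NULL) {
  model <- structure(list(kind = spec$kind, spec = spec,
                          params = new.env(parent = emptyenv()),
                          state = new.env(parent = emptyenv()),
                          stochastic = FALSE),
                     class = "bayes_net")
  if (!is.null(seed)) set.seed(seed)
  # one dummy forward instantiates every weight with the seeded RNG
  dummy <- array(0, c(16, 16, 3, 1))
  invisible(net_forward(model, dummy, training = FALSE, stochastic = FALSE))
  model
}

#' Build the Bayesian MultiResUNet segmenter
#'
#' Encoder of four MultiRes blocks with 2x2 max pooling and a dropout layer
#' after each pooling, a fifth MultiRes bridge, and a decoder of four
#' 2x2 transposed-convolution (+ dropout) and MultiRes stages. Encoder
#' features reach the decoder through Res paths of 4, 3, 2, 1 residual conv
#' blocks; a final 1x1 convolution with sigmoid activation emits an
#' (H, W) probability map. All other convolutions use batch normalization
#' and ReLU.
#'
#' @param spec a [bayesian_net_spec()] with `kind = "segmenter"`
#' @param seed optional seed for weight initialization
#' @return a `bayes_net`
#' @export
build_bayesian_multiresunet <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "bayesian_net_spec"), spec$kind == "segmenter")
  if (any(spec$input_size %% 16 != 0)) {
    stop("segmenter input_size must be divisible by 16 (four 2x poolings)")
  }
  new_bayes_net(spec, seed)
}

#' Build a Bayesian dropout classifier
#'
#' A compact convolutional backbone (four conv/batch-norm/ReLU/pool stages,
#' global average pooling, dense softmax head) with dropout layers inserted
#' at the configured positions — the same Bayesian-dropout contract as a
#' full-size backbone, at desk scale.
#'
#' @param spec a [bayesian_net_spec()] with `kind = "classifier"`
#' @param seed optional seed for weight initialization
#' @return a `bayes_net`
#' @export
build_bayesian_classifier <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "bayesian_net_spec"), spec$kind == "classifier")
  if (spec$n_classes < 2) stop("classifier needs n_classes >= 2")
  if (length(spec$dropout_positions) == 0 && spec$dropout_rate > 0) {
    stop("no dropout_positions configured; stochastic mode would be a no-op")
  }
  new_bayes_net(spec, seed)
}

#' Toggle Monte-Carlo (test-time) dropout
#'
#' When enabled, dropout layers sample fresh Bernoulli masks on every
#' forward pass even at inference, while batch-norm keeps using its frozen
#' running statistics.
#'
#' @param model a `bayes_net`
#' @param enabled logical
#' @return the model with the stochastic flag set
#' @export
set_stochastic_mode <- function(model, enabled) {
  stopifnot(inherits(model, "bayes_net"))
  model$stochastic <- isTRUE(enabled)
  model
}

#' Run a model on images
#'
#' @param model a `bayes_net` (or a plain function `f(image, stochastic)`,
#'   accepted anywhere the package takes a predictor)
#' @param x (H, W, 3) image or (H, W, 3, N) batch
#' @param stochastic override the model's stochastic flag
#' @return classifier: probability vector (single image) or (N, K) matrix;
#'   segmenter: (H, W) probability map or (H, W, N) array
#' @export
net_predict <- function(model, x, stochastic = NULL) {
  single <- length(dim(x)) == 3
  if (is.function(model)) {
    out <- if (single) model(x, isTRUE(stochastic)) else
      vapply_images(x, function(im) model(im, isTRUE(stochastic)))
    return(out)
  }
  st <- if (is.null(stochastic)) isTRUE(model$stochastic) else isTRUE(stochastic)
  res <- net_forward(model, x, training = FALSE, stochastic = st)
  p <- res$probs$value
  if (model$spec$kind == "classifier") {
    if (single) as.vector(p[1, ]) else p
  } else {
    if (single) p[, , 1, 1] else p[, , 1, , drop = TRUE]
  }
}

# apply a single-image predictor over a batch, stacking results
vapply_images <- function(x, f) {
  N <- dim(x)[4]
  outs <- lapply(seq_len(N), function(i) f(x[, , , i]))
  if (is.matrix(outs[[1]]) || length(dim(outs[[1]])) == 2) {
    array(unlist(outs), c(dim(outs[[1]]), N))
  } else {
    do.call(rbind, outs)
  }
}

#' Save a model (weights as RDS, architecture spec as YAML sidecar)
#'
#' @param model a `bayes_net`
#' @param path output path for the RDS file; a `.yaml` sidecar is written
#'   alongside
#' @export
save_model <- function(model, path) {
  obj <- list(kind = model$kind, spec = unclass(model$spec),
              params = as.list(model$params), state = as.list(model$state))
  saveRDS(obj, path)
  yaml::write_yaml(unclass(model$spec), paste0(path, ".yaml"))
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path path to the RDS file
#' @return a `bayes_net`
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  spec <- structure(obj$spec, class = "bayesian_net_spec")
  model <- structure(list(kind = obj$kind, spec = spec,
                          params = list2env(obj$params, parent = emptyenv()),
                          state = list2env(obj$state, parent = emptyenv()),
                          stochastic = FALSE),
                     class = "bayes_net")
  model
}

#' Build a stand-alone MultiRes block
#'
#' Mostly useful for inspecting the block contract (channel bookkeeping,
#' shape preservation) in isolation.
#'
#' @param input_channels channels of the input tensor
#' @param U nominal filter count
#' @param alpha width scale factor
#' @param seed optional init seed
#' @return a `net_block` with `$forward(x, training = FALSE)` and
#'   `$out_channels`
#' @export
build_multires_block <- function(input_channels, U, alpha = 1.67, seed = NULL) {
  sp <- multires_splits(U, alpha)
  shell <- structure(list(spec = list(dropout_rate = 0, kind = "block"),
                          params = new.env(parent = emptyenv()),
                          state = new.env(parent = emptyenv())),
                     class = "bayes_net")
  if (!is.null(seed)) set.seed(seed)
  fwd <- function(x, training = FALSE) {
    if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
    stopifnot(dim(x)[3] == input_channels)
    fw <- fw_ctx(shell, ad_tape(), training, FALSE)
    mrb_forward(fw, ad_leaf(fw$tape, x), "blk", U, alpha)$value
  }
  invisible(fwd(array(0, c(8, 8, input_channels, 1))))
  structure(list(forward = fwd, out_channels = sum(sp), splits = sp),
            class = "net_block")
}

#' Build a stand-alone Res path
#'
#' @param depth_index which of the four skip depths (1..4); path `d` chains
#'   `5 - d` residual conv blocks
#' @param input_channels channels of the input tensor
#' @param filters per-path filter counts (defaults 32, 64, 128, 256)
#' @param seed optional init seed
#' @return a `net_block` with `$forward(x, training = FALSE)`,
#'   `$n_blocks`, `$filters`
#' @export
build_res_path <- function(depth_index, input_channels,
                           filters = c(32, 64, 128, 256), seed = NULL) {
  if (!(depth_index %in% 1:4)) stop("depth_index must be in 1..4")
  nb <- 5 - depth_index
  f <- filters[depth_index]
  shell <- structure(list(spec = list(dropout_rate = 0, kind = "block"),
                          params = new.env(parent = emptyenv()),
                          state = new.env(parent = emptyenv())),
                     class = "bayes_net")
  if (!is.null(seed)) set.seed(seed)
  fwd <- function(x, training = FALSE) {
    if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
    stopifnot(dim(x)[3] == input_channels)
    fw <- fw_ctx(shell, ad_tape(), training, FALSE)
    respath_forward(fw, ad_leaf(fw$tape, x), "rp", nb, f)$value
  }
  invisible(fwd(array(0, c(8, 8, input_channels, 1))))
  structure(list(forward = fwd, n_blocks = nb, filters = f),
            class = "net_block")
}
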