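# Seeded training loops: Adam on binary cross-entropy (segmenter, pixel-wise)
# or categorical cross-entropy (classifier). Dropout is always active in
# training mode regardless of the inference-time stochastic flag.

#' Training configuration
#'
#' @param learning_rate Adam step size
#' @param batch_size minibatch size
#' @param epochs number of passes over the data
#' @param seed integer seed governing weight init order, shuffling and
#'   dropout masks
#' @param checkpoint_dir optional directory; when set, weights are saved
#'   after every epoch
#' @param shuffle reshuffle the sample order each epoch
#' @return a `train_config` list
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 16, epochs = 10,
                         seed = 1L, checkpoint_dir = NULL, shuffle = TRUE) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir, shuffle = shuffle),
            class = "train_config")
}

adam_new <- function() new.env(parent = emptyenv())

adam_step <- function(opt, params, pnodes, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  opt$t <- (opt$t %||% 0L) + 1L
  t <- opt$t
  for (nm in ls(pnodes)) {
    g <- pnodes[[nm]]$grad
    if (is.null(g)) next
    st <- opt[[nm]]
    if (is.null(st)) st <- list(m = g * 0, v = g * 0)
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    opt[[nm]] <- st
    mh <- st$m / (1 - b1^t)
    vh <- st$v / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stack_images <- function(samples) {
  d <- dim(samples[[1]]$image)
  x <- array(0, c(d[1], d[2], 3, length(samples)))
  for (i in seq_along(samples)) x[, , , i] <- samples[[i]]$image
  x
}

stack_masks <- function(samples) {
  d <- dim(samples[[1]]$mask)
  y <- array(0, c(d[1], d[2], 1, length(samples)))
  for (i in seq_along(samples)) y[, , 1, i] <- samples[[i]]$mask
  y
}

train_batches <- function(n, batch_size, shuffle) {
  ord <- if (shuffle) sample.int(n) else seq_len(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

run_training <- function(model, samples, config, make_loss) {
  set.seed(config$seed)
  opt <- adam_new()
  n <- length(samples)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    losses <- c()
    for (bi in train_batches(n, config$batch_size, config$shuffle)) {
      batch <- samples[bi]
      res <- net_forward(model, stack_images(batch), training = TRUE)
      loss <- make_loss(res, batch)
      ad_backward(res$tape, loss)
      adam_step(opt, model$params, res$fw$pnodes, config$learning_rate)
      losses <- c(losses, loss$value)
    }
    history[ep] <- mean(losses)
    if (!is.null(config$checkpoint_dir)) {
      dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      save_model(model, file.path(config$checkpoint_dir,
                                  sprintf("epoch_%03d.rds", ep)))
    }
  }
  list(model = model, history = data.frame(epoch = seq_len(config$epochs),
                                           loss = history))
}

#' Train the Bayesian segmenter
#'
#' Minimizes pixel-wise binary cross-entropy between the sigmoid map and
#' the binary mask with Adam. Fully deterministic given `config$seed`.
#'
#' @param model a segmenter `bayes_net`
#' @param samples list of [lesion_sample()] (or a `lesion_dataset`), every
#'   sample carrying a mask
#' @param config a [train_config()]
#' @return list with the trained `model` and a per-epoch `history`
#'   data.frame
#' @export
train_segmenter <- function(model, samples, config = train_config()) {
  stopifnot(inherits(model, "bayes_net"), model$spec$kind == "segmenter")
  samples <- sample_list(samples)
  for (sm in samples) {
    if (is.null(sm$mask)) stop(sprintf("sample '%s' has no mask", sm$sample_id))
  }
  run_training(model, samples, config, function(res, batch) {
    ad_bce_logits(res$tape, res$logits, stack_masks(batch))
  })
}

#' Train the Bayesian classifier
#'
#' Minimizes categorical cross-entropy (the multi-class extension of the
#' binary form) with one-hot targets and Adam. Fully deterministic given
#' `config$seed`.
#'
#' @param model a classifier `bayes_net`
#' @param samples list of labeled [lesion_sample()] or a `lesion_dataset`
#' @param config a [train_config()]
#' @return list with the trained `model` and a per-epoch `history`
#' @export
train_classifier <- function(model, samples, config = train_config()) {
  stopifnot(inherits(model, "bayes_net"), model$spec$kind == "classifier")
  samples <- sample_list(samples)
  K <- model$spec$n_classes
  for (sm in samples) {
    if (is.null(sm$label)) stop(sprintf("sample '%s' has no label", sm$sample_id))
    if (sm$label < 1 || sm$label > K) {
      stop(sprintf("sample '%s' label %d out of range 1..%d",
                   sm$sample_id, sm$label, K))
    }
  }
  eye <- diag(K)
  run_training(model, samples, config, function(res, batch) {
    oh <- eye[vapply(batch, `[[`, 0L, "label"), , drop = FALSE]
    ad_softmax_ce(res$tape, res$logits, oh)
  })
}

#' Seeded train/validation split
#'
#' @param samples list of samples or a `lesion_dataset`
#' @param frac fraction assigned to the training split
#' @param seed shuffle seed
#' @return list with `train` and `validation` sample lists
#' @export
split_dataset <- function(samples, frac = 0.8, seed = 1L) {
  samples <- sample_list(samples)
  set.seed(seed)
  n <- length(samples)
  idx <- sample.int(n)
  ntr <- floor(frac * n)
  list(train = samples[idx[seq_len(ntr)]],
       validation = samples[idx[(ntr + 1):n]])
}
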