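# Shared fixtures: tiny seeded models and datasets, plus lazily computed
# end-to-end artifacts reused across test files.

tiny_classifier <- function(n_classes = 3, base_filters = 4, size = c(16, 16),
                            dropout_rate = 0.5, seed = 1,
                            dropout_positions = c("stage3", "stage4", "head")) {
  spec <- bayesian_net_spec("classifier", input_size = size,
                            n_classes = n_classes,
                            dropout_rate = dropout_rate,
                            dropout_positions = dropout_positions,
                            base_filters = base_filters)
  build_bayesian_classifier(spec, seed = seed)
}

tiny_segmenter <- function(base_filters = 4, size = c(16, 16),
                           dropout_rate = 0.5, seed = 1) {
  spec <- bayesian_net_spec("segmenter", input_size = size,
                            dropout_rate = dropout_rate,
                            base_filters = base_filters)
  build_bayesian_multiresunet(spec, seed = seed)
}

tiny_config <- function(size = 16, n_classes = 3, seed = 5, artifact_rate = 0,
                        noise_sd = 0.05) {
  synthetic_config(image_height = size, image_width = size,
                   n_classes = n_classes,
                   class_palette = default_class_palette(n_classes),
                   artifact_rate = artifact_rate, noise_sd = noise_sd,
                   seed = seed)
}

rand_image <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

# numeric gradient of a scalar function by central differences
numeric_gradient <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Desk-scale end-to-end study: 7 classes, 200 samples per class at 32x32,
# trained segmenter and classifier. Computed once per test run and cached.
.e2e_cache <- new.env(parent = emptyenv())

e2e_artifacts <- function() {
  if (!is.null(.e2e_cache$art)) return(.e2e_cache$art)
  cfg <- synthetic_config(image_height = 32, image_width = 32, n_classes = 7,
                          artifact_rate = 0.3, noise_sd = 0.05, seed = 7)
  ds <- generate_dataset(cfg, 200)
  sp <- split_dataset(ds, 0.8, seed = 3)

  cls <- build_bayesian_classifier(
    bayesian_net_spec("classifier", input_size = c(32, 32), n_classes = 7,
                      base_filters = 8), seed = 1)
  cls_fit <- train_classifier(cls, sp$train,
                              train_config(epochs = 14, batch_size = 16,
                                           seed = 11))

  seg <- build_bayesian_multiresunet(
    bayesian_net_spec("segmenter", input_size = c(32, 32), base_filters = 4),
    seed = 2)
  seg_fit <- train_segmenter(seg, sp$train[seq_len(200)],
                             train_config(epochs = 6, batch_size = 8,
                                          seed = 12))

  unc <- batch_uncertainty(cls, sp$validation, mode = "combined", count = 20,
                           phi_T = 0.35, seed = 99)

  .e2e_cache$art <- list(config = cfg, dataset = ds, split = sp,
                         classifier = cls, classifier_history = cls_fit$history,
                         segmenter = seg, segmenter_history = seg_fit$history,
                         uncertainty = unc)
  .e2e_cache$art
}
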