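# Predictive-uncertainty estimation. Epistemic uncertainty is sampled by
# Monte-Carlo dropout (B stochastic passes over the unmodified input),
# aleatoric uncertainty by test-time augmentation (V augmented passes with
# dropout off), and the combined posterior by M passes with both a fresh
# augmentation and a fresh dropout mask. The scalar uncertainty is the
# predictive entropy of the averaged probability vector, normalized into
# [0, 1]; predictions whose normalized entropy reaches the threshold are
# flagged for referral.

#' Test-time augmentation family
#'
#' The label-preserving transform family used both for offline training
#' augmentation and test-time augmentation: random horizontal/vertical
#' flips and rotations drawn uniformly from `rotation_range_deg`.
#'
#' @param rotation_range_deg rotation range in degrees
#' @param flip_horizontal,flip_vertical allow the respective flips
#' @param identity_only degenerate family containing only the identity
#'   (useful for controls)
#' @return a `tta_family` list
#' @export
tta_transforms <- function(rotation_range_deg = c(-65, 65),
                           flip_horizontal = TRUE, flip_vertical = TRUE,
                           identity_only = FALSE) {
  structure(list(rotation_range_deg = rotation_range_deg,
                 flip_horizontal = flip_horizontal,
                 flip_vertical = flip_vertical,
                 identity_only = identity_only),
            class = "tta_family")
}

sample_tta <- function(family) {
  if (family$identity_only) {
    return(list(hflip = FALSE, vflip = FALSE, angle = 0))
  }
  list(hflip = family$flip_horizontal && stats::runif(1) < 0.5,
       vflip = family$flip_vertical && stats::runif(1) < 0.5,
       angle = stats::runif(1, family$rotation_range_deg[1],
                            family$rotation_range_deg[2]))
}

apply_tta <- function(img, tf, fill = 0) {
  out <- flip_image(img, horizontal = tf$hflip, vertical = tf$vflip)
  if (tf$angle != 0) {
    out <- rotate_image(out, tf$angle, fill = fill)
    out <- pmin(pmax(out, 0), 1)
  }
  out
}

# map an output probability map back through the inverse geometric transform
invert_tta_map <- function(map, tf) {
  if (tf$angle != 0) map <- rotate_image(map, -tf$angle, fill = 0)
  flip_image(map, horizontal = tf$hflip, vertical = tf$vflip)
}

as_input_image <- function(input) {
  if (inherits(input, "lesion_sample")) input$image else input
}

input_id <- function(input) {
  if (inherits(input, "lesion_sample")) input$sample_id else "input"
}

# single-image prediction through either a bayes_net or a plain function
predict_one <- function(model, img, stochastic) {
  if (is.function(model)) model(img, stochastic) else
    net_predict(model, img, stochastic = stochastic)
}

# any bayes_net or prediction function supports stochastic passes (with
# zero dropout they are degenerate but well defined)
supports_stochastic <- function(model) {
  is.function(model) || inherits(model, "bayes_net")
}

new_posterior <- function(samples_list, mode, source_id) {
  is_map <- !is.null(dim(samples_list[[1]]))
  if (is_map) {
    d <- dim(samples_list[[1]])
    arr <- array(unlist(samples_list), c(d[1], d[2], length(samples_list)))
  } else {
    arr <- do.call(rbind, samples_list)
  }
  structure(list(samples = arr, mode = mode, count = length(samples_list),
                 type = if (is_map) "map" else "class",
                 source_id = source_id),
            class = "posterior_samples")
}

#' Epistemic posterior via Monte-Carlo dropout
#'
#' `B` stochastic forward passes (fresh dropout masks, unmodified input);
#' the mean over passes is the epistemic posterior mean.
#'
#' @param model a `bayes_net` (or function `f(image, stochastic)`)
#' @param input a [lesion_sample()] or (H, W, 3) image
#' @param B number of Monte-Carlo samples
#' @param seed optional RNG seed
#' @return a `posterior_samples` object
#' @export
epistemic_posterior <- function(model, input, B = 20, seed = NULL) {
  stopifnot(B >= 1)
  if (!supports_stochastic(model)) {
    stop("model does not support stochastic (Monte-Carlo dropout) mode")
  }
  if (!is.null(seed)) set.seed(seed)
  img <- as_input_image(input)
  out <- lapply(seq_len(B), function(i) predict_one(model, img, stochastic = TRUE))
  new_posterior(out, "epistemic", input_id(input))
}

#' Aleatoric posterior via test-time augmentation
#'
#' `V` augmented copies passed with dropout off. Segmentation outputs are
#' mapped back through the inverse geometric transform before averaging,
#' so the posterior maps live in the original image frame.
#'
#' @param model predictor (dropout is disabled during the passes)
#' @param input a [lesion_sample()] or image
#' @param V number of augmented passes
#' @param transform_family a [tta_transforms()] family
#' @param seed optional RNG seed
#' @return a `posterior_samples` object
#' @export
aleatoric_posterior <- function(model, input, V = 20,
                                transform_family = tta_transforms(),
                                seed = NULL) {
  stopifnot(V >= 1)
  if (!is.null(seed)) set.seed(seed)
  img <- as_input_image(input)
  fill <- estimate_bg_tone(input)
  out <- lapply(seq_len(V), function(i) {
    tf <- sample_tta(transform_family)
    y <- predict_one(model, apply_tta(img, tf, fill), stochastic = FALSE)
    if (!is.null(dim(y))) y <- invert_tta_map(y, tf)
    y
  })
  new_posterior(out, "aleatoric", input_id(input))
}

#' Combined posterior: augmentation plus Monte-Carlo dropout
#'
#' `M` passes, each with a fresh augmentation and a fresh dropout mask.
#'
#' @inheritParams aleatoric_posterior
#' @param M number of passes
#' @return a `posterior_samples` object
#' @export
combined_posterior <- function(model, input, M = 20,
                               transform_family = tta_transforms(),
                               seed = NULL) {
  stopifnot(M >= 1)
  if (!is.null(seed)) set.seed(seed)
  img <- as_input_image(input)
  fill <- estimate_bg_tone(input)
  out <- lapply(seq_len(M), function(i) {
    tf <- sample_tta(transform_family)
    y <- predict_one(model, apply_tta(img, tf, fill), stochastic = TRUE)
    if (!is.null(dim(y))) y <- invert_tta_map(y, tf)
    y
  })
  new_posterior(out, "combined", input_id(input))
}

#' Posterior mean over sampled passes
#'
#' @param posterior a `posterior_samples` object
#' @return probability vector (classification) or map (segmentation)
#' @export
posterior_mean <- function(posterior) {
  if (posterior$type == "class") {
    colMeans(posterior$samples)
  } else {
    apply(posterior$samples, c(1, 2), mean)
  }
}

#' Predictive entropy of a probability vector
#'
#' `-sum(p * log(p))` in nats, with `0 * log(0) := 0`.
#'
#' @param p probability vector (non-negative, summing to one within 1e-6)
#' @return entropy in nats, in `[0, log(length(p))]`
#' @export
predictive_entropy <- function(p) {
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
    stop("p must be a probability vector summing to 1")
  }
  p <- pmax(p, 0)
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Normalize an entropy into \[0, 1\]
#'
#' Linear rescaling between `phi_min` and `phi_max`; values outside the
#' bounds are clamped with a warning.
#'
#' @param phi entropy in nats
#' @param phi_min,phi_max normalization bounds (`phi_max > phi_min`);
#'   the analytic defaults are 0 and `log(N)` for an N-class vector
#' @return normalized uncertainty in \[0, 1\]
#' @export
normalize_uncertainty <- function(phi, phi_min = 0, phi_max = log(2)) {
  if (phi_max <= phi_min) stop("phi_max must exceed phi_min")
  if (phi < phi_min - 1e-12 || phi > phi_max + 1e-12) {
    warning("phi outside [phi_min, phi_max]; clamping")
  }
  min(max((phi - phi_min) / (phi_max - phi_min), 0), 1)
}

#' Empirical normalization bounds from a calibration batch
#'
#' The entropy range observed over a batch of posterior means; an
#' alternative to the analytic bounds when the Monte-Carlo sample count is
#' small.
#'
#' @param phis vector of observed entropies
#' @return list with `phi_min` and `phi_max`
#' @export
empirical_entropy_bounds <- function(phis) {
  stopifnot(length(phis) >= 2)
  list(phi_min = min(phis), phi_max = max(phis))
}

#' Uncertainty report for a classification posterior
#'
#' @param posterior a `posterior_samples` of class-probability vectors
#' @param phi_T referral threshold on the normalized uncertainty
#' @param phi_min,phi_max normalization bounds; default analytic
#'   `[0, log(N)]`
#' @return an `uncertainty_report` with the posterior mean, `phi`,
#'   `phi_norm`, predicted class (argmax, ties to the lowest index) and
#'   `is_uncertain` (`phi_norm >= phi_T`)
#' @export
classification_uncertainty <- function(posterior, phi_T = 0.35,
                                       phi_min = 0, phi_max = NULL) {
  stopifnot(posterior$type == "class")
  mu <- posterior_mean(posterior)
  if (is.null(phi_max)) phi_max <- log(length(mu))
  phi <- predictive_entropy(mu)
  phi_norm <- normalize_uncertainty(phi, phi_min, phi_max)
  structure(list(posterior_mean = mu, phi = phi, phi_norm = phi_norm,
                 phi_min = phi_min, phi_max = phi_max,
                 mode = posterior$mode, count = posterior$count,
                 predicted = which.max(mu),
                 is_uncertain = phi_norm >= phi_T, phi_T = phi_T),
            class = "uncertainty_report")
}

#' Per-pixel entropy map and scalar uncertainty of a segmentation posterior
#'
#' The per-pixel binary entropy of the mean map is averaged and divided by
#' `log(2)` so the scalar lies in \[0, 1\] (`reduction = "mean_entropy"`,
#' the default). The alternative reduction reports the fraction of pixels
#' whose entropy exceeds half the binary maximum.
#'
#' @param posterior a `posterior_samples` of probability maps
#' @param reduction `"mean_entropy"` or `"fraction_uncertain"`
#' @return list with `mean_map`, `entropy_map` (nats) and scalar `phi_norm`
#' @export
segmentation_uncertainty <- function(posterior,
                                     reduction = c("mean_entropy",
                                                   "fraction_uncertain")) {
  reduction <- match.arg(reduction)
  stopifnot(inherits(posterior, "posterior_samples"), posterior$type == "map")
  pbar <- posterior_mean(posterior)
  pc <- pmin(pmax(pbar, 0), 1)
  ent <- matrix(0, nrow(pc), ncol(pc))
  nz <- pc > 0 & pc < 1
  ent[nz] <- -(pc[nz] * log(pc[nz]) + (1 - pc[nz]) * log(1 - pc[nz]))
  phi_norm <- if (reduction == "mean_entropy") {
    mean(ent) / log(2)
  } else {
    mean(ent > 0.5 * log(2))
  }
  list(mean_map = pbar, entropy_map = ent, phi_norm = phi_norm)
}

#' Certainty-correctness category of a prediction
#'
#' A prediction is certain iff `phi_norm < phi_T` (equality counts as
#' uncertain); crossing with correctness yields one of `"cc"`, `"cu"`,
#' `"ic"`, `"iu"`. Vectorized.
#'
#' @param correct logical: was the prediction correct
#' @param phi_norm normalized uncertainty in \[0, 1\]
#' @param phi_T threshold in \[0, 1\]
#' @return character vector of categories
#' @export
categorize <- function(correct, phi_norm, phi_T) {
  stopifnot(all(phi_norm >= 0 & phi_norm <= 1), phi_T >= 0, phi_T <= 1)
  certain <- phi_norm < phi_T
  ifelse(correct,
         ifelse(certain, "cc", "cu"),
         ifelse(certain, "ic", "iu"))
}

#' Category counts
#'
#' @param cc,cu,ic,iu non-negative counts of correct-certain,
#'   correct-uncertain, incorrect-certain and incorrect-uncertain cases
#' @return a `category_counts` list
#' @export
category_counts <- function(cc, cu, ic, iu) {
  if (any(c(cc, cu, ic, iu) < 0)) stop("category counts must be non-negative")
  structure(list(cc = cc, cu = cu, ic = ic, iu = iu),
            class = "category_counts")
}

#' Tally categories returned by [categorize()]
#'
#' @param categories character vector of `"cc"`, `"cu"`, `"ic"`, `"iu"`
#' @return a [category_counts()]
#' @export
count_categories <- function(categories) {
  category_counts(sum(categories == "cc"), sum(categories == "cu"),
                  sum(categories == "ic"), sum(categories == "iu"))
}

#' Diagnostic accuracy A(phi_T)
#'
#' The fraction of desirable outcomes — correct-certain plus
#' incorrect-uncertain — among all predictions:
#' `A = (L_cc + L_iu) / (L_cc + L_cu + L_ic + L_iu)`.
#'
#' @param counts a [category_counts()]
#' @return A in \[0, 1\]
#' @export
diagnostic_accuracy <- function(counts) {
  total <- counts$cc + counts$cu + counts$ic + counts$iu
  if (total == 0) stop("diagnostic accuracy undefined for zero total")
  (counts$cc + counts$iu) / total
}

#' Misclassification rate among uncertain predictions
#'
#' @param n_uncertain number of uncertain predictions (> 0)
#' @param n_misclassified_among_uncertain misclassified cases among them
#' @return percentage `100 * misclassified / uncertain`
#' @export
uncertain_misclassification_rate <- function(n_uncertain,
                                             n_misclassified_among_uncertain) {
  if (n_uncertain <= 0) stop("rate undefined: no uncertain predictions")
  if (n_misclassified_among_uncertain > n_uncertain) {
    stop("misclassified count cannot exceed uncertain count")
  }
  100 * n_misclassified_among_uncertain / n_uncertain
}

#' Batch classification uncertainty over a dataset
#'
#' Runs the requested posterior for every sample (passes are batched across
#' the dataset for `bayes_net` classifiers) and reports prediction,
#' entropy, normalized uncertainty and certainty category per sample.
#'
#' @param model classifier `bayes_net` or prediction function
#' @param samples list of labeled [lesion_sample()] or a `lesion_dataset`
#' @param mode `"combined"`, `"epistemic"` or `"aleatoric"`
#' @param count number of posterior passes (B, V or M)
#' @param phi_T referral threshold
#' @param transform_family augmentation family for TTA-based modes
#' @param seed optional RNG seed
#' @return data.frame with one row per sample: `sample_id`, `label`,
#'   `predicted`, `correct`, `phi`, `phi_norm`, `uncertain`, `category`
#' @export
batch_uncertainty <- function(model, samples,
                              mode = c("combined", "epistemic", "aleatoric"),
                              count = 20, phi_T = 0.35,
                              transform_family = tta_transforms(),
                              seed = NULL) {
  mode <- match.arg(mode)
  samples <- sample_list(samples)
  stopifnot(length(samples) > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(samples)
  use_aug <- mode %in% c("combined", "aleatoric")
  use_dropout <- mode %in% c("combined", "epistemic")
  batched <- inherits(model, "bayes_net") && model$spec$kind == "classifier"
  K <- if (batched) model$spec$n_classes else
    length(predict_one(model, samples[[1]]$image, FALSE))
  acc <- matrix(0, n, K)
  x0 <- stack_images(samples)
  fills <- lapply(samples, estimate_bg_tone)
  for (m in seq_len(count)) {
    x <- x0
    if (use_aug) {
      for (i in seq_len(n)) {
        tf <- sample_tta(transform_family)
        x[, , , i] <- apply_tta(x0[, , , i], tf, fills[[i]])
      }
    }
    if (batched) {
      p <- net_predict(model, x, stochastic = use_dropout)
    } else {
      p <- t(vapply(seq_len(n),
                    function(i) predict_one(model, x[, , , i], use_dropout),
                    numeric(K)))
    }
    acc <- acc + p
  }
  mu <- acc / count
  phi <- apply(mu, 1, predictive_entropy)
  phi_norm <- vapply(phi, normalize_uncertainty, 0, phi_min = 0, phi_max = log(K))
  predicted <- apply(mu, 1, which.max)
  label <- vapply(samples, function(s) s$label %||% NA_integer_, 0L)
  correct <- predicted == label
  data.frame(
    sample_id = vapply(samples, `[[`, "", "sample_id"),
    label = label, predicted = predicted, correct = correct,
    phi = phi, phi_norm = phi_norm,
    uncertain = phi_norm >= phi_T,
    category = categorize(correct, phi_norm, phi_T),
    stringsAsFactors = FALSE
  )
}
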