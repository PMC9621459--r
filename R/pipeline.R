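# The uncertainty-gated two-stage diagnosis flow: Bayesian segmentation with
# entropy gating decides whether the classifier sees the lesion-focused
# image or the original; Bayesian classification with entropy gating decides
# between emitting a diagnosis and referring to an expert; a saliency map
# accompanies every diagnosis.

#' Pipeline configuration
#'
#' @param phi_T_seg segmentation gate threshold on normalized uncertainty
#'   (0.25: below it the segmented image is handed to the classifier)
#' @param phi_T_cls classification referral threshold (0.35: at or above it
#'   the case is referred for a second opinion)
#' @param sample_counts list with `B` (MC-dropout), `V` (TTA) and `M`
#'   (combined) pass counts
#' @param uncertainty_mode posterior used for gating: `"combined"`
#'   (default), `"epistemic"` or `"aleatoric"`
#' @param handoff `"bbox_crop"` (tight box around the lesion with a 10%
#'   margin, then resized) or `"masked"` (background zeroed)
#' @param seg_input_size,cls_input_size stage input sizes `c(H, W)`
#' @param binarize_threshold threshold turning the mean mask binary
#' @param saliency_method attribution method attached to diagnoses
#' @param attach_saliency compute the attribution map in [run_skinet()]
#' @param transform_family TTA family for the aleatoric/combined posteriors
#' @param seg_reduction scalar reduction of the segmentation entropy map
#' @param seed base RNG seed for all posterior sampling
#' @param verbose log one line per stage
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(phi_T_seg = 0.25, phi_T_cls = 0.35,
                            sample_counts = list(B = 20, V = 20, M = 20),
                            uncertainty_mode = c("combined", "epistemic",
                                                 "aleatoric"),
                            handoff = c("bbox_crop", "masked"),
                            seg_input_size = c(224, 224),
                            cls_input_size = c(450, 600),
                            binarize_threshold = 0.5,
                            saliency_method = "xrai",
                            attach_saliency = TRUE,
                            transform_family = tta_transforms(),
                            seg_reduction = "mean_entropy",
                            seed = 1L, verbose = FALSE) {
  uncertainty_mode <- match.arg(uncertainty_mode)
  handoff <- match.arg(handoff)
  stopifnot(phi_T_seg >= 0, phi_T_seg <= 1, phi_T_cls >= 0, phi_T_cls <= 1,
            all(unlist(sample_counts) >= 1))
  structure(list(phi_T_seg = phi_T_seg, phi_T_cls = phi_T_cls,
                 sample_counts = sample_counts,
                 uncertainty_mode = uncertainty_mode, handoff = handoff,
                 seg_input_size = seg_input_size,
                 cls_input_size = cls_input_size,
                 binarize_threshold = binarize_threshold,
                 saliency_method = saliency_method,
                 attach_saliency = attach_saliency,
                 transform_family = transform_family,
                 seg_reduction = seg_reduction,
                 seed = as.integer(seed), verbose = verbose),
            class = "pipeline_config")
}

mode_count <- function(config) {
  switch(config$uncertainty_mode,
         epistemic = config$sample_counts$B,
         aleatoric = config$sample_counts$V,
         combined = config$sample_counts$M)
}

stage_posterior <- function(model, input, config, seed) {
  cnt <- mode_count(config)
  switch(config$uncertainty_mode,
         epistemic = epistemic_posterior(model, input, B = cnt, seed = seed),
         aleatoric = aleatoric_posterior(model, input, V = cnt,
                                         transform_family = config$transform_family,
                                         seed = seed),
         combined = combined_posterior(model, input, M = cnt,
                                       transform_family = config$transform_family,
                                       seed = seed))
}

#' Derive the classifier handoff image from a segmentation mask
#'
#' In `"masked"` mode the background is zeroed; in `"bbox_crop"` mode the
#' tight bounding box of the binarized mask, dilated by a 10% margin, is
#' cropped and resized back to the input size. An empty mask degrades
#' gracefully to the original image with a warning.
#'
#' @param image (H, W, 3) array
#' @param mean_mask (H, W) probability map from the segmentation posterior
#' @param mode `"bbox_crop"` or `"masked"`
#' @param binarize_threshold mask binarization threshold
#' @return (H, W, 3) image
#' @export
handoff_image <- function(image, mean_mask, mode = c("bbox_crop", "masked"),
                          binarize_threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(all(dim(mean_mask) == dim(image)[1:2]))
  bin <- mean_mask >= binarize_threshold
  if (!any(bin)) {
    warning("empty segmentation mask; returning the original image")
    return(image)
  }
  if (mode == "masked") {
    out <- image
    for (c in seq_len(dim(image)[3])) out[, , c] <- image[, , c] * bin
    return(out)
  }
  rows <- range(which(rowSums(bin) > 0))
  cols <- range(which(colSums(bin) > 0))
  mr <- ceiling(0.10 * (rows[2] - rows[1] + 1))
  mc <- ceiling(0.10 * (cols[2] - cols[1] + 1))
  r0 <- max(1, rows[1] - mr); r1 <- min(dim(image)[1], rows[2] + mr)
  c0 <- max(1, cols[1] - mc); c1 <- min(dim(image)[2], cols[2] + mc)
  crop <- image[r0:r1, c0:c1, , drop = FALSE]
  resize_image(crop, dim(image)[1], dim(image)[2])
}

#' Crop bounds used by the bounding-box handoff
#'
#' @inheritParams handoff_image
#' @param margin bounding-box dilation as a fraction of the box size
#' @return list with `rows` and `cols` (inclusive crop ranges), or `NULL`
#'   for an empty mask
#' @export
handoff_bbox <- function(mean_mask, binarize_threshold = 0.5, margin = 0.10) {
  bin <- mean_mask >= binarize_threshold
  if (!any(bin)) return(NULL)
  rows <- range(which(rowSums(bin) > 0))
  cols <- range(which(colSums(bin) > 0))
  mr <- ceiling(margin * (rows[2] - rows[1] + 1))
  mc <- ceiling(margin * (cols[2] - cols[1] + 1))
  list(rows = c(max(1, rows[1] - mr), min(nrow(bin), rows[2] + mr)),
       cols = c(max(1, cols[1] - mc), min(ncol(bin), cols[2] + mc)))
}

#' Run the two-stage uncertainty-gated diagnosis on one image
#'
#' Stage 1 resizes the image for the Bayesian segmenter, samples the
#' configured posterior and scores the segmentation uncertainty; when it is
#' below `phi_T_seg` the classifier receives the lesion-focused handoff
#' image, otherwise the original. Stage 2 samples the classification
#' posterior; below `phi_T_cls` the argmax class is diagnosed, otherwise
#' the case is referred. An attribution map for the classifier's top class
#' on the image actually classified accompanies the result.
#'
#' @param input a [lesion_sample()] or (H, W, 3) image
#' @param segmenter segmenter `bayes_net` (or function `f(image,
#'   stochastic)` returning a probability map)
#' @param classifier classifier `bayes_net` (or function returning a
#'   probability vector)
#' @param config a [pipeline_config()]
#' @return a `skinet_diagnosis` with the gate outcomes, uncertainties,
#'   decision (`"diagnose"` or `"refer"`), predicted class (`NA` when
#'   referred; the classifier's argmax is kept in `predicted_internal`),
#'   posterior mean and optional `explanation`
#' @export
run_skinet <- function(input, segmenter, classifier,
                       config = pipeline_config()) {
  img <- as_input_image(input)
  sid <- input_id(input)
  seg_in <- resize_image(img, config$seg_input_size[1], config$seg_input_size[2])
  seg_post <- stage_posterior(segmenter, seg_in, config, seed = config$seed)
  seg_unc <- segmentation_uncertainty(seg_post, reduction = config$seg_reduction)
  use_seg <- seg_unc$phi_norm < config$phi_T_seg
  if (config$verbose) {
    message(sprintf("[seg] phi_norm=%.3f gate=%s", seg_unc$phi_norm,
                    if (use_seg) "segmented" else "original"))
  }
  base_img <- if (use_seg) {
    handoff_image(seg_in, seg_unc$mean_map, config$handoff,
                  config$binarize_threshold)
  } else {
    seg_in
  }
  cls_in <- resize_image(base_img, config$cls_input_size[1],
                         config$cls_input_size[2])
  cls_post <- stage_posterior(classifier, cls_in, config,
                              seed = config$seed + 1L)
  rep <- classification_uncertainty(cls_post, phi_T = config$phi_T_cls)
  decision <- if (rep$phi_norm < config$phi_T_cls) "diagnose" else "refer"
  if (config$verbose) {
    message(sprintf("[cls] phi_norm=%.3f decision=%s", rep$phi_norm, decision))
  }
  explanation <- NULL
  if (config$attach_saliency && inherits(classifier, "bayes_net")) {
    explanation <- compute_saliency(classifier, cls_in,
                                    method = config$saliency_method,
                                    target_class = rep$predicted)
  }
  structure(list(input_id = sid,
                 seg_phi_norm = seg_unc$phi_norm,
                 used_segmented_input = use_seg,
                 seg_mean_mask = seg_unc$mean_map,
                 seg_entropy_map = seg_unc$entropy_map,
                 predicted_class = if (decision == "diagnose") rep$predicted else NA_integer_,
                 predicted_internal = rep$predicted,
                 cls_phi_norm = rep$phi_norm,
                 decision = decision,
                 posterior_mean = rep$posterior_mean,
                 explanation = explanation),
            class = "skinet_diagnosis")
}

#' @export
print.skinet_diagnosis <- function(x, ...) {
  cat(sprintf("diagnosis for '%s'\n", x$input_id))
  cat(sprintf("  segmentation phi_norm %.3f -> %s input\n", x$seg_phi_norm,
              if (x$used_segmented_input) "segmented" else "original"))
  cat(sprintf("  classification phi_norm %.3f -> %s", x$cls_phi_norm, x$decision))
  if (x$decision == "diagnose") cat(sprintf(" (class %d)", x$predicted_class))
  cat("\n")
  invisible(x)
}

#' Evaluate the pipeline on a labeled dataset
#'
#' Runs [run_skinet()] per sample but always records the classifier's
#' argmax prediction (referred cases keep their underlying prediction and
#' land in the uncertain categories), tallies the four
#' certainty-correctness categories at `phi_T_cls`, and reports the
#' diagnostic accuracy plus plain prediction accuracy under both
#' accountings (refer cases counted as predictions, and excluded).
#'
#' @param samples labeled [lesion_sample()] list or `lesion_dataset`
#' @param segmenter,classifier trained models
#' @param config a [pipeline_config()]; saliency is skipped during
#'   evaluation unless `attach_saliency` is set
#' @return a `skinet_evaluation` list: `per_sample` data.frame, `counts`
#'   ([category_counts()]), `diagnostic_accuracy`, `prediction_accuracy`,
#'   `prediction_accuracy_diagnosed`
#' @export
evaluate_pipeline <- function(samples, segmenter, classifier,
                              config = pipeline_config(attach_saliency = FALSE)) {
  samples <- sample_list(samples)
  if (length(samples) == 0) stop("evaluation undefined on empty dataset")
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    sm <- samples[[i]]
    cfg <- config
    cfg$seed <- config$seed + 2L * i
    dg <- run_skinet(sm, segmenter, classifier, cfg)
    rows[[i]] <- data.frame(
      sample_id = sm$sample_id, label = sm$label,
      predicted = dg$predicted_internal,
      correct = dg$predicted_internal == sm$label,
      seg_phi_norm = dg$seg_phi_norm,
      used_segmented_input = dg$used_segmented_input,
      cls_phi_norm = dg$cls_phi_norm,
      decision = dg$decision, stringsAsFactors = FALSE
    )
  }
  per <- do.call(rbind, rows)
  per$category <- categorize(per$correct, per$cls_phi_norm, config$phi_T_cls)
  counts <- count_categories(per$category)
  diagnosed <- per$decision == "diagnose"
  structure(list(
    per_sample = per,
    counts = counts,
    diagnostic_accuracy = diagnostic_accuracy(counts),
    prediction_accuracy = mean(per$correct),
    prediction_accuracy_diagnosed =
      if (any(diagnosed)) mean(per$correct[diagnosed]) else NA_real_
  ), class = "skinet_evaluation")
}

#' Diagnostic accuracy as a function of the threshold
#'
#' Categorizes every (correct, phi_norm) record at each threshold in the
#' grid and computes A(phi_T).
#'
#' @param records data.frame with logical `correct` and numeric `phi_norm`
#' @param thresholds numeric grid of thresholds in \[0, 1\]
#' @param out_csv optional CSV output path
#' @return data.frame with `phi_T`, the four category counts and `A`
#' @export
threshold_sweep <- function(records, thresholds = seq(0, 1, by = 0.05),
                            out_csv = NULL) {
  stopifnot(nrow(records) > 0)
  rows <- lapply(thresholds, function(th) {
    cats <- categorize(records$correct, records$phi_norm, th)
    cnt <- count_categories(cats)
    data.frame(phi_T = th, cc = cnt$cc, cu = cnt$cu, ic = cnt$ic, iu = cnt$iu,
               A = diagnostic_accuracy(cnt))
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Serialize a diagnosis to JSON
#'
#' @param diagnosis a `skinet_diagnosis`
#' @param path output path
#' @export
write_diagnosis_json <- function(diagnosis, path) {
  obj <- list(input_id = diagnosis$input_id,
              seg_phi_norm = diagnosis$seg_phi_norm,
              used_segmented_input = diagnosis$used_segmented_input,
              predicted_class = diagnosis$predicted_class,
              cls_phi_norm = diagnosis$cls_phi_norm,
              decision = diagnosis$decision,
              posterior_mean = diagnosis$posterior_mean)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
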