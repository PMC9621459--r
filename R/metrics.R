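# Evaluation metrics: accuracy and F1 for classification, Dice and Jaccard
# for segmentation masks, and the binary cross-entropy training loss.

#' Confusion counts
#'
#' @param Tp,Tn,Fp,Fn non-negative true/false positive/negative counts
#' @return a `confusion_counts` list
#' @export
confusion_counts <- function(Tp, Tn, Fp, Fn) {
  counts <- c(Tp = Tp, Tn = Tn, Fp = Fp, Fn = Fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  structure(as.list(counts), class = "confusion_counts")
}

#' Classification accuracy (Tp + Tn) / total
#'
#' @param counts a [confusion_counts()]
#' @return accuracy in \[0, 1\]
#' @export
accuracy <- function(counts) {
  total <- counts$Tp + counts$Tn + counts$Fp + counts$Fn
  if (total == 0) stop("accuracy undefined for zero total count")
  (counts$Tp + counts$Tn) / total
}

#' F1 score, the harmonic mean of precision and recall
#'
#' Returns 0 when there are no true positives but errors exist.
#'
#' @param counts a [confusion_counts()]
#' @return F1 in \[0, 1\]
#' @export
f1_score <- function(counts) {
  if (counts$Tp + counts$Fp + counts$Fn == 0) {
    stop("F1 undefined: no positives predicted or present")
  }
  if (counts$Tp == 0) return(0)
  precision <- counts$Tp / (counts$Tp + counts$Fp)
  recall <- counts$Tp / (counts$Tp + counts$Fn)
  2 * precision * recall / (precision + recall)
}

#' Overlap summary of two binary masks
#'
#' @param M ground-truth binary mask (matrix)
#' @param C predicted binary mask of the same size
#' @return a `mask_overlap` list with `intersection`, `size_M`, `size_C`
#' @export
mask_overlap <- function(M, C) {
  stopifnot(all(dim(M) == dim(C)))
  if (!all(M %in% c(0, 1)) || !all(C %in% c(0, 1))) {
    stop("masks must be binary")
  }
  structure(list(intersection = sum(M * C), size_M = sum(M), size_C = sum(C)),
            class = "mask_overlap")
}

#' Dice coefficient 2|M∩C| / (|M| + |C|)
#'
#' Two empty masks are defined to agree perfectly (Dice 1).
#'
#' @param overlap a [mask_overlap()]
#' @return Dice similarity in \[0, 1\]
#' @export
dice <- function(overlap) {
  denom <- overlap$size_M + overlap$size_C
  if (denom == 0) return(1)
  2 * overlap$intersection / denom
}

#' Jaccard index |M∩C| / |M∪C|
#'
#' Returns the similarity by default. Note that the distance form
#' `1 - similarity` is sometimes printed as "the Jaccard index" in the
#' segmentation literature even where similarity-scale values (comparable
#' to Dice) are reported; set `as_distance = TRUE` for the distance.
#'
#' @param overlap a [mask_overlap()]
#' @param as_distance return `1 - similarity` instead of the similarity
#' @return value in \[0, 1\]
#' @export
jaccard <- function(overlap, as_distance = FALSE) {
  denom <- overlap$size_M + overlap$size_C - overlap$intersection
  j <- if (overlap$size_M + overlap$size_C == 0) 1 else overlap$intersection / denom
  if (as_distance) 1 - j else j
}

#' Mean binary cross-entropy
#'
#' Probabilities are clipped to `[epsilon, 1 - epsilon]` before the logs.
#'
#' @param y binary truth values (vector/array)
#' @param p predicted probabilities in \[0, 1\], same shape as `y`
#' @param epsilon clipping constant in (0, 1e-6]
#' @return non-negative mean negative log-likelihood (nats)
#' @export
bce_loss <- function(y, p, epsilon = 1e-12) {
  stopifnot(length(y) > 0, length(y) == length(p))
  if (!all(y %in% c(0, 1))) stop("y must be binary")
  if (min(p) < 0 || max(p) > 1) stop("p must lie in [0, 1]")
  if (epsilon <= 0 || epsilon > 1e-6) stop("epsilon must be in (0, 1e-6]")
  p <- pmin(pmax(p, epsilon), 1 - epsilon)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Batch segmentation evaluation
#'
#' Computes Dice and Jaccard per mask pair plus two aggregates: the mean of
#' per-image values and the global-pixel value (all pixels pooled), since
#' published summary tables rarely state which aggregation they used.
#'
#' @param pred list of predicted binary masks
#' @param truth list of ground-truth binary masks (same length/sizes)
#' @return list with `per_sample` (data.frame) and `aggregate` (data.frame
#'   with rows `mean_per_image` and `global_pixel`)
#' @export
evaluate_segmentation <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) > 0)
  per <- lapply(seq_along(pred), function(i) {
    ov <- mask_overlap(truth[[i]], pred[[i]])
    data.frame(index = i, dice = dice(ov), jaccard = jaccard(ov))
  })
  per <- do.call(rbind, per)
  inter <- sum(vapply(seq_along(pred), function(i) sum(truth[[i]] * pred[[i]]), 0))
  sm <- sum(vapply(truth, sum, 0)); sc <- sum(vapply(pred, sum, 0))
  gl <- structure(list(intersection = inter, size_M = sm, size_C = sc),
                  class = "mask_overlap")
  aggregate <- data.frame(
    mode = c("mean_per_image", "global_pixel"),
    dice = c(mean(per$dice), dice(gl)),
    jaccard = c(mean(per$jaccard), jaccard(gl))
  )
  list(per_sample = per, aggregate = aggregate)
}

#' Evaluate mask PNG pairs listed in a manifest CSV
#'
#' The manifest must contain `pred_path` and `truth_path` columns naming
#' binary mask PNGs.
#'
#' @param manifest_csv path to the manifest
#' @param out_csv optional path to write the per-sample metrics as CSV
#' @return as [evaluate_segmentation()]
#' @export
evaluate_mask_files <- function(manifest_csv, out_csv = NULL) {
  mf <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  pred <- lapply(mf$pred_path, function(p) round(png::readPNG(p)))
  truth <- lapply(mf$truth_path, function(p) round(png::readPNG(p)))
  res <- evaluate_segmentation(pred, truth)
  if (!is.null(out_csv)) utils::write.csv(res$per_sample, out_csv, row.names = FALSE)
  res
}
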