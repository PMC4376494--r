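# Segmentation evaluation: TPR / FPR / accuracy against ground truth within
# a field-of-view mask, and FOV construction by per-channel thresholding.

#' Field-of-view mask from an RGB fundus image
#'
#' A pixel belongs to the FOV iff every colour channel exceeds its
#' threshold; the raw threshold mask is then cleaned by keeping only the
#' largest 8-connected component (channel thresholding alone leaves
#' speckle outside the aperture).
#'
#' @param image `H x W x 3` array on a 0-255 scale (or a path).
#' @param thresholds Per-channel thresholds, recycled to length 3.
#' @return Logical matrix.
#' @export
fov_mask_from_rgb <- function(image, thresholds = c(40, 40, 40)) {
  image <- as_image(image)
  if (length(dim(image)) != 3 || dim(image)[3] < 3) {
    stop("fov_mask_from_rgb needs a 3-channel image; ",
         "for grayscale input pass an explicit FOV mask instead",
         call. = FALSE)
  }
  thresholds <- rep_len(thresholds, 3)
  mask <- image[, , 1] > thresholds[1] &
          image[, , 2] > thresholds[2] &
          image[, , 3] > thresholds[3]
  if (!any(mask)) return(mask)
  lab <- label_components(mask)
  largest <- which.max(lab$component_sizes)
  lab$labels == largest
}

#' Segmentation metrics within a field of view
#'
#' Computes TPR = tp/(tp+fn), FPR = fp/(fp+tn) and accuracy =
#' (tp+tn)/(tp+fp+tn+fn) with all counts restricted to the FOV mask.
#' Whole-image accuracy (no FOV restriction) is reported alongside, since
#' both conventions are in use.
#'
#' @param pred Predicted binary vessel mask (logical matrix or path).
#' @param truth Ground-truth binary vessel mask.
#' @param fov Optional FOV mask; defaults to the whole image.
#' @return A list of class `segmentation_metrics` with fields `tpr`, `fpr`,
#'   `accuracy`, `accuracy_whole_image` and the counts `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
compute_metrics <- function(pred, truth, fov = NULL) {
  pred <- as_mask(pred)
  truth <- as_mask(truth)
  stopifnot_same_dim(pred, truth, "truth mask")
  if (is.null(fov)) {
    fov <- matrix(TRUE, nrow(pred), ncol(pred))
  } else {
    fov <- as_mask(fov)
    stopifnot_same_dim(pred, fov, "fov mask")
  }
  tp_w <- sum(pred & truth); tn_w <- sum(!pred & !truth)
  p <- pred[fov]; t <- truth[fov]
  tp <- sum(p & t); fp <- sum(p & !t)
  fn <- sum(!p & t); tn <- sum(!p & !t)
  metrics <- list(
    tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    accuracy_whole_image = (tp_w + tn_w) / length(pred),
    tp = tp, fp = fp, tn = tn, fn = fn)
  structure(metrics, class = "segmentation_metrics")
}

#' @export
print.segmentation_metrics <- function(x, ...) {
  cat(sprintf("TPR %.4f  FPR %.4f  ACC %.4f (FOV) / %.4f (whole image)\n",
              x$tpr, x$fpr, x$accuracy, x$accuracy_whole_image))
  cat(sprintf("counts: tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Serialize metrics to JSON
#'
#' @param metrics A [compute_metrics()] result.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
metrics_to_json <- function(metrics, path = NULL) {
  s <- jsonlite::toJSON(unclass(metrics), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
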