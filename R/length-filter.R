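# Length filter: 8-connected component labelling and pixel-count
# thresholding of the mixture-model output.

#' Label 8-connected components of a binary mask
#'
#' @param mask Logical matrix.
#' @return A list of class `labeled_mask` with `labels` (integer matrix,
#'   0 = background, components numbered consecutively from 1),
#'   `n_components`, and `component_sizes` (pixel count per label).
#' @export
label_components <- function(mask) {
  mask <- as_mask(mask)
  res <- .label_cpp(mask)
  structure(list(labels = res$labels,
                 n_components = res$n,
                 component_sizes = as.integer(res$sizes)),
            class = "labeled_mask")
}

#' Discard small connected components
#'
#' Keeps exactly the components whose pixel count is at least `min_size`
#' (components of size strictly less than the threshold are discarded).
#'
#' @param labeled A [label_components()] result, or a logical mask (which is
#'   labelled first).
#' @param min_size Minimum component size in pixels (>= 0).
#' @return Logical matrix; a subset of the input foreground.
#' @export
filter_by_size <- function(labeled, min_size) {
  if (is.logical(labeled) || is.matrix(labeled)) {
    labeled <- label_components(labeled)
  }
  if (min_size < 0) stop("min_size must be >= 0", call. = FALSE)
  if (labeled$n_components == 0) {
    return(labeled$labels > 0)
  }
  keep <- which(labeled$component_sizes >= min_size)
  matrix(labeled$labels %in% keep & labeled$labels > 0,
         nrow = nrow(labeled$labels))
}

# Default component-size threshold: 100 px at DRIVE-scale resolution
# (565 x 584), scaled proportionally to image area.
scaled_min_size <- function(h, w, base = 100, reference_area = 565 * 584) {
  max(1L, as.integer(round(base * (h * w) / reference_area)))
}
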