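# Vessel enhancement: windowed rank-based adaptive histogram equalisation,
# quantile binarization + morphological opening, and the Euclidean distance
# map fed to the mixture-model stage.

#' Enhancement stage configuration
#'
#' @param r Contrast exponent (>= 1). Larger `r` suppresses mid-rank pixels
#'   and widens the gap between vessel and background responses.
#' @param h Square window width in pixels (odd, >= 3).
#' @param open_radius Disk radius (pixels) of the binary opening used to
#'   prune speckle; `0` disables the opening.
#' @param binarize_quantile Quantile of the enhanced image used as the
#'   foreground threshold, in (0, 1).
#' @return A list of class `enhancement_config`.
#' @export
enhancement_config <- function(r = 3, h = 81, open_radius = 1,
                               binarize_quantile = 0.85) {
  if (h < 3 || h %% 2 == 0) {
    stop("window width h must be odd and >= 3 (got ", h, ")", call. = FALSE)
  }
  if (r < 1) stop("contrast exponent r must be >= 1", call. = FALSE)
  if (open_radius < 0) stop("open_radius must be >= 0", call. = FALSE)
  if (binarize_quantile <= 0 || binarize_quantile >= 1) {
    stop("binarize_quantile must be in (0, 1)", call. = FALSE)
  }
  structure(list(r = r, h = h, open_radius = open_radius,
                 binarize_quantile = binarize_quantile),
            class = "enhancement_config")
}

#' Adaptive histogram equalisation (windowed rank transform)
#'
#' For every pixel q, counts the pixels q' in the h-by-h window centred on q
#' whose intensity is strictly below I(q), and maps the count c(q) to
#' `255 * (c(q) / h^2)^r`. The transform depends only on strict intensity
#' ranks inside each window, so it is invariant under any strictly
#' increasing remapping of the input. Borders are handled by mirror
#' reflection so every pixel sees a full window.
#'
#' @param image Numeric matrix of intensities (any linear scale).
#' @param config An [enhancement_config()].
#' @return Numeric matrix in \[0, 255\].
#' @export
adaptive_hist_eq <- function(image, config = enhancement_config()) {
  image <- as_image(image)
  if (!is.matrix(image)) stop("adaptive_hist_eq expects a grayscale matrix",
                              call. = FALSE)
  if (!all(is.finite(image))) stop("image contains non-finite values",
                                   call. = FALSE)
  if (config$h %% 2 == 0) stop("window width h must be odd", call. = FALSE)
  .ahe_cpp(image, as.integer(config$h), as.numeric(config$r))
}

#' Threshold and open an enhanced image
#'
#' Keeps pixels strictly above the `binarize_quantile` quantile of the
#' enhanced image, then applies a binary morphological opening (erosion
#' followed by dilation) with a disk of radius `open_radius`. Opening can
#' only remove foreground pixels, never add them.
#'
#' @param enhanced Numeric matrix in \[0, 255\].
#' @param config An [enhancement_config()].
#' @return Logical matrix (pruned vessel candidate mask).
#' @export
binarize_and_open <- function(enhanced, config = enhancement_config()) {
  enhanced <- as_image(enhanced)
  thr <- stats::quantile(enhanced, config$binarize_quantile, names = FALSE)
  mask <- enhanced > thr
  binary_open(mask, config$open_radius)
}

#' Binary morphological opening with a disk
#'
#' @param mask Logical matrix.
#' @param radius Disk radius in pixels; `0` returns the mask unchanged.
#' @return Logical matrix, a subset of `mask`.
#' @export
binary_open <- function(mask, radius = 1) {
  mask <- as_mask(mask)
  if (radius <= 0) return(mask)
  off <- disk_offsets(radius)
  er <- .morph_cpp(mask, off$dy, off$dx, dilate = FALSE)
  .morph_cpp(er, off$dy, off$dx, dilate = TRUE)
}

disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  keep <- g$dy^2 + g$dx^2 <= radius^2
  list(dy = as.integer(g$dy[keep]), dx = as.integer(g$dx[keep]))
}

#' Euclidean distance map of a binary mask
#'
#' Assigns each foreground pixel its exact Euclidean distance to the nearest
#' background pixel; background pixels get 0. If the mask has no background
#' pixel at all, the distance to the image border is used instead (treating
#' everything outside the image as background) and a warning is issued.
#'
#' @param mask Logical matrix.
#' @return Numeric matrix of class `distance_map` (non-negative).
#' @export
distance_map <- function(mask) {
  mask <- as_mask(mask)
  if (all(mask)) {
    warning("mask has no background pixel; using distance to image border")
    h <- nrow(mask); w <- ncol(mask)
    d <- pmin(outer(1:h, rep(1, w)), outer(h:1, rep(1, w)),
              outer(rep(1, h), 1:w), outer(rep(1, h), w:1))
    return(structure(d, class = c("distance_map", class(d))))
  }
  d <- .edt_cpp(mask)$dist
  structure(d, class = c("distance_map", class(d)))
}

# Feature transform: 1-based linear index of the nearest FALSE pixel for
# every pixel (used to extend fields beyond a field-of-view mask).
nearest_background_index <- function(mask) {
  .edt_cpp(mask)$nearest
}
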