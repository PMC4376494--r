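# Iterative log-domain bias-field correction. The multiplicative model
# v(x) = v'(x) * f(x) becomes additive after taking logs; each iteration
# estimates the expected true log image from the current corrected image by
# histogram sharpening, smooths the residual (current - expected) with a
# least-squares tensor-product cubic B-spline, and accumulates the smoothed
# residual into the total field. The field is only identifiable up to a
# constant, so every residual is centred to zero mean inside the FOV.

#' Bias-correction configuration
#'
#' @param max_iterations Iteration cap per resolution level.
#' @param convergence_threshold Stop a level when the coefficient of
#'   variation of `exp(field update)` inside the FOV drops below this.
#' @param fitting_levels Number of multi-resolution levels; the control-point
#'   spacing is halved at each successive level.
#' @param control_point_spacing B-spline control-point spacing in pixels at
#'   the coarsest level.
#' @param histogram_bins Bins of the log-intensity histogram used by the
#'   sharpening step.
#' @param sharpening_fwhm Full width at half maximum (log-intensity units)
#'   of the Gaussian deconvolved from the histogram.
#' @param wiener_noise Noise term of the Wiener deconvolution filter.
#' @return A list of class `n4_config`.
#' @export
n4_config <- function(max_iterations = 50, convergence_threshold = 1e-3,
                      fitting_levels = 4, control_point_spacing = 256,
                      histogram_bins = 200, sharpening_fwhm = 0.15,
                      wiener_noise = 0.01) {
  stopifnot(max_iterations >= 1, fitting_levels >= 1, histogram_bins >= 1,
            convergence_threshold > 0, control_point_spacing > 0,
            sharpening_fwhm > 0, wiener_noise > 0)
  structure(list(max_iterations = max_iterations,
                 convergence_threshold = convergence_threshold,
                 fitting_levels = fitting_levels,
                 control_point_spacing = control_point_spacing,
                 histogram_bins = histogram_bins,
                 sharpening_fwhm = sharpening_fwhm,
                 wiener_noise = wiener_noise),
            class = "n4_config")
}

#' Expected true image by histogram sharpening
#'
#' Builds a histogram of the log-intensity field, deconvolves it with a
#' Gaussian of FWHM `config$sharpening_fwhm` by Wiener deconvolution, and
#' maps every pixel to the conditional expectation of the sharpened
#' intensity given its observed intensity. Sharpening pulls each pixel
#' toward the nearest intensity mode and never increases histogram entropy.
#'
#' @param log_image Numeric matrix (or vector) of log intensities.
#' @param config An [n4_config()].
#' @return Field of the same shape as `log_image`.
#' @export
expected_true_image <- function(log_image, config = n4_config()) {
  if (!all(is.finite(log_image))) {
    stop("log_image contains non-finite values", call. = FALSE)
  }
  v <- as.numeric(log_image)
  rng <- range(v)
  if (diff(rng) < 1e-12) return(log_image)  # constant: nothing to sharpen
  nb <- config$histogram_bins
  binw <- diff(rng) / (nb - 1)
  centers <- seq(rng[1], rng[2], length.out = nb)
  idx <- pmin(pmax(round((v - rng[1]) / binw) + 1, 1), nb)
  hist <- tabulate(idx, nbins = nb)

  np <- 2^ceiling(log2(max(4 * nb, 64)))
  # centre the histogram in the padded array so deconvolution side lobes
  # never wrap circularly onto far-away intensity coordinates
  pad <- (np - nb) %/% 2
  hp <- c(rep(0, pad), hist, rep(0, np - nb - pad))
  # Gaussian kernel wrapped so offset 0 sits at index 1
  sigma <- config$sharpening_fwhm / (2 * sqrt(2 * log(2)))
  off <- c(0:(np / 2), (-np / 2 + 1):(-1)) * binw
  kern <- exp(-off^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  fK <- fft(kern)

  # Wiener deconvolution of the blur from the histogram
  fH <- fft(hp)
  fG <- Conj(fK) / (Mod(fK)^2 + config$wiener_noise)
  sharp <- Re(fft(fH * fG, inverse = TRUE)) / np
  sharp[sharp < 0] <- 0

  # E[true | observed]: blur the sharpened mass and its first moment back
  centers_p <- rng[1] + (seq_len(np) - 1 - pad) * binw
  num <- Re(fft(fft(sharp * centers_p) * fK, inverse = TRUE)) / np
  den <- Re(fft(fft(sharp) * fK, inverse = TRUE)) / np
  mapping <- ifelse(den > 1e-12 * max(den), num / den, centers_p)
  mapping <- mapping[pad + seq_len(nb)]
  out <- approx(centers, mapping, xout = v, rule = 2)$y
  if (is.matrix(log_image)) {
    out <- matrix(out, nrow(log_image), ncol(log_image))
  }
  out
}

#' Least-squares B-spline smoothing of a field
#'
#' Projects the field onto a tensor product of uniform cubic B-spline bases
#' with the given control-point spacing. The projection reproduces
#' constants and linear ramps exactly and is idempotent: applying it twice
#' equals applying it once (up to numerical tolerance).
#'
#' @param field Numeric matrix.
#' @param spacing Control-point spacing in pixels (>= 2; must not exceed
#'   both image dimensions).
#' @return Smoothed numeric matrix of the same shape.
#' @export
smooth_field <- function(field, spacing) {
  h <- nrow(field); w <- ncol(field)
  if (spacing < 2) stop("control-point spacing must be >= 2", call. = FALSE)
  if (spacing > h && spacing > w) {
    stop("control-point spacing (", spacing,
         ") exceeds both image dimensions", call. = FALSE)
  }
  By <- bspline_basis(h, spacing)
  Bx <- bspline_basis(w, spacing)
  # projection: B (B'B)^-1 B' F ... applied separably on both axes
  cy <- solve(crossprod(By) + diag(1e-10, ncol(By)), t(By) %*% field)
  cxy <- solve(crossprod(Bx) + diag(1e-10, ncol(Bx)), t(Bx) %*% t(By %*% cy))
  t(Bx %*% cxy)
}

# Uniform cubic B-spline basis over coordinates 1..n with control-point
# spacing close to `spacing` (adjusted so the knot grid exactly covers the
# domain). Cached per (n, spacing).
bspline_basis <- local({
  cache <- new.env(parent = emptyenv())
  function(n, spacing) {
    key <- paste0(n, "_", spacing)
    if (!is.null(cache[[key]])) return(cache[[key]])
    nseg <- max(1L, as.integer(ceiling((n - 1) / spacing)))
    step <- (n - 1) / nseg
    knots <- 1 + step * seq(-3, nseg + 3)
    B <- splines::splineDesign(knots, seq_len(n), ord = 4)
    cache[[key]] <- B
    B
  }
})

#' Iterative bias-field correction
#'
#' Removes smooth multiplicative intensity inhomogeneity. The image must be
#' strictly positive inside the FOV (its log is taken). Residual fields are
#' estimated at `fitting_levels` successively finer control-point spacings;
#' the total field is exactly the sum of all per-iteration residual fields,
#' each centred to zero mean inside the FOV so overall brightness is kept.
#'
#' @param image Numeric matrix (grayscale, linear intensity scale) or path.
#' @param fov Optional logical FOV mask; defaults to the whole image.
#' @param config An [n4_config()].
#' @return A list of class `n4_result` with `corrected` (equal to
#'   `exp(log(image) - total_field)` inside the FOV, unchanged outside) and
#'   `bias` (class `bias_field_estimate`: `residual_fields`, `total_field`,
#'   `spacings`, `n_iterations`).
#' @export
run_n4 <- function(image, fov = NULL, config = n4_config()) {
  image <- as_image(image)
  if (!is.matrix(image)) {
    stop("run_n4 expects a grayscale matrix; select a channel first",
         call. = FALSE)
  }
  h <- nrow(image); w <- ncol(image)
  if (is.null(fov)) fov <- matrix(TRUE, h, w) else fov <- as_mask(fov)
  stopifnot_same_dim(image, fov, "fov mask")
  if (!any(fov)) stop("FOV mask is empty", call. = FALSE)
  bad <- which(fov & image <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive intensity inside the FOV at pixel (row ",
         bad[1, 1], ", col ", bad[1, 2], "); cannot take log",
         call. = FALSE)
  }

  u <- matrix(0, h, w)
  u[fov] <- log(image[fov])
  # nearest-FOV extension indices, for smoothing fields past the FOV rim
  fill_idx <- if (all(fov)) NULL else nearest_background_index(!fov)

  f_total <- matrix(0, h, w)
  residuals <- list()
  spacings <- numeric(0)
  for (level in seq_len(config$fitting_levels)) {
    spacing <- config$control_point_spacing / 2^(level - 1)
    spacing <- max(2, min(spacing, max(h, w)))
    for (iter in seq_len(config$max_iterations)) {
      u_hat <- u[fov] - f_total[fov]
      sharp <- expected_true_image(u_hat, config)
      resid <- matrix(0, h, w)
      resid[fov] <- u_hat - sharp
      if (!is.null(fill_idx)) {
        outside <- !fov
        resid[outside] <- resid[fill_idx[outside]]
      }
      rs <- smooth_field(resid, spacing)
      rs <- rs - mean(rs[fov])
      f_total <- f_total + rs
      residuals[[length(residuals) + 1]] <- rs
      spacings <- c(spacings, spacing)
      ers <- exp(rs[fov])
      cv <- sd(ers) / mean(ers)
      if (cv < config$convergence_threshold) break
    }
  }

  corrected <- image
  corrected[fov] <- exp(u[fov] - f_total[fov])
  bias <- structure(list(residual_fields = residuals,
                         total_field = f_total,
                         spacings = spacings,
                         n_iterations = length(residuals)),
                    class = "bias_field_estimate")
  structure(list(corrected = corrected, bias = bias, fov = fov),
            class = "n4_result")
}
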