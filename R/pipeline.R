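# End-to-end orchestration: bias correction -> adaptive histogram
# equalisation -> binarization + opening -> distance map -> two-component
# EM classification -> length filter, with optional evaluation against
# ground truth.

#' Pipeline configuration
#'
#' @param bias An [n4_config()].
#' @param enhancement An [enhancement_config()].
#' @param em List with `init`, `tol`, `max_iter`, `seed` for [fit_em()].
#' @param length_filter List with `min_size` (pixel-count threshold at
#'   DRIVE-scale resolution, 565 x 584) and `scale_with_area` (scale the
#'   threshold proportionally to the image area).
#' @param channel Color channel fed to the grayscale pipeline
#'   (`"green"` by fundus convention).
#' @param save_intermediates Write per-stage images when an output
#'   directory is given to [run_pipeline()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(bias = n4_config(),
                            enhancement = enhancement_config(),
                            em = list(init = "quantile", tol = 1e-6,
                                      max_iter = 200, seed = 1L),
                            length_filter = list(min_size = 100,
                                                 scale_with_area = TRUE),
                            channel = "green",
                            save_intermediates = FALSE) {
  structure(list(bias = bias, enhancement = enhancement, em = em,
                 length_filter = length_filter, channel = channel,
                 save_intermediates = save_intermediates),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipeline_config()]: blocks `bias:`, `enhancement:`, `em:`,
#' `length_filter:` plus `channel` and `save_intermediates`. Missing keys
#' keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  cfg <- defaults
  for (block in c("em", "length_filter")) {
    if (!is.null(raw[[block]])) {
      cfg[[block]] <- modifyList(defaults[[block]], raw[[block]])
    }
  }
  if (!is.null(raw$bias)) {
    cfg$bias <- do.call(n4_config, modifyList(unclass(defaults$bias),
                                              raw$bias))
  }
  if (!is.null(raw$enhancement)) {
    cfg$enhancement <- do.call(enhancement_config,
                               modifyList(unclass(defaults$enhancement),
                                          raw$enhancement))
  }
  if (!is.null(raw$channel)) cfg$channel <- raw$channel
  if (!is.null(raw$save_intermediates)) {
    cfg$save_intermediates <- isTRUE(raw$save_intermediates)
  }
  cfg
}

#' Run the full vessel-extraction pipeline
#'
#' Stages, in order: bias-field correction of the selected channel,
#' contrast inversion (vessels are dark in fundus images; the rank
#' transform lights up locally bright structures), adaptive histogram
#' equalisation, quantile binarization with morphological opening,
#' Euclidean distance map, two-component EM classification of the
#' distance values, and the connected-component length filter. All
#' randomness is seeded through the config, so identical inputs give
#' bit-identical outputs.
#'
#' @param image Path or `H x W (x 3)` image on the 0-255 scale.
#' @param fov Optional FOV mask (path or logical matrix). EM is fitted on
#'   FOV pixels when a mask is given, on all pixels otherwise.
#' @param truth Optional ground-truth vessel mask; when given, metrics are
#'   computed.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for outputs (`vessels.png` plus
#'   intermediates when `save_intermediates`).
#' @return A list of class `segmentation_result`: `mask` (final binary
#'   vessel mask), `metrics` (or `NULL`), `stages` (provenance: names of
#'   executed stages in order) and the per-stage intermediates
#'   `bias_field`, `corrected`, `enhanced`, `opened_mask`, `distance`,
#'   `em_mask`, `em_fit`.
#' @export
run_pipeline <- function(image, fov = NULL, truth = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  img <- as_image(image)
  gray <- select_channel(img, config$channel)
  h <- nrow(gray); w <- ncol(gray)
  if (!is.null(fov)) {
    fov <- as_mask(fov)
    stopifnot_same_dim(gray, fov, "fov mask")
  }
  if (!is.null(truth)) {
    truth <- as_mask(truth)
    stopifnot_same_dim(gray, truth, "truth mask")
  }
  stages <- character(0)

  n4 <- run_n4(gray, fov = fov, config = config$bias)
  stages <- c(stages, "bias_correction")
  fov_eff <- if (is.null(fov)) matrix(TRUE, h, w) else fov

  # rescale to [0, 255] within the FOV and invert so vessels are bright
  cv <- n4$corrected
  rng <- range(cv[fov_eff])
  inv <- matrix(0, h, w)
  if (diff(rng) > 0) {
    inv[fov_eff] <- 255 - 255 * (cv[fov_eff] - rng[1]) / diff(rng)
  }
  stages <- c(stages, "invert_rescale")

  enhanced <- adaptive_hist_eq(inv, config$enhancement)
  enhanced[!fov_eff] <- 0
  stages <- c(stages, "adaptive_hist_eq")

  opened <- binarize_and_open(enhanced, config$enhancement)
  opened <- opened & fov_eff
  stages <- c(stages, "binarize_open")

  dmap <- distance_map(opened)
  stages <- c(stages, "distance_map")

  vals <- as.numeric(dmap)[as.logical(fov_eff)]
  fit <- fit_em(vals, k = 2, init = config$em$init, tol = config$em$tol,
                max_iter = config$em$max_iter, seed = config$em$seed)
  vessel_k <- which.max(fit$params$means[, 1])
  em_mask <- matrix(FALSE, h, w)
  em_mask[fov_eff] <- fit$responsibilities[, vessel_k] >= 0.5
  stages <- c(stages, "em_classification")

  min_size <- config$length_filter$min_size
  if (isTRUE(config$length_filter$scale_with_area)) {
    min_size <- scaled_min_size(h, w, base = min_size)
  }
  mask <- filter_by_size(label_components(em_mask), min_size)
  stages <- c(stages, "length_filter")

  metrics <- if (!is.null(truth)) compute_metrics(mask, truth, fov_eff)

  res <- structure(list(mask = mask, metrics = metrics, stages = stages,
                        bias_field = n4$bias, corrected = n4$corrected,
                        enhanced = enhanced, opened_mask = opened,
                        distance = dmap, em_mask = em_mask, em_fit = fit,
                        min_size = min_size),
                   class = "segmentation_result")
  if (!is.null(out_dir)) save_pipeline_outputs(res, out_dir, config)
  res
}

save_pipeline_outputs <- function(res, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_image(res$mask, file.path(out_dir, "vessels.png"))
  if (!is.null(res$metrics)) {
    metrics_to_json(res$metrics, file.path(out_dir, "metrics.json"))
  }
  if (isTRUE(config$save_intermediates)) {
    tf <- res$bias_field$total_field
    write_image(255 * (tf - min(tf)) / max(diff(range(tf)), 1e-12),
                file.path(out_dir, "bias_field.png"))
    write_image(res$corrected, file.path(out_dir, "corrected.png"))
    write_image(res$enhanced, file.path(out_dir, "enhanced.png"))
    write_image(res$opened_mask, file.path(out_dir, "opened.png"))
    d <- unclass(res$distance)
    write_image(255 * d / max(d, 1), file.path(out_dir, "distance.png"))
    write_image(res$em_mask, file.path(out_dir, "em_mask.png"))
    em_fit_to_json(res$em_fit, file.path(out_dir, "em_fit.json"))
  }
  invisible(out_dir)
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("vessel segmentation:", sum(x$mask), "vessel pixels,",
      length(x$stages), "stages:", paste(x$stages, collapse = " -> "), "\n")
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}
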