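#!/usr/bin/env Rscript
# OPTIONAL benchmark harness (not part of acceptance): given locally
# supplied DRIVE- or STARE-style directories, runs the pipeline on every
# image and prints per-image TPR / FPR / accuracy plus the averages, in the
# layout used for dataset comparisons.
#
# Expected layout (images converted to PNG or PPM beforehand; GIF masks
# from DRIVE must be converted, e.g. `convert mask.gif mask.png`):
#   --images DIR   fundus images
#   --truth  DIR   first-expert vessel masks, matching file order
#   --fov    DIR   FOV masks (optional; derived by channel thresholding
#                  from the RGB image when omitted)
#
# Usage:
#   Rscript scripts/benchmark_datasets.R --images d/img --truth d/gt \
#       [--fov d/mask] [--config cfg.yaml]

suppressPackageStartupMessages({
  library(optparse)
  library(retvessel)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--images", type = "character"),
  make_option("--truth", type = "character"),
  make_option("--fov", type = "character", default = NULL),
  make_option("--config", type = "character", default = NULL))))

if (is.null(opts$images) || is.null(opts$truth)) {
  stop("--images and --truth directories are required")
}
cfg <- if (is.null(opts$config)) pipeline_config()
       else read_pipeline_config(opts$config)

list_imgs <- function(d) sort(list.files(d, "\\.(png|ppm|pgm)$",
                                         full.names = TRUE))
imgs <- list_imgs(opts$images)
gts <- list_imgs(opts$truth)
stopifnot(length(imgs) == length(gts), length(imgs) > 0)
fovs <- if (!is.null(opts$fov)) list_imgs(opts$fov)

cat(sprintf("%-28s %8s %8s %8s\n", "Image", "TPR", "FPR", "Accuracy"))
acc <- tpr <- fpr <- numeric(length(imgs))
for (i in seq_along(imgs)) {
  img <- read_image(imgs[i])
  fov <- if (!is.null(fovs)) fovs[i] else fov_mask_from_rgb(img)
  res <- run_pipeline(img, fov = fov, truth = gts[i], config = cfg)
  m <- res$metrics
  tpr[i] <- m$tpr; fpr[i] <- m$fpr; acc[i] <- m$accuracy
  cat(sprintf("%-28s %8.4f %8.4f %8.4f\n", basename(imgs[i]),
              m$tpr, m$fpr, m$accuracy))
}
cat(sprintf("%-28s %8.4f %8.4f %8.4f\n", "Average",
            mean(tpr), mean(fpr), mean(acc)))
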