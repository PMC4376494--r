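# Seeded synthetic fundus phantoms: tree-structured dark vessels with
# Gaussian cross-section profiles on a bright background, a smooth
# multiplicative bias field (band-limited cosine surface), additive
# Gaussian noise, and a circular field-of-view aperture. Every artifact is
# deterministic given the spec's seed and the generating bias field and
# clean image are returned so correction and segmentation stages have
# their oracles.

#' Phantom specification
#'
#' @param width,height Image size in pixels.
#' @param n_trees Number of vessel trees seeded on the aperture rim.
#' @param branch_prob Per-step probability that a walking vessel spawns a
#'   branch.
#' @param width_root Root vessel half-width in pixels.
#' @param width_decay Child/parent half-width ratio at a branch, in (0, 1].
#' @param vessel_contrast Intensity dip depth at a vessel centreline, as a
#'   fraction of the background level.
#' @param profile_sigma_factor Gaussian cross-section sigma as a fraction
#'   of the local half-width.
#' @param bias_amplitude Range (max - min, in log units) of the
#'   multiplicative bias field inside the aperture.
#' @param noise_sigma Additive Gaussian noise standard deviation
#'   (intensity units on the 0-255 scale).
#' @param aperture_radius FOV disk radius in pixels.
#' @param background_level Background intensity inside the aperture.
#' @param seed Integer seed; all generated artifacts are deterministic
#'   given it.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 512, height = 512, n_trees = 4,
                         branch_prob = 0.08, width_root = 4,
                         width_decay = 0.8, vessel_contrast = 0.35,
                         profile_sigma_factor = 0.85, bias_amplitude = 0.5,
                         noise_sigma = 4, aperture_radius = 240,
                         background_level = 170, seed = 1L) {
  spec <- list(width = width, height = height, n_trees = n_trees,
               branch_prob = branch_prob, width_root = width_root,
               width_decay = width_decay, vessel_contrast = vessel_contrast,
               profile_sigma_factor = profile_sigma_factor,
               bias_amplitude = bias_amplitude, noise_sigma = noise_sigma,
               aperture_radius = aperture_radius,
               background_level = background_level, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  if (spec$width < 8 || spec$height < 8 || spec$aperture_radius <= 0) {
    stop("phantom dimensions must be positive", call. = FALSE)
  }
  if (spec$width_root > spec$aperture_radius) {
    stop("width_root exceeds aperture_radius: no vessel fits the aperture",
         call. = FALSE)
  }
  if (spec$branch_prob < 0 || spec$branch_prob > 1) {
    stop("branch_prob must be in [0, 1]", call. = FALSE)
  }
  if (spec$width_decay <= 0 || spec$width_decay > 1) {
    stop("width_decay must be in (0, 1]", call. = FALSE)
  }
  if (spec$vessel_contrast < 0 || spec$vessel_contrast > 1) {
    stop("vessel_contrast must be in [0, 1]", call. = FALSE)
  }
  invisible(spec)
}

aperture_mask <- function(spec) {
  cx <- (spec$width + 1) / 2; cy <- (spec$height + 1) / 2
  dy2 <- (seq_len(spec$height) - cy)^2
  dx2 <- (seq_len(spec$width) - cx)^2
  outer(dy2, dx2, "+") <= spec$aperture_radius^2
}

#' Grow a random vessel tree with ground truth
#'
#' Seeds `n_trees` random branching walks on the aperture rim, each heading
#' inward with small random turns, slow tapering, and random branching
#' (child half-width = `width_decay` times the parent's). The truth mask
#' marks every pixel within the local half-width of a centreline. If the
#' vessel pixel fraction of the aperture falls outside \[0.05, 0.18\] the
#' tree is regenerated with a perturbed seed (the realized seed is
#' recorded in the result).
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `vessel_tree` with `truth_mask` (logical),
#'   `centerlines` (data.frame of `x`, `y`, `halfwidth`, `tree`),
#'   `vessel_fraction`, and `seed_used`.
#' @export
generate_vessel_tree <- function(spec) {
  validate_phantom_spec(spec)
  ap <- aperture_mask(spec)
  ap_area <- sum(ap)
  for (attempt in 0:24) {
    seed_used <- spec$seed + 7919L * attempt
    res <- with_seed(seed_used, grow_trees(spec, ap))
    frac <- sum(res$truth_mask & ap) / ap_area
    if (spec$n_trees == 0 || (frac >= 0.05 && frac <= 0.18)) {
      return(structure(list(truth_mask = res$truth_mask,
                            centerlines = res$centerlines,
                            vessel_fraction = frac,
                            seed_used = seed_used),
                       class = "vessel_tree"))
    }
  }
  stop("could not generate a vessel tree with aperture coverage in ",
       "[0.05, 0.18]; the phantom spec appears unsatisfiable",
       call. = FALSE)
}

grow_trees <- function(spec, ap) {
  H <- spec$height; W <- spec$width
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  R <- spec$aperture_radius
  truth <- matrix(FALSE, H, W)
  pts <- list()
  if (spec$n_trees > 0) {
    # centreline budget per tree targeting ~11% aperture coverage: mean
    # stroke width along a tapering tree is about 1.2 x the root half-width
    budget_per_tree <- 0.11 * sum(ap) / (spec$n_trees * 1.2 * spec$width_root)
    angles <- runif(spec$n_trees, 0, 2 * pi)
    for (tree in seq_len(spec$n_trees)) {
      a0 <- angles[tree]
      start <- c(cx + (R - 2) * cos(a0), cy + (R - 2) * sin(a0))
      # head inward with jitter
      queue <- list(list(x = start[1], y = start[2],
                         dir = a0 + pi + rnorm(1, 0, 0.3),
                         w = spec$width_root))
      length_left <- budget_per_tree
      while (length(queue) > 0 && length_left > 0) {
        seg <- queue[[1]]; queue[[1]] <- NULL
        x <- seg$x; y <- seg$y; dir <- seg$dir; w <- seg$w
        while (w >= 0.7 && length_left > 0) {
          length_left <- length_left - 1
          dir <- dir + rnorm(1, 0, 0.12)
          # steer back toward the centre near the rim
          dcen <- sqrt((x - cx)^2 + (y - cy)^2)
          if (dcen > 0.85 * R) {
            toc <- atan2(cy - y, cx - x)
            dir <- dir + 0.15 * sin(toc - dir)
          }
          x <- x + cos(dir); y <- y + sin(dir)
          if (sqrt((x - cx)^2 + (y - cy)^2) > R - 1) break
          pts[[length(pts) + 1]] <- c(x, y, w, tree)
          w <- w * 0.9985  # slow taper along the run
          if (runif(1) < spec$branch_prob) {
            side <- sample(c(-1, 1), 1)
            queue[[length(queue) + 1]] <-
              list(x = x, y = y, dir = dir + side * runif(1, 0.35, 0.9),
                   w = w * spec$width_decay)
            dir <- dir - side * runif(1, 0.05, 0.25)
          }
        }
      }
    }
  }
  if (length(pts) > 0) {
    cl <- do.call(rbind, pts)
    centerlines <- data.frame(x = cl[, 1], y = cl[, 2], halfwidth = cl[, 3],
                              tree = as.integer(cl[, 4]))
    truth <- stamp_disks(truth, centerlines, ap)
  } else {
    centerlines <- data.frame(x = numeric(0), y = numeric(0),
                              halfwidth = numeric(0), tree = integer(0))
  }
  list(truth_mask = truth & ap, centerlines = centerlines)
}

# Mark every pixel within `halfwidth` of a centreline point.
stamp_disks <- function(truth, centerlines, ap) {
  H <- nrow(truth); W <- ncol(truth)
  offsets <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(centerlines))) {
    w <- centerlines$halfwidth[i]
    key <- sprintf("%.1f", w)
    off <- offsets[[key]]
    if (is.null(off)) {
      r <- ceiling(w)
      g <- expand.grid(dy = -r:r, dx = -r:r)
      keep <- g$dy^2 + g$dx^2 <= w^2
      off <- cbind(g$dy[keep], g$dx[keep])
      offsets[[key]] <- off
    }
    yy <- round(centerlines$y[i]) + off[, 1]
    xx <- round(centerlines$x[i]) + off[, 2]
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    truth[cbind(yy[ok], xx[ok])] <- TRUE
  }
  truth
}

#' Render a fundus-style image from a vessel tree
#'
#' The clean green channel is `background_level * (1 - vessel_contrast *
#' dip)` where the dip profile is Gaussian across each vessel
#' (sigma = `profile_sigma_factor` x local half-width, full depth at the
#' centreline). The clean image is multiplied by `exp(bias_truth)` — a
#' band-limited random cosine surface with at most 2 cycles per image,
#' rescaled to `bias_amplitude` log units of range inside the aperture —
#' then Gaussian noise is added, the result is clipped to \[0, 255\] and
#' zeroed outside the aperture. Red and blue channels carry reduced vessel
#' contrast so the green channel is the informative one.
#'
#' @param tree A [generate_vessel_tree()] result.
#' @param spec The same [phantom_spec()].
#' @return A list of class `fundus_phantom`: `image` (`H x W x 3`),
#'   `green` (noisy biased green channel), `clean` (uncorrupted green
#'   channel), `bias_truth` (log-domain field), `fov`, `truth_mask`,
#'   `spec`.
#' @export
render_fundus <- function(tree, spec) {
  H <- spec$height; W <- spec$width
  ap <- aperture_mask(spec)
  dip <- gaussian_dip_profile(tree$centerlines, H, W, spec)
  B <- spec$background_level
  clean <- B * (1 - spec$vessel_contrast * dip)
  clean[!ap] <- 0

  with_seed(spec$seed + 104729L, {
    g <- cosine_bias_surface(H, W, ap, spec$bias_amplitude)
    mk_channel <- function(base, contrast_scale) {
      ch <- base * (1 - contrast_scale * spec$vessel_contrast * dip)
      ch <- ch * exp(g)
      if (spec$noise_sigma > 0) ch <- ch + rnorm(H * W, 0, spec$noise_sigma)
      ch <- pmin(pmax(ch, 0), 255)
      ch[!ap] <- 0
      ch
    }
    green <- mk_channel(B, 1)
    red <- mk_channel(min(B * 1.05, 240), 0.5)
    blue <- mk_channel(B * 0.45, 0.2)
    img <- array(0, dim = c(H, W, 3))
    img[, , 1] <- red; img[, , 2] <- green; img[, , 3] <- blue
    structure(list(image = img, green = green, clean = clean,
                   bias_truth = g, fov = ap, truth_mask = tree$truth_mask,
                   spec = spec),
              class = "fundus_phantom")
  })
}

# Max-combined Gaussian cross-section dips stamped along the centrelines.
gaussian_dip_profile <- function(centerlines, H, W, spec) {
  dip <- matrix(0, H, W)
  if (nrow(centerlines) == 0 || spec$vessel_contrast == 0) return(dip)
  for (i in seq_len(nrow(centerlines))) {
    sgm <- max(spec$profile_sigma_factor * centerlines$halfwidth[i], 0.5)
    r <- ceiling(3 * sgm)
    y0 <- round(centerlines$y[i]); x0 <- round(centerlines$x[i])
    ys <- max(1, y0 - r):min(H, y0 + r)
    xs <- max(1, x0 - r):min(W, x0 + r)
    d2 <- outer((ys - centerlines$y[i])^2, (xs - centerlines$x[i])^2, "+")
    patch <- exp(-d2 / (2 * sgm^2))
    dip[ys, xs] <- pmax(dip[ys, xs], patch)
  }
  dip
}

# Smooth band-limited random surface: sum of cosine plane waves with at
# most 2 cycles per image, centred and rescaled to the requested range
# inside the aperture.
cosine_bias_surface <- function(H, W, ap, amplitude) {
  if (amplitude <= 0) return(matrix(0, H, W))
  g <- matrix(0, H, W)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (j in 1:6) {
    freq <- runif(1, 0.3, 2)
    th <- runif(1, 0, 2 * pi)
    ph <- runif(1, 0, 2 * pi)
    amp <- runif(1, 0.4, 1)
    g <- g + amp * cos(2 * pi * freq *
                         (cos(th) * xx / W + sin(th) * yy / H) + ph)
  }
  gv <- g[ap]
  g <- (g - mean(gv)) * (amplitude / (max(gv) - min(gv)))
  g
}

#' Generate a complete phantom (tree + rendering)
#'
#' @param spec A [phantom_spec()].
#' @return A `fundus_phantom` (see [render_fundus()]) with the
#'   `vessel_tree` attached as `$tree`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  tree <- generate_vessel_tree(spec)
  ph <- render_fundus(tree, spec)
  ph$tree <- tree
  ph
}
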