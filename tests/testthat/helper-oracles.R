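# Independent brute-force oracles. These deliberately share no code with
# the package internals: nested loops, exhaustive searches and explicit
# normal equations only.

# Windowed rank transform by explicit double loop with reflection padding.
oracle_ahe <- function(im, h, r) {
  H <- nrow(im); W <- ncol(im); k <- h %/% 2
  refl <- function(i, n) {
    if (n == 1) return(1)
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- matrix(0, H, W)
  for (y in 1:H) {
    for (x in 1:W) {
      cnt <- 0
      for (dy in -k:k) {
        for (dx in -k:k) {
          if (im[y, x] - im[refl(y + dy, H), refl(x + dx, W)] > 0) {
            cnt <- cnt + 1
          }
        }
      }
      out[y, x] <- 255 * (cnt / h^2)^r
    }
  }
  out
}

# Brute-force min/max morphology over a disk footprint (outside = FALSE).
oracle_morph <- function(mask, radius, dilate) {
  H <- nrow(mask); W <- ncol(mask)
  r <- floor(radius)
  out <- matrix(NA, H, W)
  for (y in 1:H) {
    for (x in 1:W) {
      v <- !dilate
      for (dy in -r:r) {
        for (dx in -r:r) {
          if (dy^2 + dx^2 > radius^2) next
          yy <- y + dy; xx <- x + dx
          p <- if (yy >= 1 && yy <= H && xx >= 1 && xx <= W) mask[yy, xx]
               else FALSE
          if (dilate && p) v <- TRUE
          if (!dilate && !p) v <- FALSE
        }
      }
      out[y, x] <- v
    }
  }
  out
}

oracle_open <- function(mask, radius) {
  oracle_morph(oracle_morph(mask, radius, dilate = FALSE), radius,
               dilate = TRUE)
}

# Exhaustive nearest-background Euclidean distance.
oracle_edt <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, H, W)
  for (y in 1:H) {
    for (x in 1:W) {
      if (mask[y, x]) {
        out[y, x] <- sqrt(min((bg[, 1] - y)^2 + (bg[, 2] - x)^2))
      }
    }
  }
  out
}

# Recursive-style flood fill (explicit stack) over the 8-neighbourhood.
oracle_flood_labels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (x0 in 1:W) {
    for (y0 in 1:H) {
      if (!mask[y0, x0] || lab[y0, x0] != 0) next
      nxt <- nxt + 1L
      stack <- list(c(y0, x0))
      lab[y0, x0] <- nxt
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dy in -1:1) {
          for (dx in -1:1) {
            yy <- p[1] + dy; xx <- p[2] + dx
            if (yy >= 1 && yy <= H && xx >= 1 && xx <= W &&
                mask[yy, xx] && lab[yy, xx] == 0) {
              lab[yy, xx] <- nxt
              stack[[length(stack) + 1]] <- c(yy, xx)
            }
          }
        }
      }
    }
  }
  lab
}

# Direct per-point 1-D Gaussian mixture log-likelihood.
oracle_loglik_1d <- function(x, mu, sigma2, pi_k) {
  tot <- 0
  for (xi in x) {
    dens <- 0
    for (k in seq_along(mu)) {
      dens <- dens + pi_k[k] *
        exp(-(xi - mu[k])^2 / (2 * sigma2[k])) / sqrt(2 * pi * sigma2[k])
    }
    tot <- tot + log(dens)
  }
  tot
}

# Direct Bayes-ratio responsibilities, 1-D.
oracle_estep_1d <- function(x, mu, sigma2, pi_k) {
  K <- length(mu)
  g <- matrix(0, length(x), K)
  for (i in seq_along(x)) {
    num <- sapply(seq_len(K), function(k) {
      pi_k[k] * exp(-(x[i] - mu[k])^2 / (2 * sigma2[k])) /
        sqrt(2 * pi * sigma2[k])
    })
    g[i, ] <- num / sum(num)
  }
  g
}

# Direct weighted-moment M-step, 1-D.
oracle_mstep_1d <- function(x, gamma) {
  K <- ncol(gamma)
  Nk <- colSums(gamma)
  mu <- sapply(seq_len(K), function(k) sum(gamma[, k] * x) / Nk[k])
  s2 <- sapply(seq_len(K), function(k) {
    sum(gamma[, k] * (x - mu[k])^2) / Nk[k]
  })
  list(mu = mu, sigma2 = s2, pi = Nk / length(x))
}

# Explicit tensor-product cubic B-spline least squares (normal equations on
# the full Kronecker design), small fields only.
oracle_bspline_fit <- function(field, spacing) {
  basis1 <- function(n) {
    nseg <- max(1L, as.integer(ceiling((n - 1) / spacing)))
    step <- (n - 1) / nseg
    splines::splineDesign(1 + step * seq(-3, nseg + 3), seq_len(n), ord = 4)
  }
  By <- basis1(nrow(field)); Bx <- basis1(ncol(field))
  Bfull <- kronecker(Bx, By)  # vec(F) = Bfull %*% vec(C)
  coef <- qr.solve(crossprod(Bfull), crossprod(Bfull, as.numeric(field)))
  matrix(Bfull %*% coef, nrow(field), ncol(field))
}

# Two-tissue bias phantom (values 50 / 150 under a smooth exp field).
make_two_tissue <- function(H = 128, W = 128, range_log = 0.6) {
  tissue <- matrix(50, H, W)
  tissue[round(H * 0.3):round(H * 0.7), round(W * 0.25):round(W * 0.8)] <- 150
  g <- outer(seq(0, 1, length.out = H), seq(0, 1, length.out = W),
             function(a, b) cos(2 * pi * 0.7 * a) +
               sin(2 * pi * (0.5 * b + 0.3 * a)))
  g <- (g - mean(g)) * (range_log / diff(range(g)))
  list(clean = tissue, field = g, image = tissue * exp(g))
}

# A small phantom spec that keeps test-suite runtime low.
small_phantom_spec <- function(seed = 1, n_trees = 3, width_root = 3, ...) {
  phantom_spec(width = 192, height = 192, aperture_radius = 88,
               width_root = width_root, n_trees = n_trees, seed = seed, ...)
}

# Shared discrete histogram entropy (base-2, over occupied bins).
hist_entropy <- function(x, nbins = 64) {
  p <- tabulate(cut(x, nbins, labels = FALSE), nbins)
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}
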