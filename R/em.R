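# Two-component Gaussian mixture fitted by expectation maximisation.
# Pixels of the distance map are the data; the component with the larger
# mean is taken as the vessel class. All densities are evaluated in log
# space with log-sum-exp, so exact-zero distance plateaus cannot underflow
# responsibilities to NaN. The code is written for general dimension D
# (covariances are D x D per component) although the pipeline uses D = 1.

#' Construct and validate mixture parameters
#'
#' @param means `K x D` matrix (or length-K vector for D = 1) of component
#'   means.
#' @param covariances `K x D x D` array (or length-K vector of variances
#'   for D = 1); each slice must be symmetric positive-definite.
#' @param mixing Length-K vector of mixing coefficients; non-negative,
#'   summing to 1.
#' @return A list of class `mixture_parameters` with `K`, `D`, `means`,
#'   `covariances`, `mixing`.
#' @export
mixture_parameters <- function(means, covariances, mixing) {
  if (is.null(dim(means))) means <- matrix(means, ncol = 1)
  K <- nrow(means); D <- ncol(means)
  if (is.null(dim(covariances))) {
    covariances <- array(covariances, dim = c(K, 1, 1))
  }
  if (!all(dim(covariances) == c(K, D, D))) {
    stop("covariances must be a K x D x D array", call. = FALSE)
  }
  if (length(mixing) != K || any(mixing < 0) || any(mixing > 1)) {
    stop("mixing must be K probabilities in [0, 1]", call. = FALSE)
  }
  if (abs(sum(mixing) - 1) > 1e-8) {
    stop("mixing coefficients must sum to 1", call. = FALSE)
  }
  for (k in seq_len(K)) {
    S <- matrix(covariances[k, , ], D, D)
    if (any(abs(S - t(S)) > 1e-10) || any(eigen(S, TRUE)$values <= 0)) {
      stop("covariance of component ", k,
           " is not symmetric positive-definite", call. = FALSE)
    }
  }
  structure(list(K = K, D = D, means = means, covariances = covariances,
                 mixing = mixing / sum(mixing)),
            class = "mixture_parameters")
}

# Vectors and distance maps become an M x 1 feature column; a plain matrix
# is taken as an already-assembled M x D feature matrix.
as_pixel_matrix <- function(data) {
  if (inherits(data, "distance_map")) data <- as.numeric(data)
  if (is.null(dim(data))) data <- matrix(as.numeric(data), ncol = 1)
  if (!all(is.finite(data))) stop("data contains non-finite values",
                                  call. = FALSE)
  data
}

# M x K matrix of log(pi_k) + log N(x_i | mu_k, Sigma_k)
log_component_densities <- function(X, params) {
  M <- nrow(X); K <- params$K; D <- params$D
  out <- matrix(0, M, K)
  for (k in seq_len(K)) {
    S <- matrix(params$covariances[k, , ], D, D)
    ch <- tryCatch(chol(S), error = function(e)
      stop("covariance of component ", k, " is numerically singular",
           call. = FALSE))
    logdet <- 2 * sum(log(diag(ch)))
    ctr <- sweep(X, 2, params$means[k, ], "-")
    # Mahalanobis via triangular solve
    z <- backsolve(ch, t(ctr), transpose = TRUE)
    maha <- colSums(z^2)
    out[, k] <- log(params$mixing[k]) -
      0.5 * (D * log(2 * pi) + logdet + maha)
  }
  out
}

log_sum_exp_rows <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), list(-Inf)))
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

#' Mixture log-likelihood
#'
#' `sum_i log sum_k pi_k N(x_i | mu_k, Sigma_k)`, evaluated in log space.
#'
#' @param data Numeric vector, `M x D` matrix, or distance map.
#' @param params A [mixture_parameters()] object.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(data, params) {
  X <- as_pixel_matrix(data)
  sum(log_sum_exp_rows(log_component_densities(X, params)))
}

#' E-step: posterior responsibilities
#'
#' Computes the responsibility matrix by Bayes' theorem,
#' `gamma_ik = pi_k N(x_i|mu_k,Sigma_k) / sum_j pi_j N(x_i|mu_j,Sigma_j)`,
#' in log space so that points far from every component still yield a
#' valid (row-stochastic) posterior.
#'
#' @inheritParams log_likelihood
#' @return `M x K` matrix; entries in \[0, 1\], rows summing to 1.
#' @export
e_step <- function(data, params) {
  X <- as_pixel_matrix(data)
  lg <- log_component_densities(X, params)
  exp(lg - log_sum_exp_rows(lg))
}

#' M-step: maximum-likelihood parameter update
#'
#' Weighted-moment updates: `mu_k = sum_i gamma_ik x_i / N_k`,
#' `Sigma_k = sum_i gamma_ik (x_i - mu_k)(x_i - mu_k)' / N_k`, and
#' `pi_k = N_k / M` with `N_k = sum_i gamma_ik`. Variances are floored at
#' `var_floor_frac` times the global per-dimension variance so that
#' constant plateaus (the zero background of a distance map) cannot
#' collapse a component.
#'
#' @param data Numeric vector, matrix or distance map.
#' @param resp `M x K` responsibility matrix.
#' @param var_floor_frac Fraction of the global variance used as the
#'   variance floor.
#' @return A [mixture_parameters()] object.
#' @export
m_step <- function(data, resp, var_floor_frac = 1e-6) {
  X <- as_pixel_matrix(data)
  M <- nrow(X); D <- ncol(X); K <- ncol(resp)
  Nk <- colSums(resp)
  gvar <- apply(X, 2, function(col) max(var(col), .Machine$double.eps))
  floorv <- var_floor_frac * gvar
  means <- matrix(0, K, D)
  covs <- array(0, dim = c(K, D, D))
  empty <- which(Nk <= 0)
  if (length(empty) > 0) {
    # reinitialize the component in place from the point the mixture
    # explains worst (largest squared deviation from the grand mean, a
    # density-free proxy); its mixing weight Nk/M stays 0
    warning("empty mixture component reinitialized from the worst-fit point")
    dev <- rowSums(sweep(X, 2, colMeans(X))^2)
  }
  for (k in seq_len(K)) {
    if (k %in% empty) {
      idx <- which.max(dev)
      dev[idx] <- -Inf
      means[k, ] <- X[idx, ]
      covs[k, , ] <- diag(gvar, D)
      next
    }
    w <- resp[, k]
    means[k, ] <- colSums(X * w) / Nk[k]
    ctr <- sweep(X, 2, means[k, ], "-")
    S <- crossprod(ctr * sqrt(w)) / Nk[k]
    diag(S) <- pmax(diag(S), floorv)
    covs[k, , ] <- S
  }
  mixing <- pmax(Nk, 0) / M
  mixture_parameters(means, covs, mixing / sum(mixing))
}

#' Fit a Gaussian mixture by EM
#'
#' Starts from a deterministic two-quantile initialization (or a seeded
#' k-means partition) and alternates [e_step()] and [m_step()] until the
#' relative change of the log-likelihood falls below `tol` or `max_iter`
#' is reached. Every update is guaranteed not to decrease the
#' log-likelihood; the returned trace records it per iteration.
#'
#' @param data Numeric vector, `M x D` matrix, or distance map.
#' @param k Number of components (>= 1).
#' @param init `"quantile"` (means at the 25th/90th percentiles, equal
#'   variances, equal mixing — deterministic) or `"kmeans"` (seeded).
#' @param tol Relative log-likelihood change at convergence.
#' @param max_iter Iteration cap.
#' @param seed Integer seed used by the `"kmeans"` initializer.
#' @return A list of class `em_fit` with `params`, `responsibilities`,
#'   `log_likelihood_trace`, `n_iterations`, `converged`.
#' @export
fit_em <- function(data, k = 2, init = c("quantile", "kmeans"),
                   tol = 1e-6, max_iter = 200, seed = 1L) {
  init <- match.arg(init)
  X <- as_pixel_matrix(data)
  M <- nrow(X); D <- ncol(X)
  if (M < k) stop("need at least k = ", k, " data points (got ", M, ")",
                  call. = FALSE)
  params <- em_initialize(X, k, init, seed)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0
  resp <- NULL
  while (iter < max_iter) {
    iter <- iter + 1
    resp <- e_step(X, params)
    params <- m_step(X, resp)
    ll <- log_likelihood(X, params)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  resp <- e_step(X, params)
  structure(list(params = params, responsibilities = resp,
                 log_likelihood_trace = trace, n_iterations = iter,
                 converged = converged),
            class = "em_fit")
}

em_initialize <- function(X, k, init, seed) {
  D <- ncol(X)
  gvar <- apply(X, 2, function(col) max(var(col), .Machine$double.eps))
  covs <- array(0, dim = c(k, D, D))
  for (j in seq_len(k)) covs[j, , ] <- diag(gvar, D)
  if (init == "kmeans" && k > 1) {
    means <- with_seed(seed, {
      km <- kmeans(X, centers = k, nstart = 3)
      km$centers
    })
  } else if (k == 1) {
    means <- matrix(colMeans(X), 1, D)
  } else {
    # quantile ladder; for k = 2 this is the 25th / 90th percentile pair,
    # matched to a bimodal distance map with a heavy zero plateau
    probs <- if (k == 2) c(0.25, 0.90) else seq(0.1, 0.9, length.out = k)
    means <- apply(X, 2, quantile, probs = probs, names = FALSE)
    means <- matrix(means, k, D)
    if (any(duplicated(means))) {
      # degenerate quantiles (e.g. mostly-constant data): spread by sd
      means <- means + outer(seq_len(k) - (k + 1) / 2, sqrt(gvar))
    }
  }
  mixture_parameters(means, covs, rep(1 / k, k))
}

#' Classify pixels from a fitted two-component mixture
#'
#' The vessel component is the one with the larger mean (first feature):
#' vessels carry positive distance-map values while pruned background is
#' exactly 0. A pixel is labelled vessel when its responsibility for that
#' component is >= 0.5 (ties go to vessel).
#'
#' @param resp `M x K` responsibility matrix (or an `em_fit`).
#' @param params A [mixture_parameters()] object (ignored when `resp` is an
#'   `em_fit`).
#' @param shape `c(height, width)` used to reshape the labels.
#' @return Logical matrix of dimension `shape`.
#' @export
classify_vessels <- function(resp, params = NULL, shape) {
  if (inherits(resp, "em_fit")) {
    params <- resp$params
    resp <- resp$responsibilities
  }
  if (is.null(params) || params$K != 2) {
    stop("vessel classification requires exactly K = 2 components",
         call. = FALSE)
  }
  vessel_k <- which.max(params$means[, 1])
  lab <- resp[, vessel_k] >= 0.5
  if (length(lab) != prod(shape)) {
    stop("shape does not match the number of classified pixels",
         call. = FALSE)
  }
  matrix(lab, nrow = shape[1], ncol = shape[2])
}

#' Serialize fitted mixture parameters to JSON
#'
#' @param fit An `em_fit` object.
#' @param path Optional output path.
#' @return JSON string (invisibly when written).
#' @export
em_fit_to_json <- function(fit, path = NULL) {
  obj <- list(K = fit$params$K,
              means = fit$params$means,
              covariances = fit$params$covariances,
              mixing = fit$params$mixing,
              log_likelihood_trace = fit$log_likelihood_trace,
              n_iterations = fit$n_iterations,
              converged = fit$converged)
  s <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

# Run code under a temporary RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
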