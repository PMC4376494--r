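test_that("log_likelihood matches closed forms and the direct oracle", {
  set.seed(3)
  x <- rnorm(50, 2, 1.5)
  p1 <- mixture_parameters(means = 2.2, covariances = 1.3, mixing = 1)
  closed <- -length(x) / 2 * log(2 * pi * 1.3) -
    sum((x - 2.2)^2) / (2 * 1.3)
  expect_equal(log_likelihood(x, p1), closed, tolerance = 1e-10)

  # duplicating a component with split mixing leaves the value unchanged
  p2 <- mixture_parameters(means = c(2.2, 2.2), covariances = c(1.3, 1.3),
                           mixing = c(0.5, 0.5))
  expect_equal(log_likelihood(x, p2), log_likelihood(x, p1),
               tolerance = 1e-10)

  # 5 hand-listed points vs term-by-term oracle
  pts <- c(-1.2, 0.0, 0.7, 2.5, 4.1)
  mu <- c(0, 3); s2 <- c(0.8, 1.5); pk <- c(0.35, 0.65)
  p3 <- mixture_parameters(mu, s2, pk)
  expect_equal(log_likelihood(pts, p3), oracle_loglik_1d(pts, mu, s2, pk),
               tolerance = 1e-10)
})

test_that("e_step is the Bayes posterior", {
  x <- c(0, 1, 2, 3)
  same <- mixture_parameters(c(1, 1), c(0.5, 0.5), c(0.5, 0.5))
  expect_true(all(abs(e_step(x, same) - 0.5) < 1e-12))

  far <- mixture_parameters(c(0, 50), c(1, 1), c(0.5, 0.5))
  g <- e_step(0, far)
  expect_gt(g[1, 1], 1 - 1e-6)

  p <- mixture_parameters(c(0.5, 2.5), c(0.25, 0.25), c(0.4, 0.6))
  expect_equal(e_step(x, p), oracle_estep_1d(x, c(0.5, 2.5), c(0.25, 0.25),
                                             c(0.4, 0.6)),
               tolerance = 1e-12)
  # row-stochastic
  expect_true(all(abs(rowSums(e_step(x, p)) - 1) < 1e-12))

  # extreme outliers must not produce NaN (log-space computation)
  g2 <- e_step(c(0, 1e4), p)
  expect_true(all(is.finite(g2)))
  expect_true(all(abs(rowSums(g2) - 1) < 1e-12))
})

test_that("m_step reproduces the weighted-moment formulas", {
  set.seed(8)
  x <- rnorm(20, 1, 2)

  # all mass on component 1: its moments are the sample moments and the
  # empty component is reinitialized in place with zero weight
  g1 <- cbind(rep(1, 20), rep(0, 20))
  expect_warning(p <- m_step(x, g1), "empty")
  expect_equal(p$means[1, 1], mean(x))
  expect_equal(p$covariances[1, 1, 1], mean((x - mean(x))^2),
               tolerance = 1e-12)
  expect_equal(p$mixing, c(1, 0))
  expect_equal(p$means[2, 1], x[which.max(abs(x - mean(x)))])

  # uniform responsibilities: both components collapse to the sample moments
  gu <- matrix(0.5, 20, 2)
  pu <- m_step(x, gu)
  expect_equal(pu$means[, 1], rep(mean(x), 2))
  expect_equal(pu$mixing, c(0.5, 0.5))

  # random responsibilities vs direct oracle
  raw <- matrix(runif(40), 20, 2)
  g <- raw / rowSums(raw)
  pr <- m_step(x, g)
  orc <- oracle_mstep_1d(x, g)
  expect_equal(pr$means[, 1], orc$mu, tolerance = 1e-12)
  expect_equal(c(pr$covariances[1, 1, 1], pr$covariances[2, 1, 1]),
               orc$sigma2, tolerance = 1e-12)
  expect_equal(pr$mixing, orc$pi, tolerance = 1e-12)
  expect_equal(sum(pr$mixing), 1)
})

test_that("m_step is the exact maximiser of the expected log-likelihood", {
  set.seed(15)
  x <- c(rnorm(200, 0, 1), rnorm(100, 5, 1))
  p0 <- mixture_parameters(c(1, 4), c(2, 2), c(0.5, 0.5))
  g <- e_step(x, p0)
  p <- m_step(x, g)
  # expected complete-data log-likelihood at fixed responsibilities
  q_of <- function(pp) {
    ld <- sapply(1:2, function(k) {
      log(pp$mixing[k]) - 0.5 * (log(2 * pi * pp$covariances[k, 1, 1]) +
        (x - pp$means[k, 1])^2 / pp$covariances[k, 1, 1])
    })
    sum(g * ld)
  }
  base <- q_of(p)
  for (k in 1:2) {
    for (eps in c(-0.01, 0.01)) {
      pp <- p
      pp$means[k, 1] <- pp$means[k, 1] + eps * sqrt(pp$covariances[k, 1, 1])
      expect_lt(q_of(pp), base + 1e-10)
    }
  }
})

test_that("fit_em recovers parameters and keeps the likelihood monotone", {
  set.seed(4)
  x <- rnorm(500, -1, 0.7)
  f1 <- fit_em(x, k = 1)
  expect_equal(f1$params$means[1, 1], mean(x), tolerance = 1e-8)
  expect_equal(f1$params$covariances[1, 1, 1], mean((x - mean(x))^2),
               tolerance = 1e-8)

  gen <- function(seed, n = 10000) {
    set.seed(seed)
    n2 <- rbinom(1, n, 0.3)
    c(rnorm(n - n2, 0.5, 0.4), rnorm(n2, 4.0, 0.8))
  }
  x2 <- gen(1)
  fit <- fit_em(x2, k = 2)
  ord <- order(fit$params$means[, 1])
  mu <- fit$params$means[ord, 1]
  sg <- sqrt(c(fit$params$covariances[ord[1], 1, 1],
               fit$params$covariances[ord[2], 1, 1]))
  pk <- fit$params$mixing[ord]
  expect_lt(max(abs(mu - c(0.5, 4.0)) / c(0.5, 4.0)), 0.05)
  expect_lt(max(abs(sg - c(0.4, 0.8)) / c(0.4, 0.8)), 0.05)
  expect_lt(max(abs(pk - c(0.7, 0.3)) / c(0.7, 0.3)), 0.05)
  expect_true(all(diff(fit$log_likelihood_trace) >= -1e-8))
  expect_true(fit$converged)

  expect_error(fit_em(c(1), k = 2), "at least")
})

test_that("EM is invariant to pixel permutation and deterministic", {
  set.seed(6)
  x <- c(rnorm(300, 0, 0.5), rnorm(200, 3, 0.7))
  perm <- sample(length(x))
  f1 <- fit_em(x, k = 2)
  f2 <- fit_em(x[perm], k = 2)
  expect_equal(f2$params$means, f1$params$means, tolerance = 1e-9)
  expect_equal(f2$params$mixing, f1$params$mixing, tolerance = 1e-9)
  expect_equal(f2$responsibilities[order(perm), ], f1$responsibilities,
               tolerance = 1e-9)
  # bitwise determinism of a rerun
  f3 <- fit_em(x, k = 2)
  expect_identical(f3$params, f1$params)
  # kmeans init is deterministic given the seed
  k1 <- fit_em(x, k = 2, init = "kmeans", seed = 99)
  k2 <- fit_em(x, k = 2, init = "kmeans", seed = 99)
  expect_identical(k1$params, k2$params)
})

test_that("classify_vessels picks the larger-mean component, ties to vessel", {
  p <- mixture_parameters(c(0, 2), c(0.5, 0.5), c(0.5, 0.5))
  resp <- rbind(c(0.1, 0.9), c(0.9, 0.1), c(0.5, 0.5))
  got <- classify_vessels(resp, p, shape = c(3, 1))
  expect_equal(as.logical(got), c(TRUE, FALSE, TRUE))

  p1 <- mixture_parameters(0, 1, 1)
  expect_error(classify_vessels(matrix(1, 3, 1), p1, c(3, 1)), "K = 2")
})

test_that("a drawn band on a distance map is recovered by k = 2 EM", {
  band <- matrix(FALSE, 40, 60); band[15:25, 5:55] <- TRUE
  d <- distance_map(band)
  fit <- fit_em(as.numeric(d), k = 2)
  mask <- classify_vessels(fit, shape = dim(band))
  expect_lt(mean(mask != band), 0.02)
})

test_that("mixture parameter validation rejects bad inputs", {
  expect_error(mixture_parameters(c(0, 1), c(1, 1), c(0.7, 0.7)), "sum to 1")
  expect_error(mixture_parameters(c(0, 1), c(-1, 1), c(0.5, 0.5)),
               "positive-definite")
})
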