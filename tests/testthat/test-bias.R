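test_that("smooth_field reproduces constants and ramps, kills high freq", {
  const <- matrix(3.7, 40, 50)
  expect_equal(smooth_field(const, 16), const, tolerance = 1e-8)

  ramp <- outer(1:48, 1:64, function(a, b) 0.2 * a - 0.05 * b + 2)
  expect_lt(max(abs(smooth_field(ramp, 16) - ramp)) / max(abs(ramp)), 1e-6)

  cb <- outer(1:64, 1:64, function(a, b) (-1)^(a + b))
  expect_lt(max(abs(smooth_field(cb, 32))), 0.05)

  # idempotence at fixed spacing
  set.seed(10)
  f <- matrix(rnorm(64 * 64), 64, 64)
  s1 <- smooth_field(f, 16)
  s2 <- smooth_field(s1, 16)
  expect_lt(sqrt(mean((s2 - s1)^2)) / sqrt(mean(s1^2)), 1e-6)

  expect_error(smooth_field(matrix(0, 8, 8), 9), "exceeds")
  expect_error(smooth_field(matrix(0, 8, 8), 1), ">= 2")
})

test_that("smooth_field agrees with explicit normal-equations least squares", {
  set.seed(19)
  f <- matrix(rnorm(36 * 44), 36, 44) +
    outer(seq(0, 2, length.out = 36), seq(0, 1, length.out = 44))
  got <- smooth_field(f, 12)
  ref <- oracle_bspline_fit(f, 12)
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("expected_true_image sharpens without merging modes", {
  cfg <- n4_config()
  # constant image unchanged
  const <- matrix(1.25, 20, 20)
  expect_equal(expected_true_image(const, cfg), const)

  # two well-separated deltas stay separated, each mapped near its own value
  two <- matrix(rep(c(0, 1), each = 200), 20, 20)
  out <- expected_true_image(two, cfg)
  expect_lt(max(abs(out[two == 0])), 0.2)
  expect_gt(min(out[two == 1]), 0.8)

  # two-Gaussian field: >= 95% of pixels move toward their own mode;
  # cross-checked against a direct deconvolution oracle at 4x resolution
  set.seed(13)
  modes <- rep(c(0, 1), each = 10000)
  v <- rnorm(20000, modes, 0.15)
  got <- expected_true_image(matrix(v, 100, 200), cfg)
  closer <- abs(as.numeric(got) - modes) < abs(v - modes) | v == got
  expect_gte(mean(closer), 0.95)

  # independent oracle: explicit discrete Wiener deconvolution on a 4x grid
  nb <- 4 * cfg$histogram_bins
  rng <- range(v); binw <- diff(rng) / (nb - 1)
  centers <- seq(rng[1], rng[2], length.out = nb)
  hist <- tabulate(pmin(pmax(round((v - rng[1]) / binw) + 1, 1), nb), nb)
  sig <- cfg$sharpening_fwhm / (2 * sqrt(2 * log(2)))
  # explicit circulant convolution matrix on the padded grid
  npd <- 2 * nb
  hp <- c(hist, rep(0, nb))
  offs <- pmin(0:(npd - 1), npd - 0:(npd - 1)) * binw
  kern <- exp(-offs^2 / (2 * sig^2)); kern <- kern / sum(kern)
  FK <- fft(kern)
  sharp <- Re(fft(fft(hp) * Conj(FK) / (Mod(FK)^2 + cfg$wiener_noise),
                  inverse = TRUE)) / npd
  sharp[sharp < 0] <- 0
  sharp <- sharp[1:nb]
  # oracle mapping: blurred conditional mean, computed by direct convolution
  blur <- function(x) {
    out <- numeric(nb)
    half <- min(nb - 1, ceiling(6 * sig / binw))
    w <- exp(-((-half:half) * binw)^2 / (2 * sig^2))
    for (i in 1:nb) {
      j <- (i - half):(i + half)
      ok <- j >= 1 & j <= nb
      out[i] <- sum(x[j[ok]] * w[ok])
    }
    out
  }
  den <- blur(sharp); num <- blur(sharp * centers)
  map_o <- ifelse(den > 1e-12 * max(den), num / den, centers)
  oracle_out <- approx(centers, map_o, xout = v, rule = 2)$y
  closer_o <- abs(oracle_out - modes) < abs(v - modes) | oracle_out == v
  expect_gte(mean(closer_o), 0.95)
  # package mapping and oracle mapping agree closely per pixel
  expect_lt(mean(abs(as.numeric(got) - oracle_out)), 0.02)

  expect_error(expected_true_image(matrix(c(1, Inf, 2, 3), 2, 2)),
               "non-finite")
})

test_that("run_n4 leaves an unbiased phantom alone", {
  tt <- make_two_tissue(96, 96, range_log = 0)
  res <- run_n4(tt$clean, config = n4_config(control_point_spacing = 48))
  expect_lt(sd(res$bias$total_field), 0.05)
  expect_lt(sqrt(mean((res$corrected - tt$clean)^2)) / mean(tt$clean), 0.05)
})

test_that("run_n4 recovers a smooth multiplicative field", {
  tt <- make_two_tissue(128, 128, range_log = 0.6)
  res <- run_n4(tt$image, config = n4_config(control_point_spacing = 64))
  tf <- res$bias$total_field
  expect_gte(cor(as.numeric(tf - mean(tf)),
                 as.numeric(tt$field - mean(tt$field))), 0.90)
  # corrected image close to the clean one
  expect_lt(sqrt(mean((res$corrected - tt$clean)^2)),
            0.5 * sqrt(mean((tt$image - tt$clean)^2)))
  # accumulation identity
  total <- Reduce(`+`, res$bias$residual_fields)
  expect_lt(max(abs(res$bias$total_field - total)), 1e-9)
  # mean invariance
  expect_lt(abs(mean(res$corrected) / mean(tt$image) - 1), 0.10)
  # every residual field is idempotent under its own smoothing spacing
  for (i in seq_along(res$bias$residual_fields)) {
    rf <- res$bias$residual_fields[[i]]
    sm <- smooth_field(rf, res$bias$spacings[i])
    expect_lt(max(abs(sm - rf)), 1e-6 * max(1, max(abs(rf))))
  }
})

test_that("run_n4 respects the FOV and validates input", {
  tt <- make_two_tissue(96, 96, range_log = 0.5)
  fov <- matrix(FALSE, 96, 96)
  fov[10:90, 10:90] <- TRUE
  img <- tt$image
  img[!fov] <- 0  # camera-black outside, would break an unmasked log
  res <- run_n4(img, fov = fov, config = n4_config(control_point_spacing = 48))
  expect_equal(res$corrected[!fov], img[!fov])  # untouched outside
  expect_gte(cor(res$bias$total_field[fov] - mean(res$bias$total_field[fov]),
                 tt$field[fov] - mean(tt$field[fov])), 0.85)

  bad <- tt$image; bad[5, 7] <- 0
  expect_error(run_n4(bad), "row 5, col 7")
  expect_error(run_n4(tt$image, fov = matrix(FALSE, 96, 96)), "empty")
})
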