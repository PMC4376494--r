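test_that("adaptive_hist_eq matches the nested-loop oracle and its limits", {
  # constant image: no pixel strictly exceeds any neighbour
  const <- matrix(7, 9, 9)
  expect_true(all(adaptive_hist_eq(const, enhancement_config(h = 3)) == 0))

  set.seed(11)
  img <- matrix(sample(0:255, 49, replace = TRUE), 7, 7)
  for (h in c(3, 5)) {
    for (r in c(1, 3, 6)) {
      got <- adaptive_hist_eq(img, enhancement_config(r = r, h = h))
      expect_equal(got, oracle_ahe(img, h, r),
                   tolerance = 1e-12,
                   label = sprintf("ahe h=%d r=%d", h, r))
    }
  }

  # monotone in r: base (c/h^2) <= 1, so a larger exponent never increases
  a3 <- adaptive_hist_eq(img, enhancement_config(r = 3, h = 3))
  a6 <- adaptive_hist_eq(img, enhancement_config(r = 6, h = 3))
  expect_true(all(a6 <= a3 + 1e-12))

  expect_error(enhancement_config(h = 4), "odd")
  expect_error(adaptive_hist_eq(matrix(c(1, NA, 3, 4), 2, 2)), "finite")
})

test_that("adaptive_hist_eq is invariant under strictly increasing remaps", {
  set.seed(5)
  for (rep in 1:5) {
    img <- matrix(runif(15 * 13, 0, 100), 15, 13)
    cfg <- enhancement_config(r = 3, h = 5)
    base <- adaptive_hist_eq(img, cfg)
    expect_equal(adaptive_hist_eq(exp(img / 25), cfg), base)
    expect_equal(adaptive_hist_eq(img^3 + 5 * img, cfg), base)
  }
})

test_that("binarize_and_open thresholds then opens, never adding pixels", {
  expect_equal(sum(binarize_and_open(matrix(0, 10, 10))), 0)

  # isolated dot is destroyed by a radius-1 opening
  dot <- matrix(0, 11, 11); dot[6, 6] <- 255
  cfg <- enhancement_config(open_radius = 1, binarize_quantile = 0.5)
  expect_equal(sum(binarize_and_open(dot, cfg)), 0)

  # salt noise over a wide bar: oracle equality, bar kept, salt removed
  # (salt touching the bar merges with it under dilation, so keep a margin)
  set.seed(21)
  H <- 60; W <- 60
  bar <- matrix(FALSE, H, W); bar[28:32, ] <- TRUE
  margin <- bar; margin[26:34, ] <- TRUE
  salt <- matrix(runif(H * W) < 0.02, H, W) & !margin
  mask <- bar | salt
  opened <- binary_open(mask, 1)
  expect_equal(opened, oracle_open(mask, 1))
  expect_true(all(opened[29:31, 3:(W - 2)]))      # bar interior retained
  expect_lt(sum(opened & salt), 0.05 * max(sum(salt), 1))
  expect_true(all(!opened | mask))                # output subset of input

  # thresholded-but-unopened pixels: opening is applied after the quantile
  set.seed(22)
  enh <- matrix(runif(900, 0, 255), 30, 30)
  got <- binarize_and_open(enh, cfg)
  thr <- quantile(enh, 0.5, names = FALSE)
  expect_equal(got, oracle_open(enh > thr, 1))
})

test_that("distance_map is the exact Euclidean transform", {
  expect_true(all(distance_map(matrix(FALSE, 8, 8)) == 0))

  # 5-wide horizontal band on a tall image: profile 1 2 3 2 1
  band <- matrix(FALSE, 11, 61); band[4:8, ] <- TRUE
  d <- distance_map(band)
  expect_equal(as.numeric(d[4:8, 31]), c(1, 2, 3, 2, 1))

  set.seed(9)
  for (rep in 1:3) {
    m <- matrix(runif(32 * 32) < c(0.4, 0.6, 0.85)[rep], 32, 32)
    expect_equal(unclass(distance_map(m)), oracle_edt(m), tolerance = 1e-12)
  }

  # neighbour Lipschitz bound: d(p) <= d(q) + sqrt(2) for 8-neighbours
  m <- matrix(runif(900) < 0.7, 30, 30)
  d <- unclass(distance_map(m))
  for (sh in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    a <- d[2:29, 2:29]
    b <- d[2:29 + sh[1], 2:29 + sh[2]]
    expect_true(all(a <= b + sqrt(2) + 1e-9))
  }

  expect_warning(dall <- distance_map(matrix(TRUE, 5, 7)), "border")
  expect_equal(dall[3, 4], 3)  # centre of a 5-row image: 3 steps off-image
})

test_that("distance map is zero outside the opened mask", {
  set.seed(33)
  enh <- matrix(runif(40 * 40, 0, 255), 40, 40)
  cfg <- enhancement_config(open_radius = 1, binarize_quantile = 0.7)
  opened <- binarize_and_open(enh, cfg)
  d <- distance_map(opened)
  expect_true(all(d[!opened] == 0))
  expect_true(all(d[opened] >= 1))
})
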