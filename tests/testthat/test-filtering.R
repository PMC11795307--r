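test_that("band-pass removes DC and matches the analytic DoG transfer", {
  roi <- full_roi(64, 64, 25)
  bc <- bandpass_and_downsample(matrix(5, 64, 64), roi, 30, 195)
  expect_lt(max(abs(bc$pattern), na.rm = TRUE), 1e-10)

  # plane sinusoid of 1.0 mm wavelength: attenuation equals the
  # difference-of-Gaussians frequency response at that frequency
  n <- 256; px <- 25
  roi2 <- full_roi(n, n, px)
  xx <- matrix(rep(seq_len(n), each = n), n, n, byrow = TRUE)
  sinp <- sin(2 * pi * xx * px / 1000)
  b <- bandpass_and_downsample(sinp, roi2, 30, 195)
  f <- 1 / 1000
  transfer <- exp(-2 * pi^2 * f^2 * 30^2) - exp(-2 * pi^2 * f^2 * 195^2)
  inner <- 64:192
  att <- sd(b$pattern[inner, inner]) / sd(sinp[inner, inner])
  expect_lt(abs(att / transfer - 1), 0.05)
})

test_that("640x540 downsamples to 160x135 with factor 4", {
  roi <- full_roi(640, 540, 22)
  set.seed(14)
  b <- bandpass_and_downsample(matrix(rnorm(640 * 540), 640, 540), roi,
                               30, 195, target_dims = c(160, 135))
  expect_equal(dim(b$pattern), c(160L, 135L))
  expect_equal(b$pixel_um_ds, 88)
  expect_equal(b$factor, 4L)
  expect_error(
    bandpass_and_downsample(matrix(0, 64, 64), full_roi(64, 64, 22),
                            30, 195, target_dims = c(16, 13)),
    "integer factor")
  expect_error(
    bandpass_and_downsample(matrix(0, 8, 8), full_roi(8, 8, 22), 195, 30),
    "s_low_um")
})

test_that("a small ROI triggers the unreliable-filter warning", {
  expect_warning(
    bandpass_and_downsample(matrix(rnorm(100), 10, 10), full_roi(10, 10, 22),
                            30, 195),
    "unreliable")
})

test_that("correlation fields equal a brute-force Pearson loop", {
  set.seed(15)
  pats <- array(rnorm(3 * 2 * 2), c(3, 2, 2))   # N = 3 patterns of 4 px
  ps <- pattern_set(pats, matrix(TRUE, 2, 2), 100)
  cf <- correlation_field(ps, c(1, 1))
  for (i in 1:2) for (j in 1:2)
    expect_lt(abs(cf$values[i, j] - cor(pats[, 1, 1], pats[, i, j])), 1e-10)

  set.seed(16)
  for (n_pat in c(5, 20)) {
    pats <- array(rnorm(n_pat * 8 * 8), c(n_pat, 8, 8))
    ps <- pattern_set(pats, matrix(TRUE, 8, 8), 100)
    seed <- c(4, 6)
    cf <- correlation_field(ps, seed)
    expect_lt(abs(cf$values[seed[1], seed[2]] - 1), 1e-12)
    brute <- matrix(NA, 8, 8)
    for (i in 1:8) for (j in 1:8)
      brute[i, j] <- cor(pats[, seed[1], seed[2]], pats[, i, j])
    expect_lt(max(abs(cf$values - brute)), 1e-10)
  }
})

test_that("rank-1 pattern sets give |C| = 1 everywhere defined", {
  set.seed(17)
  base <- matrix(rnorm(36), 6, 6)
  w <- c(2, -1, 0.5, 3, -2)
  pats <- array(0, c(5, 6, 6))
  for (i in 1:5) pats[i, , ] <- w[i] * base
  ps <- pattern_set(pats, matrix(TRUE, 6, 6), 100)
  cf <- correlation_field(ps, c(2, 2))
  expect_true(all(abs(abs(cf$values) - 1) < 1e-10))
})

test_that("correlation fields are invariant to affine rescaling", {
  set.seed(18)
  pats <- array(rnorm(10 * 6 * 6), c(10, 6, 6))
  ps1 <- pattern_set(pats, matrix(TRUE, 6, 6), 100)
  ps2 <- pattern_set(3.7 * pats + 0.5, matrix(TRUE, 6, 6), 100)
  f1 <- correlation_field(ps1, c(3, 4))$values
  f2 <- correlation_field(ps2, c(3, 4))$values
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("degenerate correlation inputs raise errors", {
  ps1 <- pattern_set(array(rnorm(4), c(1, 2, 2)), matrix(TRUE, 2, 2), 100)
  expect_error(correlation_field(ps1, c(1, 1)), "at least 2")
  pats <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
  pats[, 1, 1] <- 5
  ps <- pattern_set(pats, matrix(TRUE, 2, 2), 100)
  expect_error(correlation_field(ps, c(1, 1)), "zero-variance")
})

test_that("surrogate transforms: identity, involution, determinism", {
  set.seed(19)
  pat <- matrix(rnorm(40 * 40), 40, 40)
  roi <- matrix(TRUE, 40, 40)
  ctr <- c(20.5, 20.5)
  id <- modmap:::transform_pattern(pat, roi, 0, FALSE, FALSE, ctr)
  expect_equal(id, pat)
  once <- modmap:::transform_pattern(pat, roi, 0, TRUE, FALSE, ctr)
  twice <- modmap:::transform_pattern(once, roi, 0, TRUE, FALSE, ctr)
  expect_equal(twice, pat)

  ps <- pattern_set(array(rnorm(5 * 20 * 20), c(5, 20, 20)),
                    matrix(TRUE, 20, 20), 100)
  s1 <- make_surrogate_ensemble(ps, 77)
  s2 <- make_surrogate_ensemble(ps, 77)
  expect_identical(s1$patterns, s2$patterns)
  expect_identical(s1$transforms, s2$transforms)
})

test_that("right-angle rotations preserve the value histogram exactly", {
  set.seed(20)
  pat <- matrix(rnorm(21 * 21), 21, 21)
  roi <- disc_roi(21, 100, radius_px = 9)$mask
  ctr <- c(11, 11)
  for (ang in c(90, 180, 270)) {
    rot <- modmap:::transform_pattern(pat, roi, ang, FALSE, FALSE, ctr)
    src <- pat; src[!roi] <- NA
    expect_equal(sort(rot[is.finite(rot)]), sort(src[is.finite(src)]))
  }
})

test_that("surrogate angles are uniform over the 36 allowed values", {
  tr <- draw_surrogate_transforms(1e4, 42)
  expect_true(all(tr$angle_deg %% 10 == 0))
  freq <- table(factor(tr$angle_deg, levels = seq(0, 350, 10))) / 1e4
  expect_equal(length(freq), 36L)
  expect_lt(max(abs(freq - 1 / 36)), 0.01)
  expect_gt(abs(mean(tr$flip_x) - 0.5), -1)  # draws exist
  expect_lt(abs(mean(tr$flip_x) - 0.5), 0.02)
  expect_lt(abs(mean(tr$flip_y) - 0.5), 0.02)
})
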