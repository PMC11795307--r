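test_that("radial autocorrelation matches brute-force all-pairs binning", {
  set.seed(22)
  n <- 24
  pat <- matrix(rnorm(n * n), n, n)
  pat[1:4, 1:6] <- NA                     # irregular ROI corner
  roi <- matrix(TRUE, n, n); roi[1:4, 1:6] <- FALSE
  px <- 50
  prof <- radial_autocorrelation(pat, roi, px)

  # independent oracle: loop over all pixel pairs, bin by rounded distance
  idx <- which(roi, arr.ind = TRUE)
  v <- pat[roi] - mean(pat[roi])
  bw <- px / 1000
  dmat <- as.matrix(dist(idx)) * px / 1000
  bins <- round(dmat / bw)
  prods <- outer(v, v)
  num <- tapply(prods, bins, sum)
  cnt <- tapply(rep(1, length(bins)), bins, sum)
  ac <- (num / cnt) / (num[["0"]] / cnt[["0"]])
  radii <- as.numeric(names(num)) * bw
  o <- order(radii)
  expect_equal(prof$radii_mm, radii[o])
  expect_lt(max(abs(prof$values - as.numeric(ac)[o])), 1e-8)
})

test_that("white noise decorrelates beyond a few pixels", {
  set.seed(23)
  pat <- matrix(rnorm(64 * 64), 64, 64)
  prof <- radial_autocorrelation(pat, matrix(TRUE, 64, 64), 50)
  # annuli near the corner lags hold only a handful of pairs and are pure
  # sampling noise; the decorrelation claim concerns populated annuli
  far <- prof$radii_mm > 3 * 50 / 1000 & prof$n_pairs >= 2e4
  expect_lt(max(abs(prof$values[far])), 0.05)
  expect_equal(prof$values[1], 1)
})

test_that("constant patterns have no defined autocorrelation", {
  expect_error(radial_autocorrelation(matrix(2, 16, 16),
                                      matrix(TRUE, 16, 16), 50),
               "constant")
})

test_that("wavelength and modularity read off a cosine profile", {
  bw <- 0.04
  radii <- seq(0, 2, by = bw)
  prof <- structure(list(radii_mm = radii, values = cos(2 * pi * radii / 1.0),
                         bin_width_mm = bw), class = "modmap_radial")
  wm <- wavelength_and_modularity(prof)
  expect_true(wm$valid)
  expect_lt(abs(wm$wavelength_mm - 1.0), 2 * bw + 1e-9)
  # trough -1 to crest +1, slightly shrunk by the 3-bin smoothing
  expect_gt(wm$modularity, 1.8)
  expect_lte(wm$modularity, 2.0)

  decay <- structure(list(radii_mm = radii, values = exp(-radii * 3),
                          bin_width_mm = bw), class = "modmap_radial")
  wm2 <- wavelength_and_modularity(decay)
  expect_false(wm2$valid)
  expect_true(is.na(wm2$wavelength_mm))
})

test_that("wavelength and modularity are amplitude invariant", {
  comps <- generate_modular_components(c(64, 64), 50, 1.0, 1, rng_seed = 8)
  roi <- matrix(TRUE, 64, 64)
  p1 <- radial_autocorrelation(comps[1, , ], roi, 50)
  p2 <- radial_autocorrelation(5 * comps[1, , ], roi, 50)
  expect_equal(wavelength_and_modularity(p1), wavelength_and_modularity(p2),
               tolerance = 1e-12)
})

test_that("synthetic modular events recover a 0.8 mm wavelength", {
  comps <- generate_modular_components(c(96, 96), 40, 0.8, 5, rng_seed = 30)
  cm <- matrix(comps, 5)
  roi <- full_roi(96, 96, 40)
  set.seed(31)
  wl <- replicate(20, {
    pat <- as.vector(rnorm(5) %*% cm)
    frame <- matrix(pat - min(pat), 96, 96)
    b <- bandpass_and_downsample(frame, roi, 30, 195)
    wavelength_and_modularity(
      radial_autocorrelation(b$pattern, b$roi_ds, b$pixel_um_ds))$wavelength_mm
  })
  expect_gte(median(wl), 0.72)
  expect_lte(median(wl), 0.88)
})

test_that("module amplitude is peak over half-wavelength background", {
  n <- 61; px <- 25                      # wavelength 1 mm = 40 px
  ctr <- (n + 1) / 2
  r_um <- outer(seq_len(n), seq_len(n),
                function(i, j) sqrt((i - ctr)^2 + (j - ctr)^2)) * px
  roi <- disc_roi(n, px, radius_px = 28)
  frame <- 0.10 + 0.05 * cos(2 * pi * r_um / 1000)
  ma <- module_amplitude(frame, roi, 1.0)
  expect_true(ma$valid)
  expect_equal(ma$n_peaks, 1L)
  expect_lt(abs(ma$value - 3.0), 0.15)   # peak 0.15 over trough 0.05

  # offset below the modulation depth: trough background goes nonpositive,
  # so the peak is excluded and the result flagged invalid
  low <- 0.04 + 0.05 * cos(2 * pi * r_um / 1000)
  expect_warning(ma2 <- module_amplitude(low, roi, 1.0), "nonpositive")
  expect_false(ma2$valid)

  # uniform frame: no peaks
  ma3 <- module_amplitude(matrix(0.1, n, n), roi, 1.0)
  expect_false(ma3$valid)
  expect_equal(ma3$n_peaks, 0L)
})

test_that("synthetic events recover a known peak/background ratio", {
  # lattice of Gaussian bumps (spacing 1 mm) on a dim floor: the generator
  # fixes the peak:background ratio at 2
  n <- 80; px <- 25
  coords <- as.matrix(expand.grid(r = c(20, 60), c = c(20, 60)))
  bump <- matrix(0, n, n)
  for (k in seq_len(nrow(coords))) {
    d2 <- outer(seq_len(n), seq_len(n),
                function(i, j) (i - coords[k, 1])^2 + (j - coords[k, 2])^2)
    bump <- bump + exp(-d2 / (2 * 36))
  }
  floor_v <- 0.1
  frame <- floor_v + bump * floor_v     # peaks ~0.2 over background ~0.1
  roi <- full_roi(n, n, px)
  ma <- module_amplitude(frame, roi, 1.0)
  expect_true(ma$valid)
  expect_gte(ma$value, 1.8)
  expect_lte(ma$value, 2.2)
})

test_that("modular events are significantly more modular than quiet frames", {
  sm <- synthetic_dff_movie(shape = c(40, 40), pixel_um = 80,
                            wavelength_mm = 1.0, n_events = 10,
                            n_frames = 600, rng_seed = 41)
  roi <- full_roi(40, 40, 80)
  cat_ev <- suppressWarnings(detect_events(sm$dff, roi))
  met <- event_metrics(cat_ev, roi)
  ms <- modularity_significance(met$modularity[met$valid], sm$dff, cat_ev,
                                roi, rng_seed = 4)
  expect_lt(ms$p_value, 0.05)
  expect_length(ms$control_medians, 100)
  expect_gt(ms$p_value, 0)
})

test_that("events drawn from the control pool are not significant", {
  nm <- null_event_dff_movie(rng_seed = 55)
  cat_ev <- catalog_from_times(nm$dff, nm$event_times, nm$kernel_len)
  roi <- full_roi(32, 32, 100)
  # "event" modularities measured from quiet frames themselves
  d <- dim(nm$dff$data)
  in_event <- logical(d[1])
  for (i in seq_len(nrow(cat_ev$events)))
    in_event[cat_ev$events$start[i]:cat_ev$events$end[i]] <- TRUE
  quiet <- which(!in_event)
  set.seed(6)
  fake_mod <- vapply(sample(quiet, 8), function(t)
    modmap:::frame_modularity(nm$dff$data[t, , ], roi, 30, 195, 1L),
    numeric(1))
  hits <- 0L
  for (s in 1:10) {
    ms <- modularity_significance(fake_mod, nm$dff, cat_ev, roi, rng_seed = s)
    hits <- hits + (ms$p_value >= 0.05)
  }
  expect_gte(hits, 9L)
})
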