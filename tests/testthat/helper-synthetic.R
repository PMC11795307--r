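# shared fixture builders; everything is generated in code at test time

# circular ROI (rotation-invariant support, like a cranial window)
disc_roi <- function(n, pixel_um, radius_px = n / 2 - 1) {
  ctr <- (n + 1) / 2
  m <- outer(seq_len(n), seq_len(n),
             function(i, j) sqrt((i - ctr)^2 + (j - ctr)^2) <= radius_px)
  roi_mask(m, pixel_um)
}

full_roi <- function(h, w, pixel_um) roi_mask(matrix(TRUE, h, w), pixel_um)

# pattern set built directly from k modular components: each pattern is a
# random weighted combination plus pixel noise
component_pset <- function(k, n_patterns, seed, wavelength_mm = 1.0,
                           n_grid = 64, pixel_um = 50, noise_sd = 0.02,
                           roi = NULL) {
  if (is.null(roi)) roi <- full_roi(n_grid, n_grid, pixel_um)
  comps <- generate_modular_components(c(n_grid, n_grid), pixel_um,
                                       wavelength_mm, k, rng_seed = seed)
  cm <- matrix(comps, k)
  set.seed(seed + 7919)
  w <- matrix(rnorm(n_patterns * k), n_patterns, k)
  pats <- array(0, c(n_patterns, n_grid, n_grid))
  for (i in seq_len(n_patterns))
    pats[i, , ] <- matrix(w[i, , drop = FALSE] %*% cm +
                            rnorm(n_grid^2, sd = noise_sd), n_grid, n_grid)
  pattern_set(pats, roi$mask, pixel_um)
}

# isotropic unstructured patterns: lightly smoothed white noise (no shared
# spatial structure across patterns)
noise_pset <- function(n_patterns, seed, n_grid = 40, pixel_um = 80,
                       smooth_px = 3, roi = NULL) {
  if (is.null(roi)) roi <- disc_roi(n_grid, pixel_um)
  full <- matrix(TRUE, n_grid, n_grid)
  set.seed(seed)
  pats <- array(0, c(n_patterns, n_grid, n_grid))
  for (i in seq_len(n_patterns))
    pats[i, , ] <- gauss_blur_masked(matrix(rnorm(n_grid^2), n_grid, n_grid),
                                     full, smooth_px)
  pattern_set(pats, roi$mask, pixel_um)
}

# dF/F movie with known modular events (drift off, baseline = 1, so
# dF/F = movie - 1 exactly)
synthetic_dff_movie <- function(shape = c(48, 48), pixel_um = 66,
                                wavelength_mm = 0.9, k = 4, n_events = 12,
                                n_frames = 600, noise_sd = 0.01,
                                weight_sd = 0.05, rng_seed = 1L) {
  truth <- simulate_ground_truth(shape = shape, pixel_um = pixel_um,
                                 wavelength_mm = wavelength_mm, k = k,
                                 n_events = n_events, n_frames = n_frames,
                                 noise_sd = noise_sd, weight_sd = weight_sd,
                                 drift_amplitude = 0, rng_seed = rng_seed)
  syn <- synthesize_movie(truth)
  dff <- movie(syn$movie$data - 1, pixel_um, syn$movie$frame_rate_hz, "dff")
  list(dff = dff, truth = truth, labels = syn$labels,
       event_frames_true = syn$event_frames_true,
       clean_mean = syn$clean_mean)
}

# dF/F movie whose "events" are rectified white noise (spatially
# unstructured), for null calibration of the modularity test
null_event_dff_movie <- function(shape = c(32, 32), pixel_um = 100,
                                 n_events = 8, n_frames = 800,
                                 noise_sd = 0.01, amp = 0.15, rng_seed = 1L) {
  h <- shape[1]; w <- shape[2]
  kern <- modmap:::event_kernel(15, decay_s = 0.5)
  len <- length(kern)
  gap <- (n_frames - len) %/% n_events
  times <- as.integer((seq_len(n_events) - 1L) * gap + 2L)
  set.seed(rng_seed)
  dat <- matrix(rnorm(n_frames * h * w, sd = noise_sd), n_frames, h * w)
  for (e in seq_along(times)) {
    pat <- rnorm(h * w)
    pat <- (pat - min(pat)) / diff(range(pat)) * amp
    fr <- times[e]:(times[e] + len - 1L)
    dat[fr, ] <- dat[fr, ] + outer(kern, pat)
  }
  list(dff = movie(array(dat, c(n_frames, h, w)), pixel_um, 15, "dff"),
       event_times = times, kernel_len = len)
}

# catalog constructed from known event times (bypasses detection when the
# test targets a downstream stage)
catalog_from_times <- function(dff, times, kernel_len) {
  ev <- tibble::tibble(event_id = seq_along(times), start = times,
                       end = pmin(times + kernel_len - 1L, dim(dff$data)[1]),
                       event_frame = times + 1L)
  cat_ev <- structure(list(events = ev, n_active_frames = sum(ev$end - ev$start + 1)),
                      class = "modmap_events")
  n <- nrow(ev)
  d <- dim(dff$data)
  fr <- array(NA_real_, c(n, d[2], d[3]))
  for (i in seq_len(n)) fr[i, , ] <- dff$data[ev$event_frame[i], , ]
  cat_ev$frames_raw <- fr
  cat_ev
}
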