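#' @name pattern_metrics
#' @title Wavelength, modularity and module amplitude of event patterns
#'
#' @description
#' The wavelength of an event is read from the 1-D radial average of the
#' spatial autocorrelation of its band-passed pattern: the radius of the
#' first minimum is half the wavelength. Modularity is the absolute
#' difference in autocorrelation amplitude between that first minimum and the
#' subsequent maximum — the depth of the first "ring", which reflects how
#' regularly the active domains are spaced. Module amplitude works on the
#' raw (unfiltered) event frame: the dF/F at detected module peaks divided by
#' the median background dF/F half a wavelength away.
NULL

#' Radial average of the masked spatial autocorrelation
#'
#' Computes the 2-D spatial autocorrelation of the pattern (only pixel pairs
#' with both ends inside the ROI contribute, each lag normalised by its pair
#' count), then averages over annuli of width `bin_width_mm`. The profile is
#' normalised to 1 at zero lag. The pattern is centred to zero mean over the
#' ROI first.
#'
#' @param pattern numeric `h x w` band-passed pattern (NA allowed outside
#'   the ROI).
#' @param roi_ds logical `h x w` mask.
#' @param pixel_um pixel pitch of the pattern grid in micrometres.
#' @param bin_width_mm annulus width; default one pixel.
#' @return object of class `modmap_radial`: `radii_mm`, `values` (1 at
#'   radius 0), `bin_width_mm`, `n_pairs`.
#' @export
radial_autocorrelation <- function(pattern, roi_ds, pixel_um,
                                   bin_width_mm = pixel_um / 1000) {
  stopifnot(all(dim(pattern) == dim(roi_ds)))
  mask <- roi_ds & is.finite(pattern)
  if (sum(mask) < 9) stop("too few ROI pixels for autocorrelation")
  vals <- pattern[mask]
  if (sd(vals) == 0) stop("constant pattern: autocorrelation undefined")
  h <- nrow(pattern); w <- ncol(pattern)
  p <- pattern
  p[!mask] <- 0
  p[mask] <- vals - mean(vals)
  m <- mask * 1

  nr <- stats::nextn(2 * h)
  nc <- stats::nextn(2 * w)
  pp <- matrix(0, nr, nc); pp[1:h, 1:w] <- p
  mm <- matrix(0, nr, nc); mm[1:h, 1:w] <- m
  fp <- fft(pp); fm <- fft(mm)
  num <- Re(fft(fp * Conj(fp), inverse = TRUE)) / (nr * nc)
  cnt <- Re(fft(fm * Conj(fm), inverse = TRUE)) / (nr * nc)

  di <- c(0:(h - 1), -( (h - 1):1 ))
  dj <- c(0:(w - 1), -( (w - 1):1 ))
  rows <- c(1:h, (nr - h + 2):nr)
  cols <- c(1:w, (nc - w + 2):nc)
  num <- num[rows, cols]
  cnt <- round(cnt[rows, cols])
  lag_mm <- sqrt(outer(di^2, dj^2, "+")) * pixel_um / 1000
  bin <- round(lag_mm / bin_width_mm)

  keep <- cnt > 0.5
  num_k <- rowsum(num[keep], bin[keep])
  cnt_k <- rowsum(cnt[keep], bin[keep])
  ks <- as.integer(rownames(num_k))
  o <- order(ks)
  ks <- ks[o]
  ac <- (num_k[o] / cnt_k[o])
  ac <- ac / ac[ks == 0L]
  structure(list(radii_mm = ks * bin_width_mm, values = as.numeric(ac),
                 bin_width_mm = bin_width_mm,
                 n_pairs = as.numeric(cnt_k[o])),
            class = "modmap_radial")
}

# first interior strict local extremum of v (plateaus resolved to the
# smallest radius, i.e. the first index of the plateau); type = -1 for a
# minimum, +1 for a maximum; returns NA if none
first_local_extremum <- function(v, type) {
  r <- rle(-type * v)   # minima of -type*v are extrema of the requested type
  k <- length(r$values)
  if (k < 3) return(NA_integer_)
  starts <- cumsum(r$lengths) - r$lengths + 1L
  for (s in 2:(k - 1)) {
    if (r$values[s] < r$values[s - 1] && r$values[s] < r$values[s + 1])
      return(starts[s])
  }
  NA_integer_
}

#' Wavelength and modularity from a radial profile
#'
#' The profile is lightly smoothed (3-bin moving average), the first interior
#' local minimum located, and the wavelength taken as twice its radius.
#' Modularity is the absolute difference between the profile value at the
#' subsequent local maximum and at that minimum. When no interior minimum or
#' no subsequent maximum exists, the metrics are flagged invalid rather than
#' thrown.
#'
#' @param profile a [radial_autocorrelation()] result with >= 3 bins.
#' @return list with `wavelength_mm`, `modularity`, `valid`, and the bin
#'   indices `i_min`, `i_max`.
#' @export
wavelength_and_modularity <- function(profile) {
  stopifnot(inherits(profile, "modmap_radial"))
  v <- profile$values
  L <- length(v)
  if (L < 3) stop_invalid("radial profile needs at least 3 bins")
  vs <- v
  for (i in seq_len(L)) vs[i] <- mean(v[max(1, i - 1):min(L, i + 1)])

  i_min <- first_local_extremum(vs, -1)
  if (is.na(i_min))
    return(list(wavelength_mm = NA_real_, modularity = NA_real_,
                valid = FALSE, i_min = NA_integer_, i_max = NA_integer_))
  tail_idx <- i_min:L
  i_max_rel <- first_local_extremum(vs[tail_idx], +1)
  if (is.na(i_max_rel))
    return(list(wavelength_mm = NA_real_, modularity = NA_real_,
                valid = FALSE, i_min = i_min, i_max = NA_integer_))
  i_max <- i_min + i_max_rel - 1L
  list(wavelength_mm = 2 * profile$radii_mm[i_min],
       modularity = abs(vs[i_max] - vs[i_min]),
       valid = TRUE, i_min = i_min, i_max = i_max)
}

#' Module amplitude of a raw event frame
#'
#' Detects module peaks on a lightly smoothed copy of the raw dF/F frame
#' (Gaussian SD `smooth_sd_px`, peaks = local maxima over a disk of radius a
#' quarter wavelength, with a minimum prominence of twice the pixel-noise
#' SD), then divides each peak's raw dF/F by the median raw dF/F over an
#' annulus at half the experiment-mean wavelength from the peak. The event
#' value is the mean over peaks.
#'
#' @param frame_raw numeric `H x W` raw dF/F event frame.
#' @param roi a [roi_mask()].
#' @param mean_wavelength_mm mean wavelength across all events of the
#'   experiment (mm).
#' @param smooth_sd_px SD of the smoothing Gaussian in pixels (default 2).
#' @param annulus_halfwidth_um half-width of the background annulus; default
#'   4 pixels (one downsampled pixel at the default geometry).
#' @return list with `value` (mean peak/background ratio), `valid`,
#'   `n_peaks`, `n_excluded`.
#' @export
module_amplitude <- function(frame_raw, roi, mean_wavelength_mm,
                             smooth_sd_px = 2, annulus_halfwidth_um = NULL) {
  stopifnot(inherits(roi, "modmap_roi"))
  if (!is.finite(mean_wavelength_mm) || mean_wavelength_mm <= 0)
    stop_invalid("mean_wavelength_mm must be > 0")
  px <- roi$pixel_um
  hw <- annulus_halfwidth_um %||% (4 * px)
  sm <- gauss_blur_masked(frame_raw, roi$mask, smooth_sd_px)
  resid <- frame_raw[roi$mask] - sm[roi$mask]
  noise_sd <- mad(resid)
  radius_px <- max(1L, round(0.25 * mean_wavelength_mm * 1000 / px))
  mf <- .max_filter_disk(sm, radius_px)
  # candidate peaks must have their whole detection disk inside the ROI;
  # otherwise clipped neighbourhoods at the ROI border produce spurious
  # boundary maxima
  outside <- (!roi$mask) * 1
  interior <- .max_filter_disk(outside, radius_px) == 0
  floor_v <- median(sm[roi$mask]) + 2 * noise_sd
  eps <- 1e-8 * (abs(floor_v) + 1e-12)
  is_peak <- roi$mask & interior & is.finite(sm) &
    sm >= mf - 1e-12 & sm > floor_v + eps
  pk <- which(is_peak, arr.ind = TRUE)
  if (nrow(pk) == 0)
    return(list(value = NA_real_, valid = FALSE, n_peaks = 0L,
                n_excluded = 0L))

  half_um <- mean_wavelength_mm * 1000 / 2
  rows <- matrix(seq_len(nrow(frame_raw)), nrow(frame_raw), ncol(frame_raw))
  cols <- matrix(rep(seq_len(ncol(frame_raw)), each = nrow(frame_raw)),
                 nrow(frame_raw), ncol(frame_raw))
  amps <- numeric(0)
  n_excl <- 0L
  for (i in seq_len(nrow(pk))) {
    d_um <- sqrt((rows - pk[i, 1])^2 + (cols - pk[i, 2])^2) * px
    ann <- roi$mask & abs(d_um - half_um) <= hw
    if (!any(ann)) { n_excl <- n_excl + 1L; next }
    bg <- median(frame_raw[ann])
    if (!is.finite(bg) || bg <= 0) {
      warning("nonpositive background at peak (", pk[i, 1], ", ", pk[i, 2],
              "); peak excluded")
      n_excl <- n_excl + 1L
      next
    }
    amps <- c(amps, frame_raw[pk[i, 1], pk[i, 2]] / bg)
  }
  if (!length(amps))
    return(list(value = NA_real_, valid = FALSE, n_peaks = nrow(pk),
                n_excluded = n_excl))
  list(value = mean(amps), valid = TRUE, n_peaks = nrow(pk),
       n_excluded = n_excl)
}

# modularity of one raw frame through the standard filtering path; invalid
# profiles (no interior minimum) count as zero modularity
frame_modularity <- function(frame, roi, s_low_um, s_high_um, factor,
                             bin_width_mm = NULL) {
  b <- suppressWarnings(
    bandpass_and_downsample(frame, roi, s_low_um, s_high_um, factor = factor))
  bw <- bin_width_mm %||% (b$pixel_um_ds / 1000)
  prof <- tryCatch(
    radial_autocorrelation(b$pattern, b$roi_ds, b$pixel_um_ds, bw),
    error = function(e) NULL)
  if (is.null(prof)) return(0)
  wm <- wavelength_and_modularity(prof)
  if (isTRUE(wm$valid)) wm$modularity else 0
}

#' Bootstrap significance of event modularity
#'
#' Control frames are drawn from the bottom 10% (by ROI-mean activity) of
#' frames that are not part of any detected event. 100 control sets, each of
#' the same size as the event set, are passed through the identical
#' filtering + radial-autocorrelation + modularity path; the p-value is the
#' fraction of control median modularities at least as large as the observed
#' median (with a +1/(n+1) continuity correction so p > 0). Frames whose
#' profile has no interior minimum contribute zero modularity.
#'
#' @param event_modularity numeric per-event modularity values.
#' @param dff the dF/F [movie()] the events were detected in.
#' @param catalog the `modmap_events` catalog.
#' @param roi a [roi_mask()].
#' @param rng_seed integer seed.
#' @param n_sets number of control sets (default 100).
#' @param bottom_frac quantile of quiet frames forming the control pool.
#' @param s_low_um,s_high_um,factor filtering parameters, which must match
#'   those used for the event patterns.
#' @return object of class `modmap_modsig`: `observed_median`,
#'   `control_medians`, `p_value`, `pool_frames`.
#' @export
modularity_significance <- function(event_modularity, dff, catalog, roi,
                                    rng_seed, n_sets = 100,
                                    bottom_frac = 0.10,
                                    s_low_um = 30, s_high_um = 195,
                                    factor = 1L) {
  stopifnot(inherits(dff, "modmap_movie"), inherits(catalog, "modmap_events"))
  d <- dim(dff$data)
  in_event <- logical(d[1])
  ev <- catalog$events
  for (i in seq_len(nrow(ev))) in_event[ev$start[i]:ev$end[i]] <- TRUE
  non_event <- which(!in_event)
  if (length(non_event) < 10)
    stop_invalid("need at least 10 non-event frames for the control pool")

  roivec <- as.vector(roi$mask)
  m <- matrix(dff$data, d[1], d[2] * d[3])
  mean_act <- rowMeans(m[non_event, roivec, drop = FALSE])
  k <- max(1L, floor(bottom_frac * length(non_event)))
  pool <- non_event[order(mean_act)][seq_len(k)]

  # each pool frame's modularity is computed once and reused across sets
  pool_mod <- vapply(pool, function(t)
    frame_modularity(dff$data[t, , ], roi, s_low_um, s_high_um, factor),
    numeric(1))

  n_ev <- length(event_modularity)
  replace <- length(pool) < n_ev
  if (replace)
    warning("control pool smaller than event count; sampling with replacement")
  ctrl <- with_seed(rng_seed, {
    vapply(seq_len(n_sets), function(b)
      median(pool_mod[sample.int(length(pool), n_ev, replace = replace)]),
      numeric(1))
  })
  obs <- median(event_modularity)
  p <- (1 + sum(ctrl >= obs)) / (n_sets + 1)
  structure(list(observed_median = obs, control_medians = ctrl,
                 p_value = p, pool_frames = pool),
            class = "modmap_modsig")
}

#' @export
print.modmap_modsig <- function(x, ...) {
  cat(sprintf("<modmap_modsig> observed median %.4f vs %d controls, p = %.4f\n",
              x$observed_median, length(x$control_medians), x$p_value))
  invisible(x)
}

#' Per-event metrics table
#'
#' Runs the full per-event metric chain: band-pass each raw event frame,
#' estimate wavelength and modularity from the radial autocorrelation, then
#' compute module amplitude on the raw frame using the experiment-mean
#' wavelength.
#'
#' @param catalog a [detect_events()] catalog (with `frames_raw`).
#' @param roi a [roi_mask()].
#' @param s_low_um,s_high_um band-pass SDs (um).
#' @param factor downsampling factor for the filtered patterns.
#' @return tibble with one row per event: `event_id`, `start`, `end`,
#'   `event_frame`, `wavelength_mm`, `modularity`, `module_amplitude`,
#'   `valid`.
#' @export
event_metrics <- function(catalog, roi, s_low_um = 30, s_high_um = 195,
                          factor = 1L) {
  stopifnot(inherits(catalog, "modmap_events"), !is.null(catalog$frames_raw))
  n <- nrow(catalog$events)
  wl <- mod <- amp <- rep(NA_real_, n)
  ok <- logical(n)
  pset <- if (n > 0) build_pattern_set(catalog$frames_raw, roi, s_low_um,
                                       s_high_um, factor = factor) else NULL
  for (i in seq_len(n)) {
    prof <- tryCatch(
      radial_autocorrelation(pset$patterns[i, , ], pset$roi_ds,
                             pset$pixel_um_ds),
      error = function(e) NULL)
    if (is.null(prof)) next
    wm <- wavelength_and_modularity(prof)
    wl[i] <- wm$wavelength_mm
    mod[i] <- wm$modularity
    ok[i] <- wm$valid
  }
  mean_wl <- mean(wl[ok])
  if (is.finite(mean_wl) && mean_wl > 0) {
    for (i in seq_len(n)) {
      ma <- suppressWarnings(
        module_amplitude(catalog$frames_raw[i, , ], roi, mean_wl))
      amp[i] <- ma$value
    }
  }
  tibble::tibble(event_id = catalog$events$event_id,
                 start = catalog$events$start,
                 end = catalog$events$end,
                 event_frame = catalog$events$event_frame,
                 wavelength_mm = wl, modularity = mod,
                 module_amplitude = amp, valid = ok)
}
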