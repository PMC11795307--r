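#' @name synthetic
#' @title Ground-truth synthetic movies
#'
#' @description
#' The generator produces fluorescence movies with the statistical structure
#' the downstream analyses assume: sparse large events whose spatial patterns
#' are weighted combinations of a small number of band-limited ("modular")
#' component fields, riding on a slowly drifting baseline with i.i.d. pixel
#' noise. Because every quantity (wavelength, number of components, event
#' times, amplitudes) is known exactly, each analysis stage has a
#' parameter-recovery test without any external data.
NULL

# first minimum of the Bessel J0 autocorrelation of an isotropic field with
# a narrow ring spectrum sits at j_{1,1} / (2 pi f0), j_{1,1} = 3.8317
BESSEL_J1_ZERO1 <- 3.831706

#' Generate mutually uncorrelated modular component fields
#'
#' Builds `k` zero-mean, unit-SD isotropic spatial fields by filtering white
#' noise in the Fourier domain with a narrow Gaussian ring of spatial
#' frequencies. The carrier frequency is calibrated so that the first minimum
#' of the field's radial autocorrelation — the downstream operational
#' definition of (half) the wavelength — falls at `wavelength_mm / 2`: for a
#' ring spectrum the autocorrelation is a Bessel `J0(2 pi f0 r)` whose first
#' minimum is at `j_{1,1} / (2 pi f0)`, so `f0 = j_{1,1} / (pi wavelength)`.
#' Because the band is narrow, the broad analysis band-pass applied before
#' measurement rescales the spectrum almost uniformly and leaves the measured
#' wavelength unbiased. Successive fields are orthogonalised against earlier
#' ones so pairwise correlations are exactly zero.
#'
#' @param shape integer `c(H, W)` grid dimensions.
#' @param pixel_um pixel pitch in micrometres.
#' @param wavelength_mm target modular wavelength in millimetres.
#' @param k number of component fields (>= 1).
#' @param rng_seed integer seed; fields are reproducible from it.
#' @param rel_bandwidth SD of the Gaussian ring relative to the carrier
#'   frequency (default 0.1).
#' @return `k x H x W` array with attributes `f0_per_um` (carrier frequency,
#'   cycles/um) and `rel_bandwidth`.
#' @export
generate_modular_components <- function(shape, pixel_um, wavelength_mm, k,
                                        rng_seed = 1L, rel_bandwidth = 0.1) {
  stopifnot(length(shape) == 2L, k >= 1)
  lam_um <- wavelength_mm * 1000
  if (lam_um < 2 * pixel_um)
    stop_invalid("wavelength below the 2-pixel Nyquist limit at this pixel size")
  if (lam_um < 8 * pixel_um)
    warning("wavelength below 8 pixels; modular structure will be poorly resolved")

  f0 <- BESSEL_J1_ZERO1 / (pi * lam_um)     # cycles per um
  sf <- rel_bandwidth * f0
  h <- shape[1]; w <- shape[2]
  fx <- ifelse(seq_len(h) - 1 <= h / 2, seq_len(h) - 1, seq_len(h) - 1 - h) / (h * pixel_um)
  fy <- ifelse(seq_len(w) - 1 <= w / 2, seq_len(w) - 1, seq_len(w) - 1 - w) / (w * pixel_um)
  fmag <- sqrt(outer(fx^2, fy^2, "+"))
  transfer <- exp(-(fmag - f0)^2 / (2 * sf^2))

  comps <- array(NA_real_, c(k, h, w))
  with_seed(rng_seed, {
    for (j in seq_len(k)) {
      z <- matrix(rnorm(h * w), h, w)
      f <- Re(fft(fft(z) * transfer, inverse = TRUE)) / (h * w)
      v <- as.vector(f)
      v <- v - mean(v)
      if (j > 1) {
        for (jj in seq_len(j - 1L)) {
          u <- as.vector(comps[jj, , ])
          v <- v - sum(v * u) / sum(u * u) * u
        }
        v <- v - mean(v)
      }
      comps[j, , ] <- v / sd(v)
    }
  })
  attr(comps, "f0_per_um") <- f0
  attr(comps, "rel_bandwidth") <- rel_bandwidth
  comps
}

#' Assemble a ground-truth description for a synthetic movie
#'
#' @param component_maps `k x H x W` array of zero-mean component fields,
#'   typically from [generate_modular_components()].
#' @param pixel_um pixel pitch of the component grid.
#' @param true_wavelength_mm the wavelength the components were built with.
#' @param event_times strictly increasing frame indices of event onsets.
#' @param event_weights `n_events x k` matrix of component weights; each
#'   event's spatial pattern is the weighted sum of the components, rectified
#'   by subtracting its minimum (fluorescence is nonnegative).
#' @param n_frames movie length in frames.
#' @param noise_sd SD of i.i.d. Gaussian pixel noise, in dF/F units.
#' @param drift_amplitude peak amplitude of the slow multiplicative baseline
#'   drift, in dF/F units.
#' @param rng_seed integer seed for noise and drift phases.
#' @return an object of class `modmap_truth`.
#' @export
ground_truth <- function(component_maps, pixel_um, true_wavelength_mm,
                         event_times, event_weights, n_frames,
                         noise_sd = 0.01, drift_amplitude = 0.02,
                         rng_seed = 1L) {
  stopifnot(length(dim(component_maps)) == 3L)
  k <- dim(component_maps)[1]
  if (k < 1) stop_invalid("need at least one component map")
  if (true_wavelength_mm <= 0) stop_invalid("true_wavelength_mm must be > 0")
  event_times <- as.integer(event_times)
  if (length(event_times) && any(diff(event_times) <= 0))
    stop_invalid("event_times must be strictly increasing")
  event_weights <- as.matrix(event_weights)
  if (length(event_times) &&
      (nrow(event_weights) != length(event_times) || ncol(event_weights) != k))
    stop_invalid("event_weights must be n_events x k")
  mu <- apply(component_maps, 1, mean)
  if (any(abs(mu) > 1e-6))
    stop_invalid("component maps must have zero mean")
  structure(list(component_maps = component_maps, pixel_um = pixel_um,
                 true_wavelength_mm = true_wavelength_mm,
                 event_times = event_times, event_weights = event_weights,
                 n_frames = as.integer(n_frames), noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 rng_seed = as.integer(rng_seed)),
            class = "modmap_truth")
}

# temporal kernel: linear 2-frame rise, exponential decay (tau seconds),
# truncated where the decay falls below 5% of peak
event_kernel <- function(frame_rate_hz, decay_s = 1) {
  nd <- ceiling(3 * decay_s * frame_rate_hz)
  c(0.5, 1, exp(-(1:nd) / (decay_s * frame_rate_hz)))
}

#' Render a ground truth into a fluorescence movie
#'
#' The movie is `baseline(t) * (1 + sum of events) + noise`, where the
#' baseline is `1` plus a slow sinusoidal drift (periods >= 30 s, removable by
#' a 10-64 s running-median baseline), each event is its rectified component
#' combination scaled by a calcium-like temporal kernel (2-frame linear rise,
#' 1 s exponential decay), and noise is i.i.d. Gaussian per pixel and frame.
#'
#' @param truth a [ground_truth()] object.
#' @param frame_rate_hz acquisition rate (default 15 Hz).
#' @param decay_s decay time constant of the event kernel in seconds.
#' @return list with `movie` (a raw [movie()]), `labels` (integer per-frame
#'   event id, 0 = no event), `event_frames_true` (frame index of each
#'   event's kernel peak), `clean_mean` (frame-mean trace of the noise-free
#'   movie), and `truth`.
#' @export
synthesize_movie <- function(truth, frame_rate_hz = 15, decay_s = 1) {
  stopifnot(inherits(truth, "modmap_truth"))
  tt <- truth$n_frames
  kern <- event_kernel(frame_rate_hz, decay_s)
  len <- length(kern)
  et <- truth$event_times
  if (length(et)) {
    if (any(et < 1L) || any(et + len - 1L > tt))
      stop_invalid("event_times (plus kernel support) must lie within the movie")
    if (any(diff(et) < len + 3L))
      stop_invalid("overlapping event supports: events must be separated by the kernel length plus 3 frames")
  }

  h <- dim(truth$component_maps)[2]
  w <- dim(truth$component_maps)[3]
  k <- dim(truth$component_maps)[1]
  cm <- matrix(truth$component_maps, nrow = k)   # k x (h*w)

  labels <- integer(tt)
  signal <- matrix(0, tt, h * w)
  for (e in seq_along(et)) {
    pat <- as.vector(truth$event_weights[e, , drop = FALSE] %*% cm)
    pat <- pat - min(pat)                        # rectified, nonnegative
    fr <- et[e]:(et[e] + len - 1L)
    signal[fr, ] <- signal[fr, ] + outer(kern, pat)
    labels[fr] <- e
  }

  out <- with_seed(truth$rng_seed, {
    drift <- numeric(tt)
    if (truth$drift_amplitude > 0) {
      periods_s <- c(31, 47, 61)
      ph <- runif(3, 0, 2 * pi)
      t_idx <- seq_len(tt)
      raw <- rowSums(sapply(seq_along(periods_s), function(i)
        sin(2 * pi * t_idx / (periods_s[i] * frame_rate_hz) + ph[i])))
      drift <- truth$drift_amplitude * raw / max(abs(raw))
    }
    base <- 1 + drift
    clean <- base * (1 + signal)                 # recycles base down columns
    noise <- matrix(rnorm(tt * h * w, sd = truth$noise_sd), tt, h * w)
    list(clean = clean, data = clean + noise)
  })

  mv <- movie(array(out$data, c(tt, h, w)),
              pixel_um = truth$pixel_um, frame_rate_hz = frame_rate_hz,
              kind = "raw")
  list(movie = mv,
       labels = labels,
       event_frames_true = if (length(et)) et + 1L else integer(0),
       clean_mean = rowMeans(out$clean),
       truth = truth)
}

#' One-call synthetic ground truth with sensible defaults
#'
#' Draws component maps, evenly spaced (jittered) event times and i.i.d.
#' normal event weights for a movie emulating a wide-field recording:
#' 15 Hz, sparse large events with modular patterns at the requested
#' wavelength, weak slow drift and pixel noise.
#'
#' @param shape,pixel_um grid geometry.
#' @param wavelength_mm modular wavelength (default 1 mm).
#' @param k number of spatial components (default 5).
#' @param n_events number of events.
#' @param n_frames movie length in frames.
#' @param frame_rate_hz frame rate used to space events (default 15).
#' @param weight_sd SD of the normal component weights (dF/F scale of one
#'   component; default 0.05 gives rectified event peaks near 0.3 dF/F).
#' @param noise_sd,drift_amplitude see [ground_truth()].
#' @param rng_seed integer seed.
#' @return a `modmap_truth` object.
#' @export
simulate_ground_truth <- function(shape, pixel_um, wavelength_mm = 1, k = 5,
                                  n_events = 20, n_frames = 1200,
                                  frame_rate_hz = 15, weight_sd = 0.05,
                                  noise_sd = 0.01, drift_amplitude = 0.02,
                                  rng_seed = 1L) {
  comps <- generate_modular_components(shape, pixel_um, wavelength_mm, k,
                                       derive_seed(rng_seed, "components"))
  len <- length(event_kernel(frame_rate_hz)) + 3L
  need <- n_events * (len + 3L) + len
  if (n_frames < need)
    stop_invalid("n_frames too short for ", n_events,
                 " non-overlapping events (need >= ", need, ")")
  gap <- (n_frames - len) %/% n_events
  with_seed(derive_seed(rng_seed, "events"), {
    jit <- sample.int(max(1L, gap - len - 2L), n_events, replace = TRUE)
    times <- as.integer((seq_len(n_events) - 1L) * gap + jit)
    times <- pmax(times, 1L)
    wts <- matrix(rnorm(n_events * k, sd = weight_sd), n_events, k)
  })
  ground_truth(comps, pixel_um, wavelength_mm, times, wts, n_frames,
               noise_sd = noise_sd, drift_amplitude = drift_amplitude,
               rng_seed = derive_seed(rng_seed, "noise"))
}
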