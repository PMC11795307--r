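#' @name preprocess
#' @title Registration, baseline estimation and dF/F
#'
#' @description
#' Raw movies are rigidly registered (translation-only, phase correlation
#' against a temporal-median reference), a per-pixel baseline `F0` is
#' estimated with a running median over a 10-64 s window, and the
#' baseline-corrected activity is `(F - F0) / F0`.
NULL

# integer translation of a frame, zero-filled at the exposed border
shift_frame <- function(x, dr, dc) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  src_r <- seq_len(h) - dr
  src_c <- seq_len(w) - dc
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[ok_r, ok_c] <- x[src_r[ok_r], src_c[ok_c]]
  out
}

# translation between two frames by the peak of the FFT cross-correlation
phase_shift <- function(ref_f, frame, h, w) {
  cc <- Re(fft(ref_f * Conj(fft(frame)), inverse = TRUE))
  i <- which.max(cc)
  dr <- (i - 1) %% h
  dc <- (i - 1) %/% h
  if (dr > h / 2) dr <- dr - h
  if (dc > w / 2) dc <- dc - w
  c(dr, dc)
}

#' Rigid (translation) registration of a movie
#'
#' Registers every frame to a reference by phase correlation and applies the
#' recovered integer pixel shift. Rotations are assumed negligible under head
#' fixation, so "rigid" reduces to translation.
#'
#' @param movie a raw [movie()].
#' @param reference `"median"` (temporal median frame, default), `"first"`,
#'   or an integer frame index.
#' @return list with `movie` (registered) and `shifts` (`T x 2` matrix of
#'   applied (row, col) shifts in pixels).
#' @export
register_rigid <- function(movie, reference = "median") {
  stopifnot(inherits(movie, "modmap_movie"))
  if (movie$kind != "raw")
    stop_invalid("register_rigid expects a raw movie")
  d <- dim(movie$data)
  tt <- d[1]; h <- d[2]; w <- d[3]
  ref <- if (identical(reference, "median")) {
    apply(movie$data, c(2, 3), median)
  } else if (identical(reference, "first")) {
    movie$data[1, , ]
  } else {
    movie$data[as.integer(reference), , ]
  }
  ref_f <- fft(ref)
  out <- movie$data
  shifts <- matrix(0L, tt, 2, dimnames = list(NULL, c("row", "col")))
  for (t in seq_len(tt)) {
    fr <- movie$data[t, , ]
    if (all(fr == 0)) {
      warning("frame ", t, " is all zero; registered with zero shift")
      next
    }
    s <- phase_shift(ref_f, fr, h, w)   # correction that realigns the frame
    if (any(s != 0)) out[t, , ] <- shift_frame(fr, s[1], s[2])
    shifts[t, ] <- s
  }
  list(movie = movie(out, movie$pixel_um, movie$frame_rate_hz, "raw"),
       shifts = shifts)
}

# running median with truncated (shrinking) windows at both edges
running_median_truncated <- function(x, k) {
  n <- length(x)
  half <- (k - 1L) %/% 2L
  out <- runmed(x, k, endrule = "keep")
  em <- .edge_medians(x, half)
  m <- length(em$left)
  out[seq_len(m)] <- em$left
  out[n + 1L - seq_len(m)] <- em$right
  out
}

#' Per-pixel running-median baseline
#'
#' The baseline fluorescence `F0` of each pixel is the running median of its
#' trace over a window of `window_s` seconds (10-64 s), chosen so that the
#' baseline follows the slow trend of the fluorescence while ignoring brief
#' transients. Edge frames use truncated windows rather than reflected data.
#'
#' @param movie a [movie()].
#' @param window_s window length in seconds, in `[10, 64]`.
#' @return an object of class `modmap_baseline` with fields `f0`
#'   (`T x H x W`) and `window_s`.
#' @export
compute_baseline <- function(movie, window_s = 30) {
  stopifnot(inherits(movie, "modmap_movie"))
  if (window_s < 10 || window_s > 64)
    stop_invalid("window_s must lie in [10, 64] seconds")
  d <- dim(movie$data)
  tt <- d[1]
  k <- round(window_s * movie$frame_rate_hz)
  if (k >= tt)
    stop_invalid("baseline window (", k, " frames) is not shorter than the movie")
  if (k %% 2L == 0L) k <- k + 1L
  npx <- d[2] * d[3]
  m <- matrix(movie$data, tt, npx)
  f0 <- matrix(0, tt, npx)
  for (p in seq_len(npx)) f0[, p] <- running_median_truncated(m[, p], k)
  structure(list(f0 = array(f0, d), window_s = window_s),
            class = "modmap_baseline")
}

#' Baseline-corrected activity dF/F
#'
#' Computes `(F - F0) / F0` per pixel and frame.
#'
#' @param movie a raw [movie()].
#' @param baseline a [compute_baseline()] result of matching shape.
#' @param roi optional [roi_mask()]; positivity of `F0` is only enforced
#'   inside the ROI.
#' @return a [movie()] of kind `"dff"`.
#' @export
compute_dff <- function(movie, baseline, roi = NULL) {
  stopifnot(inherits(movie, "modmap_movie"), inherits(baseline, "modmap_baseline"))
  d <- dim(movie$data)
  if (!all(d == dim(baseline$f0)))
    stop_invalid("movie and baseline shapes differ")
  if (!is.null(roi)) {
    check_same_grid(movie, roi)
    sel <- rep(as.vector(roi$mask), each = d[1])
  } else {
    sel <- TRUE
  }
  bad <- baseline$f0 <= 0
  if (!is.null(roi)) bad <- bad & array(sel, d)
  if (any(bad)) {
    i <- which(bad)[1]
    ai <- arrayInd(i, d)
    stop_invalid(sprintf("nonpositive baseline at frame %d, pixel (%d, %d)",
                         ai[1], ai[2], ai[3]))
  }
  dff <- (movie$data - baseline$f0) / baseline$f0
  movie(dff, movie$pixel_um, movie$frame_rate_hz, "dff")
}
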