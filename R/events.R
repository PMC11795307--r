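#' @name event_detection
#' @title Detection of large spontaneous events
#'
#' @description
#' Events are found in three steps. (1) A per-pixel activity threshold:
#' either a Gaussian fitted to the sub-transient bulk of each pixel's dF/F
#' histogram (threshold = mean + 3 SD) or, for recordings where the dF/F
#' distribution is broad, the pixel's 80th percentile. (2) Spatial criteria
#' per frame: active pixels must belong to a contiguous active region of at
#' least 0.01 mm^2, and a frame counts as active only when more than 40% of
#' ROI pixels are active. (3) Runs of consecutive active frames are combined
#' into events, split at interior local minima of the ROI-mean activity; the
#' "event frame" is the frame of highest ROI-mean activity within the event.
NULL

#' Fit a Gaussian to the sub-transient bulk of a pixel trace
#'
#' Histograms the trace, locates the highest-count (mode) bin, truncates the
#' data at 1.5 times the mode's bin position counted from the histogram's
#' left edge (for a Gaussian bulk this cuts roughly 2 SD above the mode, so
#' large positive transients are excluded regardless of where the mode sits),
#' and fits a Gaussian to the retained bin counts by weighted least squares
#' on log counts (weights = squared counts, which closely approximates least
#' squares on the counts themselves and has a closed form).
#'
#' @param trace numeric dF/F series of length >= 100.
#' @param bin_width histogram bin width; default Freedman-Diaconis.
#' @return list with elements `mu` and `sigma`.
#' @export
fit_truncated_gaussian <- function(trace, bin_width = NULL) {
  n <- length(trace)
  if (n < 100) stop_invalid("trace must have at least 100 samples")
  if (sd(trace) == 0) stop_invalid("degenerate (constant) trace")
  if (is.null(bin_width)) {
    # Freedman-Diaconis on the sub-threshold bulk, so that rare large
    # transients do not inflate the bin width
    bulk <- trace[trace <= median(trace) + 3 * mad(trace)]
    if (length(bulk) < 100) bulk <- trace
    bin_width <- 2 * IQR(bulk) / length(bulk)^(1 / 3)
    if (bin_width <= 0) bin_width <- diff(range(trace)) / 64
  }
  lo <- min(trace) - bin_width / 2
  nb <- ceiling((max(trace) - lo) / bin_width) + 1L
  centers <- lo + bin_width * (seq_len(nb) - 0.5)
  idx <- pmin(pmax(floor((trace - lo) / bin_width) + 1L, 1L), nb)
  counts <- tabulate(idx, nb)
  i_mode <- which.max(counts)
  i_cut <- min(nb, ceiling(1.5 * i_mode))
  trunc_value <- lo + bin_width * i_cut    # upper edge of the cut bin

  keep <- trace <= trunc_value
  fallback <- function(reason) {
    warning("Gaussian fit failed (", reason, "); using median/MAD")
    list(mu = median(trace), sigma = mad(trace))
  }
  if (sum(keep) < 10) return(fallback("too few samples below truncation"))
  counts_t <- tabulate(idx[keep], nb)
  use <- counts_t > 0
  if (sum(use) < 4) return(fallback("fewer than 4 nonzero bins"))

  x <- centers[use]
  y <- log(counts_t[use])
  wt <- counts_t[use]^2
  X <- cbind(1, x, x^2)
  beta <- tryCatch(solve(crossprod(X, wt * X), crossprod(X, wt * y)),
                   error = function(e) NULL)
  if (is.null(beta) || !is.finite(beta[3]) || beta[3] >= 0)
    return(fallback("non-concave log histogram"))
  sigma2 <- -1 / (2 * beta[3])
  mu <- beta[2] * sigma2
  if (!is.finite(mu) || !is.finite(sigma2) || sigma2 <= 0)
    return(fallback("invalid parameters"))
  list(mu = mu, sigma = sqrt(sigma2))
}

#' @importFrom stats IQR
NULL

#' Fit the per-pixel activity threshold model
#'
#' @param dff a dF/F [movie()].
#' @param roi a [roi_mask()].
#' @param method `"gaussian3sd"` (threshold = fitted mean + 3 fitted SD) or
#'   `"percentile80"` (threshold = 80th percentile of the pixel trace).
#' @param bin_width optional histogram bin width for the Gaussian fit.
#' @return object of class `modmap_threshold` with `H x W` matrices `mu`,
#'   `sigma`, `threshold` (NA outside the ROI) and the `method`.
#' @export
fit_threshold_model <- function(dff, roi,
                                method = c("gaussian3sd", "percentile80"),
                                bin_width = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(dff, "modmap_movie"))
  check_same_grid(dff, roi)
  d <- dim(dff$data)
  h <- d[2]; w <- d[3]
  mu <- sigma <- thr <- matrix(NA_real_, h, w)
  pix <- which(roi$mask)
  m <- matrix(dff$data, d[1], h * w)
  if (method == "percentile80") {
    thr[pix] <- apply(m[, pix, drop = FALSE], 2, quantile,
                      probs = 0.8, names = FALSE)
  } else {
    n_fallback <- 0L
    for (p in pix) {
      fit <- withCallingHandlers(
        fit_truncated_gaussian(m[, p], bin_width),
        warning = function(wn) {
          n_fallback <<- n_fallback + 1L
          invokeRestart("muffleWarning")
        })
      mu[p] <- fit$mu
      sigma[p] <- fit$sigma
    }
    if (n_fallback > 0)
      warning(n_fallback, " pixel(s) used the median/MAD fallback fit")
    thr <- mu + 3 * sigma
  }
  structure(list(method = method, mu = mu, sigma = sigma, threshold = thr),
            class = "modmap_threshold")
}

#' Classify active pixels per frame
#'
#' A pixel is active on a frame when its dF/F exceeds its threshold.
#'
#' @param dff a dF/F [movie()].
#' @param model a [fit_threshold_model()] result on the same grid.
#' @return logical `T x H x W` array (FALSE outside the ROI).
#' @export
classify_active_pixels <- function(dff, model) {
  stopifnot(inherits(model, "modmap_threshold"))
  d <- dim(dff$data)
  thr <- array(rep(as.vector(model$threshold), each = d[1]), d)
  act <- dff$data > thr
  act[is.na(act)] <- FALSE
  act
}

#' Apply the spatial criteria to one frame of active pixels
#'
#' Removes active pixels that are not part of an 8-connected active region of
#' at least `min_area_mm2`, then flags the frame as active when the cleaned
#' active fraction within the ROI strictly exceeds `min_active_frac`.
#'
#' @param active_frame logical `H x W` matrix.
#' @param roi a [roi_mask()].
#' @param pixel_um pixel pitch; defaults to `roi$pixel_um`.
#' @param min_area_mm2 minimum contiguous area (default 0.01 mm^2).
#' @param min_active_frac active-fraction criterion (default 0.40, strict).
#' @return list with `cleaned` (logical `H x W`) and `is_active_frame`.
#' @export
apply_spatial_criteria <- function(active_frame, roi, pixel_um = roi$pixel_um,
                                   min_area_mm2 = 0.01,
                                   min_active_frac = 0.40) {
  stopifnot(all(dim(active_frame) == dim(roi$mask)))
  min_px <- ceiling(min_area_mm2 * 1e6 / pixel_um^2)
  cleaned <- active_frame
  if (any(active_frame)) {
    lab <- .cc_label(active_frame, 8L)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < min_px)
    if (length(small)) cleaned[lab %in% small] <- FALSE
  }
  frac <- sum(cleaned & roi$mask) / sum(roi$mask)
  list(cleaned = cleaned, is_active_frame = frac > min_active_frac)
}

# indices (relative) of strict local minima of v, interior only; plateaus
# are resolved to the LAST frame of the plateau
interior_local_minima <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  mins <- integer(0)
  for (s in 2:(k - 1)) {
    if (r$values[s] < r$values[s - 1] && r$values[s] < r$values[s + 1])
      mins <- c(mins, ends[s])
  }
  mins
}

#' Combine active frames into events
#'
#' Maximal runs of active frames become events; a run containing an interior
#' strict local minimum of the ROI-mean activity is split there, with the
#' minimum frame ending the earlier event. Each event's "event frame" is its
#' frame of highest ROI-mean activity.
#'
#' @param active_flags logical per-frame activity flags.
#' @param mean_activity numeric per-frame ROI-mean dF/F, same length.
#' @return object of class `modmap_events`: a list with `events` (tibble of
#'   `event_id`, `start`, `end`, `event_frame`) and `n_active_frames`.
#' @export
segment_events <- function(active_flags, mean_activity) {
  stopifnot(length(active_flags) == length(mean_activity))
  r <- rle(as.logical(active_flags))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    a <- starts[i]; b <- ends[i]
    cuts <- a - 1L + interior_local_minima(mean_activity[a:b])
    bounds <- c(a - 1L, cuts, b)
    for (j in seq_len(length(bounds) - 1L)) {
      s <- bounds[j] + 1L
      e <- bounds[j + 1L]
      pk <- s - 1L + which.max(mean_activity[s:e])
      ev[[length(ev) + 1L]] <- c(s, e, pk)
    }
  }
  events <- if (length(ev)) {
    m <- do.call(rbind, ev)
    tibble::tibble(event_id = seq_len(nrow(m)), start = m[, 1],
                   end = m[, 2], event_frame = m[, 3])
  } else {
    tibble::tibble(event_id = integer(0), start = integer(0),
                   end = integer(0), event_frame = integer(0))
  }
  structure(list(events = events, n_active_frames = sum(active_flags)),
            class = "modmap_events")
}

#' @export
print.modmap_events <- function(x, ...) {
  cat(sprintf("<modmap_events> %d events over %d active frames\n",
              nrow(x$events), x$n_active_frames))
  invisible(x)
}

#' Detect spontaneous events in a dF/F movie
#'
#' Convenience wrapper running the full detection chain: threshold model,
#' pixel classification, spatial criteria, and event segmentation, and
#' extracting each event's raw (unfiltered) event frame.
#'
#' @inheritParams fit_threshold_model
#' @inheritParams apply_spatial_criteria
#' @return a `modmap_events` object extended with `frames_raw`
#'   (`N x H x W` array of raw event-frame dF/F patterns), `mean_activity`,
#'   `active_flags` and `method`.
#' @export
detect_events <- function(dff, roi, method = c("gaussian3sd", "percentile80"),
                          bin_width = NULL, min_area_mm2 = 0.01,
                          min_active_frac = 0.40) {
  method <- match.arg(method)
  model <- fit_threshold_model(dff, roi, method, bin_width)
  act <- classify_active_pixels(dff, model)
  d <- dim(dff$data)
  flags <- logical(d[1])
  for (t in seq_len(d[1])) {
    flags[t] <- apply_spatial_criteria(act[t, , ], roi,
                                       min_area_mm2 = min_area_mm2,
                                       min_active_frac = min_active_frac)$is_active_frame
  }
  roivec <- as.vector(roi$mask)
  m <- matrix(dff$data, d[1], d[2] * d[3])
  mean_activity <- rowMeans(m[, roivec, drop = FALSE])
  cat_ev <- segment_events(flags, mean_activity)
  n <- nrow(cat_ev$events)
  frames_raw <- array(NA_real_, c(n, d[2], d[3]))
  for (i in seq_len(n))
    frames_raw[i, , ] <- dff$data[cat_ev$events$event_frame[i], , ]
  cat_ev$frames_raw <- frames_raw
  cat_ev$mean_activity <- mean_activity
  cat_ev$active_flags <- flags
  cat_ev$method <- method
  cat_ev
}
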