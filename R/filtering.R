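#' @name filtering
#' @title Spatial band-pass filtering of event frames
#'
#' @description
#' Event frames are band-pass filtered with a difference of Gaussians
#' (low SD minus high SD kernel) before any correlation or autocorrelation
#' analysis, then block-averaged down to a coarser grid. Filtering is
#' normalised inside the ROI: the blur of the masked frame is divided by the
#' blur of the mask, so pixels near the ROI border are averages of ROI pixels
#' only and no signal bleeds in from outside.
NULL

gauss_kernel <- function(sigma_px) {
  r <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k / sum(k)
}

# 1-D convolution matrix (n x n) for kernel k, truncated at the borders
conv_band <- function(n, k) {
  r <- (length(k) - 1L) / 2L
  m <- matrix(0, n, n)
  for (d in -r:r) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    m[cbind(i[ok], j[ok])] <- k[d + r + 1L]
  }
  m
}

#' Masked Gaussian blur of a single frame
#'
#' Convolves with a separable Gaussian, renormalising by the blurred mask so
#' that only pixels inside `mask` contribute. Pixels outside the mask are NA
#' in the result.
#'
#' @param x numeric `H x W` matrix.
#' @param mask logical `H x W` matrix.
#' @param sigma_px Gaussian SD in pixels; `0` returns `x` masked unchanged.
#' @return numeric matrix with NA outside the mask.
#' @export
gauss_blur_masked <- function(x, mask, sigma_px) {
  stopifnot(is.matrix(x), all(dim(x) == dim(mask)))
  out <- matrix(NA_real_, nrow(x), ncol(x))
  if (sigma_px <= 0) {
    out[mask] <- x[mask]
    return(out)
  }
  k <- gauss_kernel(sigma_px)
  kr <- conv_band(nrow(x), k)
  kc <- conv_band(ncol(x), k)
  m <- mask * 1
  xm <- x
  xm[!mask] <- 0
  num <- kr %*% xm %*% t(kc)
  den <- kr %*% m %*% t(kc)
  inside <- mask & den > 1e-12
  out[inside] <- num[inside] / den[inside]
  out
}

#' Band-pass filter and downsample one event frame
#'
#' Applies a Gaussian difference band-pass, `G(s_low) - G(s_high)`, each blur
#' ROI-normalised, then block-averages down by an integer factor. This is the
#' standard preparation of an event frame ("pattern") for correlation and
#' autocorrelation analysis.
#'
#' @param frame numeric `H x W` dF/F frame.
#' @param roi a [roi_mask()] on the same grid (carries `pixel_um`).
#' @param s_low_um,s_high_um SDs of the two Gaussian kernels in micrometres;
#'   defaults 30 and 195 um. `s_low_um < s_high_um` is required.
#' @param target_dims optional `c(h, w)`; source dims must be an identical
#'   integer multiple of these (e.g. 640x540 -> 160x135 is factor 4).
#' @param factor alternative to `target_dims`: integer downsampling factor
#'   (default 1, i.e. no downsampling).
#' @return list with `pattern` (`h x w`, NA outside the downsampled ROI),
#'   `roi_ds` (logical `h x w`), `pixel_um_ds`, `factor`.
#' @export
bandpass_and_downsample <- function(frame, roi, s_low_um = 30, s_high_um = 195,
                                    target_dims = NULL, factor = NULL) {
  stopifnot(inherits(roi, "modmap_roi"))
  if (s_low_um >= s_high_um) stop_invalid("s_low_um must be < s_high_um")
  h <- nrow(frame); w <- ncol(frame)
  if (h != nrow(roi$mask) || w != ncol(roi$mask))
    stop_invalid("frame and ROI grids differ")

  if (!is.null(target_dims)) {
    fr <- h / target_dims[1]; fc <- w / target_dims[2]
    if (fr != round(fr) || fc != round(fc) || fr != fc)
      stop_invalid("target_dims must divide the source dims by one integer factor")
    factor <- as.integer(fr)
  }
  factor <- as.integer(factor %||% 1L)
  if (h %% factor != 0L || w %% factor != 0L)
    stop_invalid("downsampling factor must divide both frame dimensions")

  px <- roi$pixel_um
  idx <- which(roi$mask, arr.ind = TRUE)
  ext_um <- (max(diff(range(idx[, 1])), diff(range(idx[, 2]))) + 1) * px
  if (ext_um < 2 * s_high_um)
    warning("ROI extent smaller than 2 * s_high_um; band-pass filter unreliable")

  lo <- gauss_blur_masked(frame, roi$mask, s_low_um / px)
  hi <- gauss_blur_masked(frame, roi$mask, s_high_um / px)
  band <- lo - hi

  if (factor == 1L) {
    roi_ds <- roi$mask & is.finite(band)
    band[!roi_ds] <- NA_real_
    return(list(pattern = band, roi_ds = roi_ds,
                pixel_um_ds = px, factor = 1L))
  }

  hd <- h %/% factor; wd <- w %/% factor
  # block mean over ROI pixels only
  bi <- rep(seq_len(hd), each = factor)
  bj <- rep(seq_len(wd), each = factor)
  blk <- matrix(bi, h, w) + (matrix(bj, h, w, byrow = TRUE) - 1L) * hd
  ok <- roi$mask & is.finite(band)
  sums <- rowsum_by(band, blk, ok, hd * wd)
  cnts <- rowsum_by(matrix(1, h, w), blk, ok, hd * wd)
  roi_ds <- matrix(cnts >= 0.5 * factor^2, hd, wd)
  pat <- matrix(NA_real_, hd, wd)
  pat[roi_ds] <- sums[roi_ds] / cnts[roi_ds]
  list(pattern = pat, roi_ds = roi_ds, pixel_um_ds = px * factor,
       factor = factor)
}

rowsum_by <- function(x, groups, keep, ngroups) {
  v <- x[keep]
  g <- groups[keep]
  out <- numeric(ngroups)
  s <- rowsum(v, g)
  out[as.integer(rownames(s))] <- s
  out
}

#' Assemble a set of band-passed event patterns
#'
#' Runs [bandpass_and_downsample()] over every raw event frame and collects
#' the results into a pattern set, the input unit for correlation fields,
#' surrogate ensembles, correlation strength and dimensionality.
#'
#' @param frames_raw numeric `N x H x W` array of raw event frames.
#' @param roi a [roi_mask()].
#' @param s_low_um,s_high_um band-pass SDs in micrometres.
#' @param target_dims,factor see [bandpass_and_downsample()].
#' @return an object of class `modmap_patterns` with fields `patterns`
#'   (`N x h x w`), `roi_ds`, `pixel_um_ds`, `s_low_um`, `s_high_um`.
#' @export
build_pattern_set <- function(frames_raw, roi, s_low_um = 30, s_high_um = 195,
                              target_dims = NULL, factor = NULL) {
  stopifnot(length(dim(frames_raw)) == 3L)
  n <- dim(frames_raw)[1]
  first <- bandpass_and_downsample(frames_raw[1, , ], roi, s_low_um, s_high_um,
                                   target_dims, factor)
  pats <- array(NA_real_, c(n, dim(first$pattern)))
  pats[1, , ] <- first$pattern
  if (n > 1) {
    for (i in 2:n) {
      b <- suppressWarnings(
        bandpass_and_downsample(frames_raw[i, , ], roi, s_low_um, s_high_um,
                                target_dims, factor))
      pats[i, , ] <- b$pattern
    }
  }
  pattern_set(pats, first$roi_ds, first$pixel_um_ds, s_low_um, s_high_um)
}

#' Construct a pattern set from pre-filtered patterns
#'
#' @param patterns numeric `N x h x w` array (NA allowed outside `roi_ds`).
#' @param roi_ds logical `h x w` downsampled ROI.
#' @param pixel_um_ds pixel pitch of the downsampled grid (um/px).
#' @param s_low_um,s_high_um the band-pass SDs the patterns were built with.
#' @return an object of class `modmap_patterns`.
#' @export
pattern_set <- function(patterns, roi_ds, pixel_um_ds,
                        s_low_um = NA_real_, s_high_um = NA_real_) {
  stopifnot(length(dim(patterns)) == 3L, is.logical(roi_ds))
  if (!all(dim(patterns)[2:3] == dim(roi_ds)))
    stop_invalid("patterns and roi_ds grids differ")
  structure(list(patterns = patterns, roi_ds = roi_ds,
                 pixel_um_ds = pixel_um_ds,
                 s_low_um = s_low_um, s_high_um = s_high_um),
            class = "modmap_patterns")
}

#' @export
print.modmap_patterns <- function(x, ...) {
  d <- dim(x$patterns)
  cat(sprintf("<modmap_patterns> %d patterns of %d x %d px, %.3g um/px\n",
              d[1], d[2], d[3], x$pixel_um_ds))
  invisible(x)
}
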