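#' Construct a fluorescence movie
#'
#' A movie is a `T x H x W` array of fluorescence values together with the
#' imaging geometry: pixel pitch in micrometres and frame rate in Hz. `kind`
#' records whether values are raw fluorescence (arbitrary units) or baseline
#' corrected dF/F.
#'
#' @param data numeric `T x H x W` array (frames, rows, columns).
#' @param pixel_um pixel pitch in micrometres per pixel (> 0).
#' @param frame_rate_hz acquisition rate in Hz (> 0).
#' @param kind `"raw"` or `"dff"`.
#' @return an object of class `modmap_movie`.
#' @export
movie <- function(data, pixel_um, frame_rate_hz, kind = c("raw", "dff")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_invalid("movie data must be a T x H x W array")
  if (dim(data)[1] < 1L) stop_invalid("movie must contain at least one frame")
  if (!is.numeric(pixel_um) || pixel_um <= 0) stop_invalid("pixel_um must be > 0")
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0) stop_invalid("frame_rate_hz must be > 0")
  structure(list(data = data, pixel_um = pixel_um,
                 frame_rate_hz = frame_rate_hz, kind = kind),
            class = "modmap_movie")
}

#' @export
print.modmap_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<modmap_movie> %d frames of %d x %d px (%s), %.3g um/px, %.3g Hz\n",
              d[1], d[2], d[3], x$kind, x$pixel_um, x$frame_rate_hz))
  invisible(x)
}

#' @export
dim.modmap_movie <- function(x) dim(x$data)

#' Construct a region-of-interest mask
#'
#' @param mask logical `H x W` matrix; `TRUE` marks pixels inside the ROI.
#' @param pixel_um pixel pitch in micrometres per pixel.
#' @return an object of class `modmap_roi`.
#' @export
roi_mask <- function(mask, pixel_um) {
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.matrix(mask) || !is.logical(mask))
    stop_invalid("roi mask must be a logical matrix")
  if (!any(mask)) stop_invalid("roi mask must contain at least one TRUE pixel")
  structure(list(mask = mask, pixel_um = pixel_um), class = "modmap_roi")
}

#' @export
print.modmap_roi <- function(x, ...) {
  cat(sprintf("<modmap_roi> %d x %d px, %d inside (%.1f%%)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

# centroid of the ROI in (row, col) pixel coordinates
roi_centroid <- function(roi) {
  idx <- which(roi$mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

check_same_grid <- function(movie, roi) {
  d <- dim(movie$data)
  if (d[2] != nrow(roi$mask) || d[3] != ncol(roi$mask))
    stop_invalid("movie and ROI are on different pixel grids")
  invisible(TRUE)
}
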