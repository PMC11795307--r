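#' @name network_metrics
#' @title Long-range correlation strength and dimensionality
#'
#' @description
#' Long-range correlation strength is the variance of seed-point correlation
#' values within a ring 1.8-2.2 mm from the seed, averaged over all usable
#' seeds; high variance means structured (strongly positive and negative)
#' correlations persist at distance. Because the estimate depends on the
#' number of events, it is computed from a fixed number (100) of patterns and
#' compared with surrogate (rotated/reflected) ensembles of matched size.
#' Effective dimensionality is the participation ratio of cross-validated PC
#' variances: PCA axes from one half of the events, variances from projecting
#' the held-out half, within a circular region of area half the squared
#' wavelength.
NULL

#' Participation ratio of a variance spectrum
#'
#' `d_eff = (sum lambda)^2 / sum(lambda^2)`: N for an equal spectrum of
#' length N, 1 for a rank-1 spectrum.
#'
#' @param lambda nonnegative variance spectrum.
#' @return effective dimensionality.
#' @export
participation_ratio <- function(lambda) {
  lambda <- lambda[is.finite(lambda)]
  sum(lambda)^2 / sum(lambda^2)
}

#' Variance of correlation values at a given distance
#'
#' For each seed, collects the correlation values `C(x, s)` over ROI pixels
#' whose distance from the seed lies within `ring_mm`, takes their variance,
#' and averages over all seeds with at least two ring pixels.
#'
#' @param cfields a [correlation_fields()] result.
#' @param ring_mm `c(lo, hi)` distance ring in millimetres (default
#'   `c(1.8, 2.2)`).
#' @return list with `variance` (mean over usable seeds), `n_seeds_used`,
#'   `per_seed` variances.
#' @export
correlation_variance_at_distance <- function(cfields, ring_mm = c(1.8, 2.2)) {
  stopifnot(inherits(cfields, "modmap_corrfields"))
  h <- nrow(cfields$roi_ds); w <- ncol(cfields$roi_ds)
  px_mm <- cfields$pixel_um_ds / 1000
  roi_idx <- which(cfields$roi_ds)
  rows <- (roi_idx - 1L) %% h + 1L
  cols <- (roi_idx - 1L) %/% h + 1L
  srows <- (cfields$seed_idx - 1L) %% h + 1L
  scols <- (cfields$seed_idx - 1L) %/% h + 1L

  per_seed <- rep(NA_real_, length(cfields$seed_idx))
  for (s in seq_along(cfields$seed_idx)) {
    d_mm <- sqrt((rows - srows[s])^2 + (cols - scols[s])^2) * px_mm
    ring <- roi_idx[d_mm >= ring_mm[1] & d_mm <= ring_mm[2]]
    if (length(ring) < 2) next
    v <- cfields$cor[s, ring]
    v <- v[is.finite(v)]
    if (length(v) >= 2) per_seed[s] <- var(v)
  }
  used <- which(is.finite(per_seed))
  if (!length(used))
    stop("no seed has ring pixels inside the ROI: field of view too small ",
         "for the ", ring_mm[1], "-", ring_mm[2], " mm ring")
  list(variance = mean(per_seed[used]), n_seeds_used = length(used),
       per_seed = per_seed)
}

#' Surrogate-corrected long-range correlation strength
#'
#' Draws `n_use` patterns (the fixed event count controlling for
#' finite-sample effects), computes the ring variance of their correlation
#' fields, and compares it against `n_surrogates` rotation/reflection
#' surrogate ensembles of matched size. `p` is the fraction of surrogate
#' variances at least as large as the real one (with continuity correction).
#'
#' @param pset a [pattern_set()].
#' @param n_use number of patterns to use (default 100). If fewer patterns
#'   exist they are resampled with replacement and the result is flagged.
#' @param n_surrogates number of surrogate ensembles (default 100).
#' @param ring_mm distance ring in mm.
#' @param rng_seed integer seed.
#' @param seed_stride stride of the seed grid passed to
#'   [correlation_fields()] (1 = every ROI pixel).
#' @return object of class `modmap_corrstrength`: `variance_real`,
#'   `variance_surrogate` (mean over surrogates), `surrogate_variances`,
#'   `p_value`, `significant`, `n_events_used`, `resampled`, `ring_mm`.
#' @export
corrected_long_range_strength <- function(pset, n_use = 100,
                                          n_surrogates = 100,
                                          ring_mm = c(1.8, 2.2),
                                          rng_seed = 1L, seed_stride = 1L) {
  stopifnot(inherits(pset, "modmap_patterns"))
  n <- dim(pset$patterns)[1]
  resampled <- n < n_use
  if (resampled)
    warning("fewer than ", n_use, " patterns; subsampling with replacement")
  sel <- with_seed(derive_seed(rng_seed, "select"),
                   sample.int(n, n_use, replace = resampled))
  sub <- pattern_set(pset$patterns[sel, , , drop = FALSE], pset$roi_ds,
                     pset$pixel_um_ds, pset$s_low_um, pset$s_high_um)

  cf <- correlation_fields(sub, seed_stride)
  v_real <- correlation_variance_at_distance(cf, ring_mm)$variance

  v_sur <- numeric(n_surrogates)
  for (b in seq_len(n_surrogates)) {
    sur <- make_surrogate_ensemble(sub, derive_seed(rng_seed, 1000 + b))
    cfs <- correlation_fields(sur, seed_stride)
    v_sur[b] <- correlation_variance_at_distance(cfs, ring_mm)$variance
  }
  p <- (1 + sum(v_sur >= v_real)) / (n_surrogates + 1)
  structure(list(variance_real = v_real, variance_surrogate = mean(v_sur),
                 surrogate_variances = v_sur, p_value = p,
                 significant = p < 0.05, n_events_used = n_use,
                 resampled = resampled, ring_mm = ring_mm),
            class = "modmap_corrstrength")
}

#' @export
print.modmap_corrstrength <- function(x, ...) {
  cat(sprintf(paste0("<modmap_corrstrength> ring %.1f-%.1f mm: real %.4g, ",
                     "surrogate %.4g, p = %.4f%s\n"),
              x$ring_mm[1], x$ring_mm[2], x$variance_real,
              x$variance_surrogate, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Cross-validated dimensionality of event patterns
#'
#' For each of `n_subsets` subsets of `subset_size` randomly chosen events,
#' the events are split into disjoint halves X1 and X2; PCA axes are fitted
#' on X1 restricted to a circular region of area `0.5 * wavelength_mm^2`, the
#' variances `lambda_i` of X2 projected on those axes are measured, and the
#' effective dimensionality is the participation ratio
#' `(sum lambda)^2 / sum(lambda^2)`. The result is the mean over subsets.
#' Cross-validation keeps noise-only directions from inflating the estimate.
#'
#' @param pset a [pattern_set()].
#' @param wavelength_mm median event wavelength of the experiment (mm),
#'   which sets the region size.
#' @param n_subsets number of subsets (default 10).
#' @param subset_size events per subset (default 100); resampled with
#'   replacement (and flagged) if fewer patterns exist.
#' @param rng_seed integer seed.
#' @param region_center `c(row, col)` on the downsampled grid; default the
#'   ROI centroid.
#' @param region_radius_mm override of the region radius; the default,
#'   `sqrt(0.5 * wavelength_mm^2 / pi)`, restricts the estimate to a
#'   neighbourhood of ~0.4 wavelengths, measuring *local* dimensionality as
#'   the standard analysis prescribes. Within so small a region the identity
#'   of globally orthogonal components is not recoverable, so rank-recovery
#'   checks need a radius spanning several wavelengths.
#' @return object of class `modmap_dimensionality`: `d_eff`, `per_subset`,
#'   `lambda_spectra`, `region_center`, `region_area_mm2`, `region_px`,
#'   `resampled`.
#' @export
cross_validated_dimensionality <- function(pset, wavelength_mm,
                                           n_subsets = 10, subset_size = 100,
                                           rng_seed = 1L,
                                           region_center = NULL,
                                           region_radius_mm = NULL) {
  stopifnot(inherits(pset, "modmap_patterns"))
  if (!is.finite(wavelength_mm) || wavelength_mm <= 0)
    stop_invalid("wavelength_mm must be > 0")
  d <- dim(pset$patterns)
  n <- d[1]
  px_mm <- pset$pixel_um_ds / 1000
  radius_mm <- region_radius_mm %||% sqrt(0.5 * wavelength_mm^2 / pi)
  area_mm2 <- pi * radius_mm^2
  if (radius_mm / px_mm < 2)
    stop_invalid("region radius below 2 pixels at this grid resolution")
  if (is.null(region_center)) {
    idx <- which(pset$roi_ds, arr.ind = TRUE)
    region_center <- c(round(mean(idx[, 1])), round(mean(idx[, 2])))
  }
  rows <- matrix(seq_len(d[2]), d[2], d[3])
  cols <- matrix(rep(seq_len(d[3]), each = d[2]), d[2], d[3])
  dist_mm <- sqrt((rows - region_center[1])^2 +
                  (cols - region_center[2])^2) * px_mm
  region <- which(pset$roi_ds & dist_mm <= radius_mm)
  if (length(region) < 4)
    stop_invalid("region contains fewer than 4 ROI pixels")

  A <- patterns_as_matrix(pset)[, region, drop = FALSE]
  ok_rows <- rowSums(!is.finite(A)) == 0
  A <- A[ok_rows, , drop = FALSE]
  n_ok <- nrow(A)
  if (n_ok < 4) stop_invalid("fewer than 4 patterns with complete region data")
  resampled <- n_ok < subset_size
  if (resampled)
    warning("fewer than ", subset_size,
            " patterns; subsampling with replacement")

  per_subset <- numeric(n_subsets)
  spectra <- vector("list", n_subsets)
  with_seed(derive_seed(rng_seed, "dimensionality"), {
    for (b in seq_len(n_subsets)) {
      ids <- sample.int(n_ok, subset_size, replace = resampled)
      half <- subset_size %/% 2
      x1 <- A[ids[seq_len(half)], , drop = FALSE]
      x2 <- A[ids[(half + 1):subset_size], , drop = FALSE]
      x1c <- sweep(x1, 2, colMeans(x1))
      sv <- svd(x1c, nu = 0)
      r <- sum(sv$d > sv$d[1] * 1e-10)
      proj <- x2 %*% sv$v[, seq_len(r), drop = FALSE]
      lam <- apply(proj, 2, var)
      spectra[[b]] <- lam
      per_subset[b] <- participation_ratio(lam)
    }
  })
  structure(list(d_eff = mean(per_subset), per_subset = per_subset,
                 lambda_spectra = spectra,
                 region_center = region_center,
                 region_area_mm2 = area_mm2, region_px = length(region),
                 resampled = resampled),
            class = "modmap_dimensionality")
}

#' @export
print.modmap_dimensionality <- function(x, ...) {
  cat(sprintf("<modmap_dimensionality> d_eff = %.3f (mean of %d subsets, region %d px)\n",
              x$d_eff, length(x$per_subset), x$region_px))
  invisible(x)
}
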