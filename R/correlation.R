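#' @name correlation
#' @title Seed-point correlation fields and surrogate ensembles
#'
#' @description
#' Given the set of band-passed event patterns `A_i`, the correlation field
#' of a seed point `s` is the Pearson correlation, across patterns, between
#' activity at `s` and at every other ROI location `x`:
#' `C(x, s) = <(A_i(s) - <A_i(s)>)(A_i(x) - <A_i(x)>)> / (sigma_x sigma_s)`,
#' with `< >` the average over the `N` patterns. The null ensemble is built by
#' randomly rotating (multiples of 10 degrees) and reflecting each pattern
#' about the ROI centre, which preserves single-pattern statistics while
#' destroying the spatial relationships between patterns.
NULL

# Pearson correlations, across patterns, between seed columns and all
# columns of an N x P pattern matrix. Pixels undefined (NA) in any pattern
# are excluded entirely: correlations are computed over the intersection of
# defined pixels, and undefined locations propagate as NA, never as 0.
cor_seed_vs_all <- function(A, seed_cols) {
  P <- ncol(A)
  dcols <- which(colSums(!is.finite(A)) == 0L)
  Ad <- A[, dcols, drop = FALSE]
  Ad <- sweep(Ad, 2, colMeans(Ad))
  s <- sqrt(colSums(Ad^2))
  good <- s > 0
  Zd <- sweep(Ad[, good, drop = FALSE], 2, s[good], "/")
  gcols <- dcols[good]
  out <- matrix(NA_real_, length(seed_cols), P)
  smap <- match(seed_cols, gcols)
  has <- !is.na(smap)
  if (any(has))
    out[has, gcols] <- crossprod(Zd[, smap[has], drop = FALSE], Zd)
  pmin(pmax(out, -1), 1)
}

patterns_as_matrix <- function(pset) {
  d <- dim(pset$patterns)
  m <- matrix(aperm(pset$patterns, c(1, 2, 3)), d[1], d[2] * d[3])
  m[, !as.vector(pset$roi_ds)] <- NA_real_
  m
}

#' Correlation field of one seed point
#'
#' @param pset a [pattern_set()] with `N >= 2` patterns.
#' @param seed integer `c(row, col)` of the seed pixel on the downsampled
#'   grid; must lie inside the ROI.
#' @return object of class `modmap_corrfield`: `values` (`h x w`, NA where
#'   undefined), `seed`, `n_patterns`.
#' @export
correlation_field <- function(pset, seed) {
  stopifnot(inherits(pset, "modmap_patterns"))
  d <- dim(pset$patterns)
  if (d[1] < 2) stop("correlation requires at least 2 patterns")
  if (!pset$roi_ds[seed[1], seed[2]]) stop_invalid("seed must lie inside the ROI")
  A <- patterns_as_matrix(pset)
  col <- seed[1] + (seed[2] - 1L) * d[2]
  v <- A[, col]
  if (sd(v[is.finite(v)]) == 0) stop("zero-variance seed pixel")
  cc <- cor_seed_vs_all(A, col)
  structure(list(values = matrix(cc[1, ], d[2], d[3]),
                 seed = as.integer(seed), n_patterns = d[1]),
            class = "modmap_corrfield")
}

#' Correlation fields for a grid of seed points
#'
#' Computes `C(x, s)` for every ROI pixel taken as a seed (optionally on a
#' strided subgrid for speed). This is the input for long-range correlation
#' strength.
#'
#' @param pset a [pattern_set()].
#' @param seed_stride integer stride of the seed subgrid (1 = every ROI
#'   pixel).
#' @return object of class `modmap_corrfields`: `cor` (`S x P` matrix over
#'   all grid pixels, rows = seeds), `seed_idx` (linear pixel index per
#'   seed), `roi_ds`, `pixel_um_ds`.
#' @export
correlation_fields <- function(pset, seed_stride = 1L) {
  stopifnot(inherits(pset, "modmap_patterns"))
  d <- dim(pset$patterns)
  if (d[1] < 2) stop("correlation requires at least 2 patterns")
  h <- d[2]; w <- d[3]
  sub <- matrix(FALSE, h, w)
  sub[seq(1L, h, by = seed_stride), seq(1L, w, by = seed_stride)] <- TRUE
  seed_idx <- which(pset$roi_ds & sub)
  A <- patterns_as_matrix(pset)
  cc <- cor_seed_vs_all(A, seed_idx)
  structure(list(cor = cc, seed_idx = seed_idx, roi_ds = pset$roi_ds,
                 pixel_um_ds = pset$pixel_um_ds),
            class = "modmap_corrfields")
}

#' Draw the random transforms of a surrogate ensemble
#'
#' Each pattern receives an independent rotation angle, uniform on
#' `{0, 10, ..., 350}` degrees, and independent x- and y-reflections each
#' with probability 0.5.
#'
#' @param n number of patterns.
#' @param rng_seed integer seed.
#' @return tibble with columns `angle_deg`, `flip_x`, `flip_y`.
#' @export
draw_surrogate_transforms <- function(n, rng_seed) {
  with_seed(rng_seed, {
    tibble::tibble(
      angle_deg = sample(seq(0L, 350L, by = 10L), n, replace = TRUE),
      flip_x = runif(n) < 0.5,
      flip_y = runif(n) < 0.5)
  })
}

# Inverse-mapping bilinear interpolation table for one rotation (degrees,
# about `center` = c(row, col)) followed by optional reflections about the
# horizontal/vertical axes through `center`. Returns neighbour indices and
# weights per output pixel; `valid` is FALSE where the pre-image falls
# outside the grid or outside `roi`.
build_transform_map <- function(h, w, roi, angle_deg, flip_x, flip_y, center) {
  rr <- matrix(seq_len(h), h, w) - center[1]
  cc <- matrix(rep(seq_len(w), each = h), h, w) - center[2]
  # inverse of (rotate then flip): undo flips, then rotate by -angle
  if (flip_x) cc <- -cc        # reflection across the vertical axis
  if (flip_y) rr <- -rr        # reflection across the horizontal axis
  th <- -angle_deg * pi / 180
  sr <- as.vector(rr * cos(th) - cc * sin(th) + center[1])
  sc <- as.vector(rr * sin(th) + cc * cos(th) + center[2])

  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  # snap near-exact grid hits so identity transforms are exact
  fr[fr < 1e-9] <- 0
  fc[fc < 1e-9] <- 0
  hi <- fr > 1 - 1e-9; r0[hi] <- r0[hi] + 1; fr[hi] <- 0
  hi <- fc > 1 - 1e-9; c0[hi] <- c0[hi] + 1; fc[hi] <- 0

  need_r <- fr > 0; need_c <- fc > 0
  inroi <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    ok[ok] <- roi[cbind(ri[ok], ci[ok])]
    ok
  }
  valid <- inroi(r0, c0) &
    (!need_r | inroi(r0 + 1, c0)) &
    (!need_c | inroi(r0, c0 + 1)) &
    (!(need_r & need_c) | inroi(r0 + 1, c0 + 1))
  # clamp indices so subscripts stay legal; invalid pixels become NA later
  cl <- function(ri, ci) pmin(pmax(ri, 1), h) + (pmin(pmax(ci, 1), w) - 1) * h
  i00 <- cl(r0, c0)
  i10 <- ifelse(need_r, cl(r0 + 1, c0), i00)
  i01 <- ifelse(need_c, cl(r0, c0 + 1), i00)
  i11 <- ifelse(need_r & need_c, cl(r0 + 1, c0 + 1), i00)
  list(i00 = i00, i10 = i10, i01 = i01, i11 = i11,
       w00 = (1 - fr) * (1 - fc), w10 = fr * (1 - fc),
       w01 = (1 - fr) * fc, w11 = fr * fc, valid = valid)
}

# apply a transform map to an N x P matrix of patterns (pixels in columns)
apply_transform_map <- function(Ag, map) {
  n <- nrow(Ag)
  out <- Ag[, map$i00, drop = FALSE] * rep(map$w00, each = n) +
    Ag[, map$i10, drop = FALSE] * rep(map$w10, each = n) +
    Ag[, map$i01, drop = FALSE] * rep(map$w01, each = n) +
    Ag[, map$i11, drop = FALSE] * rep(map$w11, each = n)
  out[, !map$valid] <- NA_real_
  out
}

# single-pattern convenience used in tests and display
transform_pattern <- function(pat, roi, angle_deg, flip_x, flip_y, center) {
  map <- build_transform_map(nrow(pat), ncol(pat), roi, angle_deg,
                             flip_x, flip_y, center)
  src <- pat
  src[!roi] <- NA_real_
  matrix(apply_transform_map(matrix(as.vector(src), 1), map),
         nrow(pat), ncol(pat))
}

#' Build a rotation/reflection surrogate ensemble
#'
#' Independently rotates each pattern about the ROI centroid by a random
#' multiple of 10 degrees and reflects it about the x- and/or y-axis with
#' probability 0.5 each. Pixels whose pre-image falls outside the original
#' ROI are NA (excluded from downstream statistics, never zero-filled).
#'
#' @param pset a [pattern_set()].
#' @param rng_seed integer seed; the ensemble is deterministic given it.
#' @return object of class `modmap_surrogate`, a `modmap_patterns` with the
#'   extra fields `transforms` (tibble) and `rng_seed`.
#' @export
make_surrogate_ensemble <- function(pset, rng_seed) {
  stopifnot(inherits(pset, "modmap_patterns"))
  d <- dim(pset$patterns)
  if (d[1] < 2) stop("surrogate ensemble requires at least 2 patterns")
  tr <- draw_surrogate_transforms(d[1], rng_seed)
  idx <- which(pset$roi_ds, arr.ind = TRUE)
  ctr <- c(mean(idx[, 1]), mean(idx[, 2]))
  A <- patterns_as_matrix(pset)
  outm <- matrix(NA_real_, d[1], d[2] * d[3])
  # one interpolation table per distinct transform, applied to all its
  # patterns at once
  key <- paste(tr$angle_deg, tr$flip_x, tr$flip_y)
  for (kk in unique(key)) {
    rows <- which(key == kk)
    i <- rows[1]
    map <- build_transform_map(d[2], d[3], pset$roi_ds, tr$angle_deg[i],
                               tr$flip_x[i], tr$flip_y[i], ctr)
    outm[rows, ] <- apply_transform_map(A[rows, , drop = FALSE], map)
  }
  out <- array(outm, d)
  res <- pattern_set(out, pset$roi_ds, pset$pixel_um_ds,
                     pset$s_low_um, pset$s_high_um)
  res$transforms <- tr
  res$rng_seed <- as.integer(rng_seed)
  class(res) <- c("modmap_surrogate", class(res))
  res
}
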