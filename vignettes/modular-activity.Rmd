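---
title: "Quantifying modular spontaneous activity in wide-field calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying modular spontaneous activity in wide-field calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modmap)
```

## The measurement problem

Wide-field calcium imaging of developing cortex records fluorescence movies
(typically ~15 Hz, a few millimetres of cortex at ~20 µm/px) in which
spontaneous activity arrives as sparse, large **events**: brief episodes in
which patches of cortex about a millimetre apart light up together. Three
families of statistics characterise this organisation:

1. **per-event geometry** — the spacing of the active patches (wavelength),
   the regularity of that spacing (modularity), and how strongly modules
   stand out over the surrounding tissue (module amplitude);
2. **network structure** — seed-point correlation fields across events, and
   the strength of correlations at millimetre distances relative to a
   surrogate null;
3. **complexity** — the effective (linear) dimensionality of the repertoire
   of event patterns.

`modmap` implements this chain end to end, plus a synthetic-movie generator
with exact ground truth, so that each stage carries a parameter-recovery
test.

## Preprocessing

Registration is translation-only phase correlation against a temporal-median
reference frame. The recordings this pipeline targets are head-fixed, so
rotation is assumed negligible; the registration contract is checked by
applying known shifts to synthetic frames and recovering them.

The baseline `F0` of each pixel is a running median of its trace with a
window of `window_s` seconds. `window_s` is a per-session parameter
constrained to 10–64 s (the range in which a median removes calcium
transients, which last ~1–3 s, while following slow drift); the default is
30 s, the midpoint. Edge frames use truncated (shrinking) windows rather
than reflected data — reflection would fabricate pre-recording samples. The
cost is a bias over the first and last half-window wherever the trace has
slope there; the package's own fidelity tests therefore assert baseline
accuracy on the interior and treat the edges as undefined-quality.
`ΔF/F = (F − F0)/F0` is exact arithmetic; nonpositive baselines inside the
ROI are an error naming the offending pixel.

## Event detection

**Pixel thresholds.** The default (`gaussian3sd`) fits a Gaussian to the
sub-transient bulk of each pixel's ΔF/F histogram and thresholds at
`µ + 3σ`. Two details are deliberately pinned down:

- *Bin width*: Freedman–Diaconis computed on the sub-threshold bulk
  (samples below median + 3·MAD). Computing it on the full trace lets rare
  large transients inflate the inter-quartile range until the noise bulk
  spans only two or three bins and the fit degenerates.
- *Truncation*: the data entering the fit are cut at 1.5 times the mode's
  **bin position**, counted from the histogram's left edge. For a Gaussian
  bulk this lands roughly 2 SD above the mode, excluding transients. The
  alternative reading — 1.5 times the mode's ΔF/F *value* — is degenerate
  for baseline-corrected traces: whenever the mode is at or below zero
  (common, because baseline leakage between events biases ΔF/F slightly
  negative) it would cut into the bulk itself. On realistic synthetic
  movies the value rule made over half of all pixels fall back to the
  robust median/MAD estimate; the position rule makes the fit succeed
  essentially everywhere while leaving the recovery tests
  (σ of N(0, 0.05) noise within 10%, contamination-resistant) unchanged.
- The fit itself is weighted least squares of a log-parabola on the bin
  counts (weights = counts²), a closed form that approximates least squares
  on the counts; if the retained histogram is non-concave or too sparse the
  pixel falls back to median/MAD with a warning.

`percentile80` (threshold = each pixel's 80th percentile) is provided for
recordings whose ΔF/F distributions are too broad for the Gaussian fit; the
acceptance suite checks that switching methods moves median wavelength and
modularity by less than 15%.

**Spatial criteria.** Active pixels not in an 8-connected component of at
least 0.01 mm² are discarded (at 22 µm/px that is 21 px: `ceil(10^4/484)`),
and a frame is active only when the *cleaned* active fraction within the ROI
strictly exceeds 40%. 8-connectivity is the permissive standard for blob
area; the strict inequality makes the boundary case deterministic. The
cleaning-before-fraction order is a choice the source description leaves
open; it is the conservative one (noise pixels cannot push a frame over the
criterion).

**Segmentation.** Maximal runs of active frames become events; a run with an
interior strict local minimum of the ROI-mean activity is split there, the
minimum frame ending the earlier event (plateau minima resolve to the last
frame of the plateau, again for determinism). Each event is represented by
its frame of highest ROI-mean activity.

## Filtering and pattern metrics

Event frames are band-pass filtered with a difference of Gaussians,
`G(30 µm) − G(195 µm)` by default, each blur ROI-normalised (blur of the
masked frame divided by the blur of the mask) so no values bleed across the
ROI border, then block-averaged down by an integer factor (the classical
geometry 640×540 → 160×135 is factor 4).

The **radial autocorrelation** is computed with FFTs on the masked pattern:
only pixel pairs with both ends in the ROI contribute, each lag is
normalised by its pair count, annuli are pair-count-weighted, and the
profile is 1 at zero lag. A brute-force all-pairs loop is kept in the test
suite as the oracle (agreement to 1e−8 on 32×32 crops, including a
non-rectangular ROI).

**Wavelength** is twice the radius of the profile's first interior local
minimum, found after a 3-bin moving average (bin width = one pixel of the
filtered grid); plateaus resolve to the smallest radius. **Modularity** is
the absolute difference between the profile at the next local maximum and at
that minimum. Profiles with no interior minimum, or no subsequent maximum,
are flagged invalid rather than given a number. One geometric point deserves
emphasis: for an isotropic pattern with a narrow ring spectrum at frequency
`f0`, the radial autocorrelation is a Bessel `J0(2π f0 r)`, so the first
minimum sits at `r = j_{1,1}/(2π f0)` (`j_{1,1} ≈ 3.83`), *not* at half the
spectral period `1/(2 f0)`. The wavelength reported here is the operational
one — twice the first-minimum radius — which is how the quantity is defined
throughout this literature; naive plane-wave intuition (first minimum at
half the period) is off by ~22% for isotropic fields and holds only at the
level of the 1-D profile itself.

**Module amplitude** works on the raw (unfiltered) event frame: local maxima
of a Gaussian-smoothed copy (SD 2 px) over a disk of radius a quarter
wavelength, with two guards that the original peak-finder leaves
unspecified: a minimum prominence of twice the pixel-noise SD (estimated as
the MAD of frame minus smoothed frame) above the ROI median, and the
requirement that the whole detection disk lie inside the ROI (clipped
neighbourhoods at the ROI border otherwise produce spurious boundary
maxima). Each peak's raw ΔF/F is divided by the median raw ΔF/F over an
annulus at half the experiment-mean wavelength (half-width one filtered-grid
pixel, 4 px at default geometry); nonpositive backgrounds exclude the peak
with a warning. The event value is the mean over peaks.

**Modularity significance** compares the observed median event modularity
against 100 control sets drawn from the bottom 10% (by ROI-mean activity) of
non-event frames, each control frame passed through the identical filtering
and autocorrelation path; invalid control profiles count as zero modularity
(no modular structure). The p-value is one-sided — the hypothesis is that
events are *more* modular than quiet frames — with a +1/(n+1) continuity
correction so p is never exactly zero. Because control sets are bootstrap
samples from a finite pool, the test is slightly anti-conservative when the
pool is tiny; calibration tests use movies long enough (~100 s) that the
pool holds >100 frames, which is the realistic regime.

## Correlation fields, surrogates, and network metrics

The correlation field of a seed `s` is the Pearson correlation, across the N
band-passed patterns, between activity at `s` and at every ROI location.
Correlations are computed over the intersection of pixels defined in all
patterns; undefined locations propagate as missing, never as zero.

The null ensemble rotates each pattern independently about the ROI centroid
by a uniform multiple of 10° and reflects it about the x- and/or y-axis with
probability ½ each, destroying the spatial relationships *between* patterns
while preserving single-pattern statistics. Interpolation is bilinear;
output pixels whose pre-image falls outside the ROI are missing rather than
zero-filled (zero-fill would deflate surrogate variance). Right-angle
rotations and reflections on symmetric supports are exact resamplings, which
the tests exploit for histogram-preservation checks. On non-circular ROIs
some support is necessarily lost under rotation, which slightly *inflates*
surrogate correlation noise (fewer defined pixels), making the significance
test conservative; calibration tests use disc ROIs, where rotations are
support-preserving.

**Long-range correlation strength** is the variance of `C(x, s)` over ROI
pixels 1.8–2.2 mm from the seed, averaged over every usable seed (any ROI
pixel whose ring intersects the ROI; a stride parameter thins the seed grid
for speed without changing the estimand). To control for the finite number
of events, the statistic is computed from a fixed number of patterns
(default 100, resampled with replacement and flagged when fewer exist) and
compared against surrogate ensembles of matched size; `p` is the fraction of
surrogate variances at least as large, and both raw values plus their
difference are reported (the difference is the headline "corrected"
strength — the source is not explicit on this point, so both components are
always emitted).

**Cross-validated dimensionality** splits each subset of 100 events into
disjoint halves, fits PCA axes on one half restricted to a circular region
of area `0.5 Λ²` (Λ = median event wavelength; the region sits at the ROI
centroid by default), measures the variances `λ_i` of the held-out half
projected on those axes, and reports the participation ratio
`(Σλ_i)²/Σλ_i²`, averaged over 10 subsets. Cross-validation keeps
noise-only directions from inflating the estimate: held-out variance along
axes that fit noise is flat, and the participation ratio discounts it.

A caveat that the design makes explicit: the prescribed region has radius
`≈ 0.4 Λ`, smaller than one wavelength, so the restriction of globally
orthogonal component fields to the region is strongly collinear — the
number of generating components is not identifiable there by any estimator,
and `d_eff` reads as *local* dimensionality. The estimator is therefore
validated two ways: monotone recovery (median `d_eff` strictly increasing in
the true component count over 1–10) with the standard region, and absolute
recovery within ±30% with a `region_radius_mm` override spanning several
wavelengths. Rank-completeness against an explicit eigendecomposition oracle
is asserted to 1e−8.

## The synthetic generator

The generator is a first-class module, not a test fixture. It emulates the
stated recording conditions: 15 Hz movies over ~3 mm of cortex, sparse large
events on a slowly drifting baseline with i.i.d. pixel noise, event patterns
drawn from a low-dimensional set of spatial components with millimetre-scale
structure. Its defaults are the stated world of all recovery tests:
wavelength 1 mm, 5 components, event weights i.i.d. normal with SD 0.05
ΔF/F (rectified event peaks ≈ 0.3 ΔF/F, matching large spontaneous events),
pixel noise SD 0.01 ΔF/F, drift amplitude 0.02 with periods ≥ 30 s (so a
10–64 s median baseline can remove it), a 2-frame linear rise and 1 s
exponential decay kernel (GCaMP6s-like, the source does not specify one).

Component fields are white noise filtered with a narrow Gaussian *ring* of
spatial frequencies (relative bandwidth 0.1) at carrier
`f0 = j_{1,1}/(π λ)`, then orthogonalised and z-scored. The ring rather
than a difference-of-Gaussians band-pass is a deliberate design decision:
the measured wavelength is defined through the first autocorrelation
minimum *after* the analysis band-pass, and a DoG-filtered field — whose
relative bandwidth is constant, no matter the ratio of its two SDs — gets
tilted by the analysis filter enough to shift that minimum by ~15%. A
narrow ring is rescaled almost uniformly by any smooth filter, and the `J0`
calibration above puts the first minimum exactly at `λ/2`; measured
recovery bias is ~4% across 0.6–1.2 mm, within the 10% contract. What the
generator does **not** emulate: hemodynamic contamination, photobleaching,
non-rigid motion, spatially correlated noise, and biophysical indicator
kinetics. A green recovery test therefore certifies the analysis chain's
correctness on its stated model, not robustness to those artifacts.

## Numerical and reproducibility choices

- All randomness flows from one configured seed; stages derive sub-seeds via
  a documented mixing function (`derive_seed`), so stages re-run in
  isolation reproduce the pipeline's draws. Re-running a pipeline with the
  same config yields byte-identical tables.
- Autocorrelation and registration use padded FFTs; correlation matrices use
  a standardised cross-product (BLAS) with missing-pixel columns excluded.
- Ties and plateaus (local minima in segmentation, extrema on radial
  profiles) have fixed, documented resolutions so results never depend on
  evaluation order.
- The events-per-subset and surrogate counts are parameters with the
  field-standard defaults (100 each); tests use smaller values where only
  calibration, not absolute scale, is at stake — a p-value from n
  surrogates can never be below 1/(n+1), so any test requiring significance
  at 0.05 uses at least 20.

## Known limitations

- Registration is integer-pixel and translation-only.
- The HDF5/TIFF interchange formats common in this field are not read or
  written here (no R-side readers were available in the build environment);
  movies enter as in-memory arrays (or RDS via the CLI wrapper), and run
  outputs are CSV/JSON.
- Module-amplitude peak detection has two unspecified-by-the-source
  parameters (smoothing SD, prominence floor) fixed at documented defaults;
  sensitivity to them is not asserted by the tests.
- The modularity bootstrap inherits mild anti-conservatism on very short
  recordings (small control pools); this is a property of the procedure, not
  of the implementation.
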