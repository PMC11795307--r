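# modmap

Analysis of modular spontaneous activity in wide-field calcium imaging of
developing cortex.

In the developing brain, spontaneous (not stimulus-driven) activity is
organised into **modular patterns**: patches of co-active cortex roughly a
millimetre apart, correlated over several millimetres, and drawn from a
low-dimensional repertoire of spatial motifs. `modmap` implements the full
quantitative pipeline used to characterise such activity in wide-field
GCaMP movies:

- **Preprocessing** — rigid (translation) registration by phase correlation,
  per-pixel baseline `F0` as a running median over a 10–64 s window, and
  baseline-corrected activity `ΔF/F = (F − F0)/F0`.
- **Event detection** — per-pixel thresholds (a Gaussian fitted to the
  sub-transient bulk of each pixel's ΔF/F histogram, threshold `μ + 3σ`; or
  the pixel's 80th percentile), then spatial criteria: active pixels must
  form contiguous regions of ≥ 0.01 mm², and a frame is active when > 40% of
  ROI pixels are active. Consecutive active frames form events, split at
  interior local minima of the ROI-mean activity; each event is summarised by
  its maximally active frame.
- **Pattern metrics** — each event frame is band-pass filtered with a
  difference of Gaussians (SDs `s_low` = 30 µm, `s_high` = 195 µm, masked to
  the ROI). The **wavelength** Λ is twice the radius of the first minimum of
  the radially averaged spatial autocorrelation; **modularity** is the
  trough-to-peak amplitude between that minimum and the next maximum;
  **module amplitude** is the raw-frame peak ΔF/F divided by the median
  background ΔF/F half a wavelength away. Modularity is tested against 100
  bootstrap sets of quiet control frames.
- **Network metrics** — seed-point correlation fields
  `C(x, s) = corr_i(A_i(x), A_i(s))` across the `N` band-passed patterns
  `A_i`; **long-range correlation strength** as the variance of `C` in a
  1.8–2.2 mm ring around each seed, compared against ensembles of randomly
  rotated/reflected surrogate patterns of matched size (100 events);
  **effective dimensionality** as the participation ratio
  `d_eff = (Σλ_i)² / Σλ_i²` of cross-validated PC variances (axes from one
  half of the events, variances from the held-out half, within a circular
  region of area `0.5 Λ²`).
- **Synthetic data** — a ground-truth generator (band-limited component
  fields with calibrated wavelength, sparse events with a GCaMP-like
  temporal kernel, slow drift, pixel noise) so every stage has a
  parameter-recovery test without external recordings.

## Worked example

```r
library(modmap)

# 1. simulate a 60 s recording: 48x48 px at 66 um/px (~3.2 mm field),
#    15 Hz, 12 modular events with a 0.9 mm wavelength from 4 components
truth <- simulate_ground_truth(shape = c(48, 48), pixel_um = 66,
                               wavelength_mm = 0.9, k = 4, n_events = 12,
                               n_frames = 900, rng_seed = 1)
syn <- synthesize_movie(truth)
roi <- roi_mask(matrix(TRUE, 48, 48), pixel_um = 66)

# 2. baseline, dF/F, event detection
f0  <- compute_baseline(syn$movie, window_s = 30)
dff <- compute_dff(syn$movie, f0, roi)
events <- detect_events(dff, roi, method = "gaussian3sd")
#> <modmap_events> 12 events over 250 active frames

# 3. per-event wavelength, modularity, module amplitude
met <- event_metrics(events, roi)
median(met$wavelength_mm)     # 0.924  (truth: 0.9 mm)
median(met$modularity)        # 0.581
median(met$module_amplitude)  # 2.09   (peak dF/F over background)

# 4. modularity against quiet-frame controls
modularity_significance(met$modularity[met$valid], dff, events, roi,
                        rng_seed = 2)
#> <modmap_modsig> observed median 0.5809 vs 100 controls, p = 0.0099

# 5. long-range correlation strength vs rotation/reflection surrogates
pset <- build_pattern_set(events$frames_raw, roi)
corrected_long_range_strength(pset, n_use = 12, n_surrogates = 20,
                              ring_mm = c(1.4, 1.8), rng_seed = 3,
                              seed_stride = 2)
#> <modmap_corrstrength> ring 1.4-1.8 mm: real 0.2721, surrogate 0.1133, p = 0.0476 *

# 6. cross-validated dimensionality of the event patterns
cross_validated_dimensionality(pset, median(met$wavelength_mm[met$valid]),
                               n_subsets = 5, subset_size = 12, rng_seed = 4)
#> <modmap_dimensionality> d_eff = 2.895 (mean of 5 subsets, region 97 px)
```

The detected events recover the generator's ground truth: the wavelength
estimate (0.924 mm) is within 3% of the nominal 0.9 mm, events are
significantly more modular than quiet frames, long-range correlations exceed
the surrogate null, and the dimensionality is low, reflecting the small
number of underlying components visible within the analysis region.

`run_pipeline()` chains all stages on one movie and writes CSV tables, a
JSON manifest and a log into a run directory; `aggregate_runs()` collects
many runs into a one-row-per-experiment table ready for group-level
statistics. A thin command-line wrapper lives at `inst/cli/modmap.R`
(subcommands `simulate`, `run`, `aggregate`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates a synthetic movie from the given seed, runs the installed
package's full pipeline end to end (baseline → detection → metrics →
significance → correlation strength → dimensionality), prints a one-line
summary, and writes the JSON report to `--out`.
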