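# numprf

Population receptive field (pRF) modelling of numerosity-tuned fMRI
responses.

Parietal, occipital and frontal cortex contain topographic *numerosity
maps*: patches of cortex where the preferred set size of neural
populations changes gradually along the surface, with disproportionate
surface devoted to small counts (cortical magnification) and tuning that
broadens as the preferred numerosity grows. `numprf` is a reusable,
tested implementation of the full analysis chain used to characterise
such maps from blocked numerosity-sweep experiments, for researchers who
want to run, validate, or simulate this style of analysis without a
proprietary toolchain.

## What it computes

Each recording site is modelled as a Gaussian in logarithmic numerosity
space,

    r(n) = exp( -(log2 n - log2 p)^2 / (2 sigma^2) ),

with preferred numerosity *p* and tuning width *sigma* (log2 units; also
reported as linear FWHM `p * (2^h - 2^-h)`, `h = sqrt(2 ln 2) * sigma`).
Predicted neural trains follow the 650 ms presentation cycle of the
block design (TR 1950 ms, 182 volumes, 2 TRs per numerosity step, 15.6 s
baseline blocks, 4 cycles), are convolved with a two-gamma HRF, and
compared to voxel time series by exhaustive grid search with per-candidate
least-squares gain/baseline; sites are kept when variance explained
exceeds 30% and the estimate falls inside the presented range. On top of
the fits the package quantifies:

* the **numerosity progression** along the map (log2 preference vs
  cortical border distance; bootstrap CI, permutation test),
* the **tuning-width scaling** with preferred numerosity (SE-weighted
  linear fit on 0.25-wide bins),
* the **small vs large range comparison**: Pearson correlation with
  effective-n correction and the percentage deviation `(slope - 1)/9.5`
  of the large-on-small regression from the unity line (0 = identical,
  1 = the extreme calibration line y = 10.5x - 9.5),
* **split-half cross-validation** within and across stimulus ranges
  (cvR², repeated-measures ANOVA),
* plus a **synthetic-data generator** (ground-truth maps, noise models,
  heterogeneous mixture voxels) so every stage is testable closed-loop.

## Worked example

Simulate a magnified ground-truth map, analyse it end to end, and compare
against the generator:

```r
library(numprf)

design   <- build_sequence(range_spec("large"), scan_protocol(), seed = 1)
timeline <- events_to_timeline(design)
map      <- make_ground_truth_map(seed = 7)            # 120 sites, 1..64, 16 mm
sim      <- simulate_experiment(map, list(large = timeline), n_runs = 8, seed = 11)

fits <- fit_voxels(sim$mean_bold$large, timeline)      # 8-run mean, grid search
sel  <- select_sites(fits)                             # r2 > 0.30 and in range
geom <- site_geometry(map$roi)

bins <- bin_by_distance(fits$preferred[sel], geom$distance_mm[sel], width = 2)
pf   <- progression_fit(bins, seed = 2)
fw   <- vapply(which(sel), function(i)
          fwhm_linear(tuning_params(fits$preferred[i], fits$width_sigma[i])), 1)
wf   <- width_vs_preference(fits$preferred[sel], fw, seed = 3)
```

This prints, via the summaries above:

```
114 of 120 sites selected (r2 > 0.30, in range); mean R2 = 0.50
progression: 0.349 log2-units/mm (95% CI 0.316..0.392, p = 0.0001); truth 0.375
width law: slope 2.00 (95% CI 1.66..2.25, p = 0.0001); truth 2.00
```

Read: at realistic noise (contrast-to-noise 2, eight averaged runs) 95%
of sites pass selection; the fitted exponential progression of preferred
numerosity along the cortical axis recovers the generator's magnification
slope within its bootstrap CI (the permutation p is at its floor,
1/10001); and the linear increase of tuning width with preferred
numerosity is recovered essentially exactly.

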