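---
title: "Numerosity pRF modelling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Numerosity pRF modelling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numprf)
```

## The model

`numprf` analyses fMRI responses of numerosity-tuned neural populations with
a population receptive field (pRF) forward model. Each recording site
(voxel) is summarised by a Gaussian tuning function in logarithmic
numerosity space:

$$ r(n) = \exp\!\left(-\frac{(\log_2 n - \log_2 p)^2}{2\sigma^2}\right), $$

where $p$ is the preferred numerosity (the dot count eliciting the maximal
response) and $\sigma$ the tuning width in log2-numerosity units. All
log-space computation in the package uses base 2: numerosity doublings are
the natural unit, and any fixed base is equivalent up to a rescaling of
$\sigma$, so the choice is recorded once here to keep fitted $\sigma$
values interpretable. Tuning width is reported either as the log2 FWHM,
$2\sqrt{2\ln 2}\,\sigma$, or as the linear FWHM
$p\,(2^h - 2^{-h})$ with $h = \sqrt{2\ln 2}\,\sigma$ — the span in dot
counts between the two half-maximum points. The linear form is the default
for the width-scaling analysis because voxels tuned to 2 with wide
populations have linear widths near 10, which is the scale on which the
width increase with preference is usually plotted.

The neural response train evaluates $r(n)$ at every 300 ms dot
presentation and is zero during the 350 ms blanks (an event-train model;
the alternative, a response sustained across each 2-volume block, yields
nearly identical predictions after hemodynamic blurring). The train is
convolved with a canonical two-gamma hemodynamic response function and
sampled at volume onsets (0-based). The HRF is parameterised so the stated
peak (6 s) and undershoot (16 s) delays are the exact kernel modes
(dispersions 1 s, undershoot ratio 1/6), and the kernel is normalised to
unit sum so a sustained unit drive plateaus at 1 — the fitted gain then
reads as a BOLD amplitude and the simulation's contrast-to-noise ratio
(gain / noise SD) is well defined. Per-participant HRF estimation is out
of scope.

## The stimulus design

The generated runs reproduce the standard numerosity-mapping block design:
repetition time 1950 ms, 182 volumes per run (354.9 s), the first 6
volumes (11.7 s) discarded. Each main numerosity occupies two volumes
(3900 ms) as six 650 ms presentation cycles; mains sweep in ascending
order, a 15.6 s baseline block follows, then the descending sweep and a
second baseline, and the whole cycle repeats four times, exactly filling
the 176 retained volumes. Built-in ranges: small (1–7 dots, baseline 20),
large (baseline 512), and a large-only control (8–64, baseline 512). The
exact membership of the large range is not fixed by the printed design, so
the default takes the seven octave-spaced values 1, 2, 4, 8, 16, 32, 64 —
the unique 7-element choice that preserves the same cycle arithmetic as
the small range; it is configurable through `range_spec()`. The
large-control set 8, 16, 32, 64 is padded by even repetition over the
seven ascending slots at build time. 10% of presentations are white-dot
attention catch trials; they affect only the rendered colour and never the
neural model. Baseline blocks cycle fresh random dot layouts like main
blocks. Dot patterns hold the total surface area constant across
numerosities (each dot has radius $\sqrt{A/(n\pi)}$) inside the central
4° aperture, placed by seeded rejection sampling with a hard attempt cap.

## Fitting

Candidate preferred numerosities are spaced at 1/8 octave over
$[2^{-2}, 2^{8}]$ — deliberately far beyond both presented ranges, so that
estimates inside the stimulus range are not merely the best of a limited
set — and widths over $[0.05, 8]$ in 30 log steps. For every candidate the
gain and baseline are solved by ordinary least squares and the candidate
minimising the residual sum of squares is returned; ties break toward
smaller preferred numerosity, then smaller width. Because the neural train
is a linear combination of per-numerosity indicator trains, all candidate
predictions come from one small convolved regressor matrix, which makes
the exhaustive search cheap. Candidate scores are computed as squared
correlations on peak-normalised columns: this is algebraically identical
at ordinary scales and remains exact for candidates whose predicted
response has underflowed toward the denormal floating-point range (very
narrow tuning far outside the presented values). Negative-gain optima are
flagged unfittable — a tuned model with negative amplitude is not a
numerosity-selective response. An optional Nelder–Mead refinement polishes
the grid optimum continuously over $(\log_2 p, \log \sigma)$ and is
accepted only if it does not lower variance explained; it is off by
default and matters only when effects smaller than the grid step are of
interest (see the heterogeneity section).

Sites are selected when variance explained exceeds 30% *and* the preferred
numerosity lies within the presented range; out-of-range estimates are
produced, never clipped, and then excluded. The eight runs per condition
are averaged before the main fit; cross-validation fits the odd-run and
even-run means (1-based acquisition order) per condition, freezes the
tuning parameters of the predictor half, re-solves only gain and baseline
on the test half (the strictest reading of extracting a model prediction
and fitting it to other data), and scores the cross-validated variance
explained. Within-condition validation gives two iterations per condition;
cross-condition validation lets each half predict both halves of the other
condition, eight iterations in total. Voxels enter the comparison when
they pass threshold in every half with preferred numerosity in the range
common to both conditions (1–7).

## Map geometry and statistics

Maps live on a flattened 2-D surface patch; distances are Euclidean in the
patch plane (the analysis context is a smoothed flattened surface;
geodesic distance on folded meshes is a possible extension, not needed for
the rectangular fixtures). Each site's distances to the low- and
high-preference border polylines give the normalized position
$u = d_{low}/(d_{low}+d_{high})$, scaled by the mean ROI length (mean over
sites of $d_{low}+d_{high}$) into a cortical distance. Binning is
left-closed from 0 with 2 mm (distance) or 10% (normalized) bins; empty
bins are dropped and standard errors are over sites within a bin.

The numerosity progression is fitted as $\log_2(\text{preference})$ linear
in cortical distance — an exponential progression, which is the reading of
a "logarithmic" magnification consistent with more cortical surface for
small numerosities (the alternative, preference linear in log distance, is
not used). Fits are summarised by the median slope and intercept over 1000
bootstrap resamples of the bins, a 2.5–97.5 percentile envelope, and a
one-sided permutation test (10,000 reorderings of the distance bins;
$p = (c+1)/(n_{perm}+1)$, so p-values are floored at $1/(n_{perm}+1)$ and
never exactly zero). On noiseless fixtures every bootstrap fit coincides,
so the intervals have zero width by construction. The tuning-width
analysis bins widths by preferred numerosity in 0.25-wide bins and fits a
line to the bin means weighted by inverse standard error; singleton bins
carry no weight and are dropped. The fit uses each bin's mean preferred
numerosity as abscissa (rather than the nominal bin centre) so that an
exactly linear width law is recovered exactly.

The small-versus-large comparison takes sites selected in both conditions,
correlates the paired preferences (Pearson), computes the correlation
probability at an effective sample size reduced by the factor by which
functional voxels were up-sampled onto the surface, and fits an ordinary
least-squares line (with intercept — the extreme calibration line
$y = 10.5x - 9.5$ implies a fitted intercept; total least squares was
considered and not adopted as the calibration is defined for OLS). The
slope is mapped to the percentage deviation $(p-1)/9.5$: 0 on the unity
line, 1 on the line sending the small-range extremes (1, 7) onto the
large-range extremes (1, 64). Group inference on a map-by-participant
table of deviations uses a two-sided Wilcoxon signed-rank test against
zero (normal approximation, z reported), a two-way ANOVA over map and
participant factors, and Bonferroni-corrected pairwise participant
comparisons. The within/cross-condition cross-validation comparison uses
a repeated-measures ANOVA with subject as the error stratum.

## The synthetic-data generator

`make_ground_truth_map()` builds a rectangular patch (default 120 sites,
16 mm × 4 mm, an NTO-like scale) whose preferred numerosities are
exponential in axial position between 1 and 64 — equal log steps occupy
equal cortex, so linear steps occupy shrinking cortex, the cortical
magnification signature. Widths follow a linear law in linear FWHM units,
default $\mathrm{FWHM} = 6 + 2\,p$, chosen to give FWHM 10 at a preferred
numerosity of 2 — the scale seen in wide population tuning. Noise is white
Gaussian by default with SD 0.5 per run against a unit gain
(contrast-to-noise 2); an AR(1) option (ρ = 0.3) adds temporal
autocorrelation for realism. These are exercise parameters, not claims
about scanner noise. All randomness flows through a single seed and every
fixture reproduces byte-for-byte.

What the generator emulates: tuned responses under the exact block
designs, run-to-run noise independence, magnified topography, width
scaling, and optional within-voxel heterogeneity. What it does not:
scanner drift, physiological noise, spatial noise correlations, motion,
and the folded 3-D geometry of real cortex. Passing the closed-loop tests
therefore demonstrates that the estimation and statistics recover what the
forward model encodes at realistic noise levels — not that real data meet
the model's assumptions.

Problem sizes used in the shipped tests (maps of 40–120 sites, 8 runs,
200-voxel recovery sets, 200-seed calibration loops, 1000 bootstrap and
up to 10,000 permutation iterations) were chosen so the whole suite
completes in about a minute while keeping every statistical check
well-powered at its stated tolerance.

## Heterogeneous voxels: what the simulation shows

A recording site contains on the order of $2.5\times10^5$ neurons, so the
package can model a voxel as $k$ sub-populations with preferred
numerosities drawn log-normally (SD `spread_log2`) around the voxel
centre, equal gains, summed linearly. Two properties of this model are
worth stating plainly, because they shape what the tests can honestly
claim.

First, the population limit is degenerate: a log-normal mixture of
log-Gaussian tuning curves with shared width and equal gains converges, as
$k \to \infty$, to *exactly* a log-Gaussian with width
$\sqrt{\sigma^2 + \mathrm{spread}^2}$ (a Gaussian convolution in log
space). A perfectly symmetric aggregate is fitted identically under any
stimulus range, so heterogeneity of this simplest form produces *no*
systematic difference between small-range and large-range estimates; at
finite $k$ the difference is a zero-mean fluctuation of the sub-population
draw (verified over hundreds of seeds). Sub-grid effects of this kind are
only resolvable at all with the continuous refinement stage, since they
are far below the 1/8-octave grid step.

Second, a reproducible positive deviation *does* emerge once mixture
voxels are run through the complete estimation procedure — noise,
30%-variance-explained thresholding, and the in-range criterion applied in
both conditions. The selection ceilings are asymmetric (7 dots in the
small range, 64 in the large), so near the top of the common range the
small-range estimates are truncated while the large-range estimates run
free, tilting the fitted relation above the unity line. The shipped
demonstration reproduces a small positive median percentage deviation
across seeds through exactly this mechanism. The heterogeneity spread is a
free parameter swept in tests; no particular biological value is asserted.

## Known limitations

* Geodesic distances on curved patches are not implemented; geometry is
  Euclidean in the 2-D patch plane.
* The per-presentation event-train convention and the volume-onset
  sampling convention are fixed rather than configurable; both choices are
  stated above and covered by tests.
* The percentage-deviation group ANOVA treats map and participant as
  crossed fixed factors (no interaction term, matching a complete
  one-observation-per-cell table).
* Tuning-width estimates are intrinsically noisy where the design carries
  little width information (very narrow or very wide populations); the
  width analysis weights bins by inverse standard error partly for this
  reason.
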