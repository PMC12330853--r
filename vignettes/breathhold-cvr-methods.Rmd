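---
title: "Breath-hold CVR mapping with lagged GLMs: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath-hold CVR mapping with lagged GLMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bholdcvr)
```

## The problem

Cerebrovascular reactivity (CVR) is the capacity of cerebral vessels to
dilate in response to a vasoactive stimulus, quantified here as the percent
BOLD signal change per mmHg of end-tidal CO2 (PetCO2) change. A breath-hold
(BH) task raises arterial CO2 transiently; voxels with healthy vasculature
respond with a delayed, dispersed BOLD increase. `bholdcvr` implements the
full desk-scale analysis: capnograph processing, construction of candidate
BOLD signal models, voxelwise fitting with per-voxel hemodynamic lag
optimization, and derivation of CVR and relative-lag maps, together with a
synthetic-data generator that makes every stage testable against known
ground truth.

## Signal models

Six models arise from crossing two regressor types with three convolution
schemes:

* **PetCO2**: the processed end-tidal CO2 trace itself, the physiological
  stimulus proxy;
* **Block**: a boxcar depicting the hold intervals, usable when CO2
  recordings are poor;

each used **without convolution (WoC)**, **convolved with a single-gamma
HRF (CSg)**, or **convolved with a double-gamma HRF (CDb)**.

The HRF is a Gamma density with shape $p_1/p_3$ and scale $p_3$ seconds;
the double-gamma subtracts a second Gamma (shape $p_2/p_4$, scale $p_4$)
divided by the amplitude ratio $p_5 = 6$. Delay and dispersion are coupled:
$p_3 = p_1/6$, $p_2 = (8/3)\,p_1$, $p_4 = p_3$, with $p_1$ on a 3–11 s grid
in 1 s steps (9 kernels per shape, 18 in the default bank). Note that with
this parametrization the mode of the positive lobe sits at $p_1 - p_3$, not
at $p_1$; the kernels follow the formula, not the label "time to peak".

Two kernel choices are the package's own, since they are conventionally
left unstated:

* **support 32 s, dt 0.1 s** — the longest undershoot (p2 = 88/3 s for
  p1 = 11) fits inside the support;
* **unit-sum normalization** — convolution then has DC gain 1, so a
  sustained response keeps the regressor's amplitude and the regression
  coefficient (hence CVR) stays comparable across delays.

## From capnograph to ΔPetCO2

The raw CO2 trace is shifted by the sampling-tube delay, end-tidal peaks
are detected (local maxima with topographic prominence of at least a
quarter of the trace's interquartile range, separated by at least 2 s — the
prominence criterion rejects cardiogenic ripples), interpolated with a
shape-preserving piecewise cubic onto a 0.1 s grid, and detrended with an
order-2 Butterworth high-pass at 1/100 Hz run forward–backward (a best-fit
line is removed first to suppress edge transients; the mean is re-added
because ΔPetCO2 must stay in absolute mmHg). A 0.1 s grid is used rather
than a sub-breathing-rate resampling: the grid must resolve individual
end-tidal peaks.

ΔPetCO2 is, per trial, the first end-tidal peak within 20 s after the hold
minus the mean end-tidal value over the preceding baseline, averaged over
trials. The baseline window excludes the first 12 s after the previous hold
(`recovery_exclude`): the elevated recovery breaths belong to the previous
trial's response, and including them would bias the next baseline upward —
with a single elevated recovery breath, exclusion makes the noiseless
generator exactly invertible (per-trial ΔPetCO2 equals the configured
increase).

## Voxelwise lagged GLM

For each model, a **bulk lag** is estimated first: the shift in
[−15, +15] s (1 s steps) maximizing the correlation between the GM mean
BOLD series and the regressor. The voxelwise grid is then the bulk lag ± 9 s
in 1 s steps — 19 candidates. A 1 s step is used throughout; finer steps
mainly add temporal resolution, not accuracy.

Per voxel and candidate lag, ordinary least squares is fitted on
[intercept | regressor | confounds], the confounds being the 24 extended
motion parameters (6 parameters, backward-difference derivatives with a
zero first row, and both sets squared) plus one spike column per motion
outlier (RMS difference to the middle volume exceeding Q75 + 1.5 IQR). The
regressor of interest is min–max normalized to [0, 1] *per candidate*
(after shifting and TR-sampling), so the coefficient has a fixed meaning
across lags; whether normalization precedes or follows the shift is
genuinely open, and per-candidate normalization is the documented choice.
The selected lag maximizes the **partial F** of the regressor of interest
(full vs. confounds-only model). Exact F ties — possible in noiseless
synthetic data — resolve to the smallest absolute offset from the bulk lag,
then the more negative lag: the least-shifted explanation wins.

Estimation is OLS by default. A single-pass pooled-AR(1) pre-whitening
(Cochrane–Orcutt with one rho pooled over in-mask voxels) is available
behind `prewhiten = TRUE`; OLS coefficient estimates are unbiased under
autocorrelation and deterministic, so OLS remains the default and the flag
records the gap with packages that pre-whiten routinely.

The **joint voxelwise search over HRF delay and lag**
(`optimize_delay_and_lag`) is provided but discouraged: delay and lag are
strongly interacting, and at realistic noise the estimated delays pile up
at the grid extremes (3 s and 11 s). The acceptance suite reproduces this
saturation qualitatively; it is why delay selection is better made at the
ROI level.

## Maps and summaries

CVR per voxel is the coefficient divided by the voxel's temporal mean
signal and ΔPetCO2, times 100 (%/mmHg). The whole-time-course mean is used
by default; a baseline-only mean changes CVR negligibly since the BH
perturbation of the mean is small. The relative lag subtracts the median
optimal lag over the brain mask (computed before any thresholding); whether
that median should be GM-only or whole-brain is unstated in common
practice, so whole-brain is the default and the mask is an argument. Maps
are thresholded by percentiles — (1, 90) for CVR and (1, 99) for relative
lag, linear-interpolation percentiles with inclusive bounds — which
invalidates extreme voxels without altering values. ROI summaries are
arithmetic means of partial F, CVR and relative lag over valid GM and WM
voxels; across subjects these feed the Friedman test (tie-corrected),
Conover post-hoc pairs ((n−1)(k−1) df, tie-robust through the squared-rank
sum) with Bonferroni correction (0.05/6 ≈ 0.008 for six comparisons,
0.05/3 ≈ 0.017 for three), and a paired sign-flip permutation test (exact
enumeration when 2^n fits the budget) as a desk-scale stand-in for
voxelwise permutation inference, which is out of scope.

## Temporal detrending of the BOLD data

The 100 s high-pass for the 4D data is implemented as a projection:
a linear trend and the demeaned discrete-cosine basis functions with
frequency below 1/100 Hz are regressed out of every voxel series. A
projection is exactly idempotent and preserves the voxel mean exactly
(both matter: the mean normalizes CVR), while a recursive filter
re-attenuates the task band on every pass. When detrending is enabled the
same projection is applied to the design columns before normalization, so
data and model see the same passband and the CVR estimate is not biased by
one-sided filtering. Spatial smoothing (default FWHM 3.5 mm, Gaussian,
separable, reflect boundary so smooth fields keep their mean) is available
but disabled in the recovery analyses below, where it would mix tissues
across the sharp synthetic GM/WM boundary.

## The synthetic-data generator

`make_paradigm()` lays out 4 trials of 15 s end-expiration holds with 30 s
cued baselines; a 59 s lead-in and a 30 s trailing baseline complete the
269 s run (213 volumes at TR 1.26 s). The published protocol states the
total but not its decomposition, so the lead-in is the configurable
remainder.

`simulate_capnograph()` produces an end-tidal peak at each breathing-cycle
end (rate 0.25 Hz by default), a decay to near-zero during holds (no
exhalation, as in real capnography — this is what makes "first peak after
the hold" logic meaningful), and a single recovery breath elevated by the
configured ΔPetCO2 (default 8 mmHg over a 38 mmHg baseline; the achieved
ΔPetCO2 of real subjects is rarely reported, so these are documented
assumptions). Peak times are snapped to the sample grid so noiseless peak
recovery is exact.

`simulate_bold()` applies the forward model per voxel
$y_i(t) = \mu_i\,[1 + a_i\,(x_i(t) - \bar x_i)] + \text{drift} +
\text{motion nuisance} + \varepsilon$, with $a_i = \mathrm{CVR}_i\,
\Delta\mathrm{PetCO2}/100$ and $x_i$ the regressor delayed by the voxel's
true lag, TR-sampled and normalized to [0, 1]. The response is expressed
as a deviation from its temporal mean so that $\mu_i$ equals the nominal
mean signal exactly and the CVR definition is exactly invertible — the
intercept absorbs the centering, so coefficients are unchanged. Drift is a
slow cosine (period 128 s, removable by the 100 s detrend), the motion
nuisance a per-voxel random mix of the six simulated motion parameters,
and noise iid Gaussian scaled to the voxel mean. Default tissue values —
GM 0.45 %/mmHg at −0.2 s, WM 0.20 %/mmHg at +0.2 s, mean signal
7905 ± 130 — sit inside ranges reported for healthy adults and are
reference points, not oracles. Per-voxel lags are truncated Gaussians
inside the searchable range.

What the generator does **not** emulate: EPI/k-space physics, vascular
transit and dispersion differences across vessels, spatially correlated
physiological noise, motion-by-susceptibility interactions, multi-echo
acquisition. Passing recovery tests therefore demonstrates correctness of
the estimator chain, not performance on real data.

## Problem sizes and numerical choices

The validation suite uses sizes chosen to exercise every code path while
staying desk-scale: the exact forward/inverse pair runs on the full
20×20×10 × 213 grid; brute-force GLM equivalence on 50 voxels; stochastic
recovery on 200 GM voxels with three noise replicates (at 1% noise the
median relative CVR error is ≈4.7%, so one replicate's median fluctuates
around the 5% bound; pooling three replicates measures it stably); the
Friedman null calibration on 1000 replicates of a 14 × 3 design.

Degenerate inputs are errors, not silent results: constant regressors
after shifting, empty masks, fewer than two end-tidal peaks, non-positive
ΔPetCO2. Collinear confound columns are dropped with a warning (never the
regressor of interest). Voxels with non-positive mean signal are excluded
from CVR with a warning.

## Known limitations

* The bulk lag and lag grid use 1 s resolution; sub-second lag structure
  is quantized.
* OLS partial-F values are optimistic under temporal autocorrelation; the
  pooled AR(1) option mitigates but does not match full per-voxel
  pre-whitening.
* Lag selection by maximum F inflates |CVR| slightly in low-SNR voxels
  (selection bias); the percentile thresholds trim the worst cases.
* Registration, segmentation, distortion and motion correction are
  consumed, not performed; inputs must be voxel-aligned.
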