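# bholdcvr

Cerebrovascular reactivity (CVR) mapping from breath-hold BOLD-fMRI with
voxelwise hemodynamic-lag optimization.

CVR — the percent BOLD signal change per mmHg of end-tidal CO2 (PetCO2)
change — indexes the dilatory reserve of cerebral vessels and is routinely
mapped with a breath-hold (BH) task: short apneas raise arterial CO2 and
drive a delayed, dispersed BOLD response. `bholdcvr` is aimed at
researchers analyzing such data (or validating analysis choices) and
implements, end to end:

* **Physio processing** — capnograph tube-delay correction, end-tidal peak
  detection, piecewise-cubic interpolation, 100 s detrending, and the
  BH-induced PetCO2 change (ΔPetCO2): first post-hold peak minus the
  preceding baseline mean, averaged over trials.
* **Signal models** — PetCO2 and Block (boxcar) regressors, each without
  convolution (WoC) or convolved with a single- (CSg) or double-gamma
  (CDb) hemodynamic response function; the HRF bank spans delays
  p1 = 3–11 s with coupled dispersion p3 = p1/6 (Gamma density with shape
  p1/p3 and scale p3; undershoot at p2 = (8/3) p1 with amplitude ratio 6).
* **Lagged GLM** — a bulk lag from GM-mean cross-correlation (±15 s), then
  per voxel an OLS fit at 19 lags (bulk ± 9 s, 1 s steps) against
  confounds (24 extended motion parameters + motion-outlier spikes), the
  optimal lag selected by the partial F-statistic of the regressor of
  interest:

  CVR_i = beta_i / (mu_i · ΔPetCO2) × 100  [%/mmHg],
  Lag_rel,i = Lag_i − median(Lag)  [s]

  with percentile thresholding — (1, 90) for CVR, (1, 99) for Lag_rel —
  and GM/WM ROI summaries.
* **Model comparison** — tie-corrected Friedman test, Conover post-hoc
  pairs with Bonferroni correction, paired sign-flip permutation test.
* **Synthetic data** — a generator for the 4 × 15 s BH paradigm (269 s,
  213 volumes at TR 1.26 s), capnograph traces, motion, and 4D BOLD with
  known per-voxel CVR and lag, making the whole chain verifiable.

## Worked example

Simulate a session with 1% noise, slow drift and motion nuisance, then run
the pipeline for two PetCO2 models:

```r
library(bholdcvr)

truth <- make_ground_truth(lag_sd = 1, seed = 42)      # GM 0.45, WM 0.20 %/mmHg
sess  <- simulate_bh_session(seed = 42, truth = truth, noise_sd = 0.01,
                             drift_amp = 0.005, motion_amp = 0.003,
                             capno_noise_sd = 0.4)
res   <- run_pipeline(sess$bold, sess$paradigm, capno = sess$capno,
                      models = enumerate_models("PetCO2", c("WoC", "CSg")),
                      smooth_fwhm = 0)

sprintf("Delta PetCO2: %.2f mmHg", res$qc$delta_petco2)
res$roi_summary[, c("model", "tissue", "mean_f", "mean_cvr", "mean_lag_rel")]
```

```
Delta PetCO2: 7.23 mmHg
                  model tissue mean_f mean_cvr mean_lag_rel
PetCO2_WoC.1 PetCO2_WoC     GM  31.44    0.388      -0.1771
PetCO2_WoC.2 PetCO2_WoC     WM   8.90    0.198       0.2982
PetCO2_CSg.1 PetCO2_CSg     GM  34.34    0.438      -0.2653
PetCO2_CSg.2 PetCO2_CSg     WM   8.79    0.215      -0.0239
```

The measured ΔPetCO2 (7.23 mmHg) is the simulated 8 mmHg increase after
detrending attenuation and end-tidal noise. GM mean CVR recovers the
simulated 0.45 %/mmHg more closely for the convolved model (0.438) than
for the unconvolved one (0.388) — convolution absorbs the hemodynamic
dispersion that otherwise biases the fit — and WM recovers its 0.20
%/mmHg; the relative lag is near zero by construction. `mean_f` is the
ROI-averaged partial F of the regressor of interest, the statistic used to
compare signal models.

Per-model maps live in `res$models[[...]]` (`fit$beta`, `fit$partial_f`,
`fit$lag_opt`, `cvr$values`, `lag_rel$values` plus thresholded validity
masks) and can be written as NIfTI with `out_dir =`. A thin CLI wrapper
(`inst/exec/bholdcvr`) exposes `simulate` and `run` subcommands over the
same functions.

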