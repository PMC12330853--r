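# Synthetic-data module: breath-hold paradigms, capnograph traces, motion
# parameters and 4D BOLD volumes with known per-voxel ground truth.

#' Construct a breath-hold task paradigm
#'
#' Lays out `n_trials` end-expiration breath-hold trials, each preceded by a
#' cued normal-breathing baseline and optionally padded by an exhalation cue
#' before the hold and a recovery window after it. A trailing baseline closes
#' the run. The defaults reproduce a 4-trial protocol with 15 s holds and
#' 30 s baselines over a 269 s acquisition.
#'
#' @param n_trials Number of breath-hold trials (may be 0 for a baseline-only
#'   run).
#' @param hold Hold (apnea) duration in seconds.
#' @param baseline Cued normal-breathing duration preceding each hold, seconds.
#' @param lead_in Initial rest before the first baseline, seconds.
#' @param exhale Exhalation-cue duration between baseline and hold, seconds.
#' @param recovery Recovery window after each hold (part of the trial, not of
#'   the next baseline), seconds.
#' @param trailing Final baseline after the last trial, seconds.
#' @param breathing_rate Cued breathing rate during baselines, Hz.
#' @return An object of class `bh_paradigm` with fields `trial_onsets`
#'   (hold onsets, seconds), `hold_duration`, `baseline_duration`,
#'   `total_duration`, `trial_span` and `breathing_rate`.
#' @examples
#' p <- make_paradigm()
#' p$total_duration  # 269
#' @export
make_paradigm <- function(n_trials = 4, hold = 15, baseline = 30,
                          lead_in = 59, exhale = 0, recovery = 0,
                          trailing = baseline, breathing_rate = 0.25) {
  if (!.is_count(n_trials)) stop("`n_trials` must be a non-negative integer")
  if (n_trials > 0 && (hold <= 0 || baseline <= 0))
    stop("hold and baseline durations must be positive")
  for (nm in c("lead_in", "exhale", "recovery", "trailing"))
    .check_scalar(get(nm), nm, lower = 0)
  .check_scalar(breathing_rate, "breathing_rate", lower = 1e-6)
  span <- baseline + exhale + hold + recovery
  onsets <- if (n_trials > 0)
    lead_in + (seq_len(n_trials) - 1) * span + baseline + exhale
  else numeric(0)
  total <- lead_in + n_trials * span + trailing
  structure(list(
    trial_onsets = onsets,
    hold_duration = hold,
    baseline_duration = baseline,
    lead_in = lead_in,
    exhale = exhale,
    recovery = recovery,
    trailing = trailing,
    trial_span = span,
    total_duration = total,
    breathing_rate = breathing_rate
  ), class = "bh_paradigm")
}

# Intervals (start, end) of the holds.
.hold_intervals <- function(paradigm) {
  cbind(start = paradigm$trial_onsets,
        end = paradigm$trial_onsets + paradigm$hold_duration)
}

# Complement of the holds within [0, total): the breathing intervals.
.breathing_intervals <- function(paradigm) {
  holds <- .hold_intervals(paradigm)
  bounds <- c(0, as.vector(t(holds)), paradigm$total_duration)
  m <- matrix(bounds, ncol = 2, byrow = TRUE)
  m[m[, 1] < m[, 2], , drop = FALSE]
}

#' Simulate a capnograph CO2 recording for a breath-hold session
#'
#' Produces a raw CO2 trace (time, mmHg) with an end-tidal peak at the end of
#' every exhalation during breathing intervals, no peaks during the holds
#' (the measured CO2 decays towards the inspiratory level as no gas is
#' exhaled), and a single elevated recovery breath immediately after each
#' hold whose peak exceeds the baseline end-tidal level by `delta`.
#'
#' @param paradigm A [make_paradigm()] object.
#' @param baseline_petco2 Baseline end-tidal CO2, mmHg.
#' @param delta Breath-hold-induced end-tidal CO2 increase, mmHg.
#' @param noise_sd Standard deviation of per-breath end-tidal noise, mmHg.
#' @param inspired Inspiratory (trough) CO2 level, mmHg.
#' @param sample_dt Sampling interval of the recording, seconds.
#' @param hold_tau Exponential decay constant of the trace during holds,
#'   seconds.
#' @param seed Optional integer seed; same seed gives a bit-identical trace.
#' @return A `capno_trace` data frame with columns `time` and `co2` and
#'   attributes `peak_times` / `peak_values` holding the ground-truth
#'   end-tidal peaks.
#' @export
simulate_capnograph <- function(paradigm, baseline_petco2 = 38, delta = 8,
                                noise_sd = 0.5, inspired = 3,
                                sample_dt = 0.1, hold_tau = 3, seed = NULL) {
  stopifnot(inherits(paradigm, "bh_paradigm"))
  .check_scalar(delta, "delta", lower = 0)
  .check_scalar(noise_sd, "noise_sd", lower = 0)
  .check_scalar(baseline_petco2, "baseline_petco2", lower = 1)
  if (!is.null(seed)) set.seed(seed)
  period <- 1 / paradigm$breathing_rate
  holds <- .hold_intervals(paradigm)
  breathing <- .breathing_intervals(paradigm)

  peak_times <- numeric(0)
  peak_values <- numeric(0)
  for (i in seq_len(nrow(breathing))) {
    a <- breathing[i, 1]; b <- breathing[i, 2]
    pts <- seq(a + period / 2, b, by = period)
    pts <- pts[pts < b - 1e-9]
    if (!length(pts)) next
    # snap to the sample grid so noiseless peak values are recoverable exactly
    pts <- round(pts / sample_dt) * sample_dt
    vals <- baseline_petco2 + stats::rnorm(length(pts), 0, noise_sd)
    if (nrow(holds) > 0 && any(abs(a - holds[, 2]) < 1e-9))
      vals[1] <- vals[1] + delta # first recovery breath is elevated
    peak_times <- c(peak_times, pts)
    peak_values <- c(peak_values, vals)
  }

  tgrid <- seq(0, paradigm$total_duration, by = sample_dt)
  co2 <- rep(inspired, length(tgrid))
  # breathing cycles: low early, cubic rise to the end-tidal peak
  cyc_start <- c(-period / 2, peak_times[-length(peak_times)])
  for (j in seq_along(peak_times)) {
    s <- max(cyc_start[j], peak_times[j] - period)
    sel <- tgrid > s & tgrid <= peak_times[j] + 1e-9
    phase <- (tgrid[sel] - s) / (peak_times[j] - s)
    co2[sel] <- inspired + (peak_values[j] - inspired) * phase^3
  }
  # holds: exponential decay towards a near-zero inspiratory level
  for (i in seq_len(nrow(holds))) {
    sel <- tgrid >= holds[i, 1] & tgrid < holds[i, 2]
    if (!any(sel)) next
    v0 <- co2[which(sel)[1]]
    co2[sel] <- 1 + (v0 - 1) * exp(-(tgrid[sel] - holds[i, 1]) / hold_tau)
  }
  co2 <- pmax(co2, 0)
  structure(data.frame(time = tgrid, co2 = co2),
            class = c("capno_trace", "data.frame"),
            peak_times = peak_times, peak_values = peak_values,
            baseline_petco2 = baseline_petco2, delta = delta)
}

#' Simulate six rigid-body motion parameters
#'
#' Slow random-walk traces for 3 translations (mm) and 3 rotations (rad).
#'
#' @param n_vols Number of volumes.
#' @param amp Approximate peak excursion (mm / rad).
#' @param seed Optional integer seed.
#' @return A numeric `n_vols` x 6 matrix with named columns.
#' @export
simulate_motion <- function(n_vols, amp = 0.2, seed = NULL) {
  if (!.is_count(n_vols) || n_vols < 2) stop("`n_vols` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  m <- sapply(1:6, function(i) {
    w <- cumsum(stats::rnorm(n_vols, 0, 1))
    w <- w - mean(w)
    w / max(1e-12, max(abs(w))) * amp * stats::runif(1, 0.3, 1)
  })
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

#' Generate per-voxel ground truth for a simulated brain
#'
#' Builds a rectangular grid whose one-voxel outer border is background and
#' whose interior is split into gray-matter (GM) and white-matter (WM)
#' compartments, each with its own CVR amplitude and hemodynamic-lag
#' distribution. Defaults place GM at 0.45 %/mmHg and WM at 0.20 %/mmHg with
#' small opposite-signed mean lags, inside ranges typical of healthy adults.
#'
#' @param shape Integer vector of 3 spatial dimensions.
#' @param gm_cvr,wm_cvr Tissue CVR amplitudes, %/mmHg.
#' @param gm_lag,wm_lag Tissue mean hemodynamic lags, seconds.
#' @param lag_sd Voxelwise lag spread (truncated-Gaussian SD), seconds.
#' @param lag_range Support of simulated lags (truncation bounds), seconds.
#' @param mean_signal,mean_signal_sd Mean and SD of per-voxel baseline BOLD
#'   intensity, scanner units.
#' @param delta_petco2 Ground-truth breath-hold PetCO2 change, mmHg.
#' @param seed Optional integer seed.
#' @return A `bh_ground_truth` list with 3D arrays `cvr` (%/mmHg), `lag`
#'   (seconds), `mean_signal`, `tissue` (0 background, 1 GM, 2 WM), logical
#'   masks `brain_mask`, `gm_mask`, `wm_mask`, and scalar `delta_petco2`.
#' @export
make_ground_truth <- function(shape = c(20, 20, 10),
                              gm_cvr = 0.45, wm_cvr = 0.20,
                              gm_lag = -0.2, wm_lag = 0.2,
                              lag_sd = 0, lag_range = c(-8, 8),
                              mean_signal = 7905, mean_signal_sd = 130,
                              delta_petco2 = 8, seed = NULL) {
  stopifnot(length(shape) == 3, all(shape >= 3))
  if (!is.null(seed)) set.seed(seed)
  tissue <- array(0L, dim = shape)
  ix <- slice.index(tissue, 1); iy <- slice.index(tissue, 2)
  iz <- slice.index(tissue, 3)
  interior <- ix > 1 & ix < shape[1] & iy > 1 & iy < shape[2] &
    iz > 1 & iz < shape[3]
  tissue[interior & ix <= ceiling(shape[1] * 0.55)] <- 1L # GM
  tissue[interior & ix > ceiling(shape[1] * 0.55)] <- 2L  # WM
  nvox <- prod(shape)
  cvr <- array(0, dim = shape)
  cvr[tissue == 1L] <- gm_cvr
  cvr[tissue == 2L] <- wm_cvr
  rtrunc <- function(n, mean, sd) {
    if (sd <= 0) return(rep(mean, n))
    x <- stats::rnorm(n, mean, sd)
    bad <- x < lag_range[1] | x > lag_range[2]
    while (any(bad)) {
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
      bad <- x < lag_range[1] | x > lag_range[2]
    }
    x
  }
  lag <- array(0, dim = shape)
  lag[tissue == 1L] <- rtrunc(sum(tissue == 1L), gm_lag, lag_sd)
  lag[tissue == 2L] <- rtrunc(sum(tissue == 2L), wm_lag, lag_sd)
  mu <- array(pmax(1, stats::rnorm(nvox, mean_signal, mean_signal_sd)),
              dim = shape)
  structure(list(
    cvr = cvr, lag = lag, mean_signal = mu, tissue = tissue,
    brain_mask = tissue > 0L, gm_mask = tissue == 1L, wm_mask = tissue == 2L,
    delta_petco2 = delta_petco2
  ), class = "bh_ground_truth")
}

#' Simulate a 4D BOLD dataset from ground truth and a response regressor
#'
#' Forward model per voxel i:
#' `y_i(t) = mu_i * (1 + a_i * (x_i(t) - mean(x_i))) + drift + motion nuisance
#' + noise`, with `a_i = cvr_i * delta_petco2 / 100` and `x_i` the response
#' regressor delayed by the voxel's true lag, sampled at the volume times and
#' min-max normalized to [0, 1]. The response term is expressed as a
#' deviation from its temporal mean so that the temporal mean of a noiseless,
#' drift-free voxel equals `mean_signal` exactly, making the CVR definition
#' (regression coefficient over temporal mean and PetCO2 change) exactly
#' invertible.
#'
#' @param paradigm A [make_paradigm()] object.
#' @param truth A [make_ground_truth()] object.
#' @param regressor_truth High-resolution regressor source (see
#'   [build_block()] / [build_petco2()] / [convolve_regressor()]).
#' @param tr Repetition time, seconds.
#' @param noise_sd Gaussian noise SD as a fraction of the voxel mean signal.
#' @param drift_amp Amplitude of a slow cosine drift as a fraction of the
#'   voxel mean signal.
#' @param drift_period Drift period, seconds (> 100 s so the standard
#'   detrending removes it).
#' @param motion Optional `n_vols` x 6 motion-parameter matrix; simulated
#'   with [simulate_motion()] when `motion_amp > 0` and `motion` is `NULL`.
#' @param motion_amp Amplitude of motion-coupled nuisance as a fraction of
#'   the voxel mean signal.
#' @param seed Optional integer seed.
#' @return A [bold_dataset()] object.
#' @export
simulate_bold <- function(paradigm, truth, regressor_truth, tr = 1.26,
                          noise_sd = 0, drift_amp = 0, drift_period = 128,
                          motion = NULL, motion_amp = 0, seed = NULL) {
  stopifnot(inherits(paradigm, "bh_paradigm"),
            inherits(truth, "bh_ground_truth"))
  .check_scalar(tr, "tr", lower = 1e-6)
  if (!is.null(seed)) set.seed(seed)
  n_vols <- floor(paradigm$total_duration / tr)
  shape <- dim(truth$cvr)
  nvox <- prod(shape)
  if (is.null(motion)) {
    motion <- if (motion_amp > 0) simulate_motion(n_vols) else
      matrix(0, n_vols, 6,
             dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                     "rot_x", "rot_y", "rot_z")))
  }
  if (nrow(motion) != n_vols || ncol(motion) != 6)
    stop("`motion` must have one row per volume and 6 columns")

  mu <- as.vector(truth$mean_signal)
  a <- as.vector(truth$cvr) * truth$delta_petco2 / 100
  lags <- as.vector(truth$lag)
  ts <- matrix(mu, nrow = n_vols, ncol = nvox, byrow = TRUE)
  active <- which(a != 0)
  if (length(active)) {
    for (lg in unique(lags[active])) {
      idx <- active[lags[active] == lg]
      x <- shift_and_sample(regressor_truth, lag = lg, tr = tr,
                            n_vols = n_vols)
      xc <- x - mean(x)
      ts[, idx] <- ts[, idx] +
        outer(xc, mu[idx] * a[idx])
    }
  }
  tvol <- (seq_len(n_vols) - 1) * tr
  if (drift_amp > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    drift <- cos(2 * pi * tvol / drift_period + phase)
    ts <- ts + outer(drift, mu * drift_amp)
  }
  if (motion_amp > 0) {
    ms <- scale(motion)
    w <- matrix(stats::rnorm(6 * nvox), 6, nvox)
    nuis <- ms %*% w
    nsd <- apply(nuis, 2, stats::sd)
    nuis <- sweep(nuis, 2, pmax(nsd, 1e-12), "/")
    ts <- ts + sweep(nuis, 2, mu * motion_amp, "*")
  }
  if (noise_sd > 0)
    ts <- ts + matrix(stats::rnorm(n_vols * nvox), n_vols, nvox) *
      matrix(mu * noise_sd, n_vols, nvox, byrow = TRUE)

  data4d <- array(t(ts), dim = c(shape, n_vols))
  bold_dataset(data4d, tr = tr, brain_mask = truth$brain_mask,
               gm_mask = truth$gm_mask, wm_mask = truth$wm_mask,
               motion = motion)
}

#' Simulate a complete breath-hold session with known ground truth
#'
#' Convenience wrapper chaining paradigm construction, capnograph simulation,
#' PetCO2 processing, regressor-source construction for the requested signal
#' model, and BOLD simulation. The forward model uses the PetCO2 change
#' measured by the physio module (after detrending), so a noiseless session
#' is exactly invertible by the analysis pipeline.
#'
#' @param seed Integer seed (mandatory; drives every stochastic component).
#' @param paradigm Optional paradigm; defaults to [make_paradigm()].
#' @param truth Optional ground truth; defaults to [make_ground_truth()].
#' @param model List with `type` ("PetCO2"/"Block"), `convolution`
#'   ("WoC"/"CSg"/"CDb"), `hrf_delay` (seconds).
#' @param tr Repetition time, seconds.
#' @param delta Capnograph end-tidal increase, mmHg.
#' @param capno_noise_sd End-tidal noise, mmHg.
#' @param noise_sd,drift_amp,motion_amp Fractions of mean signal (see
#'   [simulate_bold()]).
#' @return List with `paradigm`, `capno`, `petco2`, `delta` (measured),
#'   `truth`, `source` (high-res regressor), `bold`.
#' @export
simulate_bh_session <- function(seed, paradigm = NULL, truth = NULL,
                                model = list(type = "PetCO2",
                                             convolution = "CSg",
                                             hrf_delay = 6),
                                tr = 1.26, delta = 8, capno_noise_sd = 0,
                                noise_sd = 0, drift_amp = 0,
                                motion_amp = 0) {
  stopifnot(.is_count(seed) || (is.numeric(seed) && seed == floor(seed)))
  set.seed(seed)
  if (is.null(paradigm)) paradigm <- make_paradigm()
  if (is.null(truth)) truth <- make_ground_truth()
  capno <- simulate_capnograph(paradigm, delta = delta,
                               noise_sd = capno_noise_sd)
  pet <- process_capnograph(capno)
  dpet <- compute_delta_petco2(pet, paradigm)
  truth$delta_petco2 <- dpet$mean
  src <- build_regressor_source(model, paradigm, pet)
  bold <- simulate_bold(paradigm, truth, src, tr = tr, noise_sd = noise_sd,
                        drift_amp = drift_amp, motion_amp = motion_amp)
  list(paradigm = paradigm, capno = capno, petco2 = pet,
       delta = dpet, truth = truth, source = src, bold = bold,
       model = model)
}
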