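# Physio module: from a raw capnograph recording to a uniformly sampled,
# detrended PetCO2 trace and the breath-hold-induced PetCO2 change.

#' Correct a capnograph trace for the sampling-tube transit delay
#'
#' The gas sample travels through the tube connecting the nasal cannula to
#' the capnograph, so the recorded trace lags the true signal. All
#' timestamps are shifted by `-delay`; samples landing before time zero are
#' dropped.
#'
#' @param trace A `capno_trace` data frame (columns `time`, `co2`).
#' @param delay Tube transit delay, seconds (>= 0).
#' @return The corrected trace.
#' @export
correct_tube_delay <- function(trace, delay) {
  .check_scalar(delay, "delay", lower = 0)
  out <- trace
  out$time <- trace$time - delay
  out <- out[out$time >= -1e-12, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tube_delay") <- delay
  out
}

#' Detect end-tidal peaks in a CO2 trace
#'
#' Local maxima with topographic prominence of at least a quarter of the
#' trace's interquartile range (robust to cardiogenic ripples), separated by
#' at least `min_period` seconds. During breath-holds no exhalation occurs
#' and no peaks are emitted. A constant trace yields an empty peak set.
#'
#' @param trace A `capno_trace` data frame.
#' @param min_period Minimum separation between successive peaks, seconds.
#' @param min_prominence Absolute prominence floor, mmHg; the effective
#'   threshold is `max(min_prominence, 0.25 * IQR(co2))`.
#' @return List with `peak_times` and `peak_values`.
#' @export
detect_end_tidal_peaks <- function(trace, min_period = 2,
                                   min_prominence = 0) {
  if (!nrow(trace)) stop("empty trace")
  .check_scalar(min_period, "min_period", lower = 1e-9)
  x <- trace$co2
  t <- trace$time
  n <- length(x)
  if (n < 3) return(list(peak_times = numeric(0), peak_values = numeric(0)))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(list(peak_times = numeric(0),
                                 peak_values = numeric(0)))
  prom <- vapply(cand, function(i) {
    lv <- x[i]
    left <- if (i > 1) x[1:(i - 1)] else numeric(0)
    hi <- which(left > lv)
    lmin <- if (length(hi)) min(left[(max(hi) + 1):(i - 1)]) else min(left)
    right <- if (i < n) x[(i + 1):n] else numeric(0)
    hi <- which(right > lv)
    rmin <- if (length(hi)) min(right[1:(min(hi) - 1)]) else min(right)
    lv - max(lmin, rmin)
  }, numeric(1))
  thr <- max(min_prominence, 0.25 * stats::IQR(x))
  keep <- cand[prom >= thr & prom > 1e-12]
  if (!length(keep)) return(list(peak_times = numeric(0),
                                 peak_values = numeric(0)))
  # enforce spacing greedily, tallest peaks first
  ord <- keep[order(-x[keep])]
  sel <- logical(0)
  chosen <- integer(0)
  for (i in ord) {
    if (!length(chosen) || all(abs(t[i] - t[chosen]) >= min_period))
      chosen <- c(chosen, i)
  }
  chosen <- sort(chosen)
  list(peak_times = t[chosen], peak_values = x[chosen])
}

#' Interpolate end-tidal peaks to a uniform grid and detrend
#'
#' The detected end-tidal peaks are interpolated with a shape-preserving
#' piecewise-cubic (PCHIP) onto a uniform grid and high-pass filtered
#' (order-2 Butterworth at `1/cutoff` Hz, forward-backward, mean re-added)
#' to remove slow drifts while preserving the breath-hold response.
#'
#' @param peaks List with `peak_times` and `peak_values` (>= 2 peaks), e.g.
#'   from [detect_end_tidal_peaks()].
#' @param grid_dt Uniform sampling interval of the output trace, seconds.
#' @param cutoff Detrending cutoff period, seconds.
#' @return A `petco2_trace` list: `grid_dt`, `time`, `values` (mmHg),
#'   `peak_times`, `peak_values` (detrended values at the peak times).
#' @export
interpolate_and_detrend <- function(peaks, grid_dt = 0.1, cutoff = 100) {
  .check_scalar(grid_dt, "grid_dt", lower = 1e-6)
  .check_scalar(cutoff, "cutoff", lower = 1e-6)
  pt <- peaks$peak_times
  pv <- peaks$peak_values
  if (length(pt) < 2) stop("need at least 2 end-tidal peaks to interpolate")
  grid <- seq(pt[1], pt[length(pt)], by = grid_dt)
  vals <- signal::pchip(pt, pv, grid)
  det <- .hp_filter(vals, fs = 1 / grid_dt, cutoff = cutoff)
  pk_det <- stats::approx(grid, det, xout = pt, rule = 2)$y
  structure(list(grid_dt = grid_dt, time = grid, values = det,
                 peak_times = pt, peak_values = pk_det,
                 raw_peak_values = pv),
            class = "petco2_trace")
}

#' Process a raw capnograph trace into a PetCO2 trace
#'
#' Convenience chain: tube-delay correction, end-tidal peak detection,
#' piecewise-cubic interpolation and detrending.
#'
#' @param trace A `capno_trace` data frame.
#' @param tube_delay Tube transit delay, seconds.
#' @param min_period Minimum peak separation, seconds.
#' @param grid_dt Output sampling interval, seconds.
#' @param cutoff Detrending cutoff, seconds.
#' @return A `petco2_trace` (see [interpolate_and_detrend()]).
#' @export
process_capnograph <- function(trace, tube_delay = 0, min_period = 2,
                               grid_dt = 0.1, cutoff = 100) {
  tr <- correct_tube_delay(trace, tube_delay)
  pk <- detect_end_tidal_peaks(tr, min_period = min_period)
  interpolate_and_detrend(pk, grid_dt = grid_dt, cutoff = cutoff)
}

#' Compute the breath-hold-induced PetCO2 change
#'
#' For each breath-hold trial, the first end-tidal peak after the hold is
#' found (within `search_window` seconds of the hold's end) and the mean of
#' the baseline end-tidal peak values preceding the hold is subtracted; the
#' per-trial values are averaged. The baseline window runs from the end of
#' the previous hold (plus a short `recovery_exclude` window so that the
#' elevated recovery breaths of the previous trial do not bias the baseline)
#' to the hold onset; for the first trial it starts at the run onset.
#'
#' @param trace A `petco2_trace`.
#' @param paradigm A [make_paradigm()] object.
#' @param search_window Window after each hold in which the recovery peak is
#'   sought, seconds.
#' @param recovery_exclude Post-hold window excluded from the next trial's
#'   baseline, seconds.
#' @return A `delta_petco2` list with `per_trial` (mmHg, `NA` for trials
#'   with no recovery peak) and `mean` (mmHg, over non-missing trials).
#' @export
compute_delta_petco2 <- function(trace, paradigm, search_window = 20,
                                 recovery_exclude = 12) {
  stopifnot(inherits(trace, "petco2_trace"), inherits(paradigm, "bh_paradigm"))
  .check_scalar(search_window, "search_window", lower = 1e-9)
  .check_scalar(recovery_exclude, "recovery_exclude", lower = 0)
  onsets <- paradigm$trial_onsets
  hold <- paradigm$hold_duration
  pt <- trace$peak_times
  pv <- trace$peak_values
  n <- length(onsets)
  per_trial <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    e <- onsets[k] + hold
    post <- which(pt > e & pt <= e + search_window)
    base_start <- if (k == 1) 0 else onsets[k - 1] + hold + recovery_exclude
    base <- which(pt >= base_start & pt <= onsets[k])
    if (!length(post)) {
      warning(sprintf("trial %d: no end-tidal peak within %.1f s after the hold; excluded",
                      k, search_window))
      next
    }
    if (!length(base)) {
      warning(sprintf("trial %d: no baseline end-tidal samples; excluded", k))
      next
    }
    per_trial[k] <- pv[post[1]] - mean(pv[base])
  }
  if (all(is.na(per_trial))) stop("no trial yielded a PetCO2 change")
  structure(list(per_trial = per_trial,
                 mean = mean(per_trial, na.rm = TRUE)),
            class = "delta_petco2")
}
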