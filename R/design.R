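# Design-matrix module: candidate task regressors (PetCO2/Block x
# no-convolution/single-gamma/double-gamma x lag) and the confound matrix
# (24 extended motion parameters + motion-outlier spike regressors).

# High-resolution time grid padded on both sides of the scan window so that
# convolution start-up transients and lag shifts never pull fill values into
# the acquisition window (left pad covers kernel support + max shift).
.source_grid <- function(paradigm, grid_dt, pad = c(64, 30)) {
  seq(-pad[1], paradigm$total_duration + pad[2], by = grid_dt)
}

.new_source <- function(time, values, grid_dt, type,
                        convolution = "WoC", hrf_delay = NA_real_) {
  structure(list(time = time, values = values, grid_dt = grid_dt,
                 type = type, convolution = convolution,
                 hrf_delay = hrf_delay),
            class = "regressor_source")
}

#' Build the block (boxcar) regressor source
#'
#' Value 1 during each breath-hold interval and 0 elsewhere, on a
#' high-resolution grid padded around the scan window.
#'
#' @param paradigm A [make_paradigm()] object.
#' @param grid_dt Grid resolution, seconds.
#' @param pad Left/right padding around the scan window, seconds.
#' @return A `regressor_source` (fields `time`, `values`, `grid_dt`, `type`).
#' @export
build_block <- function(paradigm, grid_dt = 0.1, pad = c(64, 30)) {
  stopifnot(inherits(paradigm, "bh_paradigm"))
  t <- .source_grid(paradigm, grid_dt, pad)
  v <- rep(0, length(t))
  holds <- .hold_intervals(paradigm)
  for (i in seq_len(nrow(holds)))
    v[t >= holds[i, 1] & t < holds[i, 2]] <- 1
  .new_source(t, v, grid_dt, "Block")
}

#' Build the PetCO2 regressor source
#'
#' Resamples a processed PetCO2 trace onto the padded high-resolution grid;
#' outside the trace's coverage the nearest value is held.
#'
#' @param trace A `petco2_trace` (see [process_capnograph()]).
#' @param paradigm A [make_paradigm()] object.
#' @param grid_dt Grid resolution, seconds.
#' @param pad Left/right padding, seconds.
#' @return A `regressor_source`.
#' @export
build_petco2 <- function(trace, paradigm, grid_dt = 0.1, pad = c(64, 30)) {
  stopifnot(inherits(trace, "petco2_trace"), inherits(paradigm, "bh_paradigm"))
  span <- max(trace$time) - min(trace$time)
  if (span < paradigm$total_duration / 2)
    stop("PetCO2 trace covers less than half of the acquisition window")
  t <- .source_grid(paradigm, grid_dt, pad)
  v <- stats::approx(trace$time, trace$values, xout = t, rule = 2)$y
  .new_source(t, v, grid_dt, "PetCO2")
}

#' Convolve a regressor source with an HRF kernel
#'
#' Linear causal convolution on the high-resolution grid, cropped to the
#' source support. With `kernel = NULL` the source is returned unchanged
#' (the "without convolution" model).
#'
#' @param source A `regressor_source`.
#' @param kernel An [hrf_kernel()] or `NULL`.
#' @return A `regressor_source` with updated `convolution` tag.
#' @export
convolve_regressor <- function(source, kernel = NULL) {
  stopifnot(inherits(source, "regressor_source"))
  if (is.null(kernel)) return(source)
  stopifnot(inherits(kernel, "hrf_kernel"))
  if (abs(kernel$dt - source$grid_dt) > 1e-9)
    stop("kernel and source must share the same grid resolution")
  n <- length(source$values)
  v <- stats::convolve(source$values, rev(kernel$samples), type = "open")[1:n]
  conv <- if (kernel$params$shape == "single") "CSg" else "CDb"
  .new_source(source$time, v, source$grid_dt, source$type,
              convolution = conv, hrf_delay = kernel$params$p1)
}

#' Shift a high-resolution series in time
#'
#' Positive lag delays the series (the response occurs later): the shifted
#' series at time t takes the original value at t - lag.
#'
#' @param source A `regressor_source`.
#' @param lag Shift, seconds.
#' @return A `regressor_source` on the same grid.
#' @export
shift_series <- function(source, lag) {
  stopifnot(inherits(source, "regressor_source"))
  v <- stats::approx(source$time, source$values, xout = source$time - lag,
                     rule = 2)$y
  out <- source
  out$values <- v
  out
}

#' Shift, sample at volume times, and normalize a regressor
#'
#' The high-resolution series is delayed by `lag` (positive = later
#' response), sampled at the volume acquisition times `0, tr, 2 tr, ...`,
#' and min-max normalized to [0, 1].
#'
#' @param source A `regressor_source`.
#' @param lag Lag, seconds.
#' @param tr Repetition time, seconds.
#' @param n_vols Number of volumes.
#' @param normalize Min-max normalize to [0, 1] (default `TRUE`).
#' @return Numeric vector of length `n_vols`.
#' @export
shift_and_sample <- function(source, lag, tr, n_vols, normalize = TRUE) {
  stopifnot(inherits(source, "regressor_source"))
  .check_scalar(tr, "tr", lower = 1e-9)
  t_acq <- (seq_len(n_vols) - 1) * tr
  v <- stats::approx(source$time, source$values, xout = t_acq - lag,
                     rule = 2)$y
  if (normalize) {
    rng <- range(v)
    if (diff(rng) < 1e-12)
      stop("degenerate regressor: constant after shifting and sampling")
    v <- (v - rng[1]) / diff(rng)
  }
  v
}

#' Build a regressor source for one signal model
#'
#' Combines regressor type (PetCO2 or Block) with the convolution model
#' (WoC: none; CSg: single gamma; CDb: double gamma at the given delay).
#'
#' @param model List with `type` ("PetCO2"/"Block"), `convolution`
#'   ("WoC"/"CSg"/"CDb"), and `hrf_delay` (seconds, used for CSg/CDb).
#' @param paradigm A [make_paradigm()] object.
#' @param petco2 A `petco2_trace` (required for PetCO2 models).
#' @param grid_dt Grid resolution, seconds.
#' @return A `regressor_source`.
#' @export
build_regressor_source <- function(model, paradigm, petco2 = NULL,
                                   grid_dt = 0.1) {
  type <- match.arg(model$type, c("PetCO2", "Block"))
  conv <- match.arg(model$convolution, c("WoC", "CSg", "CDb"))
  src <- if (type == "Block") build_block(paradigm, grid_dt)
  else {
    if (is.null(petco2)) stop("PetCO2 models require a processed PetCO2 trace")
    build_petco2(petco2, paradigm, grid_dt)
  }
  if (conv == "WoC") return(src)
  shape <- if (conv == "CSg") "single" else "double"
  delay <- if (is.null(model$hrf_delay)) 6 else model$hrf_delay
  convolve_regressor(src, hrf_kernel(hrf_params(delay, shape), dt = grid_dt))
}

#' Enumerate the candidate signal models
#'
#' The cross of regressor types and convolution models; the default full
#' grid yields the 6 model variants.
#'
#' @param types Character vector among "PetCO2", "Block".
#' @param convolutions Character vector among "WoC", "CSg", "CDb".
#' @param hrf_delay HRF delay used by the convolution models, seconds.
#' @return Data frame with columns `type`, `convolution`, `hrf_delay`,
#'   `label`.
#' @export
enumerate_models <- function(types = c("PetCO2", "Block"),
                             convolutions = c("WoC", "CSg", "CDb"),
                             hrf_delay = 6) {
  types <- match.arg(types, c("PetCO2", "Block"), several.ok = TRUE)
  convolutions <- match.arg(convolutions, c("WoC", "CSg", "CDb"),
                            several.ok = TRUE)
  g <- expand.grid(convolution = convolutions, type = types,
                   stringsAsFactors = FALSE)[, c("type", "convolution")]
  g$hrf_delay <- ifelse(g$convolution == "WoC", NA_real_, hrf_delay)
  g$label <- paste(g$type, g$convolution, sep = "_")
  rownames(g) <- NULL
  g
}

#' Expand 6 motion parameters to the 24-parameter extended set
#'
#' Columns are, in order: the 6 parameters, their 6 temporal derivatives
#' (backward differences, first row 0), the 6 squared parameters, and the 6
#' squared derivatives.
#'
#' @param motion6 Numeric matrix, one row per volume, 6 columns.
#' @return Numeric matrix with 24 named columns.
#' @export
extend_motion_params <- function(motion6) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6) stop("`motion6` must have exactly 6 columns")
  d <- rbind(0, diff(motion6))
  out <- cbind(motion6, d, motion6^2, d^2)
  base <- colnames(motion6)
  if (is.null(base)) base <- paste0("mp", 1:6)
  colnames(out) <- c(base, paste0(base, "_deriv"), paste0(base, "_sq"),
                     paste0(base, "_deriv_sq"))
  out
}

#' Detect motion-outlier volumes
#'
#' For each volume, the root-mean-square difference to the reference volume
#' (the middle one) is computed over in-mask voxels; volumes whose metric
#' exceeds the 75th percentile by more than 1.5 times the interquartile
#' range are flagged as outliers.
#'
#' @param bold A [bold_dataset()].
#' @return A list with `metric` (per-volume RMS difference), `outliers`
#'   (volume indices) and `spikes` (volumes x n_outliers indicator matrix,
#'   one unit column per outlier).
#' @export
detect_motion_outliers <- function(bold) {
  stopifnot(inherits(bold, "bold_dataset"))
  ts <- .ts_matrix(bold$data, bold$brain_mask)
  nt <- nrow(ts)
  if (nt < 3) stop("need at least 3 volumes")
  ref <- ts[ceiling(nt / 2), ]
  metric <- sqrt(rowMeans(sweep(ts, 2, ref)^2))
  q <- stats::quantile(metric, c(0.25, 0.75), names = FALSE)
  thr <- q[2] + 1.5 * (q[2] - q[1])
  out <- which(metric > thr)
  spikes <- matrix(0, nt, length(out))
  if (length(out)) {
    spikes[cbind(out, seq_along(out))] <- 1
    colnames(spikes) <- paste0("spike_", out)
  }
  list(metric = metric, outliers = out, spikes = spikes)
}

#' Assemble the confound matrix
#'
#' 24 extended motion parameters plus one spike column per motion-outlier
#' volume.
#'
#' @param motion6 Volumes x 6 motion-parameter matrix.
#' @param spikes Optional volumes x n_outliers indicator matrix.
#' @return Numeric matrix with named columns.
#' @export
confound_matrix <- function(motion6, spikes = NULL) {
  cm <- extend_motion_params(motion6)
  if (!is.null(spikes) && ncol(spikes) > 0) {
    if (nrow(spikes) != nrow(cm))
      stop("spike matrix and motion parameters disagree in length")
    cm <- cbind(cm, spikes)
  }
  cm
}
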