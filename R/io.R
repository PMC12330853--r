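# I/O and orchestration: NIfTI / TSV / JSON readers and writers, run
# configuration, and the end-to-end pipeline.

#' Write a 3D/4D array as NIfTI
#'
#' @param x Numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @return The path, invisibly.
#' @export
write_nifti <- function(x, path, voxel_size = 2.2) {
  img <- RNifti::asNifti(x)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  RNifti::pixdim(img) <- c(voxel_size, rep(1, length(dim(x)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a plain array
#'
#' @param path Input path.
#' @return Numeric array with attribute `voxel_size`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_size") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  out
}

#' Write a capnograph or motion table as TSV
#'
#' @param x Data frame or matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("TSV file not found: ", path)
  utils::read.delim(path, sep = "\t", check.names = FALSE)
}

#' Read a capnograph TSV (columns time, co2)
#'
#' @param path Input path.
#' @return A `capno_trace` data frame.
#' @export
read_capno_tsv <- function(path) {
  df <- read_tsv(path)
  if (!all(c("time", "co2") %in% names(df)))
    stop("physio TSV must have columns `time` and `co2`: ", path)
  if (is.unsorted(df$time, strictly = TRUE))
    stop("physio TSV: `time` must be strictly increasing")
  if (any(df$co2 < 0)) stop("physio TSV: `co2` must be non-negative")
  structure(df[c("time", "co2")], class = c("capno_trace", "data.frame"))
}

#' Write a paradigm as a BIDS-style events TSV
#'
#' One row per breath-hold trial with columns `onset`, `duration`,
#' `trial_type` ("breathhold").
#'
#' @param paradigm A [make_paradigm()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(paradigm, path) {
  stopifnot(inherits(paradigm, "bh_paradigm"))
  df <- data.frame(onset = paradigm$trial_onsets,
                   duration = paradigm$hold_duration,
                   trial_type = "breathhold")
  write_tsv(df, path)
}

#' Reconstruct a paradigm from an events TSV
#'
#' Hold onsets and durations are taken from the `breathhold` rows; the
#' baseline duration is inferred from the inter-trial spacing and the
#' lead-in from the first onset.
#'
#' @param path Events TSV path (columns `onset`, `duration`, `trial_type`).
#' @param total_duration Total run duration, seconds (defaults to the last
#'   hold end plus one baseline).
#' @param breathing_rate Cued breathing rate, Hz.
#' @return A `bh_paradigm`.
#' @export
read_events_tsv <- function(path, total_duration = NULL,
                            breathing_rate = 0.25) {
  df <- read_tsv(path)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df)))
    stop("events TSV must have columns onset, duration, trial_type: ", path)
  bh <- df[df$trial_type == "breathhold", , drop = FALSE]
  if (!nrow(bh)) stop("events TSV contains no breathhold trials")
  onsets <- sort(bh$onset)
  hold <- unique(bh$duration)
  if (length(hold) != 1) stop("events TSV: variable hold durations")
  baseline <- if (length(onsets) > 1) min(diff(onsets)) - hold else onsets[1]
  lead_in <- onsets[1] - baseline
  if (lead_in < 0) { lead_in <- 0; baseline <- onsets[1] }
  if (is.null(total_duration))
    total_duration <- onsets[length(onsets)] + hold + baseline
  trailing <- total_duration - (onsets[length(onsets)] + hold)
  make_paradigm(n_trials = length(onsets), hold = hold, baseline = baseline,
                lead_in = lead_in, trailing = trailing,
                breathing_rate = breathing_rate)
}

#' Read a run configuration JSON
#'
#' @param path JSON path.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_run_config(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' Validate a run configuration
#'
#' Checks that referenced input paths exist and that a seed is present
#' whenever a stochastic stage (simulation) is enabled.
#'
#' @param config Configuration list.
#' @return The configuration, invisibly enriched with defaults.
#' @export
validate_run_config <- function(config) {
  for (key in c("bold", "brain_mask", "gm_mask", "wm_mask", "physio",
                "events", "motion")) {
    p <- config$paths[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("config: input path for `", key, "` does not exist: ", p)
  }
  if (isTRUE(config$simulate) && is.null(config$seed))
    stop("config: `seed` is required when simulation is enabled")
  defaults <- list(hrf_delay = 6, detrend_cutoff = 100, smooth_fwhm = 3.5,
                   lag_step = 1, lag_half_range = 9, bulk_search = 15,
                   tube_delay = 0, prewhiten = FALSE)
  config[names(defaults)] <- utils::modifyList(
    defaults, config[intersect(names(config), names(defaults))])
  invisible(config)
}

#' Run the full breath-hold CVR pipeline
#'
#' For each requested signal model: builds the regressor source, estimates
#' the bulk lag from the gray-matter mean series, sweeps the lag grid
#' voxelwise, selects the optimal lag by partial F, and derives CVR and
#' relative-lag maps with percentile thresholding and ROI summaries.
#'
#' @param bold A [bold_dataset()] (with GM/WM masks and motion for the full
#'   pipeline).
#' @param paradigm A [make_paradigm()] object.
#' @param capno Raw `capno_trace`; processed internally (alternatively pass
#'   `petco2`).
#' @param petco2 A processed `petco2_trace`.
#' @param models Data frame from [enumerate_models()] (default: all 6).
#' @param hrf_delay HRF delay for convolution models, seconds.
#' @param tube_delay Capnograph tube delay, seconds.
#' @param detrend_cutoff Temporal detrending cutoff, seconds (`NULL` skips
#'   detrending; the same filter is applied to the design columns).
#' @param smooth_fwhm Spatial smoothing FWHM, mm (0 skips).
#' @param bulk_search Bulk-lag search half-range, seconds.
#' @param lag_half_range,lag_step Voxelwise lag-grid half-range and step,
#'   seconds.
#' @param cvr_threshold,lag_threshold Percentile bounds for the CVR and
#'   relative-lag maps.
#' @param prewhiten Apply pooled AR(1) pre-whitening.
#' @param subject Subject label for outputs.
#' @param out_dir Optional output directory; when given, maps (NIfTI), ROI
#'   summaries (TSV) and QC (JSON) are written.
#' @return A `bh_pipeline_result` list: `delta` (PetCO2 change), `models`
#'   (per-model list with `bulk_lag`, `fit`, `cvr`, `lag_rel`,
#'   `cvr_thresholded`, `lag_rel_thresholded`, `roi`), `roi_summary`
#'   (stacked data frame), `qc`.
#' @export
run_pipeline <- function(bold, paradigm, capno = NULL, petco2 = NULL,
                         models = enumerate_models(), hrf_delay = 6,
                         tube_delay = 0, detrend_cutoff = 100,
                         smooth_fwhm = 0, bulk_search = 15,
                         lag_half_range = 9, lag_step = 1,
                         cvr_threshold = c(1, 90), lag_threshold = c(1, 99),
                         prewhiten = FALSE, subject = "sub-01",
                         out_dir = NULL) {
  stopifnot(inherits(bold, "bold_dataset"), inherits(paradigm, "bh_paradigm"))
  if (is.null(petco2)) {
    if (is.null(capno) && any(models$type == "PetCO2"))
      stop("PetCO2 models requested but no capnograph trace given")
    if (!is.null(capno))
      petco2 <- process_capnograph(capno, tube_delay = tube_delay)
  }
  delta <- if (!is.null(petco2))
    compute_delta_petco2(petco2, paradigm) else NULL
  if (any(models$type == "PetCO2") && is.null(delta))
    stop("PetCO2 change unavailable")

  if (smooth_fwhm > 0) bold <- smooth_spatial(bold, smooth_fwhm)
  column_filter <- NULL
  if (!is.null(detrend_cutoff)) {
    bold <- highpass_detrend(bold, cutoff = detrend_cutoff)
    fs <- 1 / bold$tr
    column_filter <- function(x) .hp_project(x, fs = fs,
                                             cutoff = detrend_cutoff)
  }
  confounds <- NULL
  outliers <- NULL
  if (!is.null(bold$motion) && any(abs(bold$motion) > 0)) {
    outliers <- detect_motion_outliers(bold)
    confounds <- confound_matrix(bold$motion, outliers$spikes)
  }
  gm_mask <- if (!is.null(bold$gm_mask) && any(bold$gm_mask))
    bold$gm_mask else bold$brain_mask
  wm_mask <- if (!is.null(bold$wm_mask) && any(bold$wm_mask))
    bold$wm_mask else bold$brain_mask
  gm_series <- mean_roi_series(bold, gm_mask)

  results <- list()
  roi_rows <- list()
  for (i in seq_len(nrow(models))) {
    mdl <- list(type = models$type[i], convolution = models$convolution[i],
                hrf_delay = hrf_delay)
    src <- build_regressor_source(mdl, paradigm, petco2)
    bulk <- estimate_bulk_lag(gm_series, src, tr = bold$tr,
                              search = bulk_search, step = lag_step)
    grid <- lag_grid(as.numeric(bulk), half_range = lag_half_range,
                     step = lag_step)
    fit <- sweep_and_select(bold, src, grid, confounds = confounds,
                            prewhiten = prewhiten,
                            column_filter = column_filter)
    dval <- if (!is.null(delta)) delta$mean else NA_real_
    cvr <- compute_cvr(fit, dval)
    lag_rel <- compute_lag_rel(fit)
    cvr_thr <- percentile_threshold(cvr$values, cvr$valid_mask,
                                    cvr_threshold[1], cvr_threshold[2])
    lag_thr <- percentile_threshold(lag_rel$values, lag_rel$valid_mask,
                                    lag_threshold[1], lag_threshold[2])
    roi <- roi_summary(fit,
                       list(values = cvr_thr$values,
                            valid_mask = cvr_thr$valid_mask),
                       list(values = lag_thr$values,
                            valid_mask = lag_thr$valid_mask),
                       gm_mask = gm_mask, wm_mask = wm_mask,
                       subject = subject, model = models$label[i])
    results[[models$label[i]]] <- list(
      model = mdl, bulk_lag = as.numeric(bulk),
      bulk_correlation = attr(bulk, "correlation"),
      fit = fit, cvr = cvr, lag_rel = lag_rel,
      cvr_thresholded = cvr_thr, lag_rel_thresholded = lag_thr, roi = roi)
    roi_rows[[models$label[i]]] <- roi
  }
  qc <- list(
    subject = subject,
    delta_petco2 = if (!is.null(delta)) delta$mean else NA_real_,
    delta_petco2_per_trial = if (!is.null(delta)) delta$per_trial else NULL,
    n_motion_outliers = if (!is.null(outliers)) length(outliers$outliers)
    else 0L,
    bulk_lags = vapply(results, `[[`, numeric(1), "bulk_lag"),
    boundary_fraction = vapply(results, function(r)
      r$fit$boundary_fraction, numeric(1)),
    dof = results[[1]]$fit$dof,
    n_models = nrow(models))
  out <- structure(list(delta = delta, models = results,
                        roi_summary = do.call(rbind, roi_rows), qc = qc),
                   class = "bh_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, bold, out_dir, subject)
  out
}

#' Write pipeline outputs to a directory
#'
#' BIDS-style naming: per-model beta, partial-F, lag, CVR and relative-lag
#' NIfTI maps plus validity masks, a stacked ROI summary TSV, and a QC JSON.
#'
#' @param result A `bh_pipeline_result`.
#' @param bold The analyzed [bold_dataset()] (for geometry).
#' @param out_dir Output directory (created if needed).
#' @param subject Subject label.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, bold, out_dir,
                                   subject = "sub-01") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vs <- bold$voxel_size
  nz <- function(x) { x[is.na(x)] <- 0; x }
  for (label in names(result$models)) {
    r <- result$models[[label]]
    stub <- file.path(out_dir, sprintf("%s_model-%s", subject, label))
    write_nifti(nz(r$fit$beta), paste0(stub, "_desc-beta_map.nii.gz"), vs)
    write_nifti(nz(r$fit$partial_f), paste0(stub, "_desc-partialF_map.nii.gz"), vs)
    write_nifti(nz(r$fit$lag_opt), paste0(stub, "_desc-lag_map.nii.gz"), vs)
    write_nifti(nz(r$cvr$values), paste0(stub, "_desc-cvr_map.nii.gz"), vs)
    write_nifti(nz(r$lag_rel$values), paste0(stub, "_desc-lagrel_map.nii.gz"), vs)
    write_nifti(r$cvr_thresholded$valid_mask + 0,
                paste0(stub, "_desc-cvrvalid_mask.nii.gz"), vs)
    write_nifti(r$lag_rel_thresholded$valid_mask + 0,
                paste0(stub, "_desc-lagrelvalid_mask.nii.gz"), vs)
  }
  write_tsv(result$roi_summary,
            file.path(out_dir, paste0(subject, "_roi-summary.tsv")))
  jsonlite::write_json(result$qc,
                       file.path(out_dir, paste0(subject, "_qc.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write a simulated session to disk
#'
#' BOLD and masks as NIfTI, events/physio/motion as TSV, and ground truth
#' (CVR, lag, mean signal) as NIfTI with a JSON metadata sidecar.
#'
#' @param session List from [simulate_bh_session()].
#' @param out_dir Output directory.
#' @param subject Subject label.
#' @param seed Seed recorded in the metadata.
#' @return `out_dir`, invisibly.
#' @export
write_session <- function(session, out_dir, subject = "sub-01",
                          seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vs <- session$bold$voxel_size
  stub <- file.path(out_dir, subject)
  write_nifti(session$bold$data, paste0(stub, "_bold.nii.gz"), vs)
  write_nifti(session$bold$brain_mask + 0, paste0(stub, "_desc-brain_mask.nii.gz"), vs)
  write_nifti(session$bold$gm_mask + 0, paste0(stub, "_desc-gm_mask.nii.gz"), vs)
  write_nifti(session$bold$wm_mask + 0, paste0(stub, "_desc-wm_mask.nii.gz"), vs)
  write_events_tsv(session$paradigm, paste0(stub, "_events.tsv"))
  write_tsv(session$capno, paste0(stub, "_physio.tsv"))
  write_tsv(session$bold$motion, paste0(stub, "_motion.tsv"))
  write_nifti(session$truth$cvr, paste0(stub, "_desc-cvrtrue_map.nii.gz"), vs)
  write_nifti(session$truth$lag, paste0(stub, "_desc-lagtrue_map.nii.gz"), vs)
  write_nifti(session$truth$mean_signal, paste0(stub, "_desc-mean_map.nii.gz"), vs)
  jsonlite::write_json(
    list(seed = seed, tr = session$bold$tr,
         delta_petco2 = session$truth$delta_petco2,
         model = session$model,
         total_duration = session$paradigm$total_duration),
    paste0(stub, "_truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}
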