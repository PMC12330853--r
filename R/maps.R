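# Maps module: CVR and relative-lag maps, percentile thresholding and ROI
# summaries.

#' Compute the CVR map
#'
#' Per voxel i, `CVR_i = beta_i / (mu_i * delta_petco2) * 100`, in percent
#' BOLD signal change per mmHg of PetCO2 change: the regression coefficient
#' of the (0-1 normalized) regressor of interest, normalized by the voxel's
#' mean BOLD signal over time and the subject's mean PetCO2 change.
#'
#' @param fit A `voxel_fit_maps` from [sweep_and_select()].
#' @param delta_petco2 Mean PetCO2 change, mmHg (> 0), or a `delta_petco2`
#'   object.
#' @param mu Optional 3D array of voxel temporal means; defaults to the
#'   means recorded in `fit`.
#' @return A `cvr_map` list with 3D array `values` (%/mmHg) and logical
#'   `valid_mask` (voxels with positive mean signal).
#' @export
compute_cvr <- function(fit, delta_petco2, mu = NULL) {
  stopifnot(inherits(fit, "voxel_fit_maps"))
  if (inherits(delta_petco2, "delta_petco2")) delta_petco2 <- delta_petco2$mean
  .check_scalar(delta_petco2, "delta_petco2")
  if (delta_petco2 <= 0) stop("`delta_petco2` must be positive")
  if (is.null(mu)) mu <- fit$mu
  bad <- fit$mask & !(mu > 0)
  if (any(bad, na.rm = TRUE))
    warning(sum(bad, na.rm = TRUE),
            " voxel(s) with non-positive mean signal excluded")
  values <- fit$beta / (mu * delta_petco2) * 100
  values[!fit$mask | !(mu > 0)] <- NA_real_
  structure(list(values = values, valid_mask = fit$mask & (mu > 0)),
            class = "cvr_map")
}

#' Compute the relative-lag map
#'
#' Normalizes the per-voxel optimal lags to their in-mask median:
#' `Lag_rel,i = Lag_i - median(Lag)`, so the map's median is zero and values
#' express earlier (negative) or later (positive) responses relative to the
#' bulk of the brain.
#'
#' @param lag_map 3D array of optimal lags (seconds), or a
#'   `voxel_fit_maps`.
#' @param mask Logical 3D array over which the median is taken (defaults to
#'   the fit mask).
#' @return A `lag_rel_map` list with `values` (seconds), `valid_mask` and
#'   the subtracted `median_lag`.
#' @export
compute_lag_rel <- function(lag_map, mask = NULL) {
  if (inherits(lag_map, "voxel_fit_maps")) {
    if (is.null(mask)) mask <- lag_map$mask
    lag_map <- lag_map$lag_opt
  }
  if (is.null(mask)) mask <- !is.na(lag_map)
  if (!any(mask)) stop("empty mask")
  med <- stats::median(lag_map[mask], na.rm = TRUE)
  values <- lag_map - med
  values[!mask] <- NA_real_
  structure(list(values = values, valid_mask = mask & !is.na(values),
                 median_lag = med),
            class = "lag_rel_map")
}

#' Percentile thresholding of a map
#'
#' Marks as invalid the in-mask voxels whose value falls below the
#' `low_pct` percentile or above the `high_pct` percentile (inclusive
#' bounds, linear-interpolation percentiles over in-mask finite values);
#' values are not altered, only the validity mask shrinks. Conventional
#' defaults are (1, 99) for relative-lag maps and (1, 90) for CVR maps,
#' trimming extremes deemed inadequately optimized.
#'
#' @param values 3D numeric array.
#' @param mask Logical 3D array of candidate voxels.
#' @param low_pct,high_pct Percentile bounds in [0, 100], `low < high`.
#' @return List with `values` (unchanged) and `valid_mask`.
#' @export
percentile_threshold <- function(values, mask, low_pct = 1, high_pct = 99) {
  .check_scalar(low_pct, "low_pct", lower = 0, upper = 100)
  .check_scalar(high_pct, "high_pct", lower = 0, upper = 100)
  if (low_pct >= high_pct) stop("`low_pct` must be below `high_pct`")
  sel <- mask & is.finite(values)
  v <- values[sel]
  bounds <- stats::quantile(v, c(low_pct, high_pct) / 100, names = FALSE,
                            type = 7)
  valid <- sel & values >= bounds[1] & values <= bounds[2]
  valid[is.na(valid)] <- FALSE
  list(values = values, valid_mask = valid, bounds = bounds)
}

#' ROI summary of fit, CVR and relative-lag maps
#'
#' Arithmetic means of the voxelwise-optimized partial F, CVR and relative
#' lag over the valid voxels of each tissue ROI.
#'
#' @param fit A `voxel_fit_maps`.
#' @param cvr A `cvr_map` (ideally after [percentile_threshold()]).
#' @param lag_rel A `lag_rel_map` (ideally after [percentile_threshold()]).
#' @param gm_mask,wm_mask Logical 3D tissue masks.
#' @param subject Optional subject identifier.
#' @param model Optional model label.
#' @return Data frame with one row per tissue: `subject`, `model`,
#'   `tissue`, `n_voxels`, `mean_f`, `mean_cvr`, `mean_lag_rel`.
#' @export
roi_summary <- function(fit, cvr, lag_rel, gm_mask, wm_mask,
                        subject = NA_character_, model = NA_character_) {
  rois <- list(GM = gm_mask, WM = wm_mask)
  rows <- lapply(names(rois), function(tn) {
    m <- rois[[tn]]
    if (!any(m)) stop("empty ", tn, " mask")
    mean_over <- function(vals, valid) {
      sel <- m & valid
      if (!any(sel)) {
        warning("no valid ", tn, " voxels for summary")
        return(NA_real_)
      }
      mean(vals[sel])
    }
    data.frame(subject = subject, model = model, tissue = tn,
               n_voxels = sum(m),
               mean_f = mean_over(fit$partial_f, fit$mask),
               mean_cvr = mean_over(cvr$values, cvr$valid_mask),
               mean_lag_rel = mean_over(lag_rel$values, lag_rel$valid_mask))
  })
  do.call(rbind, rows)
}
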