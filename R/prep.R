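# BOLD preprocessing module: container, temporal detrending, spatial
# smoothing, ROI mean series and percent-signal-change utilities.

#' Construct a BOLD dataset
#'
#' Bundles a 4D BOLD array with its repetition time, tissue/brain masks,
#' motion parameters and voxel geometry.
#'
#' @param data 4D numeric array (x, y, z, t) in scanner units.
#' @param tr Repetition time, seconds.
#' @param brain_mask,gm_mask,wm_mask Logical 3D arrays matching the spatial
#'   dimensions (brain mask defaults to all voxels).
#' @param motion Optional volumes x 6 motion-parameter matrix.
#' @param voxel_size Voxel edge lengths, mm (length 1 or 3).
#' @return A `bold_dataset` list.
#' @export
bold_dataset <- function(data, tr, brain_mask = NULL, gm_mask = NULL,
                         wm_mask = NULL, motion = NULL, voxel_size = 2.2) {
  d <- dim(data)
  if (length(d) != 4) stop("`data` must be a 4D array (x, y, z, t)")
  if (d[4] < 2) stop("need at least 2 volumes")
  .check_scalar(tr, "tr", lower = 1e-9)
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = d[1:3])
  for (nm in c("brain_mask", "gm_mask", "wm_mask")) {
    m <- get(nm)
    if (!is.null(m) && !identical(dim(m), d[1:3]))
      stop(sprintf("`%s` does not match the spatial dimensions", nm))
  }
  if (!is.null(motion) && nrow(motion) != d[4])
    stop("`motion` must have one row per volume")
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  structure(list(data = data, tr = tr,
                 brain_mask = array(as.logical(brain_mask), d[1:3]),
                 gm_mask = if (!is.null(gm_mask))
                   array(as.logical(gm_mask), d[1:3]),
                 wm_mask = if (!is.null(wm_mask))
                   array(as.logical(wm_mask), d[1:3]),
                 motion = motion, voxel_size = voxel_size),
            class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_dataset> %d x %d x %d voxels, %d volumes, TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Temporal high-pass detrending of a BOLD dataset
#'
#' Removes slow drifts from every voxel time series by projecting out a
#' linear trend and the discrete-cosine basis functions with frequency
#' below `1/cutoff` Hz. The basis columns are demeaned, so each voxel's
#' temporal mean is preserved exactly (absolute units are needed for CVR
#' normalization), and the operation is exactly idempotent.
#'
#' @param bold A [bold_dataset()].
#' @param cutoff Cutoff period, seconds (> 2 TR).
#' @param mask Optional logical 3D array restricting the voxels filtered
#'   (defaults to the brain mask).
#' @return The detrended `bold_dataset`.
#' @export
highpass_detrend <- function(bold, cutoff = 100, mask = NULL) {
  stopifnot(inherits(bold, "bold_dataset"))
  if (cutoff <= 2 * bold$tr)
    stop("`cutoff` must exceed twice the repetition time")
  if (is.null(mask)) mask <- bold$brain_mask
  ts <- .ts_matrix(bold$data, mask)
  B <- .hp_project_basis(nrow(ts), bold$tr, cutoff)
  ts <- ts - B %*% qr.solve(B, ts)
  out <- bold
  out$data <- .ts_unflatten(bold$data, mask, ts)
  out
}

#' Spatial Gaussian smoothing of a BOLD dataset
#'
#' Per-volume separable Gaussian smoothing with `sigma = fwhm / 2.355` per
#' axis (converted from mm to voxels), using reflect boundary handling so
#' the spatial mean is preserved. `fwhm = 0` is the identity.
#'
#' @param bold A [bold_dataset()].
#' @param fwhm Full width at half maximum, mm.
#' @return The smoothed `bold_dataset`.
#' @export
smooth_spatial <- function(bold, fwhm = 3.5) {
  stopifnot(inherits(bold, "bold_dataset"))
  .check_scalar(fwhm, "fwhm", lower = 0)
  if (fwhm == 0) return(bold)
  sigmas <- (fwhm / 2.355) / bold$voxel_size
  d <- dim(bold$data)
  ks <- lapply(sigmas, .gauss_kernel)
  out <- bold$data
  for (v in seq_len(d[4])) {
    vol <- out[, , , v]
    vol <- apply(vol, c(2, 3), .conv_reflect, k = ks[[1]])
    vol <- aperm(apply(vol, c(1, 3), .conv_reflect, k = ks[[2]]), c(2, 1, 3))
    vol <- aperm(apply(vol, c(1, 2), .conv_reflect, k = ks[[3]]), c(2, 3, 1))
    out[, , , v] <- vol
  }
  res <- bold
  res$data <- out
  res
}

#' Mean time series over a region of interest
#'
#' @param bold A [bold_dataset()].
#' @param mask Logical 3D array (non-empty).
#' @return Numeric vector, one value per volume.
#' @export
mean_roi_series <- function(bold, mask) {
  stopifnot(inherits(bold, "bold_dataset"))
  if (!any(mask)) stop("empty ROI mask")
  rowMeans(.ts_matrix(bold$data, mask))
}

#' Percent signal change (BOLD convention)
#'
#' `100 * (x - mean(x)) / mean(x)`: percent deviation from the temporal
#' mean.
#'
#' @param x Non-constant numeric series.
#' @return Numeric series in percent, mean 0.
#' @export
percent_change_bold <- function(x) {
  if (stats::sd(x) < 1e-12) stop("constant series")
  100 * (x - mean(x)) / mean(x)
}

#' Percent signal change (z-score convention)
#'
#' `100 * (x - mean(x)) / sd(x)`: demeaned, scaled by the standard
#' deviation, in percent (output SD is 100).
#'
#' @param x Non-constant numeric series.
#' @return Numeric series, mean 0, SD 100.
#' @export
percent_change_z <- function(x) {
  s <- stats::sd(x)
  if (s < 1e-12) stop("constant series")
  100 * (x - mean(x)) / s
}
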