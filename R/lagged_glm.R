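# Lagged GLM module: bulk-lag estimation, voxelwise GLM over the 19-lag
# grid, per-voxel lag selection by the partial F-statistic of the regressor
# of interest, and the optional joint HRF-delay/lag search.

#' Estimate the bulk hemodynamic lag
#'
#' The single global lag maximizing the Pearson correlation between the
#' (z-scored) gray-matter mean BOLD series and the model regressor shifted
#' by each candidate lag and sampled at the volume times. The search is
#' restricted to a limited range to avoid shifting the regressor by whole
#' task cycles. Ties are broken towards the smallest absolute lag; a warning
#' is issued when the optimum sits on the search boundary.
#'
#' @param gm_series Numeric series (one value per volume).
#' @param source A `regressor_source`.
#' @param tr Repetition time, seconds.
#' @param search Half-range of the lag search, seconds.
#' @param step Lag grid step, seconds.
#' @return Bulk lag in seconds, with attributes `correlation` and
#'   `boundary` (logical).
#' @export
estimate_bulk_lag <- function(gm_series, source, tr, search = 15, step = 1) {
  stopifnot(inherits(source, "regressor_source"))
  if (stats::sd(gm_series) < 1e-12) stop("constant GM series")
  lags <- seq(-search, search, by = step)
  n <- length(gm_series)
  cors <- vapply(lags, function(lg) {
    x <- shift_and_sample(source, lg, tr, n, normalize = FALSE)
    if (stats::sd(x) < 1e-12) return(-Inf)
    stats::cor(gm_series, x)
  }, numeric(1))
  best <- max(cors)
  cand <- which(cors >= best - 1e-12)
  pick <- cand[order(abs(lags[cand]), lags[cand])][1]
  lag <- lags[pick]
  boundary <- abs(abs(lag) - search) < 1e-9
  if (boundary)
    warning("bulk lag estimate hit the search boundary (", lag, " s)")
  structure(lag, correlation = cors[pick], boundary = boundary)
}

#' Lag grid around a bulk lag
#'
#' The 19 candidate lags: offsets of -9 to +9 s in `step` increments around
#' the bulk lag.
#'
#' @param bulk_lag Bulk lag, seconds.
#' @param half_range Half-range of the offsets, seconds.
#' @param step Offset step, seconds.
#' @return A `lag_grid` list with `bulk_lag`, `offsets`, `absolute_lags`.
#' @export
lag_grid <- function(bulk_lag, half_range = 9, step = 1) {
  offsets <- seq(-half_range, half_range, by = step)
  structure(list(bulk_lag = bulk_lag, offsets = offsets,
                 absolute_lags = bulk_lag + offsets),
            class = "lag_grid")
}

# Validate / clean a confound matrix against a design; drops collinear
# confound columns (never the regressor of interest) with a warning.
.clean_confounds <- function(confounds, n) {
  if (is.null(confounds)) return(NULL)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != n) stop("confounds and series disagree in length")
  keep <- apply(confounds, 2, function(col) stats::sd(col) > 1e-12)
  confounds <- confounds[, keep, drop = FALSE]
  if (!ncol(confounds)) return(NULL)
  q <- qr(cbind(1, confounds))
  if (q$rank < ncol(confounds) + 1) {
    drop <- sort(q$pivot[-seq_len(q$rank)]) - 1L
    drop <- drop[drop >= 1L]
    warning("dropping ", length(drop), " collinear confound column(s)")
    confounds <- confounds[, -drop, drop = FALSE]
  }
  confounds
}

#' Fit the voxelwise GLM for one voxel and one regressor
#'
#' Ordinary least squares on `[intercept | x | confounds]`. The partial
#' F-statistic tests the regressor of interest alone: the reduced model
#' omits `x` and keeps everything else, and
#' `F = (RSS_reduced - RSS_full) / (RSS_full / (T - p_full))`.
#'
#' @param y Voxel time series.
#' @param x Regressor of interest (same length).
#' @param confounds Optional confound matrix.
#' @return List with `beta` (coefficient of `x`), `partial_f`, and `dof`
#'   (numerator, residual).
#' @export
fit_voxel_glm <- function(y, x, confounds = NULL) {
  n <- length(y)
  stopifnot(length(x) == n)
  confounds <- .clean_confounds(confounds, n)
  Z <- cbind(intercept = rep(1, n), confounds)
  X <- cbind(Z, x = x)
  p <- ncol(X)
  if (n <= p) stop("insufficient degrees of freedom (T <= p)")
  qx <- qr(X)
  if (qx$rank < p) stop("regressor of interest is collinear with confounds")
  beta <- qr.coef(qx, y)
  rss_full <- sum(qr.resid(qx, y)^2)
  rss_red <- sum(qr.resid(qr(Z), y)^2)
  dof <- n - p
  f <- max(0, (rss_red - rss_full)) / (rss_full / dof)
  list(beta = unname(beta["x"]), partial_f = f, dof = c(1, dof))
}

# Pooled-rho AR(1) pre-whitening (Cochrane-Orcutt single pass): estimates a
# single lag-1 autocorrelation from reduced-model residuals pooled over
# voxels and quasi-differences both data and design.
.prewhiten <- function(Y, Z) {
  R <- Y - Z %*% qr.coef(qr(Z), Y)
  num <- sum(R[-1, ] * R[-nrow(R), ])
  den <- sum(R[-nrow(R), ]^2)
  rho <- if (den > 0) num / den else 0
  rho <- max(min(rho, 0.99), -0.99)
  transform <- function(M) M[-1, , drop = FALSE] -
    rho * M[-nrow(M), , drop = FALSE]
  list(rho = rho, transform = transform)
}

#' Sweep candidate lags and select the per-voxel optimum
#'
#' Fits, for every in-mask voxel, the GLM at each candidate lag (the
#' confounds are identical across candidates; only the regressor of interest
#' changes) and selects the lag with the highest partial F-statistic. Exact
#' F ties are broken towards the smallest absolute offset from the bulk lag,
#' then the more negative lag.
#'
#' @param bold A [bold_dataset()].
#' @param source A `regressor_source`.
#' @param grid A [lag_grid()].
#' @param confounds Optional confound matrix (volumes x k).
#' @param mask Logical 3D array (defaults to the brain mask).
#' @param prewhiten Apply single-pass pooled AR(1) pre-whitening (default
#'   `FALSE`).
#' @param column_filter Optional function applied to each candidate column
#'   before normalization (used to apply the same temporal filtering to the
#'   design as to the data).
#' @return A `voxel_fit_maps` list with 3D arrays `beta`, `partial_f`,
#'   `lag_opt` (NA outside the mask), plus `mask`, `dof`, `grid`,
#'   `boundary_fraction` (share of voxels selecting an extreme offset) and
#'   `mu` (voxel temporal means).
#' @export
sweep_and_select <- function(bold, source, grid, confounds = NULL,
                             mask = NULL, prewhiten = FALSE,
                             column_filter = NULL) {
  stopifnot(inherits(bold, "bold_dataset"), inherits(grid, "lag_grid"))
  if (is.null(mask)) mask <- bold$brain_mask
  if (!any(mask)) stop("empty mask")
  Y <- .ts_matrix(bold$data, mask)
  n <- nrow(Y)
  nv <- ncol(Y)
  mu <- colMeans(Y)
  confounds <- .clean_confounds(confounds, n)
  Z <- cbind(rep(1, n), confounds)
  cols <- lapply(grid$absolute_lags, function(lg) {
    x <- shift_and_sample(source, lg, tr = bold$tr, n_vols = n,
                          normalize = is.null(column_filter))
    if (!is.null(column_filter)) {
      x <- column_filter(x)
      rng <- range(x)
      if (diff(rng) < 1e-12) stop("degenerate regressor after filtering")
      x <- (x - rng[1]) / diff(rng)
    }
    x
  })
  if (prewhiten) {
    pw <- .prewhiten(Y, Z)
    Y <- pw$transform(Y)
    Z <- pw$transform(Z)
    cols <- lapply(cols, function(x) drop(pw$transform(matrix(x))))
    n <- nrow(Y)
  }
  p <- ncol(Z) + 1L
  if (n <= p) stop("insufficient degrees of freedom (T <= p)")
  rss_red <- colSums(qr.resid(qr(Z), Y)^2)
  dof <- n - p

  best_f <- rep(-Inf, nv)
  best_beta <- rep(NA_real_, nv)
  best_lag <- rep(NA_real_, nv)
  best_off <- rep(NA_real_, nv)
  # visit candidates in tie-break priority order (|offset| asc, lag asc);
  # a later candidate replaces the incumbent only with strictly higher F
  ord <- order(abs(grid$offsets), grid$absolute_lags)
  for (j in ord) {
    X <- cbind(Z, cols[[j]])
    qx <- qr(X)
    if (qx$rank < p) next
    beta <- qr.coef(qx, Y)[p, ]
    rss_full <- colSums(qr.resid(qx, Y)^2)
    f <- pmax(0, rss_red - rss_full) / (rss_full / dof)
    upd <- f > best_f + 1e-12
    best_f[upd] <- f[upd]
    best_beta[upd] <- beta[upd]
    best_lag[upd] <- grid$absolute_lags[j]
    best_off[upd] <- grid$offsets[j]
  }
  shape <- dim(bold$data)[1:3]
  to_map <- function(v) {
    m <- array(NA_real_, shape)
    m[mask] <- v
    m
  }
  hr <- max(abs(grid$offsets))
  structure(list(
    beta = to_map(best_beta), partial_f = to_map(best_f),
    lag_opt = to_map(best_lag), mask = mask, dof = c(1, dof), grid = grid,
    boundary_fraction = mean(abs(best_off) >= hr - 1e-9, na.rm = TRUE),
    mu = to_map(mu)
  ), class = "voxel_fit_maps")
}

#' Joint voxelwise optimization of HRF delay and lag
#'
#' Runs the lag sweep for every HRF delay in the bank and keeps, per voxel,
#' the (delay, lag) pair with the highest partial F. This joint search is
#' known to be poorly conditioned at realistic noise levels: the strong
#' interaction between HRF delay and lag concentrates the estimated delays
#' at the extremes of the grid.
#'
#' @param bold A [bold_dataset()].
#' @param sources Named list of `regressor_source`, one per HRF delay
#'   (names coercible to numeric delays).
#' @param grids List of [lag_grid()], one per source (or a single grid
#'   recycled).
#' @param confounds Optional confound matrix.
#' @param mask Logical 3D array.
#' @param prewhiten Logical.
#' @return A `voxel_fit_maps` with an additional 3D array `delay_opt`.
#' @export
optimize_delay_and_lag <- function(bold, sources, grids, confounds = NULL,
                                   mask = NULL, prewhiten = FALSE) {
  if (length(sources) < 2) stop("need at least 2 HRF delays")
  if (inherits(grids, "lag_grid")) grids <- rep(list(grids), length(sources))
  delays <- as.numeric(names(sources))
  if (any(is.na(delays))) stop("`sources` must be named by HRF delay")
  best <- NULL
  for (i in seq_along(sources)) {
    fit <- sweep_and_select(bold, sources[[i]], grids[[i]],
                            confounds = confounds, mask = mask,
                            prewhiten = prewhiten)
    if (is.null(best)) {
      best <- fit
      best$delay_opt <- fit$lag_opt * 0 + delays[i]
    } else {
      upd <- !is.na(fit$partial_f) &
        (is.na(best$partial_f) | fit$partial_f > best$partial_f + 1e-12)
      for (fld in c("beta", "partial_f", "lag_opt"))
        best[[fld]][upd] <- fit[[fld]][upd]
      best$delay_opt[upd] <- delays[i]
    }
  }
  best
}
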