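# Shared fixtures built in code.

# Small ground truth with uniform tissue parameters and grid-aligned lags.
small_truth <- function(shape = c(8, 8, 4), gm_lag = 0, wm_lag = 0,
                        lag_sd = 0, mean_signal_sd = 0, ...) {
  make_ground_truth(shape = shape, gm_lag = gm_lag, wm_lag = wm_lag,
                    lag_sd = lag_sd, mean_signal_sd = mean_signal_sd, ...)
}

# A minimal regressor source from an arbitrary series on a uniform grid.
as_source <- function(values, dt = 0.1, t0 = 0, type = "Block") {
  structure(list(time = t0 + (seq_along(values) - 1) * dt, values = values,
                 grid_dt = dt, type = type, convolution = "WoC",
                 hrf_delay = NA_real_),
            class = "regressor_source")
}

# Brute-force OLS via lm(), used as the independent oracle for the GLM.
oracle_fit <- function(y, x, confounds = NULL) {
  df <- data.frame(y = y, x = x)
  if (is.null(confounds)) {
    full <- stats::lm(y ~ x, data = df)
    red <- stats::lm(y ~ 1, data = df)
  } else {
    cf <- as.matrix(confounds)
    full <- stats::lm(y ~ x + cf)
    red <- stats::lm(y ~ cf)
  }
  rss_f <- sum(stats::residuals(full)^2)
  rss_r <- sum(stats::residuals(red)^2)
  dof <- stats::df.residual(full)
  list(beta = unname(stats::coef(full)["x"]),
       partial_f = (rss_r - rss_f) / (rss_f / dof))
}
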