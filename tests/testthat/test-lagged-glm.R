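make_sine_source <- function() {
  t <- seq(-40, 300, by = 0.1)
  as_source(pmax(0, sin(2 * pi * (t - 10) / 45)), t0 = -40)
}

test_that("bulk lag estimation maximizes the cross-correlation", {
  src <- make_sine_source()
  n <- 200
  self <- shift_and_sample(src, 0, tr = 1.26, n_vols = n)
  b0 <- estimate_bulk_lag(self, src, tr = 1.26)
  expect_equal(as.numeric(b0), 0)
  expect_equal(attr(b0, "correlation"), 1, tolerance = 1e-9)

  delayed <- shift_and_sample(src, 5, tr = 1.26, n_vols = n)
  expect_equal(as.numeric(estimate_bulk_lag(delayed, src, tr = 1.26)), 5)

  far <- shift_and_sample(src, 18, tr = 1.26, n_vols = n)
  expect_warning(bf <- estimate_bulk_lag(far, src, tr = 1.26), "boundary")
  expect_equal(abs(as.numeric(bf)), 15)
  expect_error(estimate_bulk_lag(rep(1, n), src, tr = 1.26), "constant")
})

test_that("single-voxel GLM matches exact and closed-form results", {
  set.seed(5)
  x <- stats::rnorm(100)
  y <- 2 * x + 3
  fit <- fit_voxel_glm(y, x)
  expect_equal(fit$beta, 2, tolerance = 1e-12)

  # confound-free partial F equals r^2 (T-2) / (1 - r^2)
  y2 <- 2 * x + stats::rnorm(100)
  fit2 <- fit_voxel_glm(y2, x)
  r <- stats::cor(x, y2)
  expect_equal(fit2$partial_f, r^2 * (100 - 2) / (1 - r^2), tolerance = 1e-9)
  expect_equal(fit2$dof, c(1, 98))

  # a confound orthogonal to x and y leaves beta unchanged
  ortho <- stats::residuals(stats::lm(stats::rnorm(100) ~ x + y2))
  fit3 <- fit_voxel_glm(y2, x, confounds = cbind(ortho))
  expect_equal(fit3$beta, fit2$beta, tolerance = 1e-9)

  # independent lm() oracle with arbitrary confounds
  cf <- matrix(stats::rnorm(300), 100, 3)
  mine <- fit_voxel_glm(y2, x, confounds = cf)
  orac <- oracle_fit(y2, x, cf)
  expect_equal(mine$beta, orac$beta, tolerance = 1e-10)
  expect_equal(mine$partial_f, orac$partial_f, tolerance = 1e-8)

  expect_error(suppressWarnings(
    fit_voxel_glm(y[1:3], x[1:3], confounds = cbind(x[1:3] * 2, x[1:3]))),
    "degrees of freedom|collinear")
})

test_that("lag sweep recovers noiseless voxels exactly and honors the argmax contract", {
  tr <- small_truth(shape = c(6, 6, 3), gm_lag = 2, wm_lag = -3)
  p <- make_paradigm()
  src <- make_sine_source()
  bold <- simulate_bold(p, tr, src, tr = 1.26)
  fit <- sweep_and_select(bold, src, lag_grid(0))
  sel <- tr$tissue > 0
  expect_equal(fit$lag_opt[sel], tr$lag[sel])
  beta_true <- tr$mean_signal * tr$cvr * tr$delta_petco2 / 100
  expect_lt(max(abs(fit$beta[sel] - beta_true[sel]) / beta_true[sel]), 1e-6)
  expect_true(all(is.na(fit$beta[!bold$brain_mask])))
})

test_that("vectorized sweep equals the brute-force per-voxel per-lag OLS loop", {
  set.seed(8)
  nv <- 50
  truth <- make_ground_truth(shape = c(nv + 2, 3, 3), mean_signal_sd = 100,
                             gm_lag = 0, wm_lag = 0)
  truth$lag[truth$tissue > 0] <- sample(-4:4, sum(truth$tissue > 0), TRUE)
  p <- make_paradigm()
  src <- make_sine_source()
  bold <- simulate_bold(p, truth, src, tr = 1.26, noise_sd = 0.02,
                        motion = simulate_motion(213, seed = 1),
                        motion_amp = 0.004, seed = 9)
  mask <- array(FALSE, dim(truth$cvr))
  mask[truth$brain_mask][seq_len(nv)] <- TRUE
  cf <- confound_matrix(bold$motion)
  grid <- lag_grid(0)
  fit <- sweep_and_select(bold, src, grid, confounds = cf, mask = mask)

  Y <- matrix(bold$data, ncol = dim(bold$data)[4])[as.vector(mask), ]
  cols <- lapply(grid$absolute_lags, function(lg)
    shift_and_sample(src, lg, tr = 1.26, n_vols = ncol(Y)))
  worst_beta <- 0
  for (v in seq_len(nv)) {
    y <- Y[v, ]
    fs <- vapply(cols, function(x) oracle_fit(y, x, cf)$partial_f, numeric(1))
    bs <- vapply(cols, function(x) oracle_fit(y, x, cf)$beta, numeric(1))
    best <- which.max(fs)
    vox <- which(mask)[v]
    expect_equal(fit$lag_opt[vox], grid$absolute_lags[best])
    worst_beta <- max(worst_beta, abs(fit$beta[vox] - bs[best]))
    # argmax contract: the selected F dominates every candidate
    expect_gte(fit$partial_f[vox] + 1e-8, max(fs))
  }
  expect_lt(worst_beta, 1e-8)
})

test_that("scaling the data scales beta and leaves the partial F unchanged", {
  tr <- small_truth(shape = c(5, 5, 3), gm_lag = 1, wm_lag = -1)
  p <- make_paradigm()
  src <- make_sine_source()
  set.seed(12)
  bold <- simulate_bold(p, tr, src, tr = 1.26, noise_sd = 0.01)
  fit1 <- sweep_and_select(bold, src, lag_grid(0))
  scaled <- bold
  scaled$data <- bold$data * 3
  fit2 <- sweep_and_select(scaled, src, lag_grid(0))
  sel <- bold$brain_mask
  expect_equal(fit2$beta[sel], 3 * fit1$beta[sel], tolerance = 1e-9)
  expect_equal(fit2$partial_f[sel], fit1$partial_f[sel], tolerance = 1e-9)
  expect_identical(fit2$lag_opt[sel], fit1$lag_opt[sel])
})

test_that("pure-noise voxels still yield finite fits on the grid", {
  set.seed(30)
  data <- array(stats::rnorm(4 * 4 * 2 * 213, 100, 5), dim = c(4, 4, 2, 213))
  bold <- bold_dataset(data, tr = 1.26)
  fit <- sweep_and_select(bold, make_sine_source(), lag_grid(0))
  expect_true(all(is.finite(fit$partial_f)))
  expect_true(all(fit$lag_opt %in% lag_grid(0)$absolute_lags))
  expect_true(all(fit$partial_f >= 0))
})

test_that("joint delay/lag search recovers the generating delay without noise", {
  tr <- small_truth(shape = c(5, 5, 3), gm_lag = 1, wm_lag = -1)
  p <- make_paradigm()
  cap <- simulate_capnograph(p, noise_sd = 0)
  pet <- process_capnograph(cap)
  gen <- build_regressor_source(list(type = "Block", convolution = "CSg",
                                     hrf_delay = 6), p, pet)
  bold <- simulate_bold(p, tr, gen, tr = 1.26)
  sources <- lapply(c(3, 6, 9), function(d)
    build_regressor_source(list(type = "Block", convolution = "CSg",
                                hrf_delay = d), p, pet))
  names(sources) <- c(3, 6, 9)
  joint <- optimize_delay_and_lag(bold, sources, lag_grid(0))
  sel <- tr$tissue > 0
  expect_true(all(joint$delay_opt[sel] == 6))
  expect_equal(joint$lag_opt[sel], tr$lag[sel])
  expect_error(optimize_delay_and_lag(bold, sources[2], lag_grid(0)),
               "at least 2")
})

test_that("pooled AR(1) pre-whitening leaves noiseless estimates intact", {
  tr <- small_truth(shape = c(5, 5, 3))
  p <- make_paradigm()
  src <- make_sine_source()
  bold <- simulate_bold(p, tr, src, tr = 1.26)
  fit <- sweep_and_select(bold, src, lag_grid(0), prewhiten = TRUE)
  sel <- tr$tissue > 0
  beta_true <- tr$mean_signal * tr$cvr * tr$delta_petco2 / 100
  expect_lt(max(abs(fit$beta[sel] - beta_true[sel]) / beta_true[sel]), 1e-6)
})
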