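test_that("block regressor is a boxcar over the holds", {
  p <- make_paradigm()
  src <- build_block(p, grid_dt = 0.1)
  expect_equal(sum(src$values) * src$grid_dt, 60, tolerance = 0.2 + 1e-9)

  p1 <- make_paradigm(n_trials = 1, hold = 15, baseline = 10, lead_in = 0)
  s1 <- build_block(p1)
  expect_equal(s1$values[which.min(abs(s1$time - 12))], 1)
  expect_equal(s1$values[which.min(abs(s1$time - 5))], 0)

  p0 <- make_paradigm(n_trials = 0, lead_in = 10, trailing = 10)
  expect_true(all(build_block(p0)$values == 0))
})

test_that("PetCO2 regressor source tracks the processed trace", {
  p <- make_paradigm()
  cap <- simulate_capnograph(p, noise_sd = 0)
  pet <- process_capnograph(cap)
  src <- build_petco2(pet, p)
  in_cov <- src$time >= min(pet$time) & src$time <= max(pet$time)
  ref <- stats::approx(pet$time, pet$values, xout = src$time[in_cov])$y
  expect_gte(stats::cor(src$values[in_cov], ref), 0.999)
  # constant trace -> constant source
  petc <- pet; petc$values <- rep(40, length(pet$values))
  expect_true(all(build_petco2(petc, p)$values == 40))
  # coverage error
  short <- pet
  keep <- pet$time < p$total_duration / 3
  short$time <- pet$time[keep]; short$values <- pet$values[keep]
  expect_error(build_petco2(short, p), "half")
})

test_that("convolution is causal, linear, and preserves sustained amplitude", {
  k <- hrf_kernel(hrf_params(6, "single"))
  x <- as_source(c(rep(0, 50), 1, rep(0, 500)))
  # identity without kernel
  expect_identical(convolve_regressor(x, NULL)$values, x$values)
  # impulse response equals the kernel
  conv <- convolve_regressor(x, k)
  expect_equal(conv$values[51:(51 + length(k$samples) - 1)], k$samples,
               tolerance = 1e-12)
  expect_true(all(abs(conv$values[1:50]) < 1e-14)) # causality
  # unit-sum kernel preserves a long plateau
  box <- as_source(c(rep(0, 100), rep(1, 800), rep(0, 100)))
  plateau <- convolve_regressor(box, k)$values[600]
  expect_equal(plateau, 1, tolerance = 1e-6)
  # linearity
  a <- as_source(stats::rnorm(400)); b <- as_source(stats::rnorm(400))
  lhs <- convolve_regressor(as_source(2 * a$values + 3 * b$values), k)$values
  rhs <- 2 * convolve_regressor(a, k)$values + 3 * convolve_regressor(b, k)$values
  expect_equal(lhs, rhs, tolerance = 1e-9)
  # grid mismatch
  k2 <- hrf_kernel(hrf_params(6, "single"), dt = 0.2)
  expect_error(convolve_regressor(x, k2), "grid")
})

test_that("shift-and-sample delays, samples and normalizes correctly", {
  t <- seq(-20, 120, by = 0.1)
  src <- as_source(sin(2 * pi * t / 40), t0 = -20)
  v <- shift_and_sample(src, lag = 0, tr = 1, n_vols = 80)
  expect_equal(min(v), 0)
  expect_equal(max(v), 1)
  # normalization idempotence
  rng <- range(v)
  expect_identical((v - rng[1]) / diff(rng), v)
  # shift round trip on the high-res series (interior)
  fwd <- shift_series(src, 3)
  back <- shift_series(fwd, -3)
  interior <- src$time > -10 & src$time < 110
  expect_equal(back$values[interior], src$values[interior], tolerance = 1e-6)
  # positive lag = later response: shifted series peaks later
  raw0 <- shift_and_sample(src, 0, tr = 1, n_vols = 80, normalize = FALSE)
  raw5 <- shift_and_sample(src, 5, tr = 1, n_vols = 80, normalize = FALSE)
  expect_equal(which.max(raw5) - which.max(raw0), 5)
  # degenerate constant series
  expect_error(shift_and_sample(as_source(rep(1, 100)), 0, 1, 50),
               "degenerate")
})

test_that("the six model variants are enumerable from one config", {
  g <- enumerate_models()
  expect_equal(nrow(g), 6)
  expect_equal(length(unique(g$label)), 6)
  expect_setequal(unique(g$type), c("PetCO2", "Block"))
  expect_setequal(unique(g$convolution), c("WoC", "CSg", "CDb"))
  expect_true(all(is.na(g$hrf_delay[g$convolution == "WoC"])))
})

test_that("motion parameter expansion follows the 24-column convention", {
  z <- matrix(0, 10, 6)
  expect_true(all(extend_motion_params(z) == 0))
  expect_equal(ncol(extend_motion_params(z)), 24)

  cst <- matrix(rep(c(1, -2, 0.5, 3, -1, 2), each = 10), 10, 6)
  ext <- extend_motion_params(cst)
  expect_true(all(ext[, 7:12] == 0))                 # derivatives of constant
  expect_equal(ext[5, 13:18], cst[5, ]^2, ignore_attr = TRUE)

  m <- matrix(stats::rnorm(60), 10, 6)
  ext <- extend_motion_params(m)
  expect_equal(ext[2:10, 7:12], diff(m), ignore_attr = TRUE)
  expect_true(all(ext[1, 7:12] == 0))
  expect_error(extend_motion_params(m[, 1:5]), "6 columns")
})

test_that("motion outliers are detected by the RMS-to-reference rule", {
  tr <- small_truth(shape = c(6, 6, 3))
  p <- make_paradigm()
  src <- build_block(p)
  set.seed(21)
  bold <- simulate_bold(p, tr, src, tr = 1.26, noise_sd = 0.01)
  # identical volumes: no outliers
  clean <- bold
  clean$data <- array(rep(bold$data[, , , 1], dim(bold$data)[4]),
                      dim = dim(bold$data))
  out0 <- detect_motion_outliers(clean)
  expect_equal(length(out0$outliers), 0)
  expect_equal(ncol(out0$spikes), 0)
  # reference volume's own metric is zero
  nt <- dim(bold$data)[4]
  expect_equal(detect_motion_outliers(bold)$metric[ceiling(nt / 2)], 0)
  # one heavily perturbed volume is flagged
  spiked <- bold
  spiked$data[, , , 17] <- spiked$data[, , , 17] +
    50 * 0.01 * mean(tr$mean_signal)
  out1 <- detect_motion_outliers(spiked)
  expect_true(17 %in% out1$outliers)
  expect_true(all(colSums(out1$spikes) == 1))
})

test_that("confound matrix combines motion and spikes", {
  m <- matrix(stats::rnorm(60), 10, 6)
  spikes <- matrix(0, 10, 2); spikes[3, 1] <- 1; spikes[7, 2] <- 1
  cm <- confound_matrix(m, spikes)
  expect_equal(ncol(cm), 26)
  expect_error(confound_matrix(m, matrix(0, 9, 1)), "disagree")
})
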