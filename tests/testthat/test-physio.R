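test_that("tube-delay correction shifts and crops, and round-trips", {
  tr <- structure(data.frame(time = c(0, 1, 2, 3), co2 = c(10, 20, 30, 40)),
                  class = c("capno_trace", "data.frame"))
  expect_equal(correct_tube_delay(tr, 0)$co2, tr$co2)
  shifted <- correct_tube_delay(tr, 2)
  expect_equal(shifted$time, c(0, 1))
  expect_equal(shifted$co2, c(30, 40))
  # round trip on interior samples
  back <- shifted
  back$time <- back$time + 2
  expect_equal(back$co2, tr$co2[tr$time >= 2])
  expect_error(correct_tube_delay(tr, -1))
})

test_that("end-tidal peak detection finds sinusoid maxima and ignores flats", {
  t <- seq(0, 60, by = 0.05)
  tr <- structure(data.frame(time = t, co2 = 20 + 10 * sin(2 * pi * 0.25 * t)),
                  class = c("capno_trace", "data.frame"))
  pk <- detect_end_tidal_peaks(tr, min_period = 2)
  expect_equal(length(pk$peak_times), 15)
  expect_equal(pk$peak_times, seq(1, 57, by = 4), tolerance = 0.05)

  const <- structure(data.frame(time = t, co2 = rep(38, length(t))),
                     class = c("capno_trace", "data.frame"))
  pk0 <- detect_end_tidal_peaks(const, min_period = 2)
  expect_equal(length(pk0$peak_times), 0)
})

test_that("peak detection recovers the generator's stored peaks exactly", {
  p <- make_paradigm()
  cap <- simulate_capnograph(p, noise_sd = 0)
  pk <- detect_end_tidal_peaks(cap, min_period = 2)
  true_t <- attr(cap, "peak_times")
  true_v <- attr(cap, "peak_values")
  expect_equal(length(pk$peak_times), length(true_t))
  expect_equal(pk$peak_times, true_t, tolerance = 1e-9)
  expect_equal(pk$peak_values, true_v, tolerance = 1e-9)
})

test_that("interpolation and detrending behave as a 100 s high-pass", {
  # linear drift -> constant at the mean
  times <- seq(0, 300, by = 4)
  drift <- list(peak_times = times, peak_values = 30 + 0.02 * times)
  out <- interpolate_and_detrend(drift, grid_dt = 0.1, cutoff = 100)
  expect_lt(max(abs(out$values - mean(30 + 0.02 * times))), 0.05)
  # mean preservation
  expect_equal(mean(out$values), mean(signal::pchip(times, drift$peak_values,
                                                    out$time)),
               tolerance = 1e-9)

  # 0.03 Hz sinusoid is inside the passband: amplitude preserved within 10%
  sine <- list(peak_times = times,
               peak_values = 40 + 5 * sin(2 * pi * 0.03 * times))
  outs <- interpolate_and_detrend(sine, grid_dt = 0.1, cutoff = 100)
  interior <- outs$time > 30 & outs$time < 270
  amp <- (max(outs$values[interior]) - min(outs$values[interior])) / 2
  expect_gt(amp, 5 * 0.9)
  expect_lt(amp, 5 * 1.1)

  expect_error(interpolate_and_detrend(list(peak_times = 1,
                                            peak_values = 38)),
               "at least 2")
})

test_that("cubic and linear interpolation agree on smooth traces", {
  p <- make_paradigm()
  cap <- simulate_capnograph(p, noise_sd = 0.3, seed = 4)
  pk <- detect_end_tidal_peaks(cap, min_period = 2)
  grid <- seq(pk$peak_times[1], max(pk$peak_times), by = 0.1)
  cubic <- signal::pchip(pk$peak_times, pk$peak_values, grid)
  linear <- stats::approx(pk$peak_times, pk$peak_values, xout = grid)$y
  expect_gte(stats::cor(cubic, linear), 0.99)
})

test_that("PetCO2 change follows the first-peak-minus-baseline rule", {
  p <- make_paradigm()
  holds_end <- p$trial_onsets + p$hold_duration
  # hand-built peak sequence: baselines at 38, post-hold peaks 46,45,47,46
  pt <- c(); pv <- c()
  for (k in 1:4) {
    bt <- seq(p$trial_onsets[k] - 28, p$trial_onsets[k] - 4, by = 4)
    pt <- c(pt, bt); pv <- c(pv, rep(38, length(bt)))
    pt <- c(pt, holds_end[k] + 2)
    pv <- c(pv, c(46, 45, 47, 46)[k])
  }
  trace <- structure(list(grid_dt = 0.1, time = range(pt), values = pv,
                          peak_times = pt, peak_values = pv),
                     class = "petco2_trace")
  d <- compute_delta_petco2(trace, p)
  expect_equal(d$per_trial, c(8, 7, 9, 8))
  expect_equal(d$mean, 8)
  expect_equal(length(d$per_trial), length(p$trial_onsets))

  # invariant to adding a constant to the whole trace
  tr2 <- trace; tr2$peak_values <- pv + 5; tr2$values <- pv + 5
  d2 <- compute_delta_petco2(tr2, p)
  expect_equal(d2$per_trial, d$per_trial)

  # constant trace -> zero change
  tr3 <- trace; tr3$peak_values <- rep(38, length(pt)); tr3$values <- tr3$peak_values
  expect_equal(compute_delta_petco2(tr3, p)$mean, 0)

  # missing post-hold peak -> trial flagged NA with a warning
  keep <- !(pt > holds_end[2] & pt <= holds_end[2] + 20)
  tr4 <- trace; tr4$peak_times <- pt[keep]; tr4$peak_values <- pv[keep]
  expect_warning(d4 <- compute_delta_petco2(tr4, p), "no end-tidal peak")
  expect_true(is.na(d4$per_trial[2]))
  expect_equal(d4$mean, mean(d4$per_trial, na.rm = TRUE))
})
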