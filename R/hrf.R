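# HRF bank: single- and double-gamma hemodynamic response functions over a
# coupled delay/dispersion grid.

#' HRF parameters for a given delay
#'
#' The hemodynamic response is parametrized by five coupled quantities:
#' time to the positive peak `p1` (the "delay", 3-11 s), time to the
#' undershoot `p2 = (8/3) p1`, dispersion of the positive peak
#' `p3 = p1 / 6`, dispersion of the undershoot `p4 = p3`, and
#' peak-to-undershoot amplitude ratio `p5 = 6`. The canonical response has
#' `p1 = 6` giving (6, 16, 1, 1, 6).
#'
#' @param delay Time to positive peak `p1`, seconds, in [3, 11].
#' @param shape `"single"` (positive lobe only) or `"double"` (positive lobe
#'   plus undershoot).
#' @return An `hrf_params` list with fields `p1`..`p5` and `shape`.
#' @export
hrf_params <- function(delay, shape = c("single", "double")) {
  shape <- match.arg(shape)
  .check_scalar(delay, "delay", lower = 3, upper = 11)
  p3 <- delay / 6
  structure(list(p1 = delay, p2 = (8 / 3) * delay, p3 = p3, p4 = p3,
                 p5 = 6, shape = shape),
            class = "hrf_params")
}

#' Sample an HRF kernel on a regular grid
#'
#' The single-gamma kernel is the Gamma density with shape `p1/p3` and scale
#' `p3` (seconds); the double-gamma subtracts a second Gamma density (shape
#' `p2/p4`, scale `p4`) divided by `p5`. By default the sampled kernel is
#' normalized to unit sum so that convolution preserves the amplitude of a
#' sustained input (DC gain 1), keeping regression coefficients comparable
#' across delays.
#'
#' @param params An [hrf_params()] object.
#' @param dt Sampling interval, seconds.
#' @param duration Kernel support, seconds; must exceed the undershoot time.
#' @param normalize Normalize to unit sum (default `TRUE`).
#' @return An `hrf_kernel` list: `dt`, `time`, `samples`, `duration`,
#'   `params`.
#' @export
hrf_kernel <- function(params, dt = 0.1, duration = 32, normalize = TRUE) {
  stopifnot(inherits(params, "hrf_params"))
  .check_scalar(dt, "dt", lower = 1e-6)
  if (duration <= params$p2)
    stop("kernel `duration` must exceed the undershoot time p2")
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = params$p1 / params$p3, scale = params$p3)
  if (params$shape == "double")
    h <- h - stats::dgamma(t, shape = params$p2 / params$p4,
                           scale = params$p4) / params$p5
  if (normalize) h <- h / sum(h)
  structure(list(dt = dt, time = t, samples = h, duration = duration,
                 params = params),
            class = "hrf_kernel")
}

#' Build the bank of HRF kernels over shapes and delays
#'
#' One kernel per (shape, delay) combination, in deterministic order (shapes
#' in the given order, delays ascending). The standard grid of 9 delays
#' (3-11 s in 1 s steps) for both shapes yields 18 kernels.
#'
#' @param shapes Character vector among `"single"`, `"double"`.
#' @param delays Numeric vector of delays in [3, 11].
#' @param dt Sampling interval, seconds.
#' @param duration Kernel support, seconds.
#' @return Named list of `hrf_kernel` objects (`"<shape>_<delay>"`).
#' @export
hrf_bank <- function(shapes = c("single", "double"), delays = 3:11,
                     dt = 0.1, duration = 32) {
  if (!length(shapes) || !length(delays))
    stop("`shapes` and `delays` must be non-empty")
  shapes <- match.arg(shapes, c("single", "double"), several.ok = TRUE)
  delays <- sort(unique(delays))
  bank <- list()
  for (s in shapes)
    for (d in delays)
      bank[[sprintf("%s_%g", s, d)]] <-
        hrf_kernel(hrf_params(d, s), dt = dt, duration = duration)
  bank
}

#' Export an HRF bank as a long-format table
#'
#' @param bank A list of kernels from [hrf_bank()].
#' @return Data frame with columns `kernel`, `shape`, `delay`, `time`,
#'   `value`, suitable for writing to TSV.
#' @export
hrf_bank_table <- function(bank) {
  do.call(rbind, lapply(names(bank), function(nm) {
    k <- bank[[nm]]
    data.frame(kernel = nm, shape = k$params$shape, delay = k$params$p1,
               time = k$time, value = k$samples)
  }))
}
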