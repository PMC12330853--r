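# Internal numerical helpers shared across modules.

#' @importFrom stats approx dgamma lm.fit median pchisq pt quantile rnorm sd
#'   cor setNames runif
NULL

# Order-2 Butterworth high-pass, run forward-backward, after removing the
# best-fit line (tames filtfilt edge transients on drifting inputs); the
# series mean is re-added so downstream absolute units (mmHg, scanner units)
# are preserved.
.hp_filter <- function(x, fs, cutoff) {
  n <- length(x)
  if (n < 8L) stop("series too short for high-pass detrending", call. = FALSE)
  mu <- mean(x)
  tt <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, tt), x)
  res <- fit$residuals
  w <- (1 / cutoff) / (fs / 2)
  if (w >= 1) stop("detrend cutoff shorter than twice the sampling interval",
                   call. = FALSE)
  bf <- signal::butter(2, w, type = "high")
  y <- signal::filtfilt(bf, res)
  y + mu
}

# Projection high-pass: regresses out a linear trend and the discrete-cosine
# basis functions with frequency below 1/cutoff (demeaned columns, so the
# series mean is preserved exactly). Being a projection it is exactly
# idempotent, unlike a recursive filter.
.hp_project_basis <- function(n, dt, cutoff) {
  total <- n * dt
  K <- floor(2 * total / cutoff)
  tt <- seq_len(n)
  B <- matrix(tt - mean(tt), ncol = 1)
  if (K >= 1) {
    cosines <- sapply(seq_len(K), function(k)
      cos(pi * k * (tt - 0.5) / n))
    B <- cbind(B, sweep(cosines, 2, colMeans(cosines)))
  }
  B
}

.hp_project <- function(x, fs, cutoff) {
  B <- .hp_project_basis(length(x), 1 / fs, cutoff)
  x - B %*% qr.solve(B, x)
}

# 1D Gaussian kernel truncated at 3 sigma, unit sum.
.gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# Convolve a vector with a symmetric kernel using reflect boundary.
.conv_reflect <- function(x, k) {
  m <- length(k)
  if (m == 1L) return(x)
  r <- (m - 1L) %/% 2L
  n <- length(x)
  if (n == 1L) return(x)
  pad_l <- x[pmin(n, r + 1L):2L]
  pad_r <- x[(n - 1L):pmax(1L, n - r)]
  if (r >= n) { # degenerate tiny axis: fall back to cyclic extension of reflect
    idx <- c(rev(seq_len(n)[-1L]), seq_len(n), rev(seq_len(n))[-1L])
    ext <- x[idx]
    need <- r - (n - 1L)
    ext <- c(rep(x[n], need), ext, rep(x[1L], need))
  } else {
    ext <- c(pad_l, x, pad_r)
  }
  out <- stats::convolve(ext, rev(k), type = "open")
  out[m:(m + n - 1L)] # part aligned with the original samples
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

.check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

# Flatten a 4D array to a time-by-voxel matrix restricted to a logical mask.
.ts_matrix <- function(data4d, mask) {
  d <- dim(data4d)
  nt <- d[4]
  m <- matrix(data4d, ncol = nt)
  t(m[as.vector(mask), , drop = FALSE])
}

# Write a time-by-voxel matrix back into the masked voxels of a 4D array.
.ts_unflatten <- function(data4d, mask, ts) {
  d <- dim(data4d)
  m <- matrix(data4d, ncol = d[4])
  m[as.vector(mask), ] <- t(ts)
  array(m, dim = d)
}
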