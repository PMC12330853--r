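# Independent brute-force rank implementations (loops, no shared code with
# the package) used as oracles for the comparison statistics.

bf_friedman <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- matrix(0, n, k)
  for (i in 1:n) r[i, ] <- rank(m[i, ])
  Rj <- numeric(k)
  for (j in 1:k) Rj[j] <- sum(r[, j])
  ties <- 0
  for (i in 1:n) for (tt in table(m[i, ])) ties <- ties + tt^3 - tt
  C <- 1 - ties / (n * k * (k^2 - 1))
  if (C <= 0) return(0)
  (12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)) / C
}

bf_conover <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  Rj <- colSums(r)
  A <- sum(r^2); B <- sum(Rj^2) / n
  df <- (n - 1) * (k - 1)
  se <- sqrt(2 * n * (A - B) / df)
  p <- matrix(1, k, k)
  for (i in 1:k) for (j in 1:k) if (i != j)
    p[i, j] <- 2 * stats::pt(abs(Rj[i] - Rj[j]) / se, df, lower.tail = FALSE)
  p
}
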