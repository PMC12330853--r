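# Model-comparison module: Friedman test with tie correction, Conover
# post-hoc pairwise comparisons, Bonferroni correction, and a paired
# sign-flip permutation test.

.check_blocks <- function(data) {
  data <- as.matrix(data)
  if (any(is.na(data))) stop("complete-block design required (no missing cells)")
  if (nrow(data) < 2 || ncol(data) < 2)
    stop("need at least 2 subjects and 2 conditions")
  data
}

#' Friedman rank test for repeated measures
#'
#' Within-subject ranks (average ranks for ties) are computed across
#' conditions; the chi-square approximated statistic, with the standard tie
#' correction, tests whether the conditions differ in location. With every
#' subject constant across conditions the statistic is 0 and p = 1.
#'
#' @param data Numeric subjects x conditions matrix (complete blocks).
#' @return List with `statistic`, `df` (`k - 1`) and `p_value`.
#' @export
friedman_test <- function(data) {
  data <- .check_blocks(data)
  n <- nrow(data); k <- ncol(data)
  r <- t(apply(data, 1, rank))
  Rj <- colSums(r)
  # tie correction: 1 - sum(t^3 - t) / (n k (k^2 - 1)) over tie groups
  ties <- sum(apply(data, 1, function(row) {
    tab <- table(row)
    sum(tab^3 - tab)
  }))
  C <- 1 - ties / (n * k * (k^2 - 1))
  if (C <= 0) # every row fully tied
    return(list(statistic = 0, df = k - 1, p_value = 1))
  stat <- (12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)) / C
  stat <- max(0, stat)
  list(statistic = stat, df = k - 1,
       p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE))
}

#' Conover post-hoc pairwise comparisons after a Friedman test
#'
#' Rank-based pairwise tests on the Friedman design: for conditions j and
#' j', `t = (R_j - R_j') / sqrt(2 n (A - B) / ((n-1)(k-1)))` with `A` the
#' sum of squared within-subject ranks and `B` the mean squared column rank
#' sum, referred to a t distribution with `(n-1)(k-1)` degrees of freedom
#' (tie-robust through `A`).
#'
#' @param data Numeric subjects x conditions matrix.
#' @param p_adjust_method Adjustment applied to the pairwise p-values
#'   (default `"none"`; use `"bonferroni"` for the corrected table).
#' @return List with symmetric matrices `statistic` and `p_value`
#'   (diagonal 1) and `df`.
#' @export
conover_posthoc <- function(data, p_adjust_method = "none") {
  data <- .check_blocks(data)
  n <- nrow(data); k <- ncol(data)
  r <- t(apply(data, 1, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  B <- sum(Rj^2) / n
  df <- (n - 1) * (k - 1)
  denom <- sqrt(2 * n * (A - B) / df)
  stat <- outer(Rj, Rj, "-") / if (denom > 0) denom else Inf
  p <- 2 * stats::pt(abs(stat), df = df, lower.tail = FALSE)
  if (denom == 0) { # perfect agreement: differing rank sums are maximally separated
    p[] <- ifelse(outer(Rj, Rj, "-") == 0, 1, 0)
  }
  diag(p) <- 1
  if (p_adjust_method != "none") {
    off <- upper.tri(p)
    p[off] <- stats::p.adjust(p[off], method = p_adjust_method)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  dimnames(stat) <- dimnames(p) <- list(colnames(data), colnames(data))
  list(statistic = stat, p_value = p, df = df)
}

#' Bonferroni correction
#'
#' Adjusted p-values `min(1, p * m)` and significance flags at the
#' corrected threshold `alpha / m` (e.g. 0.05 / 6 = 0.0083, 0.05 / 3 =
#' 0.0167).
#'
#' @param p Raw p-values.
#' @param m Number of comparisons (defaults to `length(p)`).
#' @param alpha Family-wise error rate.
#' @return List with `adjusted`, `significant`, `threshold`.
#' @export
bonferroni <- function(p, m = length(p), alpha = 0.05) {
  if (!.is_count(m) || m < 1) stop("`m` must be a positive integer")
  list(adjusted = pmin(1, p * m),
       significant = p < alpha / m,
       threshold = alpha / m)
}

#' Paired sign-flip permutation test
#'
#' Two-sided test of mean(a - b) = 0 under random sign flips of the paired
#' differences. When the full enumeration (2^n sign patterns) fits within
#' `n_perm`, the exact permutation p-value is returned; otherwise a seeded
#' Monte Carlo estimate (including the observed pattern) is used.
#'
#' @param a,b Paired numeric vectors (length >= 2).
#' @param n_perm Permutation budget.
#' @param seed Integer seed for the Monte Carlo branch.
#' @return List with `p_value`, `observed` (mean difference) and `exact`.
#' @export
paired_signflip_test <- function(a, b, n_perm = 10000, seed = NULL) {
  if (length(a) != length(b) || length(a) < 2)
    stop("`a` and `b` must be paired vectors of length >= 2")
  d <- a - b
  n <- length(d)
  obs <- mean(d)
  if (2^n <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats_perm <- abs(as.vector(signs %*% d) / n)
    p <- mean(stats_perm >= abs(obs) - 1e-12)
    return(list(p_value = p, observed = obs, exact = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n * (n_perm - 1), replace = TRUE),
                  ncol = n)
  stats_perm <- c(abs(obs), abs(as.vector(flips %*% d) / n))
  p <- mean(stats_perm >= abs(obs) - 1e-12)
  list(p_value = p, observed = obs, exact = FALSE)
}

#' Compare models from stacked ROI summaries
#'
#' Pivots a long table of per-subject, per-model ROI means into a subjects x
#' models matrix for a chosen metric and tissue, then runs the Friedman
#' test and Conover post-hoc with Bonferroni correction.
#'
#' @param summaries Data frame as produced by stacking [roi_summary()] rows
#'   across subjects and models.
#' @param metric One of `"mean_f"`, `"mean_cvr"`, `"mean_lag_rel"`.
#' @param tissue `"GM"` or `"WM"`.
#' @param alpha Family-wise error rate for the corrected post-hoc flags.
#' @return List with `matrix`, `friedman`, `conover`, `bonferroni`.
#' @export
compare_models <- function(summaries, metric = "mean_f", tissue = "GM",
                           alpha = 0.05) {
  metric <- match.arg(metric, c("mean_f", "mean_cvr", "mean_lag_rel"))
  sub <- summaries[summaries$tissue == tissue, , drop = FALSE]
  mat <- stats::xtabs(stats::as.formula(paste(metric, "~ subject + model")),
                      data = sub)
  mat <- matrix(as.numeric(mat), nrow = nrow(mat),
                dimnames = dimnames(mat))
  fr <- friedman_test(mat)
  co <- conover_posthoc(mat)
  m <- choose(ncol(mat), 2)
  off <- upper.tri(co$p_value)
  bf <- bonferroni(co$p_value[off], m = m, alpha = alpha)
  list(matrix = mat, friedman = fr, conover = co, bonferroni = bf)
}
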