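#' Anderson-Darling test of normality
#'
#' Tests a sample against a normal distribution with estimated mean and
#' standard deviation, using the small-sample-modified \eqn{A^2} statistic
#' and the standard estimated-parameters p-value approximation. The
#' statistic is invariant under affine rescaling of the sample.
#'
#' @param x Numeric sample with at least 8 non-missing values.
#' @return A one-row tibble: `a_squared`, `p_value`, `n`.
#' @export
ad_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 8) abort("need at least 8 observations.")
  if (sd(x) == 0) abort("constant sample: normality test undefined.")
  res <- nortest::ad.test(x)
  tibble::tibble(a_squared = unname(res$statistic),
                 p_value = res$p.value, n = length(x))
}

#' One-sample t-test
#'
#' @param x Numeric sample, at least 2 non-missing, non-constant values.
#' @param mu0 Reference mean.
#' @return A one-row tibble: `estimate` (sample mean), `t`, `df`,
#'   `p_value` (two-sided).
#' @export
one_sample_t <- function(x, mu0 = 0) {
  x <- x[!is.na(x)]
  if (length(x) < 2) abort("need at least 2 observations.")
  if (sd(x) == 0) abort("constant sample: t-test undefined.")
  tt <- t.test(x, mu = mu0)
  tibble::tibble(estimate = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value)
}

#' Sample size for a one-proportion test
#'
#' Smallest number of trials giving the target power for a two-sided
#' one-proportion z test of `p0` against the alternative `p1`, by the
#' plain normal approximation (no continuity correction):
#' \deqn{n \ge \left(\frac{z_{1-\alpha/2}\sqrt{p_0 q_0} +
#'   z_{power}\sqrt{p_1 q_1}}{p_1 - p_0}\right)^2.}
#'
#' @param p0 Null proportion.
#' @param p1 Alternative proportion (`p1 != p0`).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Integer sample size.
#' @examples
#' sample_size_one_proportion(0.5, 0.54)   # 1225
#' @export
sample_size_one_proportion <- function(p0, p1, alpha = 0.05, power = 0.8) {
  if (any(c(p0, p1) <= 0) || any(c(p0, p1) >= 1)) {
    abort("proportions must be strictly between 0 and 1.")
  }
  if (p1 == p0) abort("`p1` must differ from `p0`.")
  num <- qnorm(1 - alpha / 2) * sqrt(p0 * (1 - p0)) +
    qnorm(power) * sqrt(p1 * (1 - p1))
  as.integer(ceiling((num / (p1 - p0))^2))
}

#' Power of a one-proportion test
#'
#' Two-sided normal-approximation power of the one-proportion z test,
#' inverse-consistent with [sample_size_one_proportion()]. At `p1 == p0`
#' the power equals the level `alpha`.
#'
#' @inheritParams sample_size_one_proportion
#' @param n Number of trials.
#' @return Power in `(0, 1)`.
#' @examples
#' power_one_proportion(0.5, 0.54, 1225)   # about 0.80
#' @export
power_one_proportion <- function(p0, p1, n, alpha = 0.05) {
  if (any(c(p0, p1) <= 0) || any(c(p0, p1) >= 1)) {
    abort("proportions must be strictly between 0 and 1.")
  }
  if (any(n < 1)) abort("`n` must be at least 1.")
  za <- qnorm(1 - alpha / 2)
  s0 <- sqrt(p0 * (1 - p0)) ; s1 <- sqrt(p1 * (1 - p1))
  delta <- (p1 - p0) * sqrt(n)
  pnorm((delta - za * s0) / s1) + pnorm((-delta - za * s0) / s1)
}

#' Cronbach's alpha for inter-observer consistency
#'
#' Internal-consistency coefficient over an items-by-raters matrix
#' (e.g. 0/1-coded left/right scores given by several observers to the
#' same individuals):
#' \deqn{\alpha = \frac{k}{k-1}\left(1 -
#'   \frac{\sum_j s_j^2}{s_{total}^2}\right)}
#' with `k` raters, \eqn{s_j^2} the per-rater variance over items and
#' \eqn{s_{total}^2} the variance of the per-item rater sums (all with
#' `n - 1` denominators). A value of 0.7 or higher is the conventional
#' threshold for acceptable reproducibility.
#'
#' @param ratings A numeric matrix or data frame, items in rows, raters in
#'   columns; binary codes accepted.
#' @return Cronbach's alpha (at most 1).
#' @examples
#' m <- cbind(a = c(1, 0, 1, 1, 0, 1), b = c(1, 0, 1, 1, 0, 0))
#' cronbach_alpha(m)
#' @export
cronbach_alpha <- function(ratings) {
  m <- as.matrix(ratings)
  if (!is.numeric(m)) abort("`ratings` must be numeric (code L/R as 0/1).")
  if (ncol(m) < 2 || nrow(m) < 2) abort("need at least 2 raters and 2 items.")
  if (anyNA(m)) abort("`ratings` must not contain missing values.")
  total_var <- var(rowSums(m))
  if (total_var == 0) abort("zero total-score variance: alpha undefined.")
  k <- ncol(m)
  (k / (k - 1)) * (1 - sum(apply(m, 2, var)) / total_var)
}
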