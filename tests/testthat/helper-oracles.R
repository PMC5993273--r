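# Independent oracles used to check the package's own implementations.

# Two-sided exact binomial p by brute-force tail enumeration (tail
# doubling capped at 1), built from choose() so it shares nothing with
# the pbinom-based implementation.
oracle_exact_two_sided <- function(count, n, p0 = 0.5) {
  k <- 0:n
  pmf <- choose(n, k) * p0^k * (1 - p0)^(n - k)
  lower <- sum(pmf[k <= count])
  upper <- sum(pmf[k >= count])
  min(1, 2 * min(lower, upper))
}

# Likelihood-ratio G statistic for a 2x2 table of counts.
oracle_g_statistic <- function(tab) {
  tab <- as.matrix(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  2 * sum(ifelse(tab > 0, tab * log(tab / e), 0))
}

# Separation factor by direct mode counting on the equal-weight mixture
# 0.5 N(0, r^2) + 0.5 N(delta, 1): bisection on delta for the smallest
# separation with two density maxima, scaled by sigma1 + sigma2.
oracle_sep_factor <- function(r, grid_points = 40001) {
  modes <- function(delta) {
    xs <- seq(-4 * r, delta + 4, length.out = grid_points)
    f <- 0.5 * dnorm(xs, 0, r) + 0.5 * dnorm(xs, delta, 1)
    d <- diff(f)
    sum(d[-length(d)] > 0 & d[-1] <= 0)
  }
  lo <- 0.01; hi <- 6
  for (i in 1:45) {
    mid <- (lo + hi) / 2
    if (modes(mid) >= 2) hi <- mid else lo <- mid
  }
  hi / (r + 1)
}

# Median-centered Levene test computed directly from the one-way anova
# decomposition of absolute deviations.
oracle_levene_p <- function(x, y) {
  d <- c(abs(x - median(x)), abs(y - median(y)))
  g <- factor(rep(1:2, c(length(x), length(y))))
  anova(lm(d ~ g))$`Pr(>F)`[1]
}
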