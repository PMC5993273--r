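# Bonett (2006) two-sample test for equality of variances: compares
# log sample variances with a kurtosis-adjusted standard error, using
# trimmed means (trim proportion 1/(2*sqrt(n - 4))) in the pooled kurtosis
# estimate and the n/(n - 4) small-sample variance correction. Requires
# n > 4 in both samples; returns NA otherwise.
bonett_variance_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (min(n1, n2) <= 4) return(NA_real_)
  tmean <- function(v) mean(v, trim = 1 / (2 * sqrt(length(v) - 4)))
  gamma_hat <- (n1 + n2) *
    (sum((x - tmean(x))^4) + sum((y - tmean(y))^4)) /
    (sum((x - mean(x))^2) + sum((y - mean(y))^2))^2
  se <- sqrt((gamma_hat - (n1 - 3) / n1) / (n1 - 1) +
             (gamma_hat - (n2 - 3) / n2) / (n2 - 1))
  correction <- (n1 / (n1 - 4)) / (n2 / (n2 - 4))
  z <- log(correction * var(x) / var(y)) / se
  2 * pnorm(-abs(z))
}

#' Pretest for equal variances in two samples
#'
#' Decides whether two samples share a variance before a two-sample
#' location comparison. Two classical procedures are combined the way
#' variance pretests are commonly applied to small behavioural samples:
#' the Bonett (2006) kurtosis-adjusted comparison of log variances, and
#' the median-centered Levene (Brown-Forsythe) test. With at least 20
#' observations in both samples the Bonett p-value is used alone;
#' otherwise the smaller of the Bonett and Levene p-values is used
#' (a deliberately conservative choice for small groups).
#'
#' @param x,y Numeric samples, each with at least 3 values.
#' @return A one-row tibble: `n_x`, `n_y`, `bonett_p`, `levene_p`,
#'   `p_value` (the value the pooling rule consumes) and `rule`.
#' @examples
#' equal_variance_pretest(rnorm(15), rnorm(15, sd = 3))
#' @export
equal_variance_pretest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) abort("each sample needs at least 3 values.")
  if (sd(x) == 0 && sd(y) == 0) {
    warn("both samples are constant; returning p = 1.")
    return(tibble::tibble(n_x = length(x), n_y = length(y),
                          bonett_p = NA_real_, levene_p = NA_real_,
                          p_value = 1, rule = "degenerate"))
  }
  grp <- factor(rep(c("x", "y"), c(length(x), length(y))))
  lev <- car::leveneTest(c(x, y), grp, center = median)
  levene_p <- lev$`Pr(>F)`[1]
  bonett_p <- bonett_variance_p(x, y)
  if (length(x) >= 20 && length(y) >= 20) {
    p <- bonett_p
    rule <- "bonett"
  } else {
    p <- min(bonett_p, levene_p, na.rm = TRUE)
    rule <- "min(bonett, levene)"
  }
  tibble::tibble(n_x = length(x), n_y = length(y),
                 bonett_p = bonett_p, levene_p = levene_p,
                 p_value = p, rule = rule)
}

#' Two-sample t comparison with variance-pretested pooling
#'
#' Compares the locations of two samples (typically degrees of laterality,
#' `|LI|`) with either the pooled-variance t-test or Welch's t-test. With
#' `method = "auto"` the choice follows [equal_variance_pretest()]: pooled
#' when the pretest p-value is at least `pretest_alpha`, Welch otherwise.
#' Welch degrees of freedom are the Welch-Satterthwaite value truncated to
#' an integer, and the two-sided p-value is computed at the integer df.
#'
#' @param x,y Numeric samples, each with at least 2 values.
#' @param method `"auto"`, `"pooled"` or `"welch"`.
#' @param pretest_alpha Level for the equal-variance pretest.
#' @return A one-row tibble: `t`, `df` (integer), `p_value`, `method`,
#'   `pretest_p` (NA unless `method = "auto"`).
#' @examples
#' res <- assess_laterality(focal_horses())
#' grp <- split_by_sign(res)
#' two_sample_t(abs(grp$left$li), abs(grp$right$li))   # Welch, t = 2.28
#' @export
two_sample_t <- function(x, y, method = c("auto", "pooled", "welch"),
                         pretest_alpha = 0.05) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("each sample needs at least 2 values.")
  pretest_p <- NA_real_
  if (method == "auto") {
    pretest_p <- equal_variance_pretest(x, y)$p_value
    method <- if (pretest_p >= pretest_alpha) "pooled" else "welch"
  }
  tt <- t.test(x, y, var.equal = (method == "pooled"))
  df <- as.integer(floor(tt$parameter))
  tstat <- unname(tt$statistic)
  tibble::tibble(
    t = tstat, df = df,
    p_value = 2 * pt(-abs(tstat), df),
    method = method, pretest_p = pretest_p
  )
}
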