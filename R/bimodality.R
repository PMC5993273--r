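# Separation factors S(r) for an equal-weight mixture of two normals with
# sd ratio r = sigma1/sigma2 <= 1: the mixture has two modes iff the mean
# difference exceeds S(r) * (sigma1 + sigma2). Grid generated by bisection
# on the separation while counting density modes; S(1) = 1 recovers the
# classical equal-variance threshold of 2*sigma.
.sep_ratio_grid <- seq(0.10, 1.00, by = 0.05)
.sep_factor_grid <- c(
  0.4248, 0.5702, 0.6902, 0.7899, 0.8731, 0.9423, 0.9995, 1.0461, 1.0835,
  1.1124, 1.1337, 1.1479, 1.1552, 1.1559, 1.1497, 1.1361, 1.1136, 1.0782,
  1.0000
)

#' Split per-individual results by bias direction
#'
#' @param results A tibble with an `li` column, as from
#'   [assess_laterality()].
#' @return A named list with elements `right` (rows with `li > 0`) and
#'   `left` (rows with `li < 0`); ambilateral rows (`li == 0`) belong to
#'   neither.
#' @export
split_by_sign <- function(results) {
  list(right = dplyr::filter(results, .data$li > 0),
       left = dplyr::filter(results, .data$li < 0))
}

#' Moments of a group of laterality indices
#'
#' @param li_values Numeric vector with at least two values.
#' @return A one-row tibble: `n`, `mean`, `sd` (sample standard deviation,
#'   `n - 1` denominator).
#' @export
group_moments <- function(li_values) {
  if (length(li_values) < 2) abort("need at least 2 values to form group moments.")
  tibble::tibble(n = length(li_values), mean = mean(li_values), sd = sd(li_values))
}

#' Separation factor for the two-normal-mixture bimodality criterion
#'
#' For an equal-weight mixture of two normal components with standard
#' deviations \eqn{\sigma_1, \sigma_2}, the density is bimodal if and only
#' if the mean difference exceeds \eqn{S(r)(\sigma_1 + \sigma_2)}, where
#' the separation factor \eqn{S} depends only on the ratio
#' \eqn{r = \sigma_1/\sigma_2}. The factor is symmetric in the two
#' components, so ratios above 1 are inverted before lookup; values are
#' linearly interpolated on a tabulated grid covering `[0.1, 1]`.
#' At `r = 1` the classical equal-variance result holds:
#' \eqn{S = 1}, i.e. bimodality requires a mean difference above
#' \eqn{2\sigma}.
#'
#' @param sigma_ratio Positive standard-deviation ratio.
#' @return The separation factor (vectorised).
#' @examples
#' separation_factor(1)      # 1: classical 2-sigma threshold
#' separation_factor(0.65)
#' @export
separation_factor <- function(sigma_ratio) {
  if (any(sigma_ratio <= 0)) abort("`sigma_ratio` must be positive.")
  r <- ifelse(sigma_ratio > 1, 1 / sigma_ratio, sigma_ratio)
  if (any(r < min(.sep_ratio_grid) - 1e-12)) {
    abort(sprintf("sigma ratio outside the tabulated range [%.2f, 1] after inversion.",
                  min(.sep_ratio_grid)))
  }
  stats::approx(.sep_ratio_grid, .sep_factor_grid, xout = pmin(r, 1),
                rule = 1)$y
}

#' Bimodality assessment of a split laterality distribution
#'
#' Applies the equal-weight two-normal-mixture criterion to the right- and
#' left-biased groups of a laterality-index distribution: with group 1 the
#' right-biased and group 2 the left-biased animals, the distribution is
#' called bimodal when
#' \deqn{S(\sigma_1/\sigma_2)(\sigma_1 + \sigma_2) < \mu_1 - \mu_2.}
#' A clearly bimodal LI distribution indicates individual-level laterality
#' without a population-level bias.
#'
#' @param group_r,group_l One-row moment tibbles for the right- and
#'   left-biased groups, as from [group_moments()], or numeric vectors of
#'   LI values (moments are then computed internally).
#' @return A one-row tibble: group sizes and moments, `sigma_ratio`
#'   (\eqn{\sigma_1/\sigma_2}), `sep_factor`, `lhs`
#'   (\eqn{S(\sigma_1+\sigma_2)}), `rhs` (\eqn{\mu_1-\mu_2}) and
#'   `is_bimodal`.
#' @examples
#' grp <- split_by_sign(assess_laterality(focal_horses()))
#' assess_bimodality(grp$right$li, grp$left$li)
#' @export
assess_bimodality <- function(group_r, group_l) {
  if (is.numeric(group_r)) group_r <- group_moments(group_r)
  if (is.numeric(group_l)) group_l <- group_moments(group_l)
  stopifnot(all(c("n", "mean", "sd") %in% names(group_r)),
            all(c("n", "mean", "sd") %in% names(group_l)))
  if (group_r$sd == 0 || group_l$sd == 0) {
    abort("degenerate group: zero standard deviation.")
  }
  ratio <- group_r$sd / group_l$sd
  s <- separation_factor(ratio)
  lhs <- s * (group_r$sd + group_l$sd)
  rhs <- group_r$mean - group_l$mean
  tibble::tibble(
    n_r = group_r$n, mean_r = group_r$mean, sd_r = group_r$sd,
    n_l = group_l$n, mean_l = group_l$mean, sd_l = group_l$sd,
    sigma_ratio = ratio, sep_factor = s, lhs = lhs, rhs = rhs,
    is_bimodal = lhs < rhs
  )
}
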