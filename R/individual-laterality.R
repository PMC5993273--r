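#' Laterality index
#'
#' The laterality index summarises repeated binary side observations as a
#' signed percentage:
#' \deqn{LI = 100 (n_R - n_L) / (n_R + n_L)}
#' `+100` means every observation was right-sided, `-100` every observation
#' left-sided, and `0` an ambilateral individual with equal counts. Positive
#' values indicate a rightward bias.
#'
#' @param n_left,n_right Non-negative observation counts. Vectorised.
#' @return Numeric value(s) in `[-100, 100]`.
#' @examples
#' laterality_index(8, 20)   # 42.86: right bias
#' laterality_index(7, 0)    # -100: fully left-preferent
#' @export
laterality_index <- function(n_left, n_right) {
  if (any(n_left < 0) || any(n_right < 0)) abort("counts must be non-negative.")
  n <- n_left + n_right
  if (any(n < 1)) abort("no observations: both counts are zero.")
  100 * (n_right - n_left) / n
}

#' One-proportion test (normal approximation or exact binomial)
#'
#' Tests an observed success proportion against a null value `p0`. Two
#' methods are provided, mirroring common practice in laterality studies:
#'
#' * `method = "normal"`: the one-proportion z test with no continuity
#'   correction, \eqn{z = (\hat p - p_0)/\sqrt{p_0(1-p_0)/n}}, two-sided
#'   p-value \eqn{2\Phi(-|z|)}, and a Wald confidence interval
#'   \eqn{\hat p \pm z_{1-\alpha/2}\sqrt{\hat p(1-\hat p)/n}}.
#' * `method = "exact"`: the exact binomial test with tail doubling,
#'   \eqn{p = \min(1, 2\min(P[X \le x], P[X \ge x]))} for
#'   \eqn{X \sim Bin(n, p_0)}, used when observation counts are low. The
#'   `z` column is still populated from the normal formula so reports can
#'   carry both.
#'
#' @param count Number of successes (by convention, right-side
#'   observations).
#' @param n Number of trials.
#' @param p0 Null proportion, strictly between 0 and 1. Default `0.5`
#'   (no side preference).
#' @param method `"normal"` or `"exact"`.
#' @param conf_level Confidence level for the Wald interval.
#' @return A one-row tibble with columns `n`, `count`, `p_hat`, `z`,
#'   `p_value`, `ci_low`, `ci_high`, `method`.
#' @examples
#' one_proportion_test(20, 28)                     # z = 2.27, p = 0.023
#' one_proportion_test(14, 18, method = "exact")   # p = 0.031
#' @export
one_proportion_test <- function(count, n, p0 = 0.5,
                                method = c("normal", "exact"),
                                conf_level = 0.95) {
  method <- match.arg(method)
  if (length(n) != 1 || length(count) != 1) abort("`count` and `n` must be scalars.")
  if (is.na(n) || n < 1) abort("`n` must be at least 1.")
  if (count < 0 || count > n) abort("`count` must lie in [0, n].")
  if (p0 <= 0 || p0 >= 1) abort("`p0` must be strictly between 0 and 1.")

  p_hat <- count / n
  z <- (p_hat - p0) / sqrt(p0 * (1 - p0) / n)
  p_value <- switch(method,
    normal = 2 * pnorm(-abs(z)),
    exact = min(1, 2 * min(pbinom(count, n, p0),
                           1 - pbinom(count - 1, n, p0)))
  )
  half <- qnorm(1 - (1 - conf_level) / 2) * sqrt(p_hat * (1 - p_hat) / n)
  tibble::tibble(
    n = as.integer(n), count = as.integer(count), p_hat = p_hat,
    z = z, p_value = p_value,
    ci_low = p_hat - half, ci_high = p_hat + half,
    method = method
  )
}

#' Per-individual laterality assessment
#'
#' Runs the full per-horse analysis over a table of focal records: parses
#' each lead sequence, computes the laterality index, tests the right-lead
#' proportion against 0.5 (exact binomial when the number of observations
#' is at most `exact_threshold`, normal approximation otherwise), and
#' classifies each individual:
#'
#' * `sig_R` / `sig_L` — significant right/left bias (`p <= alpha`),
#' * `ns_R` / `ns_L` — non-significant trend,
#' * `ambi` — ambilateral (LI exactly 0).
#'
#' @param focal A tibble with columns `horse_id`, `sequence` and optionally
#'   `sex`, as from [focal_horses()] or [read_focal_records()].
#' @param alpha Significance level; comparison is `p <= alpha`.
#' @param exact_threshold Largest `n` for which the exact test is used.
#' @param p0 Null right-lead proportion.
#' @return A tibble (class `laterality_results`) with one row per horse:
#'   `horse_id`, `sex` (if present), `n`, `n_left`, `n_right`, `li`, `z`,
#'   `p_value`, `ci_low`, `ci_high`, `method`, `classification`.
#' @examples
#' assess_laterality(focal_horses())
#' @export
assess_laterality <- function(focal, alpha = 0.05, exact_threshold = 25,
                              p0 = 0.5) {
  if (!all(c("horse_id", "sequence") %in% names(focal))) {
    abort("`focal` must have horse_id and sequence columns.")
  }
  if (nrow(focal) == 0) abort("`focal` has no records.")
  seqs <- gsub("\\s", "", toupper(focal$sequence))
  ok <- grepl("^[LR]+$", seqs)
  if (!all(ok)) {
    # re-parse the first bad one for a precise error message
    parse_lead_sequence(focal$sequence[which(!ok)[1]])
  }
  # vectorised equivalent of one_proportion_test() row by row
  n <- nchar(seqs)
  count <- stringr::str_count(seqs, stringr::fixed("R"))
  p_hat <- count / n
  z <- (p_hat - p0) / sqrt(p0 * (1 - p0) / n)
  method <- ifelse(n <= exact_threshold, "exact", "normal")
  p_value <- ifelse(
    method == "exact",
    pmin(1, 2 * pmin(pbinom(count, n, p0), 1 - pbinom(count - 1, n, p0))),
    2 * pnorm(-abs(z))
  )
  half <- qnorm(0.975) * sqrt(p_hat * (1 - p_hat) / n)
  out <- tibble::tibble(
    horse_id = focal$horse_id,
    n = as.integer(n),
    n_left = as.integer(n - count),
    n_right = as.integer(count),
    li = laterality_index(n - count, count),
    z = z,
    p_value = p_value,
    ci_low = p_hat - half,
    ci_high = p_hat + half,
    method = method,
    classification = dplyr::case_when(
      n == 2 * count ~ "ambi",
      p_value <= alpha & count * 2 > n ~ "sig_R",
      p_value <= alpha ~ "sig_L",
      count * 2 > n ~ "ns_R",
      TRUE ~ "ns_L"
    )
  )
  if ("sex" %in% names(focal)) {
    out <- dplyr::mutate(out, sex = focal$sex, .after = "horse_id")
  }
  class(out) <- c("laterality_results", class(out))
  out
}

#' Median laterality index within a bias direction
#'
#' Sample median of the laterality indices over the left-trending
#' (`side = "L"`, LI < 0) or right-trending (`side = "R"`, LI > 0)
#' individuals. Ambilateral individuals (LI = 0) belong to neither class.
#'
#' @param results A tibble with an `li` column, as from
#'   [assess_laterality()].
#' @param side `"L"` or `"R"`.
#' @return The median LI of the requested class.
#' @examples
#' median_li(assess_laterality(focal_horses()), "L")   # -60
#' @export
median_li <- function(results, side = c("L", "R")) {
  side <- match.arg(side)
  vals <- if (side == "L") results$li[results$li < 0] else results$li[results$li > 0]
  if (length(vals) == 0) abort(sprintf("no individuals with %s-side bias.", side))
  median(vals)
}
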