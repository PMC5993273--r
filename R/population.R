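#' Population-level proportion test for a lead bias
#'
#' Counts leads over (an optionally filtered subset of) a race-start table
#' and tests the proportion of `side_counted` leads against `p0` with the
#' one-proportion z test (normal approximation, no continuity correction).
#'
#' @param starts A race-start tibble, as from [read_race_starts()] or
#'   [simulate_race_cohort()].
#' @param ... Optional filter expressions evaluated with
#'   [dplyr::filter()], e.g. `direction == "C"` or `is_winner`.
#' @param side_counted Which lead counts as a success, `"R"` (default)
#'   or `"L"`.
#' @param p0 Null proportion.
#' @return A one-row tibble as from [one_proportion_test()].
#' @examples
#' starts <- simulate_race_cohort(simulation_config(seed = 1))
#' population_proportion_test(starts)
#' population_proportion_test(starts, direction == "C")
#' @export
population_proportion_test <- function(starts, ..., side_counted = "R",
                                       p0 = 0.5) {
  if (!side_counted %in% c("L", "R")) abort("`side_counted` must be 'L' or 'R'.")
  sub <- dplyr::filter(starts, ...)
  if (nrow(sub) == 0) abort("no observations left after filtering.")
  one_proportion_test(sum(sub$lead == side_counted), nrow(sub), p0 = p0,
                      method = "normal")
}

#' Left-to-right lead ratio
#'
#' @param n_left,n_right Lead counts; `n_right` must be positive.
#' @return `n_left / n_right`.
#' @examples
#' lead_ratio(604, 527)   # 1.15
#' @export
lead_ratio <- function(n_left, n_right) {
  if (any(n_right < 1)) abort("zero denominator: n_right must be at least 1.")
  n_left / n_right
}

#' Association between lead choice and categorical covariates
#'
#' Fits a binary logistic regression of the lead (coded `R = 1`, `L = 0`)
#' on one or more categorical predictors and reports the likelihood-ratio
#' chi-square against the intercept-only model, the field's usual
#' "Chi-square, DF, p" association summary. Coefficients are per
#' non-reference level log-odds of a right lead.
#'
#' Predictor levels observed fewer than `min_level_n` times are dropped
#' with a warning (with their rows), mirroring the exclusion of
#' too-sparse age classes in observational cohorts.
#'
#' @param starts A race-start tibble with a `lead` column.
#' @param predictors Character vector of predictor column names; each is
#'   treated as categorical.
#' @param ref_levels Optional named list/vector giving the reference level
#'   per predictor, e.g. `c(direction = "AC", sex = "mare")`.
#' @param min_level_n Minimum observations per retained predictor level.
#' @return An object of class `lead_association` with components
#'   `chi_square`, `df`, `p_value`, `fit` (the underlying [stats::glm()]
#'   object), `n` and `dropped_levels`. Use [tidy()] for per-level
#'   coefficients and odds ratios, [glance()] for the model summary.
#' @examples
#' starts <- simulate_race_cohort(simulation_config(seed = 1))
#' fit <- lead_association(starts, "direction", ref_levels = c(direction = "AC"))
#' glance(fit)
#' tidy(fit)
#' @export
lead_association <- function(starts, predictors, ref_levels = NULL,
                             min_level_n = 2) {
  missing <- setdiff(c("lead", predictors), names(starts))
  if (length(missing) > 0) {
    abort(sprintf("column(s) not found: %s.", paste(missing, collapse = ", ")))
  }
  dat <- starts[, c("lead", predictors)]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  dropped <- list()
  for (p in predictors) {
    f <- factor(as.character(dat[[p]]))
    rare <- names(which(table(f) < min_level_n))
    if (length(rare) > 0) {
      dropped[[p]] <- rare
      warn(sprintf("dropping level(s) %s of '%s' with fewer than %d observations.",
                   paste(rare, collapse = ", "), p, min_level_n))
      dat <- dat[!f %in% rare, , drop = FALSE]
      f <- factor(as.character(dat[[p]]))
    }
    if (nlevels(f) < 2) {
      abort(sprintf("predictor '%s' has fewer than 2 usable levels.", p))
    }
    if (!is.null(ref_levels) && p %in% names(ref_levels)) {
      f <- stats::relevel(f, ref = as.character(ref_levels[[p]]))
    }
    dat[[p]] <- f
  }
  dat$.y <- as.integer(dat$lead == "R")
  form <- stats::as.formula(paste(".y ~", paste(predictors, collapse = " + ")))
  fit <- glm(form, family = binomial(), data = dat,
             control = list(maxit = 50, epsilon = 1e-8))
  if (!fit$converged) {
    abort(sprintf("logistic fit did not converge within %d iterations.", fit$iter))
  }
  mu <- stats::fitted(fit)
  if (any(mu < 1e-8 | mu > 1 - 1e-8)) {
    abort("separation detected: fitted probabilities numerically 0 or 1.")
  }
  structure(
    list(
      chi_square = unname(fit$null.deviance - fit$deviance),
      df = fit$df.null - fit$df.residual,
      p_value = unname(stats::pchisq(fit$null.deviance - fit$deviance,
                                     fit$df.null - fit$df.residual,
                                     lower.tail = FALSE)),
      fit = fit,
      n = nrow(dat),
      dropped_levels = dropped
    ),
    class = "lead_association"
  )
}

#' @export
print.lead_association <- function(x, ...) {
  cat(sprintf("Lead association (binary logit, R = 1): Chi-square = %.2f, DF = %d, p = %.3g, n = %d\n",
              x$chi_square, x$df, x$p_value, x$n))
  invisible(x)
}

#' @rdname lead_association
#' @param x A `lead_association` object.
#' @export
tidy.lead_association <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    statistic = s[, "z value"],
    p_value = s[, "Pr(>|z|)"],
    odds_ratio = exp(s[, "Estimate"])
  )
}

#' @rdname lead_association
#' @export
glance.lead_association <- function(x, ...) {
  tibble::tibble(
    chi_square = x$chi_square, df = x$df, p_value = x$p_value,
    log_lik = as.numeric(logLik(x$fit)), aic = x$fit$aic, n = x$n
  )
}

#' One-way F test of laterality indices on group membership
#'
#' Fixed-effects one-way analysis of variance of the (untransformed)
#' laterality indices on a grouping factor such as sex, the regression-style
#' check that group membership does not shift mean LI. For two groups the
#' F statistic is the square of the pooled-variance two-sample t.
#'
#' @param data A tibble holding the LI values and grouping column.
#' @param li,group Column names (tidy-eval) of the response and grouping
#'   variable.
#' @return A one-row tibble: `f_statistic`, `df_between`, `df_within`,
#'   `p_value`.
#' @examples
#' res <- assess_laterality(focal_horses())
#' li_anova(res, li, sex)
#' @export
li_anova <- function(data, li, group) {
  y <- dplyr::pull(data, {{ li }})
  g <- factor(as.character(dplyr::pull(data, {{ group }})))
  if (nlevels(g) < 2) abort("need at least 2 groups.")
  if (any(table(g) < 2)) abort("each group needs at least 2 values.")
  a <- anova(lm(y ~ g))
  tibble::tibble(
    f_statistic = a$`F value`[1],
    df_between = a$Df[1],
    df_within = a$Df[2],
    p_value = a$`Pr(>F)`[1]
  )
}
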