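#' Run the full laterality analysis over a cohort
#'
#' Orchestrates every analysis stage over population race-start data
#' and/or focal repeated-measures data:
#'
#' 1. deduplication and population proportion tests (pooled, per
#'    direction, winners) with L:R ratios;
#' 2. lead-association models (course direction, sex, age, stall position
#'    per direction);
#' 3. per-individual assessment, significance classification and
#'    per-side medians;
#' 4. sign split, group moments and bimodality assessment (all animals
#'    and per sex group);
#' 5. variance-pretested two-sample comparisons of `|LI|`;
#' 6. Anderson-Darling normality of the LIs, Johnson transformation when
#'    needed, and a one-sample t against 0;
#' 7. one-way F tests of LI on sex groupings.
#'
#' Stages whose preconditions are unmet (too few animals in a class, only
#' one direction present, ...) are skipped and logged with a reason,
#' never crash. No multiple-testing correction is applied anywhere; every
#' p-value is reported raw.
#'
#' @param starts Optional race-start tibble ([read_race_starts()],
#'   [simulate_race_cohort()]).
#' @param focal Optional focal-record tibble ([focal_horses()],
#'   [read_focal_records()], [simulate_focal_horses()]).
#' @param alpha Significance level for classification.
#' @param exact_threshold Exact-test cutoff for [assess_laterality()].
#' @param pretest_alpha Level of the equal-variance pretest.
#' @param p0 Null lead proportion.
#' @return A `laterality_report` object: a list with elements
#'   `population`, `association`, `focal`, `structure`, `distribution`,
#'   `anova`, `skipped` (stage log) and `settings`.
#' @examples
#' run_full_analysis(focal = focal_horses())
#' @export
run_full_analysis <- function(starts = NULL, focal = NULL, alpha = 0.05,
                              exact_threshold = 25, pretest_alpha = 0.05,
                              p0 = 0.5) {
  if (is.null(starts) && is.null(focal)) {
    abort("at least one of `starts` and `focal` is required.")
  }
  skipped <- list()
  skip <- function(stage, reason) {
    skipped[[length(skipped) + 1]] <<- tibble::tibble(stage = stage,
                                                      reason = reason)
    NULL
  }
  try_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) skip(stage, conditionMessage(e)))
  }

  # -- population proportion tests ------------------------------------
  population <- NULL
  association <- NULL
  if (is.null(starts)) {
    skip("population", "no starts data")
    skip("association", "no starts data")
  } else {
    starts <- deduplicate_horses(starts)
    prop_row <- function(name, sub) {
      if (nrow(sub) == 0) return(skip(paste0("population/", name), "no observations"))
      nl <- sum(sub$lead == "L"); nr <- sum(sub$lead == "R")
      t <- one_proportion_test(nr, nrow(sub), p0 = p0, method = "normal")
      tibble::tibble(analysis = name, n_left = nl, n_right = nr,
                     ratio_l_r = if (nr >= 1) nl / nr else NA_real_,
                     z = t$z, p_value = t$p_value,
                     ci_low = t$ci_low, ci_high = t$ci_high)
    }
    population <- dplyr::bind_rows(
      prop_row("pooled", starts),
      prop_row("C", dplyr::filter(starts, .data$direction == "C")),
      prop_row("AC", dplyr::filter(starts, .data$direction == "AC")),
      prop_row("winners_C", dplyr::filter(starts, .data$direction == "C",
                                          .data$is_winner)),
      prop_row("winners_AC", dplyr::filter(starts, .data$direction == "AC",
                                           .data$is_winner))
    )

    assoc_row <- function(name, data, predictors, ref_levels = NULL) {
      fit <- try_stage(paste0("association/", name),
                       suppressWarnings(lead_association(data, predictors,
                                                         ref_levels)))
      if (is.null(fit)) return(NULL)
      tibble::tibble(analysis = name, chi_square = fit$chi_square,
                     df = fit$df, p_value = fit$p_value, n = fit$n)
    }
    starts2 <- dplyr::mutate(starts,
      sex_group = dplyr::if_else(.data$sex == "mare", "female", "male"))
    association <- dplyr::bind_rows(
      assoc_row("direction", starts, "direction",
                c(direction = "AC")),
      assoc_row("sex_mf", starts2, "sex_group", c(sex_group = "female")),
      assoc_row("sex_3", starts, "sex", c(sex = "mare")),
      assoc_row("age", starts, "age"),
      assoc_row("stall_C", dplyr::filter(starts, .data$direction == "C"),
                "stall_position"),
      assoc_row("stall_AC", dplyr::filter(starts, .data$direction == "AC"),
                "stall_position")
    )
  }

  # -- per-individual analyses ----------------------------------------
  focal_section <- NULL
  structure_section <- NULL
  distribution <- NULL
  anova_section <- NULL
  if (is.null(focal)) {
    skip("focal", "no focal data")
    skip("structure", "no focal data")
    skip("distribution", "no focal data")
    skip("anova", "no focal data")
  } else {
    results <- assess_laterality(focal, alpha = alpha,
                                 exact_threshold = exact_threshold, p0 = p0)
    focal_section <- list(
      results = results,
      median_l = try_stage("focal/median_L", median_li(results, "L")),
      median_r = try_stage("focal/median_R", median_li(results, "R")),
      class_counts = dplyr::count(results, .data$classification)
    )

    has_sex <- "sex" %in% names(results)
    groups <- list(all = rep(TRUE, nrow(results)))
    if (has_sex) {
      groups <- c(groups, list(
        female = results$sex == "mare",
        male = results$sex != "mare",
        geldings = results$sex == "gelding",
        stallions = results$sex == "stallion"
      ))
    }
    bimod <- purrr::imap_dfr(groups, function(sel, nm) {
      out <- try_stage(paste0("structure/bimodality_", nm), {
        grp <- split_by_sign(results[sel, ])
        dplyr::mutate(assess_bimodality(grp$right$li, grp$left$li),
                      group = nm, .before = 1)
      })
      if (is.null(out)) tibble::tibble() else out
    })
    cmp_spec <- list(
      list("all_L_vs_R", quote(all), "left", "right"),
      list("female_L_vs_R", quote(female), "left", "right"),
      list("male_L_vs_R", quote(male), "left", "right"),
      list("geldings_L_vs_R", quote(geldings), "left", "right"),
      list("stallions_L_vs_R", quote(stallions), "left", "right")
    )
    comparisons <- purrr::map_dfr(cmp_spec, function(cs) {
      nm <- cs[[1]]; gname <- as.character(cs[[2]])
      if (!gname %in% names(groups)) return(tibble::tibble())
      out <- try_stage(paste0("structure/compare_", nm), {
        grp <- split_by_sign(results[groups[[gname]], ])
        dplyr::mutate(two_sample_t(abs(grp$left$li), abs(grp$right$li),
                                   pretest_alpha = pretest_alpha),
                      comparison = nm, .before = 1)
      })
      if (is.null(out)) tibble::tibble() else out
    })
    if (has_sex) {
      cross <- purrr::map_dfr(list(c("cross_L", "left"), c("cross_R", "right")),
        function(cs) {
          out <- try_stage(paste0("structure/compare_", cs[1]), {
            f <- split_by_sign(results[groups$female, ])[[cs[2]]]
            m <- split_by_sign(results[groups$male, ])[[cs[2]]]
            dplyr::mutate(two_sample_t(abs(f$li), abs(m$li),
                                       pretest_alpha = pretest_alpha),
                          comparison = cs[1], .before = 1)
          })
          if (is.null(out)) tibble::tibble() else out
        })
      comparisons <- dplyr::bind_rows(comparisons, cross)
    }
    structure_section <- list(bimodality = bimod, comparisons = comparisons)

    distribution <- try_stage("distribution", {
      adt <- ad_normality(results$li)
      if (adt$p_value > alpha) {
        list(ad = adt, johnson = NULL, t_test = one_sample_t(results$li, 0),
             tested_on = "untransformed")
      } else {
        jf <- johnson_transform(results$li)
        list(ad = adt, johnson = glance(jf),
             t_test = one_sample_t(jf$transformed, 0),
             tested_on = paste0("johnson_", jf$family))
      }
    })

    if (has_sex) {
      anova_section <- dplyr::bind_rows(
        if (!is.null(a <- try_stage("anova/sex_mf", {
          d <- dplyr::mutate(results, grp = dplyr::if_else(.data$sex == "mare",
                                                           "female", "male"))
          dplyr::mutate(li_anova(d, .data$li, .data$grp),
                        analysis = "sex_mf", .before = 1)
        }))) a,
        if (!is.null(a <- try_stage("anova/sex_3",
          dplyr::mutate(li_anova(results, .data$li, .data$sex),
                        analysis = "sex_3", .before = 1)))) a
      )
    } else {
      skip("anova", "no sex column in focal data")
    }
  }

  structure(
    list(
      population = population,
      association = association,
      focal = focal_section,
      structure = structure_section,
      distribution = distribution,
      anova = anova_section,
      skipped = if (length(skipped) > 0) dplyr::bind_rows(skipped)
                else tibble::tibble(stage = character(), reason = character()),
      settings = list(alpha = alpha, exact_threshold = exact_threshold,
                      pretest_alpha = pretest_alpha, p0 = p0)
    ),
    class = "laterality_report"
  )
}

#' @export
print.laterality_report <- function(x, ...) {
  cat("Laterality analysis report\n")
  cat(sprintf("settings: alpha = %g, exact test for n <= %d, pretest alpha = %g, p0 = %g\n",
              x$settings$alpha, x$settings$exact_threshold,
              x$settings$pretest_alpha, x$settings$p0))
  if (!is.null(x$population)) {
    cat("\n-- Population proportion tests (R leads vs p0) --\n")
    print(as.data.frame(x$population), digits = 4, row.names = FALSE)
  }
  if (!is.null(x$association) && nrow(x$association) > 0) {
    cat("\n-- Lead associations (likelihood-ratio chi-square) --\n")
    print(as.data.frame(x$association), digits = 4, row.names = FALSE)
  }
  if (!is.null(x$focal)) {
    cat("\n-- Per-individual classification --\n")
    print(as.data.frame(x$focal$class_counts), row.names = FALSE)
    if (!is.null(x$focal$median_l))
      cat(sprintf("median LI, left-trending:  %.2f\n", x$focal$median_l))
    if (!is.null(x$focal$median_r))
      cat(sprintf("median LI, right-trending: %.2f\n", x$focal$median_r))
  }
  if (!is.null(x$structure)) {
    if (nrow(x$structure$bimodality) > 0) {
      cat("\n-- Bimodality (two-normal-mixture criterion) --\n")
      print(as.data.frame(x$structure$bimodality[, c("group", "sigma_ratio",
                                                     "lhs", "rhs", "is_bimodal")]),
            digits = 4, row.names = FALSE)
    }
    if (nrow(x$structure$comparisons) > 0) {
      cat("\n-- |LI| comparisons (variance-pretested t) --\n")
      print(as.data.frame(x$structure$comparisons), digits = 4, row.names = FALSE)
    }
  }
  if (!is.null(x$distribution)) {
    cat(sprintf("\n-- Population-level test on LIs (%s) --\n",
                x$distribution$tested_on))
    cat(sprintf("AD normality: A2 = %.3f, p = %.3g; one-sample t vs 0: t = %.2f, p = %.3f\n",
                x$distribution$ad$a_squared, x$distribution$ad$p_value,
                x$distribution$t_test$t, x$distribution$t_test$p_value))
  }
  if (!is.null(x$anova) && nrow(x$anova) > 0) {
    cat("\n-- LI on sex groups (one-way F) --\n")
    print(as.data.frame(x$anova), digits = 4, row.names = FALSE)
  }
  if (nrow(x$skipped) > 0) {
    cat("\n-- Skipped stages --\n")
    print(as.data.frame(x$skipped), row.names = FALSE)
  }
  cat("\nNote: no multiple-testing correction is applied; p-values are raw.\n")
  invisible(x)
}
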