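# lateralize

Statistical analysis of motor laterality from repeated binary side
observations — the kind of data produced when an observer scores, start
after start, which foreleg a racehorse leads with as it breaks from the
starting stalls into gallop.

The package is written for behavioural scientists asking two distinct
questions about a cohort:

* **Population-level laterality** — does the cohort as a whole favour one
  side? Tested with one-proportion z tests on lead counts, L:R ratios,
  and logistic-regression association models (course direction, sex,
  age, stall position).
* **Individual-level laterality** — are single animals biased even when
  the population is balanced? Quantified per animal with the laterality
  index over its repeated observations,
  `LI = 100 (n_R − n_L) / (n_R + n_L)`
  (+100 fully right-preferent, −100 fully left-preferent, 0
  ambilateral), tested per animal with an exact binomial test for low
  observation counts (n ≤ 25) and the normal-approximation z test
  otherwise, and classified as significantly or non-significantly
  left/right biased or ambilateral.

Around that core the package provides the group-structure toolkit such
studies need: a two-normal-mixture bimodality criterion (an equal-weight
mixture with component moments (μ₁, σ₁), (μ₂, σ₂) is bimodal iff
`S(σ₁/σ₂)·(σ₁+σ₂) < μ₁−μ₂`, with the separation factor S tabulated and
interpolated), variance-pretested pooled/Welch t comparisons of
laterality strength |LI| (Bonett + median-centered Levene pretest),
Anderson–Darling normality testing with a percentile-method Johnson
transformation, power and sample-size design for one proportion,
Cronbach's alpha for inter-observer reliability, and a synthetic cohort
simulator (mixture of left-biased, right-biased and ambilateral animals
with Beta-distributed bias magnitudes) for operating-characteristic
studies.

A 44-horse Thoroughbred focal cohort — 11 geldings, 22 mares,
11 stallions with 5–47 repeated gallop-lead observations each — ships as
an embedded fixture (`focal_horses()`), so the full individual-level
analysis runs out of the box.

## Worked example

```r
library(lateralize)

res <- assess_laterality(focal_horses())
head(res, 5)
#>   horse_id sex     n_left n_right    li      z p_value method classification
#> 1 A        gelding      8      20  42.9  2.27  0.0233  normal sig_R
#> 2 B        gelding      4      14  55.6  2.36  0.0309  exact  sig_R
#> 3 C        gelding     17       4 -61.9 -2.84  0.00720 exact  sig_L
#> 4 D        gelding      6       8  14.3  0.535 0.791   exact  ns_R
#> 5 E        gelding      2       6  50    1.41  0.289   exact  ns_R
```

Horse A (20 right leads of 28) has LI = +42.9 and is significantly
right-biased (z = 2.27, p = 0.023); horse D trends right but is far from
significance. Over the whole cohort, 2 horses are significantly right-
and 8 significantly left-lateralised, one is ambilateral, and the median
LI is −60.00 among left-trending and 42.86 among right-trending horses
(`median_li(res, "L")`, `median_li(res, "R")`).

Is the LI distribution two-humped (individual laterality) rather than
one-humped around zero?

```r
grp <- split_by_sign(res)
assess_bimodality(grp$right$li, grp$left$li)
#>  n_r mean_r  sd_r n_l mean_l  sd_l sigma_ratio sep_factor   lhs   rhs is_bimodal
#>   22  35.05 18.83  21 -52.11 28.93      0.6507      1.148 54.83 87.16       TRUE
```

The mean separation between the right- and left-biased groups (87.2 LI
points) exceeds the mixture threshold (54.8), so the distribution is
bimodal: individual-level laterality without a population-level bias.
Are left-biased animals more strongly lateralised than right-biased
ones?

```r
two_sample_t(abs(grp$left$li), abs(grp$right$li))
#>     t df p_value method pretest_p
#>  2.28 34 0.02899  welch   0.02094
```

The variance pretest rejects equal spreads (p = 0.021), so Welch's test
is used: left-biased horses are significantly more lateralised
(t = 2.28, df = 34, p = 0.029). Population-level counts tell the
opposite story — from 2095 starts (1074 left, 1021 right):

```r
one_proportion_test(1021, 2095)
#>     n count  p_hat      z p_value ci_low ci_high method
#>  2095  1021 0.4874 -1.158  0.2469 0.4659  0.5088 normal
```

No population bias (p = 0.25). Designing such a study from scratch,
`sample_size_one_proportion(0.5, 0.54)` reports that 1225 starts give
80% power to detect a 54/46 population split at α = 0.05.

`run_full_analysis(starts = ..., focal = ...)` chains all of the above
(plus association models, per-sex subgroup structure, and the
normality/Johnson/one-sample-t population check on the LIs) into one
report object; `simulate_focal_horses()` / `simulate_race_cohort()`
generate synthetic cohorts from a documented mixture model; and
`reproduce_study()` recomputes every published headline value of the
study the fixture comes from, side by side with pass/fail flags and a
list of documented inconsistencies in the published tables.

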