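---
title: "Quantifying motor laterality from repeated side observations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motor laterality from repeated side observations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lateralize)
```

## The scientific problem

Motor laterality — handedness, in the broad sense — appears in horses as
a preference for one gallop leading leg. Two levels of the phenomenon
must be kept apart. *Population-level* laterality means most animals
share the same directional bias. *Individual-level* laterality means
most animals are biased, but left- and right-biased individuals occur in
similar numbers, so the population as a whole looks balanced. Telling
these apart takes two kinds of data and two statistical toolkits: a wide
table of single observations (one race start per horse, thousands of
horses) for the population question, and a deep table of repeated
observations (dozens of starts for a few dozen focal animals) for the
individual question. This package implements both, together with the
group-structure, distributional, design and reliability machinery the
analysis needs end to end.

## Data model

Two tabular types drive everything:

* **race starts** — one row per horse per race start: `race_id`,
  `direction` (`C` clockwise / `AC` anti-clockwise), `horse_id`, `lead`
  (`L`/`R`), `stall_position` (1 = nearest the inside rail), `age`,
  `sex` (`mare`/`gelding`/`stallion`), `finish_position`. Read and
  validated by `read_race_starts()`; `deduplicate_horses()` keeps each
  horse's first start so population tests see independent animals.
* **focal records** — one row per horse: `horse_id`, `sex`, and a
  chronological string of `L`/`R` lead observations, parsed by
  `parse_lead_sequence()`. A 44-horse fixture is embedded
  (`focal_horses()`): 11 geldings, 22 mares, 11 stallions with 5–47
  observations each.

## Per-individual analysis

For an animal with $n_L$ left and $n_R$ right observations, the
laterality index is

$$LI = \frac{100\,(n_R - n_L)}{n_R + n_L},$$

positive for rightward bias. Each animal's right-lead count is tested
against $p_0 = 0.5$. Two test variants are kept deliberately distinct
(`one_proportion_test()`):

* the **normal-approximation z test**, $z = (\hat p - p_0)/\sqrt{p_0
  q_0/n}$, with no continuity correction and a Wald confidence interval;
* the **exact binomial test** with tail doubling, $p = \min(1,\,
  2\min(P[X\le x], P[X\ge x]))$ — used when $n$ is small, where the
  normal approximation is unreliable. The doubled-tails convention (not
  the minimum-likelihood convention of `binom.test()`) is used because
  it is what desk statistics packages report for this design; the two
  agree at $p_0 = 0.5$ up to tail-assignment details.

`assess_laterality()` applies the exact test for $n \le 25$ and the
normal test above that. The cutoff is a package default chosen because
it reproduces the complete significance classification of the reference
focal cohort; any cutoff between the largest low-$n$ row (21) and the
smallest large-$n$ row (26) behaves identically there. Classification
at level $\alpha$ (default 0.05, compared as $p \le \alpha$): `sig_R`,
`sig_L`, `ns_R`, `ns_L`, or `ambi` for $LI = 0$ exactly. The $z$ column
is always populated from the normal formula, even for exact-test rows,
so exported tables carry both.

Starts are treated as exchangeable: no run-order, learning or ageing
structure is modelled within an animal's sequence.

## Group structure: bimodality and strength comparisons

Splitting the per-animal LIs by sign (`split_by_sign()`; ambilateral
animals belong to neither group) gives right- and left-biased groups
with moments $(\mu_1, \sigma_1)$ and $(\mu_2, \sigma_2)$. Under an
equal-weight two-normal-mixture model, the LI distribution is bimodal
iff

$$S(\sigma_1/\sigma_2)\,(\sigma_1 + \sigma_2) < \mu_1 - \mu_2,$$

where the separation factor $S$ depends only on the σ ratio
(`separation_factor()`). The packaged $S$ table (ratios 0.10–1.00 in
steps of 0.05, linearly interpolated, symmetric under ratio inversion)
was generated by direct mode counting on the mixture density: bisection
on the mean separation for the smallest value giving two local maxima.
At $r = 1$ it recovers the classical result that an equal-σ mixture
needs a separation above $2\sigma$, i.e. $S(1) = 1$. Equal mixture
weights are an approximation (the reference cohort splits 22/21, nearly
equal); raw group moments are used rather than histogram-binned ones, as
they reproduce the reference all-animals row exactly. The bimodality
verdict is invariant under translating or positively rescaling all LIs.

Strength-of-laterality comparisons operate on $|LI|$, since the groups
being compared are disjoint sets of animals biased in opposite
directions. `two_sample_t()` pretests equal variances
(`equal_variance_pretest()`): the Bonett (2006) kurtosis-adjusted
log-variance comparison when both groups have ≥ 20 observations,
otherwise the smaller of the Bonett and median-centered Levene p-values
— a conservative small-sample rule. Pooling follows the pretest at
α = 0.05: pooled-variance t (df $= n_1+n_2-2$) when equal variances are
not rejected, Welch's t otherwise, with the Welch–Satterthwaite df
truncated (not rounded) to an integer and the p-value evaluated at the
integer df, matching desk-package output conventions. On the fixture the
pretest selects Welch only for the all-animals comparison
(t = 2.28, df = 34) and pooling everywhere else (mares: t = 2.40,
df = 19).

## Population-level analysis

`population_proportion_test()` counts leads over an optionally filtered
start table and delegates to the normal-approximation test.
`lead_association()` fits a binary logit (lead `R` coded 1) on
categorical predictors and reports the likelihood-ratio chi-square
against the intercept-only model — the usual "Chi-square, DF, p"
association summary. Reference levels default to `AC` for direction and
`mare` for sex, so a positive clockwise coefficient reads "clockwise
courses predict right leads". Predictor levels with fewer than 2
observations are dropped with a warning (ages 12–13 in sparse cohorts,
for example). Complete separation and non-convergence raise explicit
errors rather than returning unstable estimates. `li_anova()` runs the
one-way fixed-effects F test of (untransformed) LI on group labels;
untransformed because the F test does not need normal LIs, and for two
groups $F = t^2$ of the pooled t.

An additional population check works on the focal LIs directly: an
Anderson–Darling normality test (`ad_normality()`, the estimated-
parameters case), a Johnson transformation when normality fails, and a
one-sample t of the (transformed) LIs against zero. The Johnson fit
(`johnson_transform()`) uses the percentile method: for each selection
constant $z$ in 0.25–1.25 (step 0.01), four sample quantiles at
$\Phi(\pm z), \Phi(\pm 3z)$ (type-6 quantiles) pick the family by the
quantile ratio $mn/p^2$ (SB below $1 - 0.05$, SU above $1 + 0.05$, SL
in between) and give closed-form parameters; the candidate maximising
the Anderson–Darling p-value of the transformed sample wins, ties going
to the smaller constant, and the identity is returned when the raw
sample already scores best. All Johnson transformations are strictly
increasing, so ranks are preserved. Because the fitted transformation
(and hence the exact t statistic after it) depends on these
implementation choices, only the qualitative conclusion — transformed
LIs consistent with mean zero — is asserted about the reference cohort.

## Design and reliability

`sample_size_one_proportion()` and `power_one_proportion()` implement
the two-sided normal-approximation design formulas
($n \ge (z_{1-\alpha/2}\sqrt{p_0q_0} + z_{pow}\sqrt{p_1q_1})^2 /
(p_1-p_0)^2$, no continuity correction — with $p_0=0.5$, $p_1=0.54$,
α = 0.05, power 0.8 this gives exactly 1225 starts), symmetric about
$p_0 = 0.5$ and inverse-consistent with each other.
`cronbach_alpha()` computes the internal-consistency coefficient over
an items × raters matrix of 0/1-coded side scores; 0.7 is the
conventional acceptability threshold. Note α can fall below −1 for
discordant raters; only its upper bound is 1.

## The synthetic cohort generator

`simulation_config()` + `simulate_focal_horses()` /
`simulate_race_cohort()` define the generative model used for all
operating-characteristic work. Each animal draws a latent class from
mixture weights (left / right / ambilateral); biased animals get a
right-lead probability $\theta = 0.5 \pm 0.5B$ with
$B \sim \mathrm{Beta}(a, b)$ folded to the class side — so class labels
and $\mathrm{sign}(\theta - 0.5)$ agree by construction, which is
simpler and cleaner than truncating a symmetric law. Observations are
i.i.d. Bernoulli($\theta$); per-animal observation counts are uniform
on `[starts_min, starts_max]`.

Defaults mirror the reference study's observed scales and are fixed as
the package's study conditions: 44 animals, class weights 21/22/1 over
44, 5–46 starts, sexes at 1/2–1/4–1/4, ages 2–10, stalls 1–14/15 with
one winner per race and alternating course directions.
$B \sim \mathrm{Beta}(2, 3)$ (mean bias 0.4 → mean |LI| magnitude ≈ 40)
matches the observed spread of fixture LIs; `bias_shape_b = 0` is
accepted as the degenerate $B \equiv 1$ law for boundary tests. A single
global seed drives per-animal substreams (derived with a fixed child-
seed schedule), so enlarging a cohort never perturbs existing animals,
and identical configurations are byte-identical.

What the generator deliberately does *not* emulate: course geometry and
banking, within-animal temporal drift (no age effect was found to
copy), jockey or stall-behaviour effects, and any dependence between
consecutive starts. Passing operating-characteristic tests therefore
demonstrates correctness of the statistical machinery under the stated
mixture model, not robustness to serially correlated or
covariate-confounded real data.

`recovery_study()` wraps the loop: simulate, assess, tabulate
sensitivity (biased animals flagged significant), specificity
(ambilateral animals not flagged) and sign accuracy, with replicate $r$
seeded at `seed + r`. Two useful closed-form anchors: with 5 starts no
animal can ever reach two-sided exact significance (the floor is
$2 \cdot 0.5^5 = 0.0625$), and at $\theta \approx 0.95$ with 40 starts
detection is essentially certain.

## Numerical and design choices

* No multiple-testing correction anywhere, matching standard practice
  for this design; reports say so explicitly.
* Significance uses $p \le \alpha$, not $<$.
* Exact two-sided p-values are doubled tails capped at 1.
* Wald intervals use $\hat p \pm z_{1-\alpha/2}\sqrt{\hat p \hat q/n}$.
* Welch df truncate; pooled df are exact integers.
* The separation-factor table interpolates linearly and refuses ratios
  below 0.1 (after inversion) rather than extrapolating.
* Degenerate inputs favour explicit errors (`"no observations"`,
  `"separation detected"`, `"zero total-score variance"`) or, in the
  pipeline, logged skips — `run_full_analysis()` records every skipped
  stage with a reason and never crashes on a degenerate subgroup.
* Problem sizes in the test suite (1000 replicates × 200 animals for
  the false-positive study, 400 animals × 10⁴ starts for the
  law-of-large-numbers check) were chosen as the smallest sizes at
  which the Monte Carlo error is negligible relative to the asserted
  tolerances.

## Known limitations

The bimodality criterion assumes exactly two normal components with
equal weights; strongly unequal group sizes would need the full
unequal-weight criterion. The Johnson fit is a point estimate — no
uncertainty propagates from the transformation into the downstream t
test. The exact/normal cutoff of 25 is a convention, not an estimate;
users can move it (`exact_threshold`) and `reproduce_study()`
demonstrates which published values are sensitive to it. Cronbach's
alpha treats raters as exchangeable and does not model rater-specific
bias; for a deeper reliability analysis an agreement coefficient such
as Fleiss' kappa would be the next step.
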