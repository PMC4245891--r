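---
title: "Correcting self-reported dietary energy intake at the population level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting self-reported dietary energy intake at the population level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eicorrect)
```

## The problem

Total energy intake (EI) estimated from 24-hour dietary recall is known to
be biased: most people under-report what they eat, some over-report, and in
unadjusted national survey data roughly a third of adults report an intake
that is physiologically impossible to sustain at stable body weight. The
yardstick for "impossible" is the energy-intake index

$$\mathrm{IndEI} = \mathrm{EI} / \mathrm{RMR},$$

where RMR is the resting metabolic rate predicted from sex, age and weight
by the Schofield adult weight-only equations. Under energy homeostasis
(stable weight), intake equals total energy expenditure (EE), so IndEI
equals the physical activity level PAL = EE/RMR. PAL cannot fall below 1
(one cannot expend less than resting metabolism), and values above 2.8 for
women or 3.5 for men correspond to extreme athletic workloads. A reported
intake whose index falls outside those bounds is a misreport; the fraction
of a population outside the bounds is the *failure rate*.

`eicorrect` implements two corrections that move a population of claimed
intakes toward plausibility, both trained on doubly-labeled-water (DLW)
validation data in which EE was measured directly alongside self-report:

1. **Regression correction.** Percent misreporting,
   $p = 100\,(\mathrm{EE} - \mathrm{EI}_{claimed})/\mathrm{EE}$, is modelled
   linearly in sex, age, weight, $\log \mathrm{EI}_{claimed}$ and
   $\mathrm{IndEI}_{claimed}$; a person's corrected intake is the algebraic
   inverse $\mathrm{EI}_{claimed} / (1 - \hat p / 100)$.
2. **Intake shift.** Within each sex, the PAL values of the validation
   cohort are fitted with a log-normal distribution; the ranked claimed
   indices of the target population are paired rank-for-rank with the
   fitted quantiles; the mean caloric discrepancy
   $\overline{(q_i - \mathrm{IndEI}_i)\,\mathrm{RMR}_i}$ is the single
   per-sex shift added to every claimed intake.

The package also provides the plausibility classification itself, survey
exclusion rules, age–sex stratified Monte-Carlo population simulation for
evaluating the methods, synthetic-data generators, CSV/JSON interchange and
a command-line interface.

## Assumptions that matter

* **Energy homeostasis.** Both corrections assume intake equals expenditure
  on average, which is why respondents on weight-altering diets, those who
  ate atypically on the recall day, and non-reporters are excluded
  (`apply_exclusions()`). The methods are not valid for populations
  actively changing weight.
* **Transportability.** The regression assumes misreporting behaves in the
  target population as it did in the validation cohort; the intake shift
  assumes the target population's *expenditure* distribution matches the
  validation cohort's. Both are population-level corrections: averaged over
  a population they remove bias, but neither predicts an individual's true
  intake on a given day.
* **Predicted rather than measured RMR.** The Schofield weight-only
  equations carry their own error; the lower PAL bound of 1 (rather than
  the stricter Goldberg cut-off of 1.35, available via
  `plausibility_bounds(min_indei = 1.35)`) deliberately absorbs some of
  that error.

## Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| Plausibility bounds | [1, 2.8] women, [1, 3.5] men | IndEI | Resting floor; extreme-athlete ceilings |
| Schofield variant | `fao_kcal` | kcal/day | Rounded adult weight-only coefficients (e.g. men 30–60: 11.6 W + 879); `schofield_mj` gives the original MJ-based set |
| Age bands | 18–30, 30–60, >60; 30 and 60 in the middle band | years | Published band structure; survey ages above the last band reuse the >60 equations |
| Log convention | natural | — | Selected by `calibrate_log_convention()`, see below |
| Prediction clamp | ±99 | percent | Keeps the inversion denominator away from 0 on covariate extremes |
| Reference PAL | men GM 1.83, GSD 1.14; women GM 1.63, GSD 1.13 | — | Geometric-moment reading: an *arithmetic* SD of 1.14 for PAL would imply frequent values below the resting floor, which is not physiologic |
| Stepwise threshold | 0.05 | two-sided p | Conventional retention cut-off |
| Simulation size | 1,000 replicates × 10,000 individuals | — | Survey-scale default; tests and the acceptance script use 100 × 10,000, at which the Monte-Carlo error of a mean failure rate is a few hundredths of a point |

## Numerical and design choices

**Quantile interpolation is deterministic.** The rank alignment uses the
plotting-position quantiles $\exp(\mu + \sigma\, z((i-0.5)/n))$ rather than
random draws from the fitted curve. The rank-for-rank correspondence ("the
i-th person of the simulation is the would-be i-th person of the cohort at
size n") *is* a quantile correspondence; making it deterministic removes a
seed from the method with a difference that vanishes as n grows.

**Ties and ordering.** Sorting by claimed index uses a stable radix sort,
so ties keep input order; `compute_shift()` is invariant to row
permutation. Boundary index values (exactly 1, 2.8, 3.5) are classified
plausible, because the failure definition is strict inequality outside the
range.

**Truncated draws are moment-matched.** Synthetic weight and intake are
truncated normals whose *parent* parameters are solved so the truncated
distribution hits the target mean/SD; naive truncation of an intake
distribution with CV ≈ 0.5 at zero would inflate the mean by more than 2%.

**Per-replicate reproducibility.** The simulation derives one sub-seed per
replicate from the master seed, so any single replicate can be reproduced
in isolation and results are bitwise identical for identical configuration.
Identical whole-record (joint) resampling within each age–sex stratum is
the default, preserving the weight–intake correlation; failure is evaluated
on the corrected index for both methods and on the raw claimed index for
the baseline.

**Regression delta pooling.** The 25th/75th percentiles of the per-person
caloric adjustment are computed across individuals pooled over replicates,
with a 2-million-value cap (systematic per-replicate subsampling beyond)
so survey-scale configurations stay within ordinary memory.

## What the synthetic generators emulate — and what they do not

`generate_open_like()` emulates a DLW validation cohort (ages 40–69, 45.7%
female, weight 81.0 ± 17.6 kg, claimed intake 2346 ± 808 kcal) in which
percent misreporting follows a *known* linear model plus Gaussian noise
(SD 5 by default). One design point deserves emphasis: the model's
covariates include $\log \mathrm{EI}$ and $\mathrm{IndEI}$, so intake
cannot itself be generated *from* the model — requiring
$\mathrm{EI} = \mathrm{EE}(1 - p(\mathrm{EI})/100)$ with $p$ linear in
$\log \mathrm{EI}$ yields a fixed-point equation with zero or two solutions
and explosive noise sensitivity. The generator therefore draws claimed
intake exogenously (log-normal, moment-matched), evaluates the model, and
*derives* expenditure as $\mathrm{EE} = \mathrm{EI}/(1 - p/100)$. This
makes the observed misreporting of every record exactly "linear predictor
plus noise", so ordinary least squares recovers the generating coefficients
exactly at zero noise and unbiasedly under noise — the property the test
suite checks. The price is that PAL = EE/RMR is a derived quantity in this
generator. Cohorts with a *controlled* PAL distribution and a known
constant per-sex caloric under-report are provided separately by
`generate_offset_population()` (PAL drawn from truncated per-sex
log-normals, EE = PAL·RMR, EI = EE − offset), which is the right testbed
for the intake-shift estimator.

`generate_nhanes_like()` emulates a post-exclusion national survey file:
age–sex strata, per-flavor intake and weight moments (2120 ± 1050 kcal and
80.0 ± 20.7 kg for the 2007-like flavor; 1876 ± 884 and 69.2 ± 15.3 for
the 1971-like flavor), era-specific age ceilings, and a race indicator for
the training-matched population filters. Two features of real survey
intake are built in because without them the spread of the intake index is
unrealistically wide: men report about 1.4× women's mean calories (the
per-sex split preserves the pooled moments exactly), and within sex,
reported intake is rank-correlated 0.45 with predicted RMR (larger people
report more), induced by rank reordering that leaves the per-sex marginal
untouched. An optional `implausible_fraction_target` rescales each sex's
intake multiplicatively (solved on the under-reporting branch of the
failure-rate curve) so the generated population exhibits a requested raw
failure rate, e.g. the one-third typical of real surveys.

What the generators do **not** reproduce: survey design weights,
clustering and non-response; day-of-week structure; race-specific
misreporting (an optional capability the validation cohort was too small
to support); any joint covariate structure beyond the two couplings above.
Passing tests on synthetic data therefore demonstrate the *mechanics* of
the methods — recovery of known truth, directional improvement, exact
bookkeeping — not their quantitative performance on real survey records.

## A caution about the bundled published coefficients

`default_open_model()` returns the published regression exactly as printed
(intercept 298.19; sex −2.30; age −0.36; weight 0.21; log intake −35.84;
intake index −30.47; R² 0.84). These printed values are not internally
consistent with the published cohort summary: an OLS fit must predict the
observed outcome mean at the covariate means, yet the printed model
evaluated at the published cohort means predicts strong *over*-reporting
(about −25%) instead of the observed ~10.7% mean under-reporting, under
either log convention and either Schofield variant
(`calibrate_log_convention()` quantifies this; natural log is much the
closer convention and is the default). The practical consequence is that
the as-printed model, applied to a population reconstructed from summary
moments, corrects intake *downward* on average and does not reduce the
failure rate — the corresponding acceptance check is deliberately left
failing rather than masked. Recentring only the intercept so the model's
mean prediction matches the observed training mean (`recenter_model()`,
implied intercept ≈ 325) restores the expected behaviour, with failure
rates around 1–2% on the synthetic survey population, matching the
method's published character; the recentred variant is clearly marked
`source = "refit"` and is never silently substituted for the published
model.

## Known limitations

* Population-average corrections only; per-person corrected values are not
  individual predictions.
* The intake-shift estimator carries a small positive bias (a fraction of
  a percent to ~2% of the shift) when RMR is heterogeneous, because
  ranking by claimed index and ranking by PAL then differ slightly; the
  bias vanishes at constant RMR and is well inside the tolerance used in
  its recovery tests.
* Children and adolescents, pregnancy, and measured-RMR workflows are out
  of scope; ages below 18 are rejected.
* Reproducing published survey results requires the real survey person
  files and census age–sex weights as inputs; the bundled weights are a
  labelled synthetic stand-in (uniform over age bins, 0.49/0.51 sex
  split).
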