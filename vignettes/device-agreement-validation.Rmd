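---
title: "Validating a candidate body-composition device: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a candidate body-composition device: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(almval)
```

## The problem

Appendicular lean mass (ALM, the lean soft tissue of arms and legs) is the
key quantity for detecting low muscle mass in sarcopenia screening of older
adults. The reference instrument is dual-energy X-ray absorptiometry (DXA),
which is expensive and requires trained operators; bio-electrical impedance
analysis (BIA) is the cheap, fast candidate that clinics would rather use.
`almval` implements the standard validation pipeline for this setting:
given one paired (reference, candidate) measurement per subject for ALM and
fat-free mass (FFM), it quantifies *absolute* agreement and, separately,
the candidate's ability to *rank* subjects well enough to recognize the
lowest-muscle-mass fraction of the cohort.

Those are different questions, and the package keeps them separate:

1. **Agreement** — mean bias (candidate − reference), percent bias, mean
   absolute error, the percentage of subjects whose candidate value lies
   within ±5% of the reference, and Bland–Altman limits of agreement with a
   proportional-bias regression.
2. **Diagnosis** — the lowest sex-specific quintile (20th percentile) of the
   reference distribution is taken as the low-mass cut-off; both devices
   are classified against that same cut-off and the candidate's sensitivity
   and specificity are computed with the reference classification as truth.

All analyses run for four measures — ALM, FFM, and their height-normalized
indices ALMi = ALM/height² and FFMi (kg/m²) — and for three strata (all,
male, female). A regression of the reference value on the candidate value,
sex, and their interaction decides whether stratification is statistically
indicated (interaction p < 0.10); all strata are reported regardless, for
consistency, with the decision recorded.

## Statistical definitions and conventions

- **Bias**: mean of per-subject differences d = candidate − reference;
  the SD uses the n−1 denominator (conventional in Bland–Altman work).
- **Percent bias**: per-subject 100·d/reference, then mean ± SD
  (mean-of-ratios with the *reference* in the denominator). The reference
  denominator is the consistent choice given that the ±5% accuracy band is
  defined relative to the reference; the mean-of-methods denominator was
  rejected for that reason. A consequence worth knowing: the per-subject
  percent bias of an index equals that of its mass exactly (height cancels),
  so the percent-bias rows for ALM and ALMi are identical.
- **Accuracy band**: candidate/reference in [0.95, 1.05] is accurate, with
  *inclusive* boundaries; strictly below 0.95 is an under-prediction and
  strictly above 1.05 an over-prediction. The three percentages partition
  the cohort exactly.
- **Limits of agreement**: bias ± 1.96·SD(d), with 1.96 exactly (not 2).
- **Proportional bias**: OLS of d on the per-subject mean of the two
  devices; a two-sided t-test on the slope at p < 0.05 flags it. The
  regression internals are closed-form so degenerate inputs are explicit:
  zero variance of the means is an error; a constant difference vector
  returns slope 0 with p = 1 rather than NaN.
- **Quintile cut-off**: 20th percentile by linear interpolation between
  order statistics at h = 0.2·(n−1) (the "type 7" convention, the default
  in most numerical environments). Published analyses rarely name their
  percentile algorithm and conventions can differ by one order-statistic
  gap, so the type is a parameter; the count-based checks in the test
  suite are convention-free.
- **Low / normal**: strictly below the cut-off is low; a value exactly at
  the cut-off — which interpolation can produce when it lands on a data
  value — is normal.
- **Pooled sensitivity/specificity**: per-sex confusion counts are summed
  before forming the rates. This is the only construction consistent with
  sex-specific cut-offs.
- **Subgroup comparison**: among reference-low subjects of one sex, false
  negatives vs true positives are compared per covariate (BMI, fat%) with
  a two-sample t-test, Welch by default (pooled available). The comparison
  refuses, with a named error, when either group has fewer than two
  members — with a single misclassified subject there is nothing to test.
  Welch is the default because equal group variances are an assumption the
  data rarely earn; both variants coincide exactly for equal sizes and SDs.

## What the synthetic generator emulates

`generate_cohort()` produces a two-sex cohort whose reference marginals
default to a community-dwelling 55+ cohort: 58 men and 144 women; ALM
25.6 ± 3.1 kg (men) and 18.3 ± 2.4 kg (women); FFM 60.5 ± 7.8 and
45.6 ± 5.3 kg; plausible heights, BMI and fat% per sex. Masses are
truncated-at-zero normals rather than lognormals: the reported mean ± SD
ranges are symmetric and the truncation is negligible at these means.
FFM is built as ALM plus a positive sex-specific residual (truncated
normal), so ALM < FFM holds by construction on both devices.

The device model has three knobs with units:

| parameter    | meaning                                     | default   |
|--------------|---------------------------------------------|-----------|
| `bias_add`   | additive candidate − reference bias (kg)    | −0.6      |
| `bias_slope` | slope of difference on two-device mean      | 0         |
| `noise_sd`   | candidate-device noise SD (kg)              | 1.21      |

The default `noise_sd` of 1.21 kg is a *calibration*: it makes the SD of
the ALM differences (hence the limits-of-agreement width) match the
~1.2 kg typical of BIA-vs-DXA comparisons in this population. It is not a
claim about any particular device. The default seed (780) is a fixed
documented constant; there is no hidden global randomness, and the global
RNG state is restored after generation.

**The proportional-bias construction.** The quantity a Bland–Altman plot
regresses is the difference d on the mean of methods m. If one naively
draws the reference, then adds noise only to the candidate, the noise
appears in both d and m and the fitted slope is biased upward by
Var(ε)/2 / (Var(ref) + Var(ε)/4) — about +0.12 at the defaults — even when
no proportional bias was injected. The generator therefore parameterizes
the latent two-device mean directly: t is drawn per sex from the truncated
normal, d = `bias_add` + `bias_slope`·t + ε, and the devices sit at
t ∓ d/2. Then m = t exactly and the population difference-on-mean slope
equals `bias_slope` exactly, noise included. The latent mean is offset by
(target + `bias_add`/2)/(1 − `bias_slope`/2) so that the *reference*
marginal means equal the stated per-sex targets. The reference SD is
inflated slightly (by √(σ² + noise²/4)/σ, ~3% at defaults), which is the
price of making the injected slope exact; parameter-recovery tests bound
both the bias and the slope estimates.

`generate_misclassification_scenario()` reproduces the structure in which
high-adiposity subjects are the ones the candidate device misses: the
top `obese_fraction` of subjects by BMI receive an extra positive
candidate bias, inflating their apparent lean mass. Defining the subgroup
as the existing upper BMI tail (rather than shifting BMI for a random
subset) makes the two stated degenerate cases exact: zero extra bias
returns the base cohort unchanged, and fraction 1 is equivalent to raising
`bias_add`.

**What a green test does not establish.** The generator works at the level
of reported mass values, with Gaussian noise on one device only, no
impedance physics, no reference-device error, no ALM–height or BMI–ALM
correlation, and no real covariate structure. Green property tests
establish the *statistics* are computed correctly and the pipeline is
self-consistent — not that any physical device is valid.

## Numerical and degenerate-input choices

- Strata with fewer than 2 subjects are refused; the interaction test
  needs 3 per sex; the Bland–Altman regression needs 3 pairs; cut-off
  derivation needs 5 values per sex.
- When the devices agree exactly, the interaction model is a perfect fit
  and its t-statistics are meaningless: the test returns `NA` with
  `stratify = FALSE` instead of a spurious decision.
- Accuracy classification and percent bias require strictly positive
  reference values and error otherwise.
- Display rounding is one decimal everywhere except the mean bias and its
  SD (two decimals, where the extra digit is informative); computation is
  always full precision, and the tidy CSV carries full precision — every
  number in the text report is formatted from the same tidy table.
- Sensitivity/specificity are exactly invariant under affine maps applied
  to both devices. Under general monotone maps the invariance holds
  whenever no candidate value falls inside the order-statistic gap that
  brackets the interpolated cut-off (the interpolated point itself is not
  equivariant under nonlinear maps); the property suite asserts the affine
  form, which is the one that is unconditionally true.

## Reading a cohort

`read_cohort()` accepts a delimited text table with a header, applies an
optional column-name mapping onto the canonical schema
(`subject_id, sex, age, height_m, alm_dxa_kg, alm_bia_kg, ffm_dxa_kg,
ffm_bia_kg` + optional `weight_kg, bmi, fat_pct`), converts centimeter
heights on request, parses sex case-insensitively from m/male/f/female,
and *excludes* rows that fail validation rather than failing the load —
each exclusion is reported with its input row number and reason, and
exclusions + retained always equals rows read. How a study flagged
"poor quality" assessments is not reconstructable from a flat table, so
quality-based exclusion is left to the user; only structural validity is
enforced. A missing required column, by contrast, is a schema error, and a
file with zero usable rows is an error.

## Worked example

```{r example}
params <- synthetic_params(bias_add = -0.6, noise_sd = 1.21, seed = 780)
co <- generate_cohort(params)
co

agreement_summary(paired_series(co, "ALM", "all"))

diagnostic_table(co, "ALM", "all")
```

The full pipeline, as the CLI runs it:

```{r pipeline}
report <- run_pipeline(list(synthetic = TRUE, seed = 780))
head(render_report(report, "csv"))
```

## Known limitations

- Single measurement per device per subject: no repeated-measures or
  replicate-aware limits-of-agreement variants.
- Diagnosis is low muscle mass only — no grip strength or gait speed, so
  no full sarcopenia staging.
- The candidate device is treated as the only noisy one in the generator;
  real reference devices have error too, which narrows what "sensitivity
  against the reference" can mean for any validation of this design.
- No vendor file formats; only the flat research table.
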