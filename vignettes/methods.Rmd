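---
title: "Methods: the age-adjusted modified qSOFA score and its prognostic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the age-adjusted modified qSOFA score and its prognostic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqsofa)
```

## The clinical problem

The adult quick Sequential Organ Failure Assessment (qSOFA) — respiratory
rate, systolic blood pressure, Glasgow Coma Scale — transfers poorly to
children: hypotension is a late sign of paediatric septic shock, and normal
heart and respiratory rates change by an order of magnitude between a
newborn and a teenager. The score implemented here replaces blood pressure
with capillary refill time (CRT), replaces the Glasgow scale with the
four-level AVPU responsiveness assessment, and age-adjusts the heart-rate
and respiratory-rate criteria with the 2005 International Pediatric Sepsis
Consensus Conference 95th-centile cut-offs. Each of the four items scores
0 or 1 at PICU admission:

| item | 0 points | 1 point |
|---|---|---|
| CRT | < 3 s | >= 3 s |
| Respiratory rate | <= band threshold | > band threshold |
| Heart rate | within band limits | above tachycardia or below bradycardia threshold |
| AVPU | Alert | Voice / Pain / Unresponsive |

yielding a total of 0–4. The package evaluates the score — alone and
combined with serum lactate and blood glucose — as a predictor of 28-day
all-cause mortality.

## Age bands and boundary conventions

The consensus table leaves two things unstated that an implementation must
decide.

**The 13–23-month gap.** The published bands jump from "1 month to 1 year"
to "2–5 years". We extend the infant band's thresholds (tachycardia > 180,
bradycardia < 90, RR > 34) through 23 months. This is the conservative
choice — the infant thresholds are higher, so a toddler is not flagged
tachycardic at rates that are still plausible for that age — and it makes
the bands contiguous.

**Units and boundaries.** Ages are stored in days with 1 week = 7 d,
1 month = 30.4375 d, 1 year = 365.25 d, and every band is half-open
`[lower, upper)`, so a child exactly at a boundary belongs to the older
band. `months_to_days()` applies the same convention for callers working
in months.

Threshold direction is taken literally from the score definition: heart
and respiratory rates score only strictly *above* the 95th-centile
threshold (a value exactly at the threshold scores 0), bradycardia
strictly below, and CRT inclusively at or above 3 s. Bands printed without
a bradycardia value (2 years and older) have no lower heart-rate
criterion at all. Any missing vital is an error: the score is defined on
complete admission vitals and nothing is imputed.

The threshold table ships as plain JSON (`inst/extdata/vital_thresholds.json`)
and can be replaced via `vital_thresholds(path)` for sensitivity analyses;
a replacement table is validated for contiguity, positive thresholds and
monotone non-increasing cut-offs with age.

## Discrimination: tie-corrected AUC and DeLong inference

Death within 28 days is the positive class and higher values of every
predictor mean higher predicted risk. With only five score levels, ties
dominate, so the AUC is computed in its tie-corrected Mann–Whitney form:
the probability that a randomly chosen death outranks a randomly chosen
survivor, counting ties one half. Two equivalent routes are implemented
and cross-checked in the tests — `auc_grouped()` works directly on
per-level outcome counts,

$$\mathrm{AUC} = \frac{1}{n_1 n_0}\sum_{\ell} d_\ell\left(S_{<\ell} + \tfrac{1}{2} s_\ell\right),$$

where $d_\ell, s_\ell$ are deaths and survivors at level $\ell$ and
$S_{<\ell}$ the survivors below it, while `auc_empirical()` uses midranks
on per-patient values.

The source study prints AUC confidence intervals and AUC-comparison
p-values without naming a method; we adopt DeLong's placement-value
estimator, the field standard for correlated ROC curves, for the standard
error, the Wald interval (truncated to $[0,1]$) and the paired z-test
(`delong_ci()`, `delong_test()`). Degenerate inputs — perfect separation
or an all-tied predictor — have zero placement variance and are returned
with `se = 0` rather than raised as errors. The test suite checks the
estimator against `pROC`, against a nonparametric bootstrap, and for
finite-sample interval coverage on binormal data.

Cutoffs use the Youden index $J = \text{sensitivity} + \text{specificity} - 1$
over all rules of the form "predict death iff value > c", with ties broken
toward the smallest cutoff: when two rules discriminate equally, a triage
score should prefer the more sensitive one. `confusion_metrics()` reports
the full confusion table with predictive values; a predictive value whose
denominator is empty is reported as `NA`, never as 0.

On the shipped derivation counts the pipeline reproduces the published
discrimination exactly:

```{r anchors}
auc_grouped(derivation_counts())
auc_grouped(validation_counts())
youden_cutoff(derivation_counts())
```

Two notes on the published numbers, reproduced rather than resolved.
First, the results section prints 0.719 for the score's derivation AUC
while the discussion prints 0.711; the grouped-count computation gives
0.7107, and 0.719 coincides with the lactate AUC, so 0.711 is the value
this package reports. Second, the published PPV (62.75%) and NPV (67.35%)
for the score are the reverse of what the grouped cells imply
(PPV 33/49 = 67.35%, NPV 32/51 = 62.75%) — most plausibly a column
transposition; the package reports the computed orientation. Relatedly,
the published per-level patient totals (51 children with score >= 2)
disagree by two patients with the sums of the group-conditional cells
(49); both are shipped verbatim (`derivation_level_totals()` vs
`derivation_counts()`).

## The combined model and calibration

The combined predictor is a main-effects logistic regression of 28-day
mortality on score, lactate and glucose — no interactions or splines, as
nothing beyond "combined" is specified for the published model. The
fitter (`fit_logistic()`) is the package's own iteratively reweighted
least squares: tolerance 1e-8 on the log-likelihood change, at most 50
iterations, quasi-separation flagged when any coefficient passes 15 on
the log-odds scale, and a rank-deficient design rejected with the names
of the collinear columns. Fitted probabilities are clamped to
$[10^{-12}, 1-10^{-12}]$ so that downstream calibration tests always
receive probabilities strictly inside $(0,1)$ even under quasi-separation.
Because any strictly monotone transform of the linear predictor yields
the same ranking, the fitted probability itself serves as the combined
risk score for ROC analysis.

Calibration uses the Hosmer–Lemeshow statistic
$\sum_g (O_g-E_g)^2 / (E_g(1 - E_g/n_g))$ with df = groups − 2. The
grouping rule matters with a discrete predictor: we use deciles of
predicted risk (10 groups, df 8) whenever at least ten distinct fitted
probabilities exist, and one group per distinct value otherwise — the
five-level score alone therefore gets 5 groups and df 3. This rule is the
one consistent with both published statistic/p pairs: $P(\chi^2_8 > 2.428)
= 0.965$ for the combined model and $P(\chi^2_3 > 2.423) = 0.489$ for the
score alone, matching the printed p-values at three decimals.

## The synthetic cohort generator

No patient-level data are public, so the generator reproduces the
*published grouped structure* of the two cohorts and nothing more. Per
patient: the outcome is Bernoulli (52% mortality in the derivation
configuration, 50% in the validation one); the score level is drawn from
the group-conditional categorical distribution
((17,15,14,1,1)/48 vs (7,12,16,11,6)/52 for the derivation cohort);
lactate and glucose are group-conditional log-normals.

The log-normal family was chosen for positive support and the strong
right skew of the published quartiles. `lognormal_from_quartiles()` sets
$\mu = \log(\text{median})$ and
$\sigma = (\log q_3 - \log q_1)/(2\,z_{0.75})$. A two-parameter
log-normal is log-symmetric, so it preserves the published median and the
$q_3/q_1$ spread exactly but cannot also reproduce the asymmetry of a
triple like 1.55 (1.00, 3.00); the sampled quartiles for such triples sit
about 10% inside the published ones on each side. This is a deliberate
limitation of the family, not a fitting error, and the round-trip tests
assert exactly the preserved quantities.

Score, lactate and glucose are **conditionally independent given the
outcome**, because only group-wise marginals are published. This is the
generator's most consequential limitation: the joint distribution of
score × biomarkers × outcome is not recoverable, so the combined model's
published AUC of 0.817 cannot be targeted by simulation — in fact, under
conditional independence the combined predictor pools three
conditionally-independent signals and tends to discriminate *better*
than 0.817. Tests of the combined pipeline are therefore qualitative
(the combined AUC should not fall below the best single predictor in
expectation), while exact acceptance anchors all come from the
grouped-count computations.

Ages are log-uniform in months with the range chosen so the distribution's
quartiles equal the published interquartile range (6–56 months for the
derivation cohort, giving a range of about 2.0–171 months); a
two-parameter log-uniform cannot simultaneously match the published median
of 12 months (its implied median is 18.3 months), and since ages affect
nothing but which vital-sign band a patient is scored in, quartile
matching was preferred. Each biomarker is emitted as a single value per
patient, representing the most abnormal measurement of the first 24 h as
collected in the source design; no within-stay time series is simulated.

Vitals are reverse-engineered from the drawn score: one of the
$\binom{4}{k}$ component patterns is chosen uniformly for a k-point score,
and each vital is drawn uniformly from the scoring or non-scoring side of
its band threshold within physiologic ranges (heart rate scores on the
bradycardic side half the time where that side exists). Margins of one
unit are kept around every threshold so that rounding to integer rates
(one decimal for CRT) can never flip a component, and `sample_cohort()`
asserts before returning that re-scoring reproduces every assigned score.
With a seed in the configuration the generated cohort is byte-identical
across runs, and the caller's RNG state is saved and restored.

## Problem sizes and numerical choices in the test suite

The distributional guarantees are checked by simulation at sizes chosen
to make Monte-Carlo noise small relative to the asserted bands: DeLong
interval coverage over 2,000 binormal cohorts of n = 100 (asserted within
[92%, 98%]); Hosmer–Lemeshow type-I error over 2,000 well-specified fits
of n = 500 (within [3%, 7%] at the 5% level); the DeLong standard error
against a 10,000-replicate bootstrap at n = 200 (within 5%); coefficient
recovery within 3 standard errors at n = 200; quartile round-trips at
n = 100,000 (within 2%); and the mean score-AUC over 200 default-config
synthetic cohorts against the grouped-count value (within ±0.03). All
simulations run under fixed seeds. The complete suite takes well under a
minute on one CPU.

## Known limitations

* The generator reproduces grouped marginals only; correlations between
  the score and the biomarkers within outcome groups are not modelled, so
  combined-model results on synthetic cohorts are not comparable to the
  published combined AUC.
* The Youden tie-break (smallest cutoff) and the cutoff orientation
  ("value > c") are conventions; the published tables are consistent with
  them but do not state them.
* The DeLong Wald interval can reach the boundary under near-perfect
  separation (as in the 20-patient validation cohort); no
  boundary-respecting transform (e.g. logit-AUC) is applied, matching
  common practice in the field's software.
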