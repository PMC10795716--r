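---
title: "Rule-based spirometry interpretation and its validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based spirometry interpretation and its validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spirointerp)
```

## The interpretation model

Spirometry reduces, for interpretation purposes, to three numbers per
test: the forced vital capacity (FVC, litres), the forced expiratory
volume in one second (FEV1, litres), and their ratio. Comparing the
first two against reference ("predicted") values for a person of the
same sex, age and height gives the percent-of-predicted indices FVC%
and FEV1%; the ratio FEV1/FVC is used in absolute value. `spirointerp`
implements the fixed-ratio convention used across primary-care
guidance:

* **normal** — FVC% ≥ 80, FEV1% ≥ 80, FEV1/FVC ≥ 0.70;
* **obstructive** — FEV1/FVC < 0.70 with preserved FVC% (≥ 80);
* **spirometric restriction** — FVC% < 80 with preserved ratio (≥ 0.70);
* **mixed** — FVC% < 80 and FEV1/FVC < 0.70.

Severity of airflow limitation is graded on the index the pattern
implicates — FEV1% for obstructive and mixed patterns, FVC% for
spirometric restriction — in the conventional five bands: mild (≥ 70),
moderate (60–69), moderately severe (50–59), severe (35–49), very
severe (< 35). The bronchodilator (reversibility) test compares a
repeat measurement taken after a short-acting bronchodilator against
the pre-bronchodilator value: positive when FEV1 **or** FVC improves by
at least 12% of the pre value **and** at least 0.2 L (the two criteria
are conjunctive per index; either index suffices), "not significant"
for any smaller improvement, "negative/unmodified" otherwise, and "not
evaluable" when no post-bronchodilator values exist.

All assessments are made from pre-bronchodilator values — the pattern
definitions compare the obtained basal measurement against the
reference — and no value is rounded before a threshold comparison;
rounding to one decimal happens only at display time.

### Resolving the boundary cells

Written as prose criteria, the four definitions do not partition the
index space. Two cells are left open, and this package resolves them
into a total, right-continuous partition:

* **FVC% exactly 80 with a reduced ratio.** "Preserved FVC" is taken as
  FVC% ≥ 80 everywhere, so this cell is obstructive; the record is
  flagged `BOUNDARY_FVC_80` so that equality cases remain auditable.
  The alternative (strict > 80) would leave a measure-zero gap and
  disagree with the normal-pattern criterion, which includes 80.
* **Preserved ratio and FVC but FEV1% < 80.** This "non-specific"
  constellation satisfies neither the obstruction criterion (ratio
  preserved) nor the restriction criterion (FVC preserved). It is
  classified normal and flagged `NONSPECIFIC_LOW_FEV1`, preserving the
  information without inventing a fifth pattern.

Similarly, the printed severity bands ("mild > 70, moderate 60–69")
are integer anchors that leave non-integer values such as 69.5
unassigned; the implementation uses half-open bands `[60, 70)`,
`[50, 60)`, `[35, 50)` with mild `[70, ∞)`, so each band edge belongs
to the higher band. A mixed pattern is graded on FEV1%; the convention
does not say which index to use there, and FEV1% is chosen because the
mixed pattern's obstructive component dominates management — this is
an assumption, recorded here.

The ratio threshold 0.70 is a known compromise: the lower limit of
normal is age-dependent, and a fixed ratio over-calls obstruction in
older and under-calls it in younger patients. The threshold is a
`spiro_config()` parameter so sensitivity analyses can vary it;
LLN-based classification (which needs reference-equation coefficient
tables) is out of scope, as is any assessment of the technical quality
of the manoeuvre. Predicted values are *inputs*: no reference-equation
coefficients ship with the package, but `interpret()` accepts a
user-registered predictor function for records lacking them.

## Validation statistics

The package bundles the machinery used to validate an automated
interpreter against expert raters, with the published
cross-tabulations of a 118-spirometry validation study as plain-text
fixtures (`study_tables()`).

**Diagnostic accuracy.** For accuracy work the four-level pattern is
dichotomized: any impaired pattern is "positive". From the 2×2 table
`diag_accuracy()` reports sensitivity, specificity, predictive values,
likelihood ratios, overall accuracy and the single-threshold AUC.
Interval methods follow common diagnostic-calculator practice and are
recorded per row:

* *Clopper–Pearson exact* intervals for sensitivity, specificity and
  accuracy — guaranteed coverage, sensible at boundary estimates;
* *Mercaldo standard logit* intervals for PPV/NPV, whose variance is
  assembled from the grouped binomial variances of sensitivity and
  specificity (the naive logit on the k/n proportion is noticeably
  narrower and does not reproduce published predictive-value
  intervals). At a boundary predictive value (exactly 0 or 100%) the
  logit is undefined and the Wilson continuity-corrected interval is
  used instead, with the method tag switching to `wilson_cc`;
* the *log method* for likelihood ratios (Wald interval on the log
  scale with the delta-method standard error). A perfect specificity
  makes +LR infinite with an open upper interval; a perfect
  sensitivity makes −LR exactly 0 with no log-scale interval.

Display follows reporting convention: percents to 1 decimal,
likelihood ratios to 2; an interval endpoint that is strictly inside
(0, 100) but would round to 0.0 or 100.0 is shown clamped one display
unit inside, as diagnostic calculators print it. The numeric endpoints
are never clamped.

The AUC of a single-threshold classifier is the trapezoidal area under
the two-segment ROC polygon, (sens + spec)/2, with a Hanley–McNeil
interval. It is reported for completeness; with one operating point it
adds nothing beyond sensitivity and specificity.

**Sample-size planning.** `required_sample_size(p, d, level)` is the
standard Wald formula `z² p (1−p) / d²`, rounded up. For the classic
goal of estimating a sensitivity of 0.90 to a 95% half-width of ±7
points it gives n = 71 diseased subjects. Published studies sometimes
quote smaller numbers for this goal (e.g. 45); the formula here is the
standard one and no attempt is made to reverse-engineer other
planning conventions.

**Agreement.** `cohen_kappa()` works on a square contingency table of
two raters' calls (or on raw label vectors, with pairwise deletion of
omitted calls, matching how per-column n varies when raters skip
cases). The standard error is the Fleiss–Cohen–Everitt asymptotic
formula and the interval the symmetric Wald interval, deliberately
*uncapped*: near-perfect agreement routinely produces printed upper
bounds above 1, and capping would break the symmetry that published
tables show. Supporting operations: `merge_categories()` (fold mixed
into obstructive when a rater does not distinguish them — count
conservation is guaranteed), `pool_severity()` (mild /
moderate-to-moderately-severe / severe-to-very-severe; a normal
pattern has no severity and is excluded pairwise), `landis_koch()`
(bands (0.80, 1] almost perfect, …, ≤ 0 none; boundary values belong
to the lower band), and `intra_rater_kappa()` for blinded repeat
calls.

Numerical note: at extreme small tables the three-term asymptotic
variance cancels to a tiny negative number in floating point; it is
clamped at zero before the square root.

## The synthetic cohort generator

`generate_cohort()` makes record-level data with a known ground truth
so the full pipeline is testable without patient data. Per subject it
draws a target pattern from a prevalence vector (default 64% normal,
12% obstructive, 14% restriction, 10% mixed — the validation study's
mix, respecting its floor of 10% per impaired pattern), a severity
grade from a mix (default 40/25/15/12/8% from mild to very severe,
front-loaded as in primary-care casemix), and then samples the three
indices uniformly inside the decision region of that pattern and
grade, shrunk by a `boundary_margin` (default 1 percent point; ratio
margin 1/100). Litre volumes are back-computed from the indices and a
predicted FVC drawn uniformly from 2.8–5.8 L. Bronchodilator responses
are positive at rate 0.15 by default (a plausible rate in a smoking
primary-care population; the validation study does not report one),
with the remaining records split between sub-threshold improvements
and unmodified tests.

Because the generator samples from the *interior* of each decision
region, the classifier must recover every intended label exactly
whenever the margin is positive — the generator is the inverse image
of the classifier's partition, and the round-trip test exploits that.
The flip side is what the generator does **not** emulate: indices
exactly on thresholds, measurement noise that straddles a cut-off,
correlated anthropometrics, GLI-quality predicted values, or
technically unacceptable manoeuvres. A passing round-trip therefore
validates the partition logic, not the behaviour of the algorithm on
noisy real-world boundary cases; those are covered separately by the
explicit boundary tests and flags. `simulate_rater()` layers a
row-stochastic confusion matrix and an omission rate on top of the
truth, with `expected_kappa()` providing the closed-form agreement
its draws must converge to.

## Problem sizes and reproducibility

The test-suite sizes are chosen so every distributional claim has
negligible Monte-Carlo ambiguity at desk scale: the engine-vs-oracle
comparison runs on 10^5 random records, the round-trip check on a
seeded cohort of 10^4, kappa recovery under a noisy rater on 10^4
calls (asserted within 3 asymptotic standard errors), the
likelihood-ratio bootstrap oracle on 10^5 resamples, and
Clopper–Pearson coverage is verified exhaustively for all k at n ≤ 30.
All stochastic tests fix their seeds. `scripts/acceptance.R`
recomputes the validation-study statistics from the shipped
contingency tables and the round-trip recovery from a fresh seeded
cohort, writing plain JSON.

## Known limitations

* Fixed-ratio classification only; no LLN support without reference
  coefficients.
* Severity of the mixed pattern graded on FEV1% by convention, not by
  a published rule.
* The single-threshold AUC is the standard orientation
  (sens + spec)/2; published ROC figures for rater-comparison designs
  are sometimes computed with other role assignments and need not
  match.
* Bronchodilator-test *concordance* between raters is not implemented;
  in the motivating study it could not be computed for lack of
  interpretations, so no reference values exist to validate against.
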