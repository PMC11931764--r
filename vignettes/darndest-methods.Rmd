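---
title: "Methods: layered contrast-sparing triage and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layered contrast-sparing triage and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darndest)
```

## The decision problem

Post-treatment surveillance of nasopharyngeal carcinoma images every patient
repeatedly, and the conventional protocol injects gadolinium contrast every
time. Per-sequence classifier scores make a staged alternative possible:
screen everyone with the unenhanced sequences, and spend the contrast scan
only where it changes the decision. This package evaluates exactly that
staged rule, taking as input nothing but a per-patient table of one binary
recurrence label and three scores in [0, 1] (T1WI, T2WI, T1WIC).

The package deliberately starts *after* model inference: how the scores were
produced (network architecture, training, image preprocessing) is out of
scope, which is what makes the evaluation reusable for any three scoring
models with the same contract.

## The rule and its parameters

The fused unenhanced score is the equal-weight average
$s = \tfrac12 s_{T1} + \tfrac12 s_{T2}$. Three thresholds parameterise the
rule (all unitless, on the score scale):

| parameter | meaning | default |
|---|---|---|
| `c1` | first-level cutoff on $s$; at or above: positive group | Youden cutoff of $s$ |
| `c2` | referral cutoff on $s$ (`c2 ≤ c1`); band $[c2, c1)$: suspicious group | sensitivity-floor search |
| `c3` | adjudication cutoff on the T1WIC score inside the suspicious group | Youden cutoff of T1WIC |
| `sens_floor` | overall-sensitivity floor driving the `c2` search | 0.90 |

Positives are called recurrent without T1WIC adjudication: that convention
makes the strategy's true positives the fused rule's true positives plus the
suspicious-group recoveries, which is the arithmetic the staged design is
built around, and it means an adjudication model can only *add* detections.
One call convention — "score ≥ threshold ⇒ positive" — is used everywhere,
including at cutoff boundaries.

### Youden cutoffs

`youden_cutoff()` maximises $J = \text{sensitivity} + \text{specificity} - 1$
over candidate thresholds equal to the unique observed scores. Ties in $J$
(compared with a $10^{-12}$ slack, since the sensitivities and specificities
are ratios of small integers computed along two different cumulative sums)
are broken by the *smallest* maximising threshold. The tie-break is a real
choice: the smaller threshold keeps sensitivity, which is the quantity this
surveillance setting cannot afford to lose.

### The referral cutoff search

`select_secondary_cutoff()` evaluates the full three-group rule at every
candidate `c2` (the unique fused scores below `c1`, plus 0) and returns the
**largest** candidate whose overall sensitivity meets the floor. Overall
sensitivity is non-increasing in `c2` — raising `c2` can only move patients
from suspicious (where the adjudicator may call them) to negative (where
nobody is called) — so the largest feasible candidate both exists and
minimises the number of contrast referrals at the floor, which is the
rule's economic point. Two degenerate outcomes are explicit rather than
silent: a `needed = FALSE` sentinel when the first level alone already meets
the floor (the fit then collapses `c2 = c1`, an empty suspicious band), and
an `attainable = FALSE` flag with a warning when even `c2 = 0` cannot reach
the floor (every remaining true case is adjudication-negative), in which
case 0 is returned as the least-bad value.

An ambiguity worth recording: the staged design could alternatively
threshold the suspicious band on the *T1WIC* score. We threshold the fused
score, because at triage time the negative-vs-suspicious split decides who
*gets* the contrast scan — a T1WIC score cannot exist before the scan it
would require. The adjudicator then acts only inside the suspicious group.

## Diagnostic statistics

* **Wald intervals.** All five table metrics (sensitivity, specificity,
  accuracy, PPV, NPV) carry normal-approximation intervals
  $\hat p \pm z_{0.975}\sqrt{\hat p(1-\hat p)/n}$, clipped to [0, 100]%.
  The Wald choice is deliberate: it is the interval that reproduces the
  published per-model table cells exactly from their confusion counts
  (e.g. 166/197 → 79.18–89.35). Estimates are kept unrounded internally;
  display rounds half-away-from-zero to two decimals (`round_half_up()`).
  Zero-denominator metrics are reported `NA`, never imputed.
* **McNemar's Z.** Paired classifiers are compared through per-patient
  correctness indicators; with discordant counts $b$ and $c$,
  $Z = (b-c)/\sqrt{b+c}$, two-sided normal p, and $p = 1$ when $b + c = 0$.
  The statistic is signed so that swapping the two methods flips its sign.
  The continuity-corrected variant (shrinking $|b-c|$ by 1) is available
  behind a flag but is *not* the default: the plain Z is the variant whose
  square equals the classical chi-square McNemar statistic, which the test
  suite uses as a cross-check. The default significance threshold is
  $\alpha = 0.05/3$, Bonferroni over the three pairwise model comparisons
  the analysis makes.
* **ROC/AUC.** The AUC is the tie-corrected Mann–Whitney probability (ties
  count ½), computed from midranks in $O(n\log n)$; it equals the
  trapezoidal area of the curve built from the unique-score thresholds, and
  both identities are asserted in the tests against an $O(n^2)$ pair-count
  oracle. AUC variance, the single-curve confidence interval and the paired
  AUC comparison all come from DeLong placement values; whether the original
  intervals were DeLong or bootstrap is not stated in the source material,
  and DeLong is adopted as the standard nonparametric choice. The paired
  variance reduces to
  $\operatorname{var}(V^A_{10}-V^B_{10})/m + \operatorname{var}(V^A_{01}-V^B_{01})/n$,
  cross-checked in the tests against a leave-one-out jackknife and against
  pROC.

## The economic model

A hypothetical cohort of `cohort_n = 1000` patients is populated by scaling
the test-set group proportions (`project_cohort()`: round to nearest, then a
largest-remainder reconciliation so group sizes sum exactly to the cohort).
Unit prices are a modelling decision: only whole-cohort totals are published
(all-enhanced RMB 2,444,000 and 226.4 h; all-unenhanced RMB 2,246,000 and
129.2 h per 1,000 patients), so the defaults divide those totals by 1,000 —
enhanced RMB 2,444 / 0.2264 h, unenhanced RMB 2,246 / 0.1292 h per
examination. These derived units reproduce the published time totals
exactly and the staged strategy's cost totals to within 0.003%; the small
residual implies unpublished exact prices, which is why the package treats
all four units as configurable and reports ratios computed from its own
totals. The cost of detecting one true positive in a group is the
conventional whole-cohort cost divided by the group's detected count, with
an explicit infinity when a group detects nobody; interval estimates around
those per-group costs are not implemented, because the published intervals
are not internally consistent enough to identify their generating method.
Currency converts at 7.17 RMB/USD (2024), rounded to whole dollars; hours
display to one decimal; all display rounding is half-away-from-zero.

The negative group deserves a note: its true cases are reported as *missed
at the index examination* (detected count 0). Cohort inputs may still carry
a small number of negative-group detections confirmed by later follow-up;
those enter the economics as data, not as an output of the triage rule,
which by construction calls the negative group recurrence-free.

## The synthetic cohort generator

`generate_cohort()` draws labels Bernoulli(prevalence), then for each
patient one shared latent factor $f$ and three model-specific noises:
$z_m = \sqrt{\rho}\, f + \sqrt{1-\rho}\,\varepsilon_m + y\,\delta_m$, with
scores $\operatorname{plogis}(z_m)$. The equal-variance binormal latent
gives closed-form AUC calibration, $\delta_m = \sqrt2\,\Phi^{-1}(\text{AUC}_m)$
(`auc_to_separation()`), and the logistic squashing is rank-preserving, so
the target AUC survives the transform and every score is strictly inside
(0, 1). The single-factor correlation structure uses one parameter $\rho$
to capture "the models agree on the easy cases" without a full correlation
matrix.

Defaults are the study conditions the pipeline was built around: $n = 433$,
prevalence $197/433 \approx 45.5\%$, AUC targets (0.9098, 0.9145, 0.9124)
for (T1WI, T2WI, T1WIC). The inter-score correlation is *not* an observable
of the source analysis; $\rho = 0.5$ is a one-time modelling choice
(moderate agreement) and is documented as such. A label draw yielding a
single class is redrawn at most 100 times and then errors — deterministic
failure instead of silent degeneracy. The generator restores the caller's
RNG state, so identical seeds give byte-identical cohorts regardless of
surrounding code.

What the generator does *not* emulate — and therefore what passing tests do
not show about clinical data: miscalibrated score scales (real network
outputs are not logistic-clean; synthetic cohorts make the published
*cutoff values* unreproducible by design, only the cutoff *procedures* are
testable), heavier-than-normal tails, class-dependent correlation,
time-serial dependence between a patient's follow-up scans, and any image-
or lesion-level structure.

## Problem sizes and numerical choices in the test suite

The suite checks the estimators at the sizes where their guarantees are
sharp enough to be meaningful while keeping the default run in seconds:
brute-force oracle equivalence for Youden and AUC on 100 random instances
up to $n = 500$; AUC-target recovery at $n = 20{,}000$ (±0.01); prevalence
concentration at $n = 50{,}000$ (±0.01 relative); McNemar and DeLong test
size under a simulated null with 1,000 replicates at $n = 200$ (±0.02);
jackknife agreement of the DeLong variance on 20-patient instances (15%
relative). Cutoff-recovery uses the single-score binormal optimum
$\operatorname{plogis}(\delta/2)$ with a $3n^{-1/3}$ band, the cube-root
convergence rate of empirical Youden maximisers.

## Known limitations

* The evaluation is cross-sectional: one examination per patient, no
  modelling of repeat surveillance rounds or of radiologist over-reads of
  the enhanced scans.
* Wald intervals undercover for proportions near 0 or 1 at small $n$; they
  are retained because matching the published table is a design goal, and
  the clipping to [0, 100] is documented.
* The economics excludes downstream fees (biopsy, treatment, QALYs,
  discounting) by construction.
* Detection of *regional* (nodal) recurrence is out of scope; labels here
  are local recurrence only.
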