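---
title: "CAPS methods: scoring rules, cohort statistics and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CAPS methods: scoring rules, cohort statistics and the synthetic generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capscore)
```

## The clinical problem

Disease-modifying anti-amyloid therapies require biomarker evidence of
cerebral β-amyloid deposition (Aβ+), but amyloid PET and CSF assays are
unavailable to most clinicians who first see a patient with a clinical
Alzheimer syndrome. CAPS (Clinical β-Amyloid Positivity Prediction Score)
is a simple additive point score intended for triage: it estimates, from
observations already collected in any memory clinic, whether a patient is
likely to be Aβ+ on confirmatory testing. It is a pre-test stratifier,
not a biomarker substitute, and it applies only to patients who already
meet clinical Alzheimer-syndrome criteria (not to suspected Lewy body or
frontotemporal disease).

## The score

CAPS sums three components:

| Component | Input | Points |
|---|---|---|
| Neuropsychiatric symptoms | total NPI-Q severity score | 0 if 0; 1 if 1; 2 if ≥ 2 |
| Rapid cognitive decline | annualized MMSE loss | 1 if > 2 points/year, else 0 |
| White matter microangiopathy | Fazekas rating | 1 if ≤ 1, else 0 |

The total ranges 0–4; a score of **3 or 4 predicts Aβ+** (ties at the
threshold count as positive). The rationale: neuropsychiatric symptom
burden and fast decline are both associated with amyloid pathology, while
substantial white matter disease points to a vascular contribution and
away from amyloid — hence the *absence* of microangiopathy scores a
point.

**CAPS-MT** adds a medial temporal atrophy component: 1 point when the
Scheltens (MTLA) rating exceeds 2, giving a 0–5 total. The source
description introduces MTLA as an additional binary input without
printing a revised point table, so this package implements the simplest
additive extension and keeps the positivity threshold at 3 by default.
Both the arithmetic and the threshold are explicit package design
choices, exposed as arguments (`compute_caps_mt()`, `threshold =`), and
users should treat CAPS-MT operating characteristics under this reading
as approximate. Note one consequence of additivity: an MTLA point can
only raise a score, so CAPS-MT can rescue false negatives (it does, for
the two octogenarian false negatives in the validation fixture) but can
never reclassify a CAPS false positive downward.

### Component conventions

* **NPI-Q.** Twelve domains, each rated 0–3 for severity; the total
  (0–36) drives the points. A configuration switch (`npiq_mode =
  "count"`) uses the symptom count (0–12) instead, for sensitivity
  analysis only — the total is the primary definition.
* **Decline.** `annualized_decline()` uses the first and last available
  MMSE-equivalent scores: rate = (first − last) / years, years =
  days/365.25, positive = decline. "More than 2 points/year" is strict:
  a rate of exactly 2.0 is not rapid. With more than two visits the
  first/last pair maximises the observation span and matches the
  two-time-point definition; a least-squares slope over all visits is
  available (`method = "lsq"`) but off by default. Subjects with fewer
  than two dated scores raise a classed error and are excluded from any
  analysis that uses decline — they cannot be imputed.
* **MoCA→MMSE.** Where only MoCA is available it is mapped to the MMSE
  scale through a weighted-mean crosswalk known at 12 distinct anchor
  scores (11→18, 12→19, 13→20, 14→20, 15→21, 18→24, 21→26, 24→28,
  25→28, 26→29, 28→29, 30→30). Between anchors the conversion
  interpolates linearly and rounds half-up; below the lowest anchor it
  extends the first segment's unit slope (floored at 0). This
  reproduces every known pair exactly and is monotone over the whole
  0–30 range — both properties are tested exhaustively. For non-anchor
  inputs the full published crosswalk could differ from interpolation
  by a point; this is a documented approximation.
* **CSF positivity.** The assay cut-offs are Aβ42 > 1030 ng/L,
  p-tau/Aβ42 < 0.024 and t-tau/Aβ42 < 0.29 for the normal side. The
  combination logic is this package's documented rule: ratios take
  precedence (positive if either ratio is at or above its cut-off);
  the absolute Aβ42 rule (≤ 1030) applies only when no ratio is
  available or computable; borderline equality counts positive. When a
  subject has both CSF and PET, PET — the more direct measure — takes
  precedence for the reference label.
* **Staging.** Lawton–Brody 23/23 (full ADL independence) is prodromal;
  anything less is dementia stage. Hachinski > 4 flags a vascular
  picture. Both fields are optional: a missing value makes the derived
  stage absent rather than failing the record, and only analyses that
  need the field drop the subject.

## Cohort statistics

`evaluate_score()` scores a cohort, drops unscoreable subjects with a
logged reason, and reports the 2×2 confusion table, operating
characteristics, and an ROC analysis of the raw totals.

* **Operating characteristics** are exact cell-count quotients;
  undefined metrics (zero denominator) are `NA`, never 0.
  `predictive_values()` exposes the prevalence dependence of PPV/NPV,
  which matters whenever the score leaves the memory-clinic prevalence
  it was developed at (amyloid prevalence rises with age, so false
  negatives concentrate above 80 years and false positives below 60).
* **ROC/AUC.** The c-statistic is computed by the rank (Mann–Whitney)
  formula, ties counting ½ — identical to the trapezoidal area under
  the empirical curve; the test suite verifies this equivalence against
  a brute-force pairwise oracle on hundreds of random instances. The
  95% CI uses DeLong's method via pROC by default; Hanley–McNeil is
  selectable.
* **Two-group comparisons** follow the usual clinical-SPSS workflow:
  each group is screened with the Lilliefors-corrected
  Kolmogorov–Smirnov normality test (α = 0.05 per group; the
  Lilliefors correction is used because mean and SD are estimated from
  the data — testing against a fully specified normal would be
  anticonservative); if both groups pass, an independent-samples
  (Welch) t-test is used, otherwise Mann–Whitney. Categorical variables
  use chi-square with Yates continuity correction off by default.
  The gate's overall type-I error stays at the nominal 5% (verified by
  simulation in the test suite).
* **Logistic regression** is maximum likelihood by IRLS (via
  `stats::glm`, deviance tolerance 1e-8). Quasi-complete separation is
  detected from degenerate fitted probabilities and flagged; the fit is
  then reported as non-converged rather than silently trusted. The test
  suite checks the optimum against a 0.01-step coefficient grid.

## The synthetic cohort generator

There is no deposited patient-level dataset, so the package ships a
generator (`generate_cohort()`) whose defaults encode the two-group
memory-clinic cohort in which the score was developed: 30 Aβ+ subjects
(age 69.40 ± 10.64, 63% female, illness duration 2.87 ± 1.78 y, baseline
MMSE 24.50 ± 2.52, NPI-Q total 2.73 ± 1.66, Hachinski 2.37 ± 0.85, 61%
rapid decliners) and 22 Aβ− subjects (69.73 ± 10.76, 45% female,
3.29 ± 2.54 y, MMSE 26.85 ± 3.71, NPI-Q 1.18 ± 1.14, Hachinski
2.45 ± 1.68, 50% rapid).

Design choices a user should know:

* **Mean-calibrated truncated normals.** Clinical scales are bounded and
  the published group statistics are computed on the bounded scale.
  Sampling a normal with the published mean and truncating would bias
  the realized mean — severely near a bound (an MMSE of 26.85 ± 3.71
  truncated at 30 would realize ≈ 25.6; an NPI-Q of 2.73 truncated at 0
  would realize ≈ 2.91). The generator therefore keeps the published SD
  as the latent scale and solves (by monotone root-finding on the
  closed-form truncated-normal mean, or on the discretized pmf for
  integer scales) for the latent location that makes the realized mean
  equal the published mean exactly. The realized SD is consequently
  somewhat smaller than the latent SD near a bound; the mean, which is
  what the published table pins down most reliably, is exact by
  construction. Integer scales (MMSE, NPI-Q total, Hachinski) are
  sampled from the discretized pmf directly; age (> 40) and duration
  (> 0) remain continuous.
* **Within-group independence.** The published table reports marginals
  only, so variables are drawn independently within group — except the
  deterministic link between the drawn rapid/slow status and the second
  MMSE visit. Real cohorts correlate baseline severity, decline and
  atrophy; the generator does not, which is exactly why passing
  calibration tests demonstrates that the pipeline arithmetic is right,
  not that the score would achieve the same AUC on real patients.
* **Visit synthesis.** Each subject gets two MMSE visits 366 days
  apart; rapid decliners lose 3–6 points, slow ones 0–2. Under the
  365.25-day-year convention a 2-point drop over 366 days is 1.996
  points/year (not rapid) and 3 points is 2.994 (rapid), so recomputing
  the decline rule from the synthesized visits reproduces the drawn
  status exactly; a 365-day interval would misclassify the 2-point
  boundary. The only exception is a floor effect: a subject drawn near
  MMSE 0 cannot express a large drop.
* **NPI-Q allocation.** The drawn total is distributed over the 12
  domains by weighted sequential assignment capped at severity 3, with
  depression and irritability up-weighted in the Aβ+ group (domain
  means 0.80/0.63 vs 0.14/0.18) and proportionally in the Aβ− group.
* **Imaging category probabilities.** The published white-matter row is
  internally inconsistent (percentages do not sum to 100), so the
  generator encodes P(Fazekas ≥ 2) = 0.05 (Aβ+) and 0.18 (Aβ−). The
  published MTLA row (0/1/2/3 percentages 10/60/12/4 and 35/40/15/0)
  also sums short; the remainder (14% and 10%) is assigned to Scheltens
  category 4, consistent with the reported false-negative cases having
  MTLA 4. Both are assumptions and marked as such.
* **No analyte simulation.** The reference amyloid label is the group
  membership; CSF concentrations and PET quantification are not
  simulated.

### The validation fixture

`fixture_cohort()` is a deterministic, hand-constructed 48-subject
cohort (28 Aβ+, 20 Aβ−) whose component inputs reproduce the development
classification exactly: 25/28 positives score ≥ 3 and 16/20 negatives
score ≤ 2, i.e. a confusion table of (tp 25, fp 4, tn 16, fn 3), and
therefore sensitivity 25/28, specificity 80.0%, PPV 86.2% and NPV 84.2%.
The misclassified subjects carry the clinically described features (two
false negatives over 80 with MTLA 4 — rescued by CAPS-MT; a third aged
69 scoring 2 with MTLA 1; four false positives including two under-60s
with early neuropsychiatric symptoms, three of four with MTLA 1). The
fixture pins the full pipeline in a golden test; it encodes the
published *counts*, not real patient identities.

## Numerical and testing choices

* Threshold ties are positive; the rapid-decline and MTLA rules are
  strict inequalities; the NPI-Q and Fazekas rules are inclusive, all
  as defined above. Rounding for display is half-up.
* Exact quantities (score lattice, crosswalk anchors, fixture counts,
  AUC-vs-oracle equality) are tested exhaustively or at tolerance
  1e-12; stochastic properties use fixed seeds with problem sizes
  chosen to make the checks sharp at interactive runtimes: 20,000
  draws per group for generator calibration (standard error ≈ 0.012 on
  the NPI-Q mean), 200 random instances for the AUC oracle, 20
  datasets of n = 50 against a ±0.25, 0.01-step coefficient grid for
  the logistic optimum, and 2,000 replicates of n = 200 per group for
  the 5% ± 1.5% type-I-error check.
* The development cohort's reported AUC of 0.867 (and the CAPS-MT AUC
  of 0.90, its CIs, and CAPS-MT sensitivity/specificity) depend on the
  unavailable per-subject score distribution and are therefore *not*
  asserted anywhere; the package instead tests the properties that make
  those quantities meaningful (AUC–Mann-Whitney equivalence,
  confusion-table arithmetic, fixture counts).

## Known limitations

* CAPS-MT arithmetic is an interpretation (additive, threshold 3), as
  discussed above.
* The generator draws variables independently within group; it cannot
  be used to estimate the score's real-world discrimination, only to
  exercise and calibrate the pipeline.
* The MoCA crosswalk is linear between known anchors; non-anchor
  conversions are approximations.
* The development cohort is small (n = 52, 48 with decline data) and
  memory-clinic based; all fixture-derived metrics inherit that
  context, including its roughly 58% amyloid prevalence.
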