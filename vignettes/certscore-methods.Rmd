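---
title: "Ceramide risk scoring and synthetic cohort methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ceramide risk scoring and synthetic cohort methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(certscore)
```

## The score

Plasma ceramides are sphingolipids whose circulating levels carry
independent predictive value for cardiovascular events. The CERT1 score
condenses a four-species plasma panel — Cer 16:0, Cer 18:0, Cer 24:1 and
Cer 24:0, in µmol/L — into a single 0–12 risk integer. Six variables are
scored: the three concentrations Cer 16:0, Cer 18:0, Cer 24:1, and their
three ratios to Cer 24:0. Cer 24:0 itself enters only as the denominator;
it tends to *fall* in metabolic disease, so dividing by it amplifies the
signal of the harmful long-chain species.

Each variable is scored against quartile cutoffs of a reference
population: 0 points below the median, +1 in the third quartile, +2 in
the fourth. The six subscores are summed and the total mapped to four
risk categories: low (0–2), moderate (3–6), increased (7–9), high
(10–12).

Three conventions are deliberately pinned down because the scoring rule
alone does not determine them:

* **Tie handling at the cutoffs.** Quartile membership uses half-open
  intervals: `[q50, q75)` earns +1 and `[q75, ∞)` earns +2, so a value
  exactly at the 75th percentile belongs to the fourth quartile. This is
  deterministic and total on the reals.
* **Quantile estimator.** Cutoffs are linear interpolations of order
  statistics (`stats::quantile` type 7, the default in most scientific
  software). The estimator is configurable in
  `fit_quartile_reference()`.
* **Reference population.** By default the analyzed cohort itself is the
  reference (the pooled-sample convention); a frozen external
  `quartile_reference` table can be supplied instead to score new
  individuals against a fixed population, and round-trips through a
  plain-text CSV.

A useful structural identity follows from these choices: on a tie-free
cohort whose size is divisible by 4, self-referenced scoring gives each
subscore a mean of exactly 0.75, hence a mean CERT1 of exactly 4.5. The
test suite asserts this identity, and uses an independent brute-force
quartile-membership oracle to validate the scorer on randomized cohorts.

## Companion clinical scores

**HOMA-IR** is insulin (µIU/mL) × glucose (mmol/L) / 22.5. Glucose is
carried in mg/dL and converted with the exact molar factor 1/18.016
rather than the rounded clinical factor 0.06, which would bias HOMA-IR
by about +8%; the rounded factor remains available
(`convert_glucose(..., factor = "rounded")`) for replicating reports
that used it. Insulin in mU/L and µIU/mL is the same unit.

**Metabolic syndrome** is classified from five criteria — abdominal
obesity (waist ≥ 94 cm men / ≥ 80 cm women, the Europid consensus
cutoffs), hypertriglyceridemia (≥ 150 mg/dL), reduced HDL-C
(< 40/< 50 mg/dL by sex), hypertension (≥ 130/≥ 85 mmHg), hyperglycemia
(≥ 100 mg/dL) — with any treatment flag satisfying its criterion. The
default rule counts a subject positive with **any three** of the five,
matching the clinical definition this package accompanies; the
canonical consensus variant (central obesity mandatory plus two of the
remaining four) is available via `rule = "idf"`.

**Framingham 2008 general-CVD risk** is the sex-specific Cox model on
log age, log total cholesterol, log HDL-C, log SBP (separate
coefficients for treated and untreated), smoking and diabetes. The
coefficient table, linear-predictor means and 10-year baseline survival
are shipped as a plain-text table (`frs_coefficients()`) and locked by a
test against hand-verified values, including the source publication's
worked example (61-year-old female smoker, TC 180, HDL 47, untreated
SBP 124 → 10.48%). The published validity range is ages 30–74; outside
it the linear predictor is extrapolated and flagged (the cohorts this
package targets are young, and the vascular-age construct itself
requires evaluating the curve below age 30).

**Vascular age** is the age at which a same-sex subject with all other
risk factors at normal levels has the same predicted risk. The normal
profile is non-smoker, non-diabetic, untreated, TC 160 mg/dL, HDL-C
50 mg/dL, SBP 110 mmHg (configurable). The inversion is monotone
root-finding on age to 0.1 years; risks outside the achievable range of
the normal-profile curve are clamped to the search bounds and flagged.
A grid-search oracle at 0.01-year resolution confirms the root finder in
the tests. Note that published vascular ages depend on the normal-profile
convention of the calculator used; with this profile the fixed point
(an all-normal subject's vascular age equals their age) is exact by
construction, which is the property the package guarantees.

## Statistical pipeline

All group-level inference is non-parametric, as is conventional for
skewed clinical analytes at these sample sizes:

* **Group comparison**: tie-corrected Kruskal–Wallis, then Dunn's
  pairwise z-tests on pooled mid-ranks. The multiplicity adjustment
  across the three pairs is Bonferroni by default (Holm or none are
  selectable); Bonferroni is the most conservative and the usual
  companion of Dunn's test when the source does not specify one.
* **Regression**: ordinary least squares of each ceramide endpoint and
  CERT1 on seven clinical surrogates (WC, SBP, DBP, HOMA-IR, HDL-C, TG,
  CRP), with per-coefficient t-tests. Rank-deficient designs are
  rejected with the collinear columns named.
* **Covariate-adjusted comparison**: "non-parametric ANCOVA" is realized
  as a rank-transform (Conover–Iman style) model — outcome and
  covariates replaced by pooled mid-ranks, then
  `rank(outcome) ~ group + rank(covariates)` with treatment contrasts
  against the normal-weight group. Quade's variant (group test on
  residuals of the rank–rank regression) is available via
  `method = "quade"`. Because the original analysis did not name its
  procedure, adjusted comparisons are matched at the level of the
  significance pattern, not numerically.
* **Association**: Spearman's rho (asymptotic, tie-corrected p) together
  with the OLS slope/intercept, the conventional pairing in clinical
  reports of score-versus-risk relationships.
* **Contingency**: the 3 × 4 group-by-risk-category table, Pearson
  chi-square without continuity correction, df = (3−1)(4−1) = 6. The
  statistic is computed explicitly so an unused risk category
  contributes nothing (rather than NaN); when any expected count is
  below 5 a Fisher exact p is reported alongside.

`run_full_analysis()` executes the whole battery deterministically.
Stages fail independently: a single-group cohort still yields scores and
regressions while group tests and the contingency stage record their
errors. Reports serialize to JSON at 17 significant digits, so
re-reading reproduces every numeric field bit-exactly.

## The synthetic cohort generator

The subject-level data behind the three-group study design (normal
weight n = 30, obese without metabolic syndrome n = 24, obese with
n = 30) are not public; the generator reconstructs cohorts from the
published per-group median/quartile summaries so the pipeline can be
exercised end to end.

**Marginals.** Every positive continuous analyte is lognormal with
`mu = ln(median)` and `sigma = ln(q75/q25) / (2 qnorm(0.75))`. This
matches the median exactly and the quartile *ratio* exactly; when the
printed quartiles are asymmetric about the median in log space the
individual quartiles (and the IQR difference) deviate, and the fit
reports the deviation. Lognormality is the natural single-family choice
for strictly positive right-skewed analytes summarized by median/IQR.
Age uses a normal with `sd = IQR/1.349` truncated to 18–65 years (the
adult recruitment range); truncating to the printed IQR itself would
discard half of the realistic mass. Blood pressure is sampled
continuously and snapped to the 5-mmHg sphygmomanometer grid the
summaries display. The normal-weight CRP lower quartile is printed as 0,
which no positive distribution can match; the packaged fixture uses the
assay detection limit, 0.03 mg/dL, treating sub-LOD values as
left-censored at the limit.

**Derived quantities are never simulated.** Ceramide ratios and HOMA-IR
are computed from the simulated concentrations, so definitional
consistency is guaranteed. A consequence worth stating: the median of
derived HOMA-IR in a synthetic group is the product-of-medians, not the
printed median of the index (e.g. 1.43 vs 1.54 in the normal-weight
group) — medians do not compose. Where a marginal HOMA-IR sample is
wanted (e.g. calibration checks), the fitted marginal of the printed
HOMA-IR row is drawn directly.

**Dependence.** A Gaussian copula targets a Spearman rank-correlation
matrix (converted to Pearson via 2 sin(πρ/6), repaired to the nearest
positive semi-definite correlation matrix if infeasible). The defaults
link Cer 18:0 and Cer 24:1 to waist circumference, insulin and CRP at
ρ = 0.4 each, the clinical trio among themselves at 0.3, and Cer 24:0
to waist circumference at −0.3. Insulin stands in for HOMA-IR in the
dependence targets since it is the index's dominant factor. These
values are *invented calibration constants* that encode the qualitative
association structure (adiposity, insulin resistance and inflammation
drive the harmful ceramides); they are not estimates from any data set,
and the true covariance of the real cohort is unknown.

**Binary design variables.** Sex (19/18/19 female) and smoking (7/9/9)
are assigned by the published counts and shuffled; treatment-of-
hypertension and diabetes prevalences default to 0 because the study
population excluded treated or otherwise diseased subjects.

**What the generator does and does not emulate.** Marginal location and
spread, group separation and a plausible dependence skeleton are
reproduced; measurement error, non-lognormal tail shapes, age–risk-factor
coupling, and the real joint distribution are not. Passing pipeline
tests on synthetic cohorts therefore demonstrates correctness of the
computations and reproduction of the qualitative findings — CERT1
elevated in both obese groups, loss of the obese-without-MetS contrast
after waist adjustment, strongly significant risk-category contingency —
not numerical agreement with the original cohort's coefficients. Under
the default calibration the pooled CERT1 regression recovers waist
circumference essentially always, but HOMA-IR and CRP reach per-
coefficient significance only in a minority of 84-subject replicates:
the three predictors share their between-group variance (and compete
with TG/HDL-C, which also separate the groups), so the default ρ = 0.4
within-group signal is not strong enough to make all three significant
simultaneously at this sample size. The acceptance suite measures these
rates rather than hiding them.

## Problem sizes and numerical choices

* Generator calibration checks draw n = 10,000 per group; sample medians
  land within 2% of the printed values and quartile ratios within 5%.
* Pattern-reproduction checks run 100 seeded 84-subject replicates;
  scoring-oracle equivalence runs 1,000 randomized cohorts (n = 8–200).
* Root-finding tolerances: vascular age 0.1 years (`uniroot` tol 0.01);
  quantile cutoffs and ratios are exact arithmetic, no rounding.
* All randomness flows through a single integer seed per cohort; equal
  seeds give bit-identical cohorts and reports.

## Known limitations

* CERT2 (which adds phosphatidylcholine components) is out of scope; the
  panel here has no PC measurements.
* The score's external validity depends on the reference population;
  self-referenced quartiles make scores comparable within a cohort but
  not across studies unless a frozen reference is shared.
* Vascular ages are profile-convention-dependent (see above) and the
  Framingham model is extrapolated below age 30 in young cohorts.
* The generator's dependence matrix is a stand-in; conclusions about
  regression coefficient magnitudes on synthetic cohorts do not transfer
  to real data.
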