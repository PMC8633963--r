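---
title: "Deconfounded comparative effectiveness of antidepressants by robust LASSO stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconfounded comparative effectiveness of antidepressants by robust LASSO stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratarx)
```

## The problem

Observational claims data can, in principle, answer a question randomized
trials rarely do: which antidepressant works best for patients with a
*particular* medical history.  The obstacle is confounding by indication —
clinicians prescribe different drugs to sicker or treatment-resistant
patients, so a drug's crude remission rate mixes the drug's effect with
the characteristics of the patients who receive it.

`stratarx` implements a stratification-based answer.  Instead of
propensity scoring, episodes are partitioned into subgroups defined by
the predictors that drive *either* prescribing *or* remission; within a
subgroup those predictors are (approximately) constant, so drug
comparisons inside it are deconfounded with respect to everything the
models captured.  The per-drug effect across subgroups is summarized by
the Mantel-Haenszel common odds ratio, and the Breslow-Day test asks
whether a single common odds ratio is even a meaningful summary — when
it is rejected, the per-stratum remission rates are the result.

## The outcome: a surrogate remission index

Claims data do not contain patient-reported remission, so remission is
inferred from the pattern of medication use.  An episode counts as a
remission when **all four** conditions hold:

1. duration of use exceeded 10 weeks (70 days);
2. the dose reached the therapeutic level for that drug;
3. no switch to another antidepressant in the first 10 weeks;
4. no augmentation with another antidepressant in the first 10 weeks.

When a clinician has coded remission (e.g. ICD-9 296.25) inside the
episode's observation window, the episode is a remission regardless of
the fill pattern; the override can only turn labels from false to true.

Interpretation choices we had to make (each a config flag):

* *"exceeded 10 weeks"* is read as a strict inequality on days
  (`duration > 70`); *"dose exceeded therapeutic level"* is read as
  `>=` at the published minimum therapeutic dose, the standard clinical
  reading of "reached a therapeutic dose".
* A **switch** is a fill of a different antidepressant within 70 days of
  the start with no further fills of the index drug afterwards; an
  **augmentation** is such a fill while index-drug fills continue.
  The source distinguishes the two by name but defines neither; these
  operationalizations are unit-tested.
* Episode boundaries: consecutive fills with supply gaps of at most
  `gap_days = 30` form one episode.  Claims analyses use gap rules
  between 15 and 90 days; 30 is a common middle choice and the value is
  exposed in every interface.
* The observation window for clinician remission codes runs from the
  episode start to 70 days past the end of supply.

## Treatment classification

Fifteen antidepressant monotherapies are analyzed by name
(`ad_drug_names()`); monotherapy with any other antidepressant, or two
studied drugs filled on the same first day, are pooled as `"Other"`.
An episode that later adds a second drug keeps its index drug's label —
that pattern is what the switch/augmentation flags (and hence the
outcome) capture.

## Predictors and screening

Every diagnosis code (split by inpatient/outpatient setting), mental
health procedure, and medication observed in the year before the episode
start becomes one binary column; a missing covariate means the patient
did not have the condition.  Episode-history indicators (number of prior
episodes bucketed to `>=1 / >=2 / >=3`, and last episode's remission) are
appended, which keeps the matrix fully binary.  The matrix is screened
per model to the top `K = 1000` columns by the SAFE screening statistic
`|x_j'(y - mean(y))|` on standardized columns — the correlation-type
quantity the SAFE rule bounds.  We screen to a fixed *count* rather than
applying the penalty-dependent discard inequality because the analysis
design fixes the predictor budget, not the penalty; ties are broken by
column name (at 10 significant digits) so screening is deterministic.
Screening is done per model (per drug, per target), since each
regression receives its own 1,000 variables.

## Robust selection

For each drug, two LASSO-logistic models are fit on the screened
predictors:

* **propensity**: episode received this drug (one vs rest, all episodes);
* **remission**: remission among the episodes that received the drug.

Each fit uses 5-fold stratified cross-validation on binomial deviance
over a 100-point penalty grid (down to `1e-3` of the smallest empty-
support penalty) and selects the penalty by the one-standard-error rule.
Binary predictors share a scale, so columns are not standardized by
default (a flag restores standardization).

Selection robustness comes from the bootstrap: the CV-LASSO is refit on
`B = 40` resamples drawn with replacement, and a predictor is kept only
if its coefficient is non-zero *with the same sign* in at least 95% of
the fits — `ceiling(0.95 * 40) = 38` of 40, the only integer consistent
with that phrasing.  Age and gender are always appended to the robust
set so the strata remain interpretable.  A final unpenalized logistic
refit on the kept predictors provides the reported coefficients, with a
tiny-ridge (`lambda = 1e-4`) fallback when the refit separates.  Variable
importance is the absolute coefficient in the final full-data LASSO fit.
Rare-drug class imbalance is left as is (no reweighting), matching a
plain LASSO reading of the design.

Numerical choices: the coordinate-descent threshold is `1e-5` (accurate
far below the penalty grid's resolution for binary designs, at roughly
half the cost of the library default), and bootstrap resamples that lose
an outcome class are redrawn (bounded retries).

Model discrimination is reported as the rank-statistic AROC, either on a
10% holdout or as pooled out-of-fold CV scores; both schemes exist
because accuracy tables of this kind are reported both ways.

## Stratification

The union of a drug's two robust sets is ordered by importance — age
group (13–19, 20–40, 41–64, 65–79, 80+) first, gender second, then
descending absolute LASSO coefficient (the larger of the two models'
coefficients for shared features).  Strata are the leaves of a trie:
episodes are split recursively by the ordered variables, and a split is
accepted only if every resulting child would hold at least `min_size =
100` episodes; otherwise the node becomes a leaf.  This realizes
"drop the less important variables until every stratum is large enough"
*locally*: different branches keep different numbers of variables, which
is what produces subgroups defined by different variable subsets while
guaranteeing that every episode — and any future patient history —
matches exactly one stratum (`match_history()` descends the same trie).
A minimum of 99 rather than 100 is one flag away; both readings of the
trimming threshold appear in the source material.  We also considered a
single global variable cut, but it cannot produce variable-depth
subgroups and was rejected.

Per-node trimming has two provable consistency properties (both tested):
raising `min_size` never increases the number of strata, and every
stratum at `min_size = 2m` is a union of strata at `min_size = m`.

## Effect estimation

Within each stratum, a 2x2 table contrasts the drug against all other
treatments.  Across strata:

* the **Mantel-Haenszel common odds ratio** with a 99% confidence
  interval from the Robins-Breslow-Greenland variance of its logarithm
  (the variance estimator is not named in the source; RBG is the
  standard choice for MH intervals and is what `stats::mantelhaen.test`
  uses, which serves as an independent cross-check in the tests);
* the **Breslow-Day chi-square** for homogeneity of the odds ratios,
  with Tarone's bias correction reported alongside; degenerate strata
  (a zero margin) are excluded from the degrees of freedom and counted.

No continuity corrections enter the MH or Breslow-Day sums; a 0.5
correction is applied only when displaying a single table's OR.
Per-stratum remission-rate tables blank cells with fewer than
`report_min = 25` episodes (printed tables of this kind have blank cells
with no stated rule; 25 is a conventional minimum cell size for a stable
rate and is config-exposed).  The best drug per stratum is the reported
drug with the highest rate, ties broken by larger count then name, and
the counterfactual gain report asks how many additional remissions would
have occurred had every episode experienced its stratum's best rate.
`expected_false_positives(alpha, m)` supplies the multiplicity
expectation `alpha * m` for reading thousands of per-stratum
comparisons.

## The synthetic claims generator

`generate_claims()` emulates exactly the structure the pipeline
consumes: independent Bernoulli history features (optional correlated
blocks behind `feature_cor`), drug assignment by multinomial logit over
the features (planting confounding by indication — by default each
drug's propensity model and remission model share one active feature),
and fill sequences that *encode* the remission outcome: a remitter's
fills satisfy all four index conditions; a non-remitter violates exactly
one, chosen uniformly among short duration, sub-therapeutic dose,
switch, and augmentation (the source describes no non-remitter fill
patterns, so uniform is the neutral choice).  History features are
materialized as dated diagnosis claims inside each episode's lookback,
so the feature builder reconstructs them from claims alone.

Default scale parameters are the published study conditions where they
exist: per-drug prescribing prevalences (0.5%–24%) and remission
prevalences (3%–49%) set the intercepts, and the age/gender mix follows
the published cohort table.  Where the source is silent (fill cadence,
days supply, episode spacing, number of episodes per patient), defaults
are field-standard claims conventions: 30-day supplies refilled monthly,
1–4 episodes per patient, later episodes 200–320 days apart, and
coverage spans long enough that the eligibility filter passes by design
(an `ineligible_rate` flag generates filter-violating patients on
purpose).  Every choice is config-exposed and fixed by the seed —
identical configs give byte-identical CSVs.

What the generator does *not* emulate: real ICD/NDC code frequencies and
hierarchies, correlated comorbidity structure (unless enabled),
time-varying coverage, dose titration within an episode, and partial
adherence.  Passing tests therefore demonstrate that the estimators and
the pipeline logic are correct under planted truth, not that the
clinical conclusions transfer to any real claims extract.

## What the checks compute

The test suite and `scripts/acceptance.R` recompute, at sizes chosen for
a desk-scale run: the published counterfactual-gain and multiplicity
arithmetic from the printed episode counts; the exhaustive 16-cell truth
table of the remission index; agreement of the MH/RBG/Breslow-Day
estimators with independent implementations (root-finding instead of the
closed-form quadratic, `mantelhaen.test`) to 1e-8 on random table sets;
Breslow-Day type-I calibration (1,000 simulated 10-stratum sets of 500
episodes each) and power under planted heterogeneity; recovery of a
10-signal planted support from n = 10,000, p = 200 with 40-bootstrap
sign-stability, and near-empty selection under pure noise; equality of
the trie partition with a brute-force recursion on 1,000 random small
cohorts; and the deconfounding experiment — a planted confounder with
true conditional OR = 1 produces a crude OR above 1.5 at n = 50,000
(that experiment uses B = 4 bootstraps, ample for a single strong
confounder), while the stratified MH interval recovers the null.

## Known limitations

* Switch/augmentation definitions are operationalizations; other
  readings (e.g. grace periods) would change boundary episodes.
* The importance measure inherits the LASSO's scale: binary predictors
  share a scale, but age does not, so age's coefficient is not directly
  comparable — age is forced to the front of the order regardless, which
  sidesteps the comparison.
* Strata deconfound only what the models measured; unobserved
  confounders pass through untouched.
* The generator's independence defaults make support recovery easier
  than correlated real-world predictors would; the `feature_cor` option
  exists precisely to probe that gap.
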