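---
title: "Classifying homelessness in linked administrative data and weighting overdose rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying homelessness in linked administrative data and weighting overdose rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(homeclass)
```

## The problem

Homelessness is badly under-recorded in administrative data: no single
service system observes everyone, and most systems record housing status
unreliably or not at all. When person-level records from many state systems
— insurance claims, hospital discharges, mental-health services, ambulance
runs, prescription monitoring, death certificates — are linked, two things
become possible. First, a *composite case definition* can recover the
"known cases" that any one source would miss. Second, because even the
composite definition is incomplete, a classification model fit to those
known cases can score everybody else: the patterns of service use that
accompany recorded homelessness are informative about unrecorded
homelessness.

`homeclass` implements this workflow end to end, together with the
downstream use that motivates it: comparing fatal opioid-overdose rates
between the (model-identified) homeless and non-homeless groups. Because
the real linked warehouses that motivate the method are access-restricted,
the package includes a seeded synthetic-data generator with known ground
truth, so every stage is testable and every design decision is auditable.

## The composite case definition

A person is a **known case of homelessness** when any of four criteria
holds at any point in the observation window:

1. an ICD-9 V60-family or ICD-10 Z59.0 diagnosis code on an insurance
   (APCD) or hospital (Case Mix) claim — the two claim streams are flagged
   separately;
2. any monthly *housing loss* record in the state mental-health system's
   housing-status measure;
3. the word "homeless" or "shelter" in an ambulance run narrative;
4. a prescription whose patient address matches an emergency shelter.

Three matching policies were genuinely open and are resolved as follows,
each behind an explicit argument:

* **V60 is a family prefix.** The ICD-9 category V60 ("housing, household
  and economic circumstances") contains homelessness as V60.0; sources code
  at varying depth, so `has_homeless_icd()` matches any `V60x` after
  normalization (uppercase, periods and whitespace stripped). Z59.0 is
  matched exactly. `v60_family = FALSE` restricts to the bare category.
* **Keyword matching is plain substring.** "The word appeared" is read
  literally: `narrative_indicates_homeless()` is a case-insensitive
  substring test, so "sheltered" matches. A `word_boundary = TRUE` mode is
  provided for sensitivity analyses.
* **Address matching is exact after normalization** (uppercase, punctuation
  stripped, whitespace collapsed). No fuzzy matching or geocoding: a
  shelter match should be an unambiguous signal, and fuzzy matching would
  trade specificity — the definition's strength — for sensitivity.

Time is deliberately not modelled: any record ever observed counts, because
the definition is explicitly an "ever during the window" measure.

## Fatal opioid overdoses

`classify_opioid_deaths()` applies the standard two-field rule: the
underlying cause of death must be a poisoning (X40–X49, X60–X69, X85–X90,
Y10–Y19 at the category level, or Y35.2 exactly) *and* some multiple-cause
field must carry an opioid code among T40.0–T40.4 or T40.6. T40.5
(cocaine) never qualifies, and extra non-opioid multiple causes never
change a call. Records with no ICD code assigned yet fall back to a
case-insensitive keyword search of the written cause-of-death literal
(`heroin`, `fentanyl`, `opioid`, `opiate`, `morphine`, `oxycodone`,
`methadone` by default); the authoritative term list for such literal
searches is not standardized, so the list is a visible, configurable
argument.

## Cohort, split, downsampling, model

The analytic cohort (`restrict_cohort()`) requires at least one APCD claim
(the universe source), at least one record in any other linked source — a
guard against non-resident and unresolved-duplicate claim records — and age
11 or older.

The classification workflow then proceeds:

* **Stratified 75/25 split** (`stratified_split()`) on the known-case
  label, so both partitions carry the same (low) case proportion. The
  development count per stratum is `0.75 × size` rounded *half-up*: this
  rounding rule is what makes published development totals exactly
  reproducible from the stratum sizes (e.g. strata of 41,457 and 5,009,182
  give 31,093 + 3,756,887 = 3,787,980).
* **Downsampling** (`downsample_majority()`): all known cases in the
  development sample are kept and an equal-sized uniform subsample of the
  rest joins them. With a ~0.8% positive class, a model fit to the raw
  development sample degenerates to near-perfect specificity and useless
  sensitivity; 1:1 downsampling is the standard remedy.
* **Logistic regression** (`fit_logistic()`): plain main-effects
  maximum likelihood on binary predictors, fit by an explicit IRLS loop.
  Training labels are the *known cases*, not the latent truth — the method
  assumes its label is incomplete and asks what the captured cases' record
  patterns generalize to.
* **Scoring** (`predict_probability()`): the fitted coefficients are
  applied to the whole validation partition.

One caveat is inherited deliberately: probabilities from a downsampled fit
are inflated (the intercept reflects the artificial 1:1 class balance, not
the true ~0.8% prevalence), and no intercept correction is applied before
thresholding at 0.5, because the workflow being implemented applies the raw
downsampled-model probabilities directly. Thresholding inflated
probabilities at 0.5 is roughly thresholding calibrated probabilities at a
far smaller value, which is why the flagged share of the validation sample
(≈5–12% depending on configuration) greatly exceeds the known-case
prevalence, and why PPV is low while the lift over chance remains large.

### Numerical choices in the IRLS fit

Convergence is declared when the largest absolute coefficient change falls
below 1e-8, with a hard cap of 100 iterations. Each Newton step is
step-halved until the (penalized) log-likelihood does not decrease, so the
likelihood trace is monotone by construction — a property the tests assert.
Complete or quasi-complete separation (diverging coefficients past ±30 on
the log-odds scale, or a singular weighted cross-product) switches on a
tiny ridge penalty of 1e-6 and flags the fit rather than failing or
silently returning garbage. Constant predictors are dropped with a warning.
`stats::glm` is used in the test suite as an independent cross-check of the
estimates and standard errors; the closed-form saturated 2×2 solution is a
second, package-independent oracle.

## Evaluation

`evaluate_scores()` reports the confusion metrics at an *inclusive* 0.5
threshold (a score exactly at the threshold is called positive), the
rank-based Mann–Whitney AUC with midrank tie handling (`compute_auc()`,
verified against exhaustive pairwise comparison to 1e-12), balanced
accuracy — the mean of sensitivity and specificity, the appropriate summary
under severe imbalance — PPV, NPV, the lift of PPV over prevalence, and the
reciprocal of PPV (false positives incurred per true positive, plus one).
The AUC is computed on the full imbalanced validation partition, not the
downsampled set. Undefined metrics (zero denominators) are returned as `NA`
with a warning, never as silent zeros.

## Weighted rate comparison

Three risk-score assignments are supported by `assign_risk_scores()`:
dichotomization at 0.5 (`threshold_binary`); known cases forced to 1 with
everyone else keeping their predicted probability (`known_override`); and
additionally zeroing non-known persons below 0.5 (`known_and_zeroed`).

`weighted_group_counts()` turns scores into group masses: each person
contributes `s` to the homeless group and `1 − s` to the non-homeless
group, and a death contributes its person's mass to that person's group.
Two readings of "sum the scores of those above the threshold" are
implemented:

* `full_sum` (default): sums over *all* persons, so the two group sizes
  partition the sample exactly — this is the only convention under which
  published weighted group sizes can sum exactly to the validation n, which
  they do for the weighted approaches;
* `threshold_restricted`: the literal reading, summing homeless mass only
  above the threshold and non-homeless mass only below it.

Under purely binary scores the two conventions coincide (a property the
tests check). The complement `1 − s`, not the reciprocal `1/s`, is used
for non-homeless mass: only the complement yields person counts.

`rate_ratio_ci()` compares the two crude rates per 100,000 and attaches
the standard log-normal interval `exp(log RR ± z·√(1/d₁ + 1/d₀))` with
`z = 1.959964`. This "standard technique" reproduces published intervals
for such comparisons to the printed decimal, which is the package's
evidence for the interpretation; the acceptance checks assert exactly that.

A caution the package makes explicit: the scheme-based RR estimates are
attenuated by misclassification. The predicted-homeless group is heavily
diluted with non-homeless persons at realistic PPV, so the estimated RR
under any scheme sits well below the latent person-level rate ratio, and
different schemes give visibly different answers. Parameter recovery of the
*generating* rate ratio is therefore assessed on the true-group comparison
(the generator's embedded effect plus the CI machinery), not on the
scheme estimates.

## The synthetic generator

`generate_population()` draws, per person: age (uniform 11–90 by default;
younger ages only matter for cohort-exclusion tests), sex, latent
homelessness (Bernoulli, default five-year prevalence 4.6% — the general-
population scale estimate for a five-year window), twenty binary predictors
in five groups whose prevalence shifts by a configured log-odds for the
truly homeless, and death outcomes (a five-year cumulative overdose
probability of 4.5e-4, multiplied by a rate ratio of 20 for the homeless;
background non-overdose deaths at 2%). Overdose is a cumulative
probability, not a hazard process, because the downstream comparison uses
crude period rates.

**Capture model.** Each source observes a truly homeless person with the
configured marginal sensitivity (defaults 10%, 9.4%, 0.13%, 1.4%, 2.9% for
claims, hospital, mental-health, ambulance and prescription signals — the
scale of published per-source known-case counts). Fully independent
captures with these marginals are, however, arithmetically incompatible
with two facts such data display jointly: an overall known-case prevalence
near 0.82% of the cohort and roughly a third of known cases carrying
multiple indicators. Independence would give ~1.01% and ~8%. The generator
therefore uses a two-class *service-engagement* model: 28% of the truly
homeless are engaged with services at all, and only they can be captured,
conditionally independently, with probability `sensitivity / 0.28` per
source. Marginal sensitivities are preserved exactly (a test asserts this),
while the induced positive dependence yields a known-case prevalence of
0.82% and a multi-source share of ~30%. `capture_engagement = 1` recovers
the independence model. A captured source carries the corresponding planted
signal — a messy-formatted V60x/Z59.0 code, a `housing_loss` month, a
keyword narrative, a format-jittered shelter address — so the case
definition's normalization paths are exercised, not just its happy path.

By default there are no false planted signals, so the composite definition
has specificity 1 on synthetic data by construction and every known case is
truly homeless; `false_capture_rate` adds label noise for robustness
experiments.

**What the generator does not emulate** — and what passing tests therefore
do not establish about real data: record-linkage errors and duplicate
identities (IDs arrive pre-linked and unique); realistic ICD code frequency
structure beyond planted-vs-background; temporal ordering of records,
homelessness spells and deaths; correlation between predictors within a
person beyond what the shared latent status induces; and capture that
depends on the predictors themselves (engagement is drawn independently of
the feature vector, so known cases are a random subsample of the engaged —
in real systems capture and service use are correlated, which would bias a
fitted model in ways this generator cannot reveal).

## Problem sizes and reproducibility

Everything is seeded: the generator from `sim_config(seed =)`, the split
and downsampling from their own seeds (offsets of the data seed by
default), and identical configurations reproduce byte-identical outputs —
`run_pipeline()` writes its tables and a manifest, and the test suite
asserts two runs agree file-for-file.

The simulation studies are sized for a desk machine while keeping the
statistical checks meaningful: calibration of the generator and the
classifier's operating point are assessed at 500,000 persons (known-case
counts ≈4,000, so the prevalence and multi-source bands are many binomial
standard errors wide); CI coverage of the embedded rate ratio uses 200
replicates of 500,000 (≈200 events per arm per replicate); and the
chance-level check of a signal-free model runs at 1,000,000 persons, where
the null AUC's sampling standard deviation is ≈0.007 so the [0.48, 0.52]
band is a ≥2.9σ statement rather than a coin flip. The default predictor
set (20 predictors, not the ~90 of a production model) puts the validation
AUC in the low 0.9s, the documented operating regime, while keeping fits
instantaneous.

## Known limitations

* The classifier is main-effects logistic regression only — no
  interactions, regularization paths or alternative learners; that is the
  method under study, not a recommendation.
* The weighted RR machinery propagates no uncertainty from the
  classification step into the interval; the log-normal CI treats weighted
  counts as known.
* The ICD matcher does not distinguish ICD-9 from ICD-10 claims context;
  in mixed-version claims data the V60 prefix rule relies on transport-
  accident ICD-10 V60x codes not appearing in diagnosis fields.
* Crude rates only: no person-time denominators, competing risks, or
  covariate adjustment.
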