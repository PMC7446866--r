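# homeclass

Classification of homelessness from linked administrative records, and
risk-score-weighted comparison of fatal opioid-overdose rates.

## What this is for

Homelessness is poorly captured in administrative data: each service
system sees only a slice of the population and few record housing status
reliably. When statewide person-level records are linked — insurance
claims, hospital discharges, mental-health services, ambulance runs,
prescription monitoring, death certificates — known cases of homelessness
can be assembled from a composite definition, and a classification model
fit to those known cases can score everyone else. `homeclass` is for
epidemiologists and health-services researchers who want that workflow as
tested, seeded, reusable code: the composite case definition, the
ICD-based fatal-overdose classification, the stratified-split /
downsampled logistic model, its evaluation under severe class imbalance,
and the downstream weighted rate comparison — plus a synthetic linked-data
generator with known ground truth, because the real warehouses are
access-restricted.

## The method in brief

A person is a **known case** if any of four indicators ever occurs:

1. ICD-9 V60.x or ICD-10 Z59.0 on an APCD or Case Mix claim,
2. a monthly `housing_loss` record in the mental-health system,
3. "homeless" or "shelter" in an ambulance narrative,
4. a prescription address matching an emergency shelter.

With known-case label *y* and binary predictors *x₁…xₚ*, the model is
main-effects logistic regression fit on a 1:1 downsampled development
sample (all cases plus an equal random subsample of non-cases from a
stratified 75/25 split):

    logit P(y = 1 | x) = β₀ + β₁x₁ + … + βₚxₚ

Validation-sample scores p̂ᵢ are evaluated by rank-based AUC, sensitivity,
specificity, balanced accuracy = (sens + spec)/2, PPV, NPV, and the lift
PPV/prevalence. For the rate comparison, risk scores sᵢ ∈ [0,1] (three
schemes: dichotomized at 0.5; known cases forced to 1; both) give weighted
group sizes Σsᵢ and Σ(1−sᵢ), weighted death counts Σsᵢdᵢ and Σ(1−sᵢ)dᵢ,
rates per 100,000, and a rate ratio with the log-normal interval

    exp( ln RR ± 1.959964 · √(1/d₁ + 1/d₀) )

A fatal opioid overdose is a death with a poisoning underlying cause
(X40–X49, X60–X69, X85–X90, Y10–Y19, Y35.2) and an opioid multiple cause
(T40.0–T40.4, T40.6), with a keyword fallback for records that lack ICD
codes.

## Worked example

```r
library(homeclass)

run <- run_pipeline(sim_config(n_persons = 200000, seed = 1))
run
#> <homeless_run>
#>   cohort: 179,953 persons, 1696 known cases
#>   development: 134,965 (downsampled to 2544); validation: 44,988
#>   validation AUC 0.925 | sens 82.1% | spec 88.2% | balanced acc 85.1%
#>   threshold_binary   RR 2.5 (1.3-4.6)
#>   known_override     RR 2.4 (1.3-4.2)
#>   known_and_zeroed   RR 3.4 (1.8-6.3)
```

Reading this: of 200,000 simulated persons, 179,953 survive the cohort
restriction (an APCD claim, one other source, age ≥ 11) and 1,696 (0.94%)
are known cases. The model is fit on the 2,544-person balanced development
set and scored on the 44,988-person validation partition, where it ranks a
random known case above a random non-case 92.5% of the time. The three
risk-score schemes then give weighted overdose rate ratios between 2.4 and
3.4 — far below the generating person-level ratio of 20, because the
predicted-homeless group is heavily diluted with non-homeless persons at
this PPV (6.2%); the spread across schemes is itself the point of running
all three.

The fitted model and tables are ordinary tidy objects:

```r
tidy(run$model)
#> # A tibble: 21 × 5
#>   term           estimate std.error statistic   p.value
#>   <chr>             <dbl>     <dbl>     <dbl>     <dbl>
#> 1 (Intercept)      -4.24      0.189    -22.5  6.23e-112
#> 2 medicaid          1.36      0.130     10.5  6.97e- 26
#> 3 male              0.478     0.128      3.74 1.85e-  4
#> # …

run$rates          # one row per scheme: weighted n, deaths, rates, RR, CI
autoplot(run$rates)          # RR forest plot
plot_roc(run$scores$probability, run$scores$known)
```

Individual stages are exported and pipe-friendly:
`generate_population()`, `identify_known_homeless()`, `restrict_cohort()`,
`stratified_split()`, `downsample_majority()`, `fit_logistic()`,
`predict_probability()`, `evaluate_scores()`, `classify_opioid_deaths()`,
`assign_risk_scores()`, `weighted_group_counts()`, `rate_ratio_ci()`.
A thin CLI lives at `inst/cli/homeclass.R`
(`Rscript homeclass.R all --config cfg.yaml --out dir/`).

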