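#' Default synthetic predictor set
#'
#' Twenty binary predictors spread over the five predictor groups used in
#' linked-administrative-record models of homelessness (sociodemographic,
#' drug/alcohol, mental health, physical health, other service use). Each
#' predictor has a background prevalence (`baseline_prob`) among persons who
#' never experience homelessness and a shift on the log-odds scale
#' (`log_odds`) among those who do. The defaults are calibrated so the
#' downsampled logistic workflow reaches a validation AUC in the low 0.9s,
#' the operating regime of large linked-data classification models of
#' homelessness.
#'
#' @return A tibble with columns `name`, `group`, `baseline_prob`,
#'   `log_odds`.
#' @export
default_predictor_spec <- function() {
  tibble::tribble(
    ~name,                   ~group,             ~baseline_prob, ~log_odds,
    "medicaid",              "sociodemographic", 0.25,           1.4,
    "male",                  "sociodemographic", 0.49,           0.5,
    "urban_resident",        "sociodemographic", 0.30,           0.6,
    "housing_subsidy",       "sociodemographic", 0.15,           1.0,
    "sud_dx",                "drug_alcohol",     0.08,           2.2,
    "oud_dx",                "drug_alcohol",     0.025,          2.4,
    "alcohol_dx",            "drug_alcohol",     0.06,           2.0,
    "detox_treatment",       "drug_alcohol",     0.01,           2.6,
    "psychosis_dx",          "mental_health",    0.015,          2.4,
    "schizophrenia_dx",      "mental_health",    0.008,          2.6,
    "bipolar_dx",            "mental_health",    0.03,           2.0,
    "psych_hospitalization", "mental_health",    0.01,           2.6,
    "skin_infection",        "physical_health",  0.02,           1.8,
    "hepatitis_c",           "physical_health",  0.012,          2.0,
    "copd",                  "physical_health",  0.06,           0.9,
    "injury_dx",             "physical_health",  0.18,           0.8,
    "incarceration",         "other_service",    0.01,           2.8,
    "ed_use",                "other_service",     0.35,          1.6,
    "ambulance_trip",        "other_service",     0.20,          1.2,
    "veteran_services",      "other_service",     0.02,          1.0
  )
}

predictor_groups <- c(
  "sociodemographic", "drug_alcohol", "mental_health",
  "physical_health", "other_service"
)

capture_sources <- c("apcd_icd", "casemix_icd", "dmh", "matris", "pmp")

#' Configuration for the synthetic linked-population generator
#'
#' Bundles and validates every parameter of [generate_population()]. The
#' defaults emulate the statistical structure of a statewide linked
#' administrative warehouse over a five-year window: a latent five-year
#' homelessness prevalence of 4.6%, per-source capture sensitivities whose
#' marginals reproduce source-specific known-case counts of roughly
#' 10%/9.4%/0.13%/1.4%/2.9% of the truly homeless, and an overdose-death
#' process with a 20-fold rate elevation in the homeless group.
#'
#' Captures follow a two-class engagement model: a fraction
#' `capture_engagement` of truly homeless persons are "service-engaged" and
#' only they can be captured, with conditionally independent per-source
#' capture probability `capture_sensitivity / capture_engagement`. The
#' marginal per-source sensitivity is therefore exactly
#' `capture_sensitivity`, while the positive dependence between sources
#' concentrates multi-source identification the way real service data do
#' (roughly a third of known cases carry more than one indicator). Setting
#' `capture_engagement = 1` recovers fully independent captures.
#'
#' @param n_persons Number of persons to simulate.
#' @param true_prevalence Latent five-year probability of homelessness.
#' @param capture_sensitivity Named numeric vector of marginal per-source
#'   capture probabilities for a truly homeless person; names must be
#'   `apcd_icd`, `casemix_icd`, `dmh`, `matris`, `pmp`.
#' @param capture_engagement Fraction of truly homeless persons who are
#'   service-engaged (capturable); must be at least `max(capture_sensitivity)`.
#' @param source_membership Named numeric vector of background membership
#'   probabilities (any record in the source, independent of homelessness)
#'   for `apcd`, `casemix`, `dmh`, `matris`, `pmp`.
#' @param predictor_spec Tibble describing the binary predictors; see
#'   [default_predictor_spec()].
#' @param baseline_overdose_prob Five-year fatal opioid-overdose probability
#'   for a non-homeless person.
#' @param true_rate_ratio Multiplier on `baseline_overdose_prob` for truly
#'   homeless persons (capped so the product never exceeds 1).
#' @param background_death_prob Five-year probability of a non-overdose
#'   death (generates death records that must classify negative).
#' @param literal_only_fraction Fraction of overdose death records carrying
#'   only a free-text cause-of-death literal and no ICD code yet, to
#'   exercise the literal-search fallback.
#' @param false_capture_rate Per-source probability that a non-homeless
#'   person receives a spurious planted indicator (label noise; default 0).
#' @param n_shelters Number of distinct emergency-shelter addresses.
#' @param age_range Integer vector `c(min, max)` for the uniform age draw.
#' @param seed Integer seed; identical configurations generate identical
#'   populations.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_persons = 1000, seed = 42)
#' cfg$true_prevalence
sim_config <- function(n_persons,
                       true_prevalence = 0.046,
                       capture_sensitivity = c(
                         apcd_icd = 0.100, casemix_icd = 0.094,
                         dmh = 0.0013, matris = 0.014, pmp = 0.029
                       ),
                       capture_engagement = 0.28,
                       source_membership = c(
                         apcd = 0.98, casemix = 0.60, dmh = 0.01,
                         matris = 0.30, pmp = 0.70
                       ),
                       predictor_spec = default_predictor_spec(),
                       baseline_overdose_prob = 4.5e-4,
                       true_rate_ratio = 20,
                       background_death_prob = 0.02,
                       literal_only_fraction = 0.02,
                       false_capture_rate = 0,
                       n_shelters = 25,
                       age_range = c(11L, 90L),
                       seed = 1L) {
  n_persons <- check_scalar_count(n_persons, "n_persons", min = 1)
  if (!is_prob(true_prevalence) || length(true_prevalence) != 1) {
    abort("`true_prevalence` must be a single probability in [0, 1].")
  }
  if (!is_prob(capture_sensitivity) ||
      !setequal(names(capture_sensitivity), capture_sources)) {
    abort(paste0(
      "`capture_sensitivity` must be probabilities named ",
      paste(capture_sources, collapse = ", "), "."
    ))
  }
  capture_sensitivity <- capture_sensitivity[capture_sources]
  if (!is_prob(capture_engagement) || length(capture_engagement) != 1 ||
      capture_engagement <= 0) {
    abort("`capture_engagement` must be a single probability in (0, 1].")
  }
  if (any(capture_sensitivity > capture_engagement)) {
    abort(paste0(
      "each `capture_sensitivity` must be <= `capture_engagement` ",
      "(the marginal capture probability cannot exceed the engaged fraction)."
    ))
  }
  if (!is_prob(source_membership) ||
      !setequal(names(source_membership), c("apcd", "casemix", "dmh", "matris", "pmp"))) {
    abort("`source_membership` must be probabilities named apcd, casemix, dmh, matris, pmp.")
  }
  source_membership <- source_membership[c("apcd", "casemix", "dmh", "matris", "pmp")]
  predictor_spec <- tibble::as_tibble(predictor_spec)
  required <- c("name", "group", "baseline_prob", "log_odds")
  if (!all(required %in% names(predictor_spec))) {
    abort("`predictor_spec` needs columns name, group, baseline_prob, log_odds.")
  }
  if (anyDuplicated(predictor_spec$name) > 0) {
    abort("predictor names must be unique.")
  }
  if (!all(predictor_spec$group %in% predictor_groups)) {
    abort(paste0("predictor groups must be among: ",
                 paste(predictor_groups, collapse = ", "), "."))
  }
  if (!is_prob(predictor_spec$baseline_prob)) {
    abort("`baseline_prob` values must be probabilities in [0, 1].")
  }
  if (!is_prob(baseline_overdose_prob) || length(baseline_overdose_prob) != 1) {
    abort("`baseline_overdose_prob` must be a single probability.")
  }
  if (!is.numeric(true_rate_ratio) || length(true_rate_ratio) != 1 ||
      is.na(true_rate_ratio) || true_rate_ratio <= 0) {
    abort("`true_rate_ratio` must be a single positive number.")
  }
  if (!is_prob(background_death_prob) || !is_prob(literal_only_fraction) ||
      !is_prob(false_capture_rate)) {
    abort("death/noise fractions must be probabilities in [0, 1].")
  }
  n_shelters <- check_scalar_count(n_shelters, "n_shelters", min = 1)
  if (length(age_range) != 2 || age_range[1] > age_range[2] || age_range[1] < 0) {
    abort("`age_range` must be c(min, max) with 0 <= min <= max.")
  }
  seed <- check_scalar_count(seed, "seed", min = -.Machine$integer.max)

  cfg <- structure(
    list(
      n_persons = n_persons,
      true_prevalence = true_prevalence,
      capture_sensitivity = capture_sensitivity,
      capture_engagement = capture_engagement,
      source_membership = source_membership,
      predictor_spec = predictor_spec,
      baseline_overdose_prob = baseline_overdose_prob,
      true_rate_ratio = true_rate_ratio,
      background_death_prob = background_death_prob,
      literal_only_fraction = literal_only_fraction,
      false_capture_rate = false_capture_rate,
      n_shelters = n_shelters,
      age_range = as.integer(age_range),
      seed = seed
    ),
    class = "sim_config"
  )
  profile <- capture_profile(cfg)
  if (profile$expected_observed_prevalence > true_prevalence + 1e-12 &&
      false_capture_rate == 0) {
    abort("capture configuration implies observed prevalence above `true_prevalence`.")
  }
  cfg
}

#' Analytic capture profile of a simulation configuration
#'
#' Closed-form expectations implied by the engagement-capture model: the
#' probability that a truly homeless person is a known case (captured by at
#' least one source), the probability of capture by two or more sources,
#' the multi-source share among known cases, and the expected observed
#' (known-case) prevalence in the full population. Useful for checking the
#' generator's calibration without simulation.
#'
#' @param config A [sim_config()] object.
#' @return A one-row tibble with columns `p_known_given_true`,
#'   `p_multi_given_true`, `multi_source_share`,
#'   `expected_observed_prevalence`.
#' @export
capture_profile <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  f <- config$capture_engagement
  a <- config$capture_sensitivity / f      # capture prob given engagement
  none <- prod(1 - a)
  one <- none * sum(a / (1 - a))           # exactly one source, given engaged
  p_any <- f * (1 - none)
  p_multi <- f * (1 - none - one)
  fp <- config$false_capture_rate
  p_any_fp <- 1 - (1 - fp)^length(a)
  tibble::tibble(
    p_known_given_true = p_any,
    p_multi_given_true = p_multi,
    multi_source_share = ifelse(p_any > 0, p_multi / p_any, NA_real_),
    expected_observed_prevalence =
      config$true_prevalence * p_any +
      (1 - config$true_prevalence) * p_any_fp
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  persons:           ", format(x$n_persons, big.mark = ","), "\n")
  cat("  true prevalence:   ", x$true_prevalence, "\n")
  cat("  capture (marginal):",
      paste(sprintf("%s=%g", names(x$capture_sensitivity), x$capture_sensitivity),
            collapse = " "), "\n")
  cat("  engagement:        ", x$capture_engagement, "\n")
  cat("  predictors:        ", nrow(x$predictor_spec), "\n")
  cat("  overdose baseline: ", x$baseline_overdose_prob,
      " rate ratio: ", x$true_rate_ratio, "\n")
  cat("  seed:              ", x$seed, "\n")
  invisible(x)
}
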