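#' Run the full classification and rate-comparison pipeline
#'
#' Orchestrates every stage on a synthetic linked population: generate the
#' data, identify known cases with the four-criterion definition, restrict
#' the analytic cohort, split it into stratified development/validation
#' partitions, downsample the development majority class, fit the logistic
#' classification model on known-case labels, score the validation
#' partition, evaluate it (confusion metrics and rank-based AUC), classify
#' fatal opioid overdoses from death records, and compare weighted
#' overdose rates across the risk-score schemes.
#'
#' Training labels are the observed known cases, not the latent truth: the
#' workflow assumes homelessness is under-captured and asks what the
#' captured cases' record patterns can say about everyone else.
#'
#' @param config A [sim_config()] describing the synthetic population.
#' @param dev_fraction Development fraction for the stratified split.
#' @param threshold Probability threshold for classification and the
#'   dichotomized risk-score schemes.
#' @param schemes Risk-score schemes to evaluate (default all three).
#' @param convention Weighting convention for group counts.
#' @param split_seed,downsample_seed Seeds for the two randomized stages
#'   (both default to offsets of `config$seed`).
#' @param out_dir Optional directory; when given, all result tables plus a
#'   run manifest are written there as CSV/JSON.
#' @return A list of class `homeless_run`: `population`, `indicators`,
#'   `source_summary`, `cohort`, `split`, `model`, `scores` (validation
#'   tibble with `person_id`, `probability`, `known`, `died_overdose`),
#'   `performance`, `rates`, `manifest`.
#' @export
#' @examples
#' run <- run_pipeline(sim_config(n_persons = 20000, seed = 7))
#' run$performance
run_pipeline <- function(config,
                         dev_fraction = 0.75,
                         threshold = 0.5,
                         schemes = risk_score_schemes,
                         convention = "full_sum",
                         split_seed = config$seed + 1000L,
                         downsample_seed = config$seed + 2000L,
                         out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  population <- stage("generate", generate_population(config))
  indicators <- stage("define_cases", identify_known_homeless(population))
  cohort <- stage("restrict_cohort", restrict_cohort(population))

  cohort_ids <- cohort$person_id[cohort$included]
  known <- indicators$known_homeless[match(cohort_ids, indicators$person_id)]
  if (sum(known) < 2) {
    abort("pipeline stage `split` failed: fewer than two known cases in the cohort.")
  }
  split <- stage("split", stratified_split(cohort_ids, known,
                                           dev_fraction, seed = split_seed))

  dev_ids <- split$person_id[split$partition == "development"]
  dev_known <- known[match(dev_ids, cohort_ids)]
  fit_ids <- stage("downsample",
                   downsample_majority(dev_ids, dev_known, seed = downsample_seed))

  feature_names <- config$predictor_spec$name
  persons <- population$persons
  fit_rows <- match(fit_ids, persons$person_id)
  model <- stage("fit", fit_logistic(
    persons[fit_rows, feature_names, drop = FALSE],
    known[match(fit_ids, cohort_ids)]
  ))

  val_ids <- split$person_id[split$partition == "validation"]
  val_rows <- match(val_ids, persons$person_id)
  scored <- stage("score", predict_probability(
    model, persons[val_rows, c("person_id", feature_names)]
  ))

  deaths <- stage("classify_deaths", classify_opioid_deaths(population$death_records))
  died <- scored$person_id %in% deaths$person_id[deaths$is_opioid_overdose]
  val_known <- known[match(val_ids, cohort_ids)]

  scores <- tibble::tibble(
    person_id = scored$person_id,
    probability = scored$probability,
    known = val_known,
    died_overdose = died
  )

  performance <- stage("evaluate", evaluate_scores(
    scores$probability, scores$known, threshold,
    prevalence = mean(known)
  ))
  rates <- stage("rates", compare_overdose_rates(
    scores$probability, scores$known, scores$died_overdose,
    schemes = schemes, convention = convention, threshold = threshold
  ))
  source_summary <- summarize_known_sources(indicators)

  manifest <- list(
    n_persons = config$n_persons,
    data_seed = config$seed,
    split_seed = split_seed,
    downsample_seed = downsample_seed,
    dev_fraction = dev_fraction,
    threshold = threshold,
    convention = convention,
    schemes = schemes,
    n_cohort = length(cohort_ids),
    n_known_cohort = sum(known),
    n_development = length(dev_ids),
    n_downsampled = length(fit_ids),
    n_validation = length(val_ids),
    package_version = as.character(utils::packageVersion("homeclass")),
    r_version = as.character(getRversion())
  )

  run <- structure(
    list(
      population = population,
      indicators = indicators,
      source_summary = source_summary,
      cohort = cohort,
      split = split,
      model = model,
      scores = scores,
      performance = performance,
      rates = rates,
      manifest = manifest
    ),
    class = "homeless_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Per-source counts of known homelessness indicators
#'
#' Tallies, from an indicator table, how many persons each source flags,
#' the total number of known cases, and how many known cases carry two or
#' more indicators (the multi-source overlap).
#'
#' @param indicators Output of [identify_known_homeless()].
#' @return One-row tibble: `n_apcd`, `n_casemix`, `n_dmh`, `n_matris`,
#'   `n_pmp`, `n_known`, `n_multi_source`, `multi_source_share`.
#' @export
summarize_known_sources <- function(indicators) {
  if (nrow(indicators) == 0) abort("`indicators` must be non-empty.")
  n_known <- sum(indicators$known_homeless)
  n_multi <- sum(indicators$n_sources >= 2)
  tibble::tibble(
    n_apcd = sum(indicators$via_apcd),
    n_casemix = sum(indicators$via_casemix),
    n_dmh = sum(indicators$via_dmh),
    n_matris = sum(indicators$via_matris),
    n_pmp = sum(indicators$via_pmp),
    n_known = n_known,
    n_multi_source = n_multi,
    multi_source_share = ifelse(n_known > 0, n_multi / n_known, NA_real_)
  )
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$indicators, file.path(out_dir, "indicators.csv"))
  readr::write_csv(run$cohort, file.path(out_dir, "cohort.csv"), na = "")
  readr::write_csv(run$split, file.path(out_dir, "split.csv"))
  readr::write_csv(run$scores, file.path(out_dir, "scores.csv"))
  readr::write_csv(run$performance, file.path(out_dir, "performance.csv"))
  readr::write_csv(run$rates, file.path(out_dir, "rates.csv"))
  readr::write_csv(run$source_summary, file.path(out_dir, "source_summary.csv"))
  model <- run$model
  jsonlite::write_json(
    list(
      intercept = unname(model$coefficients[1]),
      coefficients = as.list(model$coefficients[-1]),
      converged = model$converged,
      separation = model$separation,
      n_iter = model$n_iter,
      n = model$n
    ),
    file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.homeless_run <- function(x, ...) {
  m <- x$manifest
  cat("<homeless_run>\n")
  cat("  cohort:", format(m$n_cohort, big.mark = ","),
      "persons,", m$n_known_cohort, "known cases\n")
  cat("  development:", format(m$n_development, big.mark = ","),
      "(downsampled to", paste0(m$n_downsampled, ");"),
      "validation:", format(m$n_validation, big.mark = ","), "\n")
  p <- x$performance
  cat(sprintf("  validation AUC %.3f | sens %.1f%% | spec %.1f%% | balanced acc %.1f%%\n",
              p$auc, 100 * p$sensitivity, 100 * p$specificity,
              100 * p$balanced_accuracy))
  rr <- x$rates
  for (i in seq_len(nrow(rr))) {
    cat(sprintf("  %-18s RR %.1f (%.1f-%.1f)\n", rr$scheme[i],
                rr$rate_ratio[i], rr$ci_low[i], rr$ci_high[i]))
  }
  invisible(x)
}
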