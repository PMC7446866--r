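#' Apply the analytic-cohort restriction
#'
#' A person enters the analytic cohort when they have at least one claim in
#' the all-payer claims database (the cohort universe), at least one record
#' in any other linked source, and are at least `min_age` years old. The
#' restriction guards against non-resident and unresolved-duplicate records
#' that appear in the claims universe only.
#'
#' @param population A `linked_population`.
#' @param min_age Minimum age in years (default 11).
#' @return Tibble with one row per person: `person_id`, `in_apcd`,
#'   `n_other_sources` (0-4: Case Mix, mental health, ambulance,
#'   prescriptions), `age`, `included`, and `exclusion_reason` (`NA` when
#'   included).
#' @export
restrict_cohort <- function(population, min_age = 11) {
  persons <- population$persons
  ids <- persons$person_id
  claims <- population$claims
  in_apcd <- ids %in% claims$person_id[claims$source == "APCD"]
  other <- (ids %in% claims$person_id[claims$source == "CaseMix"]) +
    (ids %in% population$dmh_records$person_id) +
    (ids %in% population$ambulance_records$person_id) +
    (ids %in% population$prescription_records$person_id)
  included <- in_apcd & other >= 1 & persons$age >= min_age
  reason <- dplyr::case_when(
    !in_apcd ~ "no_apcd_record",
    other < 1 ~ "no_other_source",
    persons$age < min_age ~ "under_min_age",
    .default = NA_character_
  )
  tibble::tibble(
    person_id = ids,
    in_apcd = in_apcd,
    n_other_sources = as.integer(other),
    age = persons$age,
    included = included,
    exclusion_reason = reason
  )
}

#' Reconcile per-source demographics into a master row per person
#'
#' Many linked sources carry the same demographic fields with occasional
#' conflicts. This picks, for each person, the complete row from the
#' highest-precedence source present, yielding a deterministic "master
#' demographics" table.
#'
#' @param demographics Tibble with columns `person_id`, `source`, and any
#'   demographic fields (e.g. `age`, `sex`).
#' @param precedence Character vector of sources from most to least
#'   trusted; sources absent from it rank after all listed ones, in
#'   alphabetical order.
#' @return Tibble with one row per person (columns as in the input, minus
#'   duplicates), ordered by `person_id`.
#' @export
#' @examples
#' demo <- tibble::tribble(
#'   ~person_id, ~source, ~age,
#'   1L, "claims", 40L,
#'   1L, "mental_health", 38L
#' )
#' reconcile_demographics(demo)
reconcile_demographics <- function(demographics,
                                   precedence = c("claims", "mental_health",
                                                  "vital_records")) {
  demo <- tibble::as_tibble(demographics)
  if (!all(c("person_id", "source") %in% names(demo))) {
    abort("`demographics` needs `person_id` and `source` columns.")
  }
  if (nrow(demo) == 0) abort("`demographics` has zero rows.")
  extra <- sort(setdiff(unique(demo$source), precedence))
  rank <- match(demo$source, c(precedence, extra))
  demo |>
    dplyr::mutate(.rank = rank) |>
    dplyr::arrange(.data$person_id, .data$.rank) |>
    dplyr::distinct(.data$person_id, .keep_all = TRUE) |>
    dplyr::select(-".rank")
}
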