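#' Normalize ICD diagnosis codes
#'
#' Upper-cases a code and strips periods and surrounding whitespace, so
#' "z59.0" and " Z590 " both canonicalize to "Z590". Codes are compared
#' only in this canonical form throughout the package.
#'
#' @param code Character vector of raw codes.
#' @return Character vector of canonical codes.
#' @export
#' @examples
#' normalize_icd(c("V.60", "z59.0", " t40.1 "))
normalize_icd <- function(code) {
  if (length(code) == 0) return(character(0))
  if (any(is.na(code)) || any(trimws(code) == "")) {
    abort("malformed record: empty ICD code.")
  }
  gsub("[. ]", "", toupper(trimws(code)))
}

# per-code homelessness flag (canonical form assumed)
icd_code_is_homeless <- function(canonical, v60_family = TRUE) {
  if (v60_family) {
    startsWith(canonical, "V60") | canonical == "Z590"
  } else {
    canonical == "V60" | canonical == "Z590"
  }
}

#' Does a claim's code list indicate homelessness?
#'
#' `TRUE` if any code, after [normalize_icd()] normalization, is ICD-10
#' Z59.0 or falls in the ICD-9 V60 family ("housing, household and economic
#' circumstances", which contains homelessness). The V60 match is a prefix
#' match on the category by default because administrative sources code at
#' varying depth; set `v60_family = FALSE` to require the bare category
#' code.
#'
#' @param codes Character vector of ICD codes attached to one person or
#'   claim (may be empty).
#' @param v60_family Match any V60.x sub-code (default) or only "V60".
#' @return Single logical.
#' @export
#' @examples
#' has_homeless_icd(c("I21.9", "Z59.0"))
#' has_homeless_icd(character(0))
has_homeless_icd <- function(codes, v60_family = TRUE) {
  if (length(codes) == 0) return(FALSE)
  any(icd_code_is_homeless(normalize_icd(codes), v60_family = v60_family))
}

#' Does an ambulance narrative indicate homelessness?
#'
#' Case-insensitive substring search for "homeless" or "shelter" in
#' free-text run narratives. By default any occurrence counts (so
#' "sheltered" matches); `word_boundary = TRUE` restricts to whole-word
#' matches.
#'
#' @param narrative Character vector of narratives (empty strings allowed).
#' @param word_boundary Require whole-word matches.
#' @return Logical vector, one element per narrative.
#' @export
#' @examples
#' narrative_indicates_homeless("Pt is homeless, lives under bridge")
#' narrative_indicates_homeless("resides at home with spouse")
narrative_indicates_homeless <- function(narrative, word_boundary = FALSE) {
  if (length(narrative) == 0) return(logical(0))
  narrative[is.na(narrative)] <- ""
  pattern <- if (word_boundary) "\\b(homeless|shelter)\\b" else "homeless|shelter"
  stringr::str_detect(narrative, stringr::regex(pattern, ignore_case = TRUE))
}

#' Does a prescription address match an emergency shelter?
#'
#' Exact comparison after [normalize_address()] normalization of both
#' sides; no fuzzy matching or geocoding. Empty addresses never match.
#'
#' @param address Character vector of patient addresses.
#' @param shelters Non-empty character vector of shelter addresses.
#' @return Logical vector, one element per address.
#' @export
#' @examples
#' address_matches_shelter("123 Main St.", c("123  MAIN ST"))
address_matches_shelter <- function(address, shelters) {
  if (length(shelters) == 0) abort("`shelters` must be non-empty.")
  if (length(address) == 0) return(logical(0))
  address[is.na(address)] <- ""
  norm <- normalize_address(address)
  norm != "" & norm %in% normalize_address(shelters)
}

#' Was a housing loss ever recorded in the monthly mental-health history?
#'
#' `TRUE` if any month in a client's housing-status history is
#' `"housing_loss"`; an empty history (non-client) is `FALSE`.
#'
#' @param monthly_statuses Character vector of monthly statuses.
#' @return Single logical.
#' @export
#' @examples
#' dmh_housing_loss(c("housed", "housing_loss", "housed"))
dmh_housing_loss <- function(monthly_statuses) {
  any(monthly_statuses == "housing_loss", na.rm = TRUE)
}

check_person_ids <- function(population, ids, table) {
  bad <- setdiff(unique(ids), population$persons$person_id)
  if (length(bad) > 0) {
    abort(sprintf("`%s` references %d person_id value(s) missing from `persons` (e.g. %s).",
                  table, length(bad), bad[1]))
  }
}

#' Identify known cases of homelessness
#'
#' Applies the four-criterion composite case definition to a linked
#' population: (1) a homelessness diagnosis code (ICD-9 V60 family or
#' ICD-10 Z59.0) on an APCD or Case Mix claim, each source flagged
#' separately; (2) any monthly `housing_loss` record in the mental-health
#' table; (3) an ambulance narrative containing "homeless" or "shelter";
#' (4) a prescription address matching an emergency shelter. A person
#' meeting any criterion at any point in the observation window is a known
#' case.
#'
#' @param population A `linked_population` (or any list with the same
#'   record tables).
#' @param v60_family,word_boundary Matching policy knobs passed to
#'   [has_homeless_icd()] and [narrative_indicates_homeless()].
#' @return Tibble with one row per person: `person_id`, the five source
#'   flags `via_apcd`, `via_casemix`, `via_dmh`, `via_matris`, `via_pmp`,
#'   their union `known_homeless`, and `n_sources` (0-5).
#' @export
identify_known_homeless <- function(population, v60_family = TRUE,
                                    word_boundary = FALSE) {
  persons <- population$persons
  check_person_ids(population, population$claims$person_id, "claims")
  check_person_ids(population, population$dmh_records$person_id, "dmh_records")
  check_person_ids(population, population$ambulance_records$person_id, "ambulance_records")
  check_person_ids(population, population$prescription_records$person_id, "prescription_records")

  flag_ids <- function(ids) persons$person_id %in% unique(ids)

  claims <- population$claims
  hit <- icd_code_is_homeless(normalize_icd_lenient(claims$icd_code),
                              v60_family = v60_family)
  via_apcd <- flag_ids(claims$person_id[hit & claims$source == "APCD"])
  via_casemix <- flag_ids(claims$person_id[hit & claims$source == "CaseMix"])

  dmh <- population$dmh_records
  via_dmh <- flag_ids(dmh$person_id[dmh$housing_status == "housing_loss"])

  amb <- population$ambulance_records
  via_matris <- flag_ids(amb$person_id[
    narrative_indicates_homeless(amb$narrative, word_boundary = word_boundary)
  ])

  rx <- population$prescription_records
  via_pmp <- if (nrow(rx) == 0) {
    rep(FALSE, nrow(persons))
  } else {
    flag_ids(rx$person_id[
      address_matches_shelter(rx$patient_address, population$shelter_addresses)
    ])
  }

  n_sources <- via_apcd + via_casemix + via_dmh + via_matris + via_pmp
  tibble::tibble(
    person_id = persons$person_id,
    via_apcd = via_apcd,
    via_casemix = via_casemix,
    via_dmh = via_dmh,
    via_matris = via_matris,
    via_pmp = via_pmp,
    known_homeless = n_sources >= 1,
    n_sources = as.integer(n_sources)
  )
}

# bulk normalization for record tables: blank codes stay blank (they can
# never match) instead of erroring, so background tables with empty
# diagnosis fields are tolerated
normalize_icd_lenient <- function(code) {
  code[is.na(code)] <- ""
  gsub("[. ]", "", toupper(trimws(code)))
}
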