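# opioid multiple-cause codes (canonical): heroin, other opioids, methadone,
# other synthetic narcotics, cocaine excluded (T40.5), other/unspecified
# narcotics included
opioid_t_codes <- c("T400", "T401", "T402", "T403", "T404", "T406")

#' Default cause-of-death literal keywords for opioid deaths
#'
#' Used by the literal-text fallback of [classify_opioid_deaths()] for
#' records that have no ICD code assigned yet. Case-insensitive substring
#' match.
#'
#' @return Character vector of keywords.
#' @export
opioid_literal_keywords <- function() {
  c("heroin", "fentanyl", "opioid", "opiate", "morphine", "oxycodone",
    "methadone")
}

#' Is an underlying cause of death a poisoning/overdose?
#'
#' `TRUE` for ICD-10 underlying-cause codes in the accidental, intentional
#' self-harm, assault, and undetermined-intent poisoning ranges X40-X49,
#' X60-X69, X85-X90, Y10-Y19 (category match, any fourth character), or
#' the legal-intervention code Y35.2.
#'
#' @param code Character vector of ICD-10 codes (normalized internally).
#' @return Logical vector.
#' @export
#' @examples
#' is_poisoning_underlying(c("X42", "Y352", "X50", "I219"))
is_poisoning_underlying <- function(code) {
  if (length(code) == 0) return(logical(0))
  canonical <- normalize_icd_lenient(code)
  cat3 <- substr(canonical, 1, 3)
  letter <- substr(cat3, 1, 1)
  num <- suppressWarnings(as.integer(substr(cat3, 2, 3)))
  in_range <- !is.na(num) & (
    (letter == "X" & ((num >= 40 & num <= 49) | (num >= 60 & num <= 69) |
                        (num >= 85 & num <= 90))) |
      (letter == "Y" & num >= 10 & num <= 19)
  )
  in_range | canonical == "Y352"
}

split_codes <- function(x) {
  x[is.na(x)] <- ""
  strsplit(x, "[;|,]\\s*")
}

#' Classify fatal opioid overdoses from death records
#'
#' A death is an opioid-related overdose when the underlying cause is a
#' poisoning ([is_poisoning_underlying()]) and any multiple-cause field
#' carries an opioid code T40.0-T40.4 or T40.6 (T40.5, cocaine, never
#' qualifies). Records with no ICD code assigned fall back to a
#' case-insensitive keyword search of the written cause-of-death literal.
#'
#' @param death_records Tibble with columns `person_id`,
#'   `underlying_cause` (may be `NA`), `multiple_causes`
#'   (";"-separated, may be empty), `literal_text`.
#' @param keywords Literal-search keywords; see
#'   [opioid_literal_keywords()].
#' @return Tibble with one row per record: `person_id`, `is_poisoning`,
#'   `is_opioid_overdose`, `matched_underlying` (canonical code or `NA`),
#'   `matched_multiple` (";"-joined canonical codes, empty if none),
#'   `via_literal`.
#' @export
classify_opioid_deaths <- function(death_records,
                                   keywords = opioid_literal_keywords()) {
  rec <- tibble::as_tibble(death_records)
  needed <- c("person_id", "underlying_cause", "multiple_causes", "literal_text")
  if (!all(needed %in% names(rec))) {
    abort(paste0("`death_records` needs columns ",
                 paste(needed, collapse = ", "), "."))
  }
  if (nrow(rec) == 0) {
    return(tibble::tibble(
      person_id = rec$person_id, is_poisoning = logical(0),
      is_opioid_overdose = logical(0), matched_underlying = character(0),
      matched_multiple = character(0), via_literal = logical(0)
    ))
  }
  underlying <- normalize_icd_lenient(rec$underlying_cause)
  multiples <- lapply(split_codes(rec$multiple_causes), function(x) {
    x <- normalize_icd_lenient(x)
    x[x != ""]
  })
  literal <- rec$literal_text
  literal[is.na(literal)] <- ""

  has_any_code <- underlying != "" | lengths(multiples) > 0
  if (any(!has_any_code & trimws(literal) == "")) {
    abort("death record with neither ICD codes nor cause-of-death literal text.")
  }

  poisoning <- is_poisoning_underlying(underlying) & underlying != ""
  opioid_hits <- lapply(multiples, function(x) x[x %in% opioid_t_codes])
  code_positive <- poisoning & lengths(opioid_hits) > 0

  pattern <- stringr::regex(paste(keywords, collapse = "|"), ignore_case = TRUE)
  literal_positive <- !has_any_code & stringr::str_detect(literal, pattern)

  tibble::tibble(
    person_id = rec$person_id,
    is_poisoning = poisoning,
    is_opioid_overdose = code_positive | literal_positive,
    matched_underlying = ifelse(poisoning, underlying, NA_character_),
    matched_multiple = vapply(opioid_hits, paste, character(1), collapse = ";"),
    via_literal = literal_positive
  )
}

#' Count classified opioid-overdose deaths within a person set
#'
#' @param classifications Output of [classify_opioid_deaths()].
#' @param person_ids Vector of person ids defining the set (e.g. a cohort
#'   or validation partition).
#' @return Integer count of persons in the set classified as opioid
#'   overdoses.
#' @export
count_overdose_deaths <- function(classifications, person_ids) {
  sum(classifications$is_opioid_overdose &
        classifications$person_id %in% person_ids)
}
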