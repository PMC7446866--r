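# Phrase/code pools for the generator. Background pools deliberately contain
# no homelessness codes (V60*/Z590), no poisoning underlying-cause codes and
# no opioid T40 codes, so planted signals are the only positives.

background_icd_pool <- c(
  "I10", "E119", "J449", "F329", "M545", "K219", "E785", "J069",
  "N390", "R519", "I2510", "F419", "L709", "H522", "M1711"
)

opioid_multiple_pool <- c("T40.0", "T40.1", "T40.2", "T40.3", "T40.4", "T40.6")
extra_multiple_pool <- c("R99", "J960", "I469", "T509", "T425", "R090")
nonoverdose_underlying_pool <- c(
  "I219", "C349", "I64", "J449", "E149", "N179", "C509", "K746"
)
overdose_literal_pool <- c(
  "ACUTE FENTANYL AND HEROIN INTOXICATION",
  "acute opiate intoxication",
  "Heroin toxicity",
  "mixed drug overdose - oxycodone, benzodiazepines",
  "METHADONE INTOXICATION"
)
nonoverdose_literal_pool <- c(
  "atherosclerotic cardiovascular disease",
  "METASTATIC LUNG CANCER",
  "complications of cirrhosis"
)

residential_streets <- c(
  "MAPLE ST", "OAK AVE", "ELM ST", "BIRCH RD", "HIGHLAND AVE",
  "PLEASANT ST", "SCHOOL ST", "WASHINGTON ST", "PARK DR", "RIVER RD"
)
shelter_streets <- c(
  "HARBOR WAY", "BEACON PL", "CANAL BLVD", "FRIEND TER", "MISSION CT",
  "ANCHOR LN", "HAVEN SQ", "ALBANY PKWY", "BRIDGE ALY", "COMMON WHF",
  "LIBERTY RUN", "SUMMIT PATH"
)
ma_cities <- c(
  "BOSTON MA", "WORCESTER MA", "SPRINGFIELD MA", "LOWELL MA",
  "CAMBRIDGE MA", "BROCKTON MA", "NEW BEDFORD MA", "QUINCY MA"
)

narrative_openers <- c(
  "pt found unresponsive near bus stop", "called for 54yo male with chest pain",
  "pt ambulatory on scene, oriented x3", "fall from standing, laceration to scalp",
  "pt c/o abd pain x2 days", "possible overdose, narcan administered",
  "pt intoxicated, slurred speech", "diabetic emergency, BGL 42",
  "seizure witnessed by bystander", "pt refused transport initially"
)
narrative_closers <- c(
  "transported to ED without incident", "vitals stable en route",
  "pt placed on monitor, IV established", "report given to RN at triage",
  "no acute distress noted on exam", "pt handed over to receiving staff"
)
keyword_phrases <- c(
  "pt is %KW%, sleeping outdoors",
  "picked up outside the %KW%",
  "%KW% male, belongings in cart",
  "staff at the %KW% called 911",
  "pt states he is %KW% at this time"
)
keyword_tokens <- c(
  "homeless", "HOMELESS", "Homeless", "shelter", "SHELTER", "Shelter"
)

#' Generate distinct emergency-shelter addresses
#'
#' Draws `n_shelters` pairwise-distinct normalized address strings from a
#' street/city grid reserved for shelters (disjoint from the residential
#' street pool used elsewhere in the generator, so an address collision can
#' only be a planted one). Deterministic for a given seed.
#'
#' @param n_shelters Number of addresses (at least 1).
#' @param seed Integer seed.
#' @return Character vector of `n_shelters` distinct addresses.
#' @export
#' @examples
#' generate_shelter_addresses(3, seed = 7)
generate_shelter_addresses <- function(n_shelters, seed) {
  n_shelters <- check_scalar_count(n_shelters, "n_shelters", min = 1)
  seed <- check_scalar_count(seed, "seed", min = -.Machine$integer.max)
  grid <- expand.grid(
    number = seq(1, 999, by = 2), street = shelter_streets, city = ma_cities,
    stringsAsFactors = FALSE
  )
  if (n_shelters > nrow(grid)) {
    abort("`n_shelters` exceeds the available shelter address grid.")
  }
  withr_seed(seed, {
    rows <- sample.int(nrow(grid), n_shelters)
    sprintf("%d %s %s", grid$number[rows], grid$street[rows], grid$city[rows])
  })
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate ambulance narrative free text
#'
#' Produces EMS-style run narratives. Where `plant_keyword` is `TRUE` the
#' narrative contains the word "homeless" or "shelter" (case varied); where
#' `FALSE` it contains neither token as a substring, so a case-insensitive
#' keyword matcher gives exactly the planted answer.
#'
#' @param plant_keyword Logical vector; one narrative is produced per
#'   element.
#' @return Character vector of narratives, same length as `plant_keyword`.
#' @export
#' @examples
#' set.seed(1)
#' generate_narratives(c(TRUE, FALSE))
generate_narratives <- function(plant_keyword) {
  stopifnot(is.logical(plant_keyword), !anyNA(plant_keyword))
  n <- length(plant_keyword)
  if (n == 0) return(character(0))
  out <- paste(
    sample(narrative_openers, n, replace = TRUE),
    sample(narrative_closers, n, replace = TRUE),
    sep = "; "
  )
  k <- sum(plant_keyword)
  if (k > 0) {
    phrase <- sample(keyword_phrases, k, replace = TRUE)
    token <- sample(keyword_tokens, k, replace = TRUE)
    insert <- vapply(seq_len(k), function(i) {
      sub("%KW%", token[i], phrase[i], fixed = TRUE)
    }, character(1))
    out[plant_keyword] <- paste(insert, out[plant_keyword], sep = "; ")
  }
  out
}

# Person-level latent draws shared by generate_population() and the
# scaled-down simulation studies: latent status, demographics, binary
# predictors and death outcomes. Record tables are layered on top by
# generate_population(). Call inside an already-seeded RNG stream, or pass
# `seed` to run self-contained.

#' Simulate person-level ground truth
#'
#' Draws the latent person table of the synthetic population: uniform ages,
#' sex, Bernoulli latent homelessness at `true_prevalence`, the binary
#' predictor matrix (baseline prevalence shifted by `log_odds` on the logit
#' scale for truly homeless persons), and death outcomes. Fatal opioid
#' overdose occurs with probability `baseline_overdose_prob`, multiplied by
#' `true_rate_ratio` (capped at 1) for the truly homeless; non-overdose
#' deaths occur independently at `background_death_prob` among survivors of
#' the overdose draw.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return Tibble with `person_id`, `age`, `sex`, `true_homeless`,
#'   `died_opioid_overdose`, `died_other`, and one 0/1 column per
#'   predictor.
#' @export
simulate_persons <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) {
    return(withr_seed(seed, simulate_persons(config, seed = NULL)))
  }
  n <- config$n_persons
  spec <- config$predictor_spec
  true_homeless <- runif(n) < config$true_prevalence

  persons <- tibble::tibble(
    person_id = seq_len(n),
    age = sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE),
    true_homeless = true_homeless
  )

  p1 <- plogis(qlogis(pmin(pmax(spec$baseline_prob, 1e-12), 1 - 1e-12)) +
                 spec$log_odds)
  for (j in seq_len(nrow(spec))) {
    pj <- ifelse(true_homeless, p1[j], spec$baseline_prob[j])
    persons[[spec$name[j]]] <- as.integer(runif(n) < pj)
  }

  p_od <- pmin(config$baseline_overdose_prob *
                 ifelse(true_homeless, config$true_rate_ratio, 1), 1)
  persons$died_opioid_overdose <- runif(n) < p_od
  persons$died_other <- !persons$died_opioid_overdose &
    runif(n) < config$background_death_prob
  persons
}

#' Generate a synthetic linked administrative population
#'
#' Builds a full linked-record warehouse with known ground truth: a person
#' table (latent homelessness, predictors, deaths) plus per-source record
#' tables. Truly homeless persons are captured by each source according to
#' the engagement-capture model of [sim_config()]; a captured source carries
#' the corresponding planted signal (a homelessness diagnosis code on an
#' APCD or Case Mix claim, a monthly `housing_loss` record in the
#' mental-health table, an ambulance narrative containing a keyword, or a
#' prescription bearing an emergency-shelter address). Non-homeless persons
#' receive background records with no planted signals (unless
#' `false_capture_rate > 0`). Fatal opioid overdoses receive a death record
#' with a poisoning underlying cause and at least one opioid T40 multiple
#' cause, except for a small fraction carrying only a cause-of-death
#' literal; background deaths receive non-qualifying records.
#'
#' The same `(config, seed)` always reproduces the identical population.
#'
#' @param config A [sim_config()].
#' @return A list of class `linked_population` with elements `persons`,
#'   `claims` (`person_id`, `source`, `icd_code`; one row per diagnosis
#'   code), `dmh_records`, `ambulance_records`, `prescription_records`,
#'   `death_records`, `shelter_addresses`, and the `config` echo.
#' @export
#' @examples
#' pop <- generate_population(sim_config(n_persons = 500, seed = 3))
#' nrow(pop$persons)
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, generate_population_impl(config))
}

generate_population_impl <- function(config) {
  n <- config$n_persons
  persons <- simulate_persons(config, seed = NULL)
  true_homeless <- persons$true_homeless

  # engagement-capture draws (marginal sensitivity preserved exactly)
  engaged <- true_homeless & runif(n) < config$capture_engagement
  cond <- config$capture_sensitivity / config$capture_engagement
  captured <- sapply(capture_sources, function(s) engaged & runif(n) < cond[[s]])
  captured <- matrix(captured, nrow = n,
                     dimnames = list(NULL, capture_sources))
  if (config$false_capture_rate > 0) {
    for (s in capture_sources) {
      captured[, s] <- captured[, s] |
        (!true_homeless & runif(n) < config$false_capture_rate)
    }
  }

  m <- config$source_membership
  member_apcd <- captured[, "apcd_icd"] | runif(n) < m[["apcd"]]
  member_casemix <- captured[, "casemix_icd"] | runif(n) < m[["casemix"]]
  member_dmh <- captured[, "dmh"] | runif(n) < m[["dmh"]]
  member_matris <- captured[, "matris"] | runif(n) < m[["matris"]]
  member_pmp <- captured[, "pmp"] | runif(n) < m[["pmp"]]

  shelters <- generate_shelter_addresses(config$n_shelters,
                                         seed = config$seed + 1L)

  claims <- dplyr::bind_rows(
    make_claims(which(member_apcd), which(captured[, "apcd_icd"]), "APCD"),
    make_claims(which(member_casemix), which(captured[, "casemix_icd"]), "CaseMix")
  )
  dmh_records <- make_dmh(which(member_dmh), which(captured[, "dmh"]))
  ambulance_records <- make_ambulance(which(member_matris),
                                      which(captured[, "matris"]))
  prescription_records <- make_prescriptions(which(member_pmp),
                                             which(captured[, "pmp"]),
                                             shelters)
  death_records <- make_deaths(persons, config)

  structure(
    list(
      persons = persons,
      claims = claims,
      dmh_records = dmh_records,
      ambulance_records = ambulance_records,
      prescription_records = prescription_records,
      death_records = death_records,
      shelter_addresses = shelters,
      config = config
    ),
    class = "linked_population"
  )
}

# messy renderings of the homelessness codes, to exercise normalization
homeless_code_pool <- c("Z59.0", "z590", " Z59.0 ", "V60.0", "V60.1", "v60.9", "V600")

make_claims <- function(member_ids, captured_ids, source) {
  if (length(member_ids) == 0) {
    return(tibble::tibble(person_id = integer(0), source = character(0),
                          icd_code = character(0)))
  }
  n_codes <- sample(1:3, length(member_ids), replace = TRUE)
  base <- tibble::tibble(
    person_id = rep(member_ids, n_codes),
    source = source,
    icd_code = sample(background_icd_pool, sum(n_codes), replace = TRUE)
  )
  planted <- tibble::tibble(
    person_id = captured_ids,
    source = source,
    icd_code = sample(homeless_code_pool, length(captured_ids), replace = TRUE)
  )
  dplyr::arrange(dplyr::bind_rows(base, planted), .data$person_id)
}

make_dmh <- function(member_ids, captured_ids) {
  if (length(member_ids) == 0) {
    return(tibble::tibble(person_id = integer(0), month = integer(0),
                          housing_status = character(0)))
  }
  n_months <- sample(3:24, length(member_ids), replace = TRUE)
  months <- lapply(n_months, function(k) sort(sample.int(60, k)))
  rec <- tibble::tibble(
    person_id = rep(member_ids, n_months),
    month = unlist(months),
    housing_status = "housed"
  )
  if (length(captured_ids) > 0) {
    # flip one observed month per captured person to housing_loss
    pick <- vapply(captured_ids, function(id) {
      idx <- which(rec$person_id == id)
      idx[sample.int(length(idx), 1)]
    }, integer(1))
    rec$housing_status[pick] <- "housing_loss"
  }
  rec
}

make_ambulance <- function(member_ids, captured_ids) {
  if (length(member_ids) == 0) {
    return(tibble::tibble(person_id = integer(0), narrative = character(0)))
  }
  n_trips <- sample(1:2, length(member_ids), replace = TRUE)
  ids <- rep(member_ids, n_trips)
  first_trip <- !duplicated(ids)
  plant <- first_trip & ids %in% captured_ids
  tibble::tibble(person_id = ids, narrative = generate_narratives(plant))
}

random_residential_addresses <- function(k) {
  sprintf("%d %s %s",
          sample(seq(2, 998, by = 2), k, replace = TRUE),
          sample(residential_streets, k, replace = TRUE),
          sample(ma_cities, k, replace = TRUE))
}

# re-render an address with harmless formatting noise
jitter_address <- function(x) {
  style <- sample(3, length(x), replace = TRUE)
  x[style == 1] <- tolower(x[style == 1])
  x[style == 2] <- sub(" (?=[A-Za-z]+ MA$)", ",  ", x[style == 2], perl = TRUE)
  x
}

make_prescriptions <- function(member_ids, captured_ids, shelters) {
  if (length(member_ids) == 0) {
    return(tibble::tibble(person_id = integer(0), patient_address = character(0)))
  }
  n_rx <- sample(1:3, length(member_ids), replace = TRUE)
  ids <- rep(member_ids, n_rx)
  addr <- random_residential_addresses(length(ids))
  first_rx <- !duplicated(ids)
  plant <- first_rx & ids %in% captured_ids
  addr[plant] <- jitter_address(sample(shelters, sum(plant), replace = TRUE))
  tibble::tibble(person_id = ids, patient_address = addr)
}

poisoning_underlying_codes <- function() {
  cats <- c(sprintf("X%d", 40:49), sprintf("X%d", 60:69),
            sprintf("X%d", 85:90), sprintf("Y%d", 10:19))
  c(cats, "Y352")
}

make_deaths <- function(persons, config) {
  od_ids <- persons$person_id[persons$died_opioid_overdose]
  other_ids <- persons$person_id[persons$died_other]
  empty <- tibble::tibble(person_id = integer(0), underlying_cause = character(0),
                          multiple_causes = character(0), literal_text = character(0))
  od <- empty
  if (length(od_ids) > 0) {
    pool <- poisoning_underlying_codes()
    underlying <- sample(pool, length(od_ids), replace = TRUE)
    add4 <- runif(length(od_ids)) < 0.5 & underlying != "Y352"
    underlying[add4] <- paste0(underlying[add4],
                               sample(0:9, sum(add4), replace = TRUE))
    opioid <- sample(opioid_multiple_pool, length(od_ids), replace = TRUE)
    n_extra <- sample(0:2, length(od_ids), replace = TRUE)
    extras <- vapply(n_extra, function(k) {
      paste(sample(extra_multiple_pool, k), collapse = ";")
    }, character(1))
    multiple <- ifelse(extras == "", opioid, paste(opioid, extras, sep = ";"))
    od <- tibble::tibble(
      person_id = od_ids, underlying_cause = underlying,
      multiple_causes = multiple, literal_text = ""
    )
    literal_only <- runif(length(od_ids)) < config$literal_only_fraction
    od$underlying_cause[literal_only] <- NA_character_
    od$multiple_causes[literal_only] <- ""
    od$literal_text[literal_only] <-
      sample(overdose_literal_pool, sum(literal_only), replace = TRUE)
  }
  other <- empty
  if (length(other_ids) > 0) {
    underlying <- sample(nonoverdose_underlying_pool, length(other_ids),
                         replace = TRUE)
    n_extra <- sample(0:2, length(other_ids), replace = TRUE)
    multiple <- vapply(n_extra, function(k) {
      paste(sample(extra_multiple_pool, k), collapse = ";")
    }, character(1))
    other <- tibble::tibble(
      person_id = other_ids, underlying_cause = underlying,
      multiple_causes = multiple, literal_text = ""
    )
    literal_only <- runif(length(other_ids)) < config$literal_only_fraction
    other$underlying_cause[literal_only] <- NA_character_
    other$multiple_causes[literal_only] <- ""
    other$literal_text[literal_only] <-
      sample(nonoverdose_literal_pool, sum(literal_only), replace = TRUE)
  }
  dplyr::arrange(dplyr::bind_rows(od, other), .data$person_id)
}

#' @export
print.linked_population <- function(x, ...) {
  cat("<linked_population>\n")
  cat("  persons:       ", format(nrow(x$persons), big.mark = ","),
      " (true homeless: ", sum(x$persons$true_homeless), ")\n", sep = "")
  cat("  claims rows:   ", nrow(x$claims), "\n")
  cat("  dmh rows:      ", nrow(x$dmh_records), "\n")
  cat("  ambulance rows:", nrow(x$ambulance_records), "\n")
  cat("  rx rows:       ", nrow(x$prescription_records), "\n")
  cat("  death records: ", nrow(x$death_records), "\n")
  invisible(x)
}
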