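# hand-built linked populations for unit tests

empty_claims <- function() {
  tibble::tibble(person_id = integer(0), source = character(0),
                 icd_code = character(0))
}
empty_dmh <- function() {
  tibble::tibble(person_id = integer(0), month = integer(0),
                 housing_status = character(0))
}
empty_ambulance <- function() {
  tibble::tibble(person_id = integer(0), narrative = character(0))
}
empty_rx <- function() {
  tibble::tibble(person_id = integer(0), patient_address = character(0))
}
empty_deaths <- function() {
  tibble::tibble(person_id = integer(0), underlying_cause = character(0),
                 multiple_causes = character(0), literal_text = character(0))
}

make_population <- function(persons,
                            claims = empty_claims(),
                            dmh_records = empty_dmh(),
                            ambulance_records = empty_ambulance(),
                            prescription_records = empty_rx(),
                            death_records = empty_deaths(),
                            shelter_addresses = "1 HAVEN SQ BOSTON MA") {
  structure(
    list(
      persons = persons, claims = claims, dmh_records = dmh_records,
      ambulance_records = ambulance_records,
      prescription_records = prescription_records,
      death_records = death_records,
      shelter_addresses = shelter_addresses,
      config = NULL
    ),
    class = "linked_population"
  )
}

toy_persons <- function(n, age = 30) {
  tibble::tibble(person_id = seq_len(n), age = age,
                 sex = rep_len(c("F", "M"), n),
                 true_homeless = FALSE,
                 died_opioid_overdose = FALSE, died_other = FALSE)
}

# brute-force AUC oracle: exhaustive pairwise comparison, ties count 1/2
pairwise_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
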