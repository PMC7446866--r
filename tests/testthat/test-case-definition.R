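test_that("ICD normalization canonicalizes case, periods and whitespace", {
  expect_identical(normalize_icd("V.60"), "V60")
  expect_identical(normalize_icd("z59.0"), "Z590")
  expect_identical(normalize_icd(" t40.1 "), "T401")
  expect_identical(normalize_icd(c("i21.9", "Y35.2")), c("I219", "Y352"))
  expect_error(normalize_icd(""), "malformed")
  expect_error(normalize_icd(c("I10", NA)), "malformed")
})

test_that("homelessness codes match Z59.0 exactly and the V60 family by prefix", {
  expect_true(has_homeless_icd("Z590"))
  expect_true(has_homeless_icd(c("V600", "I219")))
  expect_true(has_homeless_icd("v60.9"))
  expect_false(has_homeless_icd("I219"))
  expect_false(has_homeless_icd(character(0)))
  # Z59.1 (inadequate housing) and Z59 category do not qualify
  expect_false(has_homeless_icd(c("Z591", "Z59")))
  # strict mode requires the bare V60 category
  expect_false(has_homeless_icd("V601", v60_family = FALSE))
  expect_true(has_homeless_icd("V.60", v60_family = FALSE))
})

test_that("narrative keyword matching is case-insensitive substring search", {
  expect_true(narrative_indicates_homeless("Pt is homeless, lives under bridge"))
  expect_true(narrative_indicates_homeless("picked up at Pine Street SHELTER"))
  expect_false(narrative_indicates_homeless("resides at home with spouse"))
  expect_false(narrative_indicates_homeless(""))
  # substring semantics: derived words match unless word_boundary is set
  expect_true(narrative_indicates_homeless("pt was sheltered from rain"))
  expect_false(narrative_indicates_homeless("pt was sheltered from rain",
                                            word_boundary = TRUE))
  expect_identical(
    narrative_indicates_homeless(c("HOMELESS male", "no complaints")),
    c(TRUE, FALSE)
  )
})

test_that("address matching is exact after normalization", {
  expect_true(address_matches_shelter("123 Main St.", "123  MAIN ST"))
  expect_false(address_matches_shelter("124 Main St", "123 MAIN ST"))
  expect_false(address_matches_shelter("", c("123 MAIN ST")))
  expect_identical(
    address_matches_shelter(c("1 Haven Sq, Boston MA", "2 Elm St"),
                            "1 HAVEN SQ BOSTON MA"),
    c(TRUE, FALSE)
  )
  expect_error(address_matches_shelter("1 Elm St", character(0)), "non-empty")
})

test_that("any monthly housing-loss record flags a mental-health client", {
  expect_true(dmh_housing_loss(c("housed", "housing_loss", "housed")))
  expect_false(dmh_housing_loss(c("housed", "housed")))
  expect_false(dmh_housing_loss(character(0)))
})

test_that("the composite definition unions the four criteria per source", {
  persons <- toy_persons(5)
  pop <- make_population(
    persons,
    claims = tibble::tibble(
      person_id = c(1L, 2L, 3L, 3L),
      source = c("APCD", "APCD", "CaseMix", "CaseMix"),
      icd_code = c("I10", "Z59.0", "v60.1", "E119")
    ),
    dmh_records = tibble::tibble(
      person_id = c(4L, 4L), month = 1:2,
      housing_status = c("housed", "housing_loss")
    ),
    ambulance_records = tibble::tibble(
      person_id = c(2L, 5L),
      narrative = c("pt HOMELESS tonight", "chest pain, stable")
    ),
    prescription_records = tibble::tibble(
      person_id = 3L, patient_address = "1 haven sq boston ma"
    )
  )
  ind <- identify_known_homeless(pop)
  expect_identical(ind$known_homeless, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(ind$n_sources, c(0L, 2L, 2L, 1L, 0L))
  expect_identical(ind$via_apcd, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(ind$via_casemix, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(ind$via_dmh, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(ind$via_matris, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(ind$via_pmp, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # type invariants
  expect_identical(ind$known_homeless, ind$n_sources >= 1L)
  # idempotence
  expect_identical(ind, identify_known_homeless(pop))
})

test_that("a single shelter-matching prescription is enough to flag a person", {
  pop <- make_population(
    toy_persons(2),
    prescription_records = tibble::tibble(
      person_id = 1L, patient_address = "1 HAVEN SQ BOSTON MA"
    )
  )
  ind <- identify_known_homeless(pop)
  expect_identical(ind$known_homeless, c(TRUE, FALSE))
  expect_identical(ind$n_sources, c(1L, 0L))
})

test_that("records referencing unknown persons are rejected", {
  pop <- make_population(
    toy_persons(2),
    claims = tibble::tibble(person_id = 9L, source = "APCD", icd_code = "I10")
  )
  expect_error(identify_known_homeless(pop), "missing from")
})

test_that("adding a record never unflags a person (monotone union)", {
  base <- make_population(
    toy_persons(3),
    claims = tibble::tibble(person_id = 1L, source = "APCD", icd_code = "Z590")
  )
  before <- identify_known_homeless(base)
  more <- base
  more$ambulance_records <- tibble::tibble(
    person_id = c(1L, 2L), narrative = c("no issues", "left at shelter door")
  )
  after <- identify_known_homeless(more)
  expect_true(all(after$known_homeless >= before$known_homeless))
  expect_true(all(after$n_sources >= before$n_sources))
})

test_that("with zero false captures every synthetic known case is truly homeless", {
  pop <- generate_population(sim_config(n_persons = 30000, seed = 13))
  ind <- identify_known_homeless(pop)
  expect_true(all(pop$persons$true_homeless[ind$known_homeless]))
})
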