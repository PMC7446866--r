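test_that("identical config and seed reproduce the identical population", {
  cfg <- sim_config(n_persons = 3000, seed = 11)
  pop1 <- generate_population(cfg)
  pop2 <- generate_population(cfg)
  expect_identical(pop1, pop2)
  # a different seed changes the draw
  pop3 <- generate_population(sim_config(n_persons = 3000, seed = 12))
  expect_false(identical(pop1$persons, pop3$persons))
})

test_that("zero prevalence yields no latent cases and no planted signals", {
  cfg <- sim_config(n_persons = 2000, true_prevalence = 0, seed = 5)
  pop <- generate_population(cfg)
  expect_false(any(pop$persons$true_homeless))
  ind <- identify_known_homeless(pop)
  expect_false(any(ind$known_homeless))
  expect_identical(sum(ind$n_sources), 0L)
})

test_that("full capture flags every true case through all five sources", {
  cfg <- sim_config(
    n_persons = 2000, true_prevalence = 0.05,
    capture_sensitivity = c(apcd_icd = 1, casemix_icd = 1, dmh = 1,
                            matris = 1, pmp = 1),
    capture_engagement = 1, seed = 9
  )
  pop <- generate_population(cfg)
  ind <- identify_known_homeless(pop)
  truth <- pop$persons$true_homeless
  expect_true(all(ind$n_sources[truth] == 5L))
  expect_identical(ind$known_homeless, truth)
})

test_that("shelter addresses are deterministic, distinct, and length-checked", {
  expect_identical(generate_shelter_addresses(3, seed = 7),
                   generate_shelter_addresses(3, seed = 7))
  expect_length(generate_shelter_addresses(1, seed = 123), 1)
  many <- generate_shelter_addresses(100, seed = 1)
  expect_length(unique(many), 100)
  expect_error(generate_shelter_addresses(0, seed = 1), "n_shelters")
})

test_that("narratives honour the keyword-planting contract", {
  set.seed(42)
  planted <- generate_narratives(rep(TRUE, 200))
  expect_true(all(grepl("homeless|shelter", planted, ignore.case = TRUE)))
  clean <- generate_narratives(rep(FALSE, 1000))
  expect_identical(sum(narrative_indicates_homeless(clean)), 0L)
})

test_that("capture profile is monotone in each sensitivity", {
  base <- sim_config(n_persons = 10, seed = 1)
  p0 <- capture_profile(base)$p_known_given_true
  for (src in names(base$capture_sensitivity)) {
    bumped <- base$capture_sensitivity
    bumped[src] <- min(bumped[src] + 0.05, base$capture_engagement)
    cfg <- sim_config(n_persons = 10, capture_sensitivity = bumped, seed = 1)
    expect_gt(capture_profile(cfg)$p_known_given_true, p0)
  }
})

test_that("marginal capture sensitivity is preserved by the engagement model", {
  cfg <- sim_config(n_persons = 400000, true_prevalence = 0.2, seed = 31)
  pop <- generate_population(cfg)
  ind <- identify_known_homeless(pop)
  truth <- pop$persons$true_homeless
  n_true <- sum(truth)
  observed <- c(
    apcd_icd = sum(ind$via_apcd[truth]) / n_true,
    casemix_icd = sum(ind$via_casemix[truth]) / n_true,
    matris = sum(ind$via_matris[truth]) / n_true,
    pmp = sum(ind$via_pmp[truth]) / n_true
  )
  target <- cfg$capture_sensitivity[names(observed)]
  # binomial tolerance: ~n_true*s draws per source
  expect_true(all(abs(observed - target) < 4 * sqrt(target / n_true)))
})

test_that("overdose deaths embed the configured rate elevation", {
  cfg <- sim_config(n_persons = 1000000, seed = 17)
  persons <- simulate_persons(cfg, seed = 17)
  d1 <- sum(persons$died_opioid_overdose[persons$true_homeless])
  n1 <- sum(persons$true_homeless)
  d0 <- sum(persons$died_opioid_overdose[!persons$true_homeless])
  n0 <- sum(!persons$true_homeless)
  est <- rate_ratio_ci(d1, n1, d0, n0)
  expect_true(est$ci_low < cfg$true_rate_ratio &&
                cfg$true_rate_ratio < est$ci_high)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_persons = 0), "n_persons")
  expect_error(sim_config(n_persons = 10, true_prevalence = 1.5), "probability")
  expect_error(sim_config(n_persons = 10, true_rate_ratio = -2), "positive")
  expect_error(
    sim_config(n_persons = 10,
               capture_sensitivity = c(apcd_icd = 0.5, casemix_icd = 0.094,
                                       dmh = 0.0013, matris = 0.014, pmp = 0.029),
               capture_engagement = 0.28),
    "capture_engagement"
  )
  spec <- default_predictor_spec()
  spec$name[2] <- spec$name[1]
  expect_error(sim_config(n_persons = 10, predictor_spec = spec), "unique")
})

test_that("populations round-trip through CSV/JSON on disk", {
  dir <- withr::local_tempdir()
  pop <- generate_population(sim_config(n_persons = 800, seed = 23))
  write_population(pop, dir)
  expect_true(all(file.exists(file.path(
    dir, c("persons.csv", "claims.csv", "truth.json", "config.json")
  ))))
  back <- read_population(dir)
  expect_equal(back$persons$person_id, pop$persons$person_id)
  expect_equal(back$persons$true_homeless, pop$persons$true_homeless)
  expect_equal(back$claims$icd_code, pop$claims$icd_code)
  expect_equal(back$shelter_addresses, pop$shelter_addresses)
  # indicators computed from the on-disk copy agree with the in-memory ones
  expect_equal(identify_known_homeless(back)$known_homeless,
               identify_known_homeless(pop)$known_homeless)
})
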