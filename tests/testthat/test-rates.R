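test_that("risk-score schemes combine predictions and known flags as defined", {
  expect_equal(assign_risk_scores(0.3, TRUE, "known_override"), 1)
  expect_equal(assign_risk_scores(0.3, FALSE, "known_and_zeroed"), 0)
  # an unknown person at p = 0.7 under each scheme
  expect_equal(assign_risk_scores(0.7, FALSE, "threshold_binary"), 1)
  expect_equal(assign_risk_scores(0.7, FALSE, "known_override"), 0.7)
  expect_equal(assign_risk_scores(0.7, FALSE, "known_and_zeroed"), 0.7)
  # the threshold itself is inclusive
  expect_equal(assign_risk_scores(0.5, FALSE, "threshold_binary"), 1)
  expect_error(assign_risk_scores(1.2, FALSE, "known_override"), "\\[0, 1\\]")
  expect_error(assign_risk_scores(0.5, FALSE, "nope"))
})

test_that("weighted group counts match hand arithmetic under both conventions", {
  scores <- c(1, 0.8, 0.6, 0.4, 0.1)
  deaths <- c(1, 0, 1, 0, 0)
  tr <- weighted_group_counts(scores, deaths, "threshold_restricted")
  expect_equal(c(tr$n_homeless, tr$n_nonhomeless,
                 tr$deaths_homeless, tr$deaths_nonhomeless),
               c(2.4, 1.5, 1.6, 0.0))
  fs <- weighted_group_counts(scores, deaths, "full_sum")
  expect_equal(c(fs$n_homeless, fs$n_nonhomeless,
                 fs$deaths_homeless, fs$deaths_nonhomeless),
               c(2.9, 2.1, 1.6, 0.4))
  # full_sum partitions the evaluated mass exactly
  expect_equal(fs$n_homeless + fs$n_nonhomeless, length(scores))
  expect_equal(fs$deaths_homeless + fs$deaths_nonhomeless, sum(deaths))
})

test_that("degenerate and binary scores collapse the two conventions", {
  ones <- rep(1, 4)
  d <- c(1, 0, 0, 1)
  for (conv in c("full_sum", "threshold_restricted")) {
    w <- weighted_group_counts(ones, d, conv)
    expect_equal(w$n_homeless, 4)
    expect_equal(w$n_nonhomeless, 0)
  }
  set.seed(31)
  binary <- as.numeric(runif(200) >= 0.5)
  deaths <- rbinom(200, 1, 0.1)
  a <- weighted_group_counts(binary, deaths, "full_sum")
  b <- weighted_group_counts(binary, deaths, "threshold_restricted")
  expect_equal(a[1:4], b[1:4], ignore_attr = TRUE)
})

test_that("weighted counts dominate weighted deaths", {
  set.seed(13)
  for (i in 1:10) {
    s <- runif(100)
    d <- rbinom(100, 1, 0.2)
    for (conv in c("full_sum", "threshold_restricted")) {
      w <- weighted_group_counts(s, d, conv)
      expect_lte(w$deaths_homeless, w$n_homeless)
      expect_lte(w$deaths_nonhomeless, w$n_nonhomeless)
    }
  }
})

test_that("per-100,000 rates reproduce published-scale arithmetic", {
  expect_equal(round(rate_per_100k(724, 69675), 1), 1039.1)
  expect_equal(round(rate_per_100k(1265, 1262659), 1), 100.2)
  expect_equal(rate_per_100k(0, 12345), 0)
  expect_error(rate_per_100k(1, 0), "positive")
})

test_that("log-normal rate-ratio intervals match published-scale arithmetic", {
  a <- rate_ratio_ci(724, 69675, 541, 1192443)
  expect_equal(round(a$rate_ratio, 1), 22.9)
  expect_equal(round(c(a$ci_low, a$ci_high), 1), c(20.5, 25.6))
  b <- rate_ratio_ci(743, 169378, 522, 1093281)
  expect_equal(round(b$rate_ratio, 1), 9.2)
  expect_equal(round(c(b$ci_low, b$ci_high), 1), c(8.2, 10.3))
  expect_true(a$ci_low <= a$rate_ratio && a$rate_ratio <= a$ci_high)
  expect_equal(a$rate_ratio, a$rate_homeless / a$rate_nonhomeless)
})

test_that("equal rates give a ratio of 1 with an interval spanning 1", {
  eq <- rate_ratio_ci(10, 1000, 10, 1000)
  expect_equal(eq$rate_ratio, 1)
  expect_true(eq$ci_low < 1 && 1 < eq$ci_high)
})

test_that("zero event counts are flagged, not silently dropped", {
  expect_warning(inf <- rate_ratio_ci(5, 100, 0, 100), "infinite")
  expect_identical(inf$rate_ratio, Inf)
  expect_true(is.na(inf$ci_low))
  expect_warning(zero <- rate_ratio_ci(0, 100, 5, 100), "CI undefined")
  expect_equal(zero$rate_ratio, 0)
  expect_true(is.na(zero$ci_high))
})

test_that("the scheme comparison table carries one coherent row per scheme", {
  set.seed(29)
  n <- 5000
  p <- runif(n)
  known <- rbinom(n, 1, 0.02) == 1
  deaths <- rbinom(n, 1, 0.01) == 1
  tab <- compare_overdose_rates(p, known, deaths)
  expect_identical(tab$scheme,
                   c("threshold_binary", "known_override", "known_and_zeroed"))
  expect_equal(tab$rate_ratio,
               (tab$deaths_homeless / tab$n_homeless) /
                 (tab$deaths_nonhomeless / tab$n_nonhomeless))
  # full_sum: group sizes sum to n for every scheme
  expect_equal(tab$n_homeless + tab$n_nonhomeless, rep(n, 3))
  expect_true(all(tab$ci_low <= tab$rate_ratio & tab$rate_ratio <= tab$ci_high))
})
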