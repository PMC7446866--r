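test_that("stratified split allocates round-half-up per stratum", {
  ids <- 1:20
  labels <- c(rep(TRUE, 8), rep(FALSE, 12))
  sp <- stratified_split(ids, labels, 0.75, seed = 1)
  tab <- table(sp$stratum, sp$partition)
  expect_identical(unname(tab["known_homeless", "development"]), 6L)
  expect_identical(unname(tab["not_known_homeless", "development"]), 9L)
  # partitions disjoint and exhaustive
  expect_setequal(sp$person_id, ids)
  expect_true(all(sp$partition %in% c("development", "validation")))
  # deterministic under the seed
  expect_identical(sp, stratified_split(ids, labels, 0.75, seed = 1))
  expect_false(identical(sp, stratified_split(ids, labels, 0.75, seed = 2)))
})

test_that("half-up rounding reproduces large published-scale allocations", {
  # strata of 41,457 and 5,009,182 at 75%: 31,093 + 3,756,887 = 3,787,980
  sizes <- c(41457, 5009182)
  dev <- floor(0.75 * sizes + 0.5)
  expect_identical(dev, c(31093, 3756887))
  expect_identical(sum(dev), 3787980)
  # a singleton stratum goes to development at 75%
  sp <- stratified_split(1:5, c(TRUE, rep(FALSE, 4)), 0.75, seed = 3)
  expect_identical(sp$partition[1], "development")
})

test_that("downsampling balances classes and keeps every minority case", {
  ids <- 101:113
  labels <- c(rep(TRUE, 3), rep(FALSE, 10))
  kept <- downsample_majority(ids, labels, seed = 5)
  expect_length(kept, 6)
  expect_true(all(101:103 %in% kept))
  expect_identical(kept, downsample_majority(ids, labels, seed = 5))
  # already balanced input is returned unchanged
  bal <- downsample_majority(1:10, rep(c(TRUE, FALSE), 5), seed = 1)
  expect_setequal(bal, 1:10)
  expect_error(downsample_majority(1:3, c(TRUE, TRUE, FALSE), seed = 1),
               "larger")
  expect_error(downsample_majority(1:3, rep(TRUE, 3), seed = 1),
               "both classes")
})

test_that("logistic fit matches the closed-form 2x2 saturated solution", {
  # exposed: 20 events / 5 non-events; unexposed: 10 / 40
  x <- data.frame(exposed = c(rep(1, 25), rep(0, 50)))
  y <- c(rep(TRUE, 20), rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 40))
  fit <- fit_logistic(x, y)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["exposed"]), log((20 * 40) / (10 * 5)),
               tolerance = 1e-6)
  expect_equal(unname(coef(fit)["(Intercept)"]), log(10 / 40),
               tolerance = 1e-6)
  # scoring an exposed person returns the empirical stratum rate 20/25
  sc <- predict_probability(fit, data.frame(exposed = c(1, 0)))
  expect_equal(sc$probability, c(20 / 25, 10 / 50), tolerance = 1e-6)
})

test_that("a label-independent predictor gets a null coefficient", {
  # perfectly balanced permutation: x independent of y by construction
  x <- data.frame(flag = rep(c(1, 1, 0, 0), 25))
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), 25)
  fit <- fit_logistic(x, y)
  expect_lt(abs(coef(fit)["flag"]), 1e-6)
})

test_that("duplicating every row leaves the estimates unchanged", {
  set.seed(7)
  x <- data.frame(a = rbinom(80, 1, 0.4), b = rbinom(80, 1, 0.2))
  y <- rbinom(80, 1, plogis(-1 + x$a + 0.5 * x$b)) == 1
  f1 <- fit_logistic(x, y)
  f2 <- fit_logistic(rbind(x, x), c(y, y))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-7)
})

test_that("IRLS agrees with glm on random data and never decreases the log-likelihood", {
  set.seed(11)
  for (i in 1:5) {
    n <- 300
    x <- data.frame(a = rbinom(n, 1, 0.3), b = rbinom(n, 1, 0.5),
                    c = rbinom(n, 1, 0.1))
    y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x$a - 0.6 * x$b + 1.2 * x$c))
    fit <- fit_logistic(x, y)
    ref <- stats::glm(y ~ a + b + c, data = cbind(x, y = y),
                      family = stats::binomial())
    expect_equal(coef(fit), coef(ref), tolerance = 1e-6)
    expect_true(all(diff(fit$loglik) >= -1e-10))
    # Wald standard errors agree too
    expect_equal(tidy(fit)$std.error,
                 unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-4)
  }
})

test_that("separation is flagged and tamed with the ridge fallback", {
  x <- data.frame(sep = c(rep(1, 20), rep(0, 20)))
  y <- c(rep(TRUE, 20), rep(FALSE, 20))
  fit <- suppressWarnings(fit_logistic(x, y))
  expect_true(fit$separation)
  expect_true(all(is.finite(coef(fit))))
})

test_that("constant predictors are dropped with a warning", {
  x <- data.frame(a = rbinom(50, 1, 0.5), always = 1)
  y <- rbinom(50, 1, 0.5) == 1
  expect_warning(fit <- fit_logistic(x, y), "constant")
  expect_identical(fit$dropped, "always")
  expect_false("always" %in% names(coef(fit)))
})

test_that("prediction respects probability bounds and validates feature names", {
  x <- data.frame(a = c(1, 0))
  y <- c(TRUE, FALSE)
  fit <- suppressWarnings(fit_logistic(rbind(x, x, x), rep(y, 3)))
  # extreme linear predictors stay inside [0, 1]
  extreme <- fit
  extreme$coefficients <- c(`(Intercept)` = 50, a = -100)
  p <- predict_probability(extreme, data.frame(a = c(0, 1)))$probability
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(p[1], plogis(50))
  # all-zero features give logistic(intercept)
  expect_equal(predict_probability(extreme, data.frame(a = 0))$probability,
               plogis(50))
  expect_error(predict_probability(fit, data.frame(b = 1)), "missing")
  expect_error(predict_probability(fit, data.frame(a = 1, zz = 2)), "unknown")
})
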