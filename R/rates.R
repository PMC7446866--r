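risk_score_schemes <- c("threshold_binary", "known_override", "known_and_zeroed")

#' Assign homelessness risk scores
#'
#' Combines model-predicted probabilities with known-case flags under one
#' of three schemes:
#' * `threshold_binary` - 1 if the predicted probability is at least
#'   `threshold`, else 0 (the principal, fully dichotomized assignment);
#' * `known_override` - known cases get 1 regardless of their prediction,
#'   everyone else keeps their predicted probability;
#' * `known_and_zeroed` - known cases get 1, persons below `threshold`
#'   get 0, the rest keep their predicted probability.
#'
#' @param probability Numeric vector of predicted probabilities in
#'   `[0, 1]`.
#' @param known Logical vector of known-case flags, aligned with
#'   `probability`.
#' @param scheme One of `"threshold_binary"`, `"known_override"`,
#'   `"known_and_zeroed"`.
#' @param threshold Dichotomization threshold (default 0.5, inclusive).
#' @return Numeric vector of risk scores in `[0, 1]`.
#' @export
#' @examples
#' assign_risk_scores(c(0.3, 0.7), c(TRUE, FALSE), "known_override")
assign_risk_scores <- function(probability, known,
                               scheme = c("threshold_binary", "known_override",
                                          "known_and_zeroed"),
                               threshold = 0.5) {
  scheme <- arg_match(scheme)
  stopifnot(length(probability) == length(known), is.logical(known),
            !anyNA(probability), !anyNA(known))
  if (any(probability < 0 | probability > 1)) {
    abort("`probability` values must lie in [0, 1].")
  }
  switch(scheme,
    threshold_binary = as.numeric(probability >= threshold),
    known_override = ifelse(known, 1, probability),
    known_and_zeroed = ifelse(known, 1,
                              ifelse(probability < threshold, 0, probability))
  )
}

#' Risk-score weighted group sizes and death counts
#'
#' Treats each person's risk score `s` as a homeless "mass" and its
#' complement `1 - s` as non-homeless mass, and tallies weighted group
#' sizes and weighted fatal-overdose counts. Two conventions are
#' provided:
#' * `full_sum` (default) - sums run over all persons, so the two group
#'   sizes always add up exactly to the number evaluated;
#' * `threshold_restricted` - homeless mass is summed only over persons
#'   with `s >=` `threshold` and non-homeless mass only over persons
#'   below it, so fractional mass on the "wrong" side of the threshold is
#'   discarded.
#'
#' @param scores Numeric risk scores in `[0, 1]` (e.g. from
#'   [assign_risk_scores()]).
#' @param deaths Logical (or 0/1) fatal-overdose flags, aligned with
#'   `scores`.
#' @param convention `"full_sum"` or `"threshold_restricted"`.
#' @param threshold Threshold used by `threshold_restricted`.
#' @return One-row tibble of class `weighted_counts`: `n_homeless`,
#'   `n_nonhomeless`, `deaths_homeless`, `deaths_nonhomeless`,
#'   `convention`.
#' @export
#' @examples
#' weighted_group_counts(c(1, 0.8, 0.6, 0.4, 0.1), c(1, 0, 1, 0, 0),
#'                       convention = "threshold_restricted")
weighted_group_counts <- function(scores, deaths,
                                  convention = c("full_sum",
                                                 "threshold_restricted"),
                                  threshold = 0.5) {
  convention <- arg_match(convention)
  deaths <- as.logical(deaths)
  stopifnot(length(scores) == length(deaths), !anyNA(scores), !anyNA(deaths))
  if (any(scores < 0 | scores > 1)) abort("`scores` must lie in [0, 1].")
  d <- as.numeric(deaths)
  if (convention == "full_sum") {
    out <- tibble::tibble(
      n_homeless = sum(scores),
      n_nonhomeless = sum(1 - scores),
      deaths_homeless = sum(scores * d),
      deaths_nonhomeless = sum((1 - scores) * d),
      convention = convention
    )
  } else {
    hi <- scores >= threshold
    out <- tibble::tibble(
      n_homeless = sum(scores[hi]),
      n_nonhomeless = sum(1 - scores[!hi]),
      deaths_homeless = sum(scores[hi] * d[hi]),
      deaths_nonhomeless = sum((1 - scores[!hi]) * d[!hi]),
      convention = convention
    )
  }
  class(out) <- c("weighted_counts", class(out))
  out
}

#' Event rate per 100,000 persons
#'
#' @param deaths Event count (may be a weighted, fractional count).
#' @param n Group size (may be weighted); must be positive.
#' @return `100000 * deaths / n`.
#' @export
#' @examples
#' rate_per_100k(724, 69675)
rate_per_100k <- function(deaths, n) {
  stopifnot(is.numeric(deaths), is.numeric(n), deaths >= 0)
  if (any(n <= 0)) abort("`n` must be positive.")
  100000 * deaths / n
}

#' Rate ratio with a log-normal 95% confidence interval
#'
#' Compares two crude event rates `d1/n1` and `d0/n0` and attaches the
#' standard log-normal interval
#' `exp(log(RR) +/- z * sqrt(1/d1 + 1/d0))`, the usual large-sample
#' interval for a ratio of Poisson-like counts. With a zero event count
#' the interval is undefined (`NA`) and, for `d0 = 0`, the point estimate
#' is infinite; both are flagged with a warning.
#'
#' @param d1,n1 Event count and group size in the exposed (homeless)
#'   group; weighted fractional counts are accepted.
#' @param d0,n0 Event count and group size in the reference group.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble of class `rate_comparison`: `rate_homeless`,
#'   `rate_nonhomeless` (per 100,000), `rate_ratio`, `ci_low`, `ci_high`,
#'   plus the input counts.
#' @export
#' @examples
#' rate_ratio_ci(724, 69675, 541, 1192443)
rate_ratio_ci <- function(d1, n1, d0, n0, conf_level = 0.95) {
  stopifnot(d1 >= 0, d0 >= 0)
  if (n1 <= 0 || n0 <= 0) abort("group sizes must be positive.")
  r1 <- d1 / n1
  r0 <- d0 / n0
  rr <- if (d0 == 0) {
    warn("zero events in the reference group; rate ratio is infinite.")
    Inf
  } else {
    r1 / r0
  }
  if (d1 > 0 && d0 > 0) {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(1 / d1 + 1 / d0)
    ci_low <- exp(log(rr) - z * se)
    ci_high <- exp(log(rr) + z * se)
  } else {
    if (d0 > 0) warn("zero events in the exposed group; CI undefined.")
    ci_low <- NA_real_
    ci_high <- NA_real_
  }
  out <- tibble::tibble(
    d1 = d1, n1 = n1, d0 = d0, n0 = n0,
    rate_homeless = rate_per_100k(d1, n1),
    rate_nonhomeless = rate_per_100k(d0, n0),
    rate_ratio = rr,
    ci_low = ci_low,
    ci_high = ci_high
  )
  class(out) <- c("rate_comparison", class(out))
  out
}

#' Compare fatal-overdose rates across risk-score schemes
#'
#' Runs [assign_risk_scores()], [weighted_group_counts()] and
#' [rate_ratio_ci()] for each requested scheme, producing one comparison
#' row per scheme (the shape of a rates-by-homeless-status summary
#' table).
#'
#' @inheritParams assign_risk_scores
#' @param deaths Logical fatal-overdose flags.
#' @param schemes Character vector of schemes to evaluate.
#' @param convention Weighting convention for [weighted_group_counts()].
#' @return Tibble of class `rate_comparison_set`, one row per scheme:
#'   `scheme`, weighted `n_homeless`, `deaths_homeless`, `rate_homeless`,
#'   the same for the non-homeless group, `rate_ratio`, `ci_low`,
#'   `ci_high`.
#' @export
compare_overdose_rates <- function(probability, known, deaths,
                                   schemes = risk_score_schemes,
                                   convention = "full_sum",
                                   threshold = 0.5) {
  schemes <- match.arg(schemes, risk_score_schemes, several.ok = TRUE)
  rows <- purrr::map(schemes, function(sch) {
    s <- assign_risk_scores(probability, known, sch, threshold)
    w <- weighted_group_counts(s, deaths, convention, threshold)
    rr <- rate_ratio_ci(w$deaths_homeless, w$n_homeless,
                        w$deaths_nonhomeless, w$n_nonhomeless)
    tibble::tibble(
      scheme = sch,
      n_homeless = w$n_homeless,
      deaths_homeless = w$deaths_homeless,
      rate_homeless = rr$rate_homeless,
      n_nonhomeless = w$n_nonhomeless,
      deaths_nonhomeless = w$deaths_nonhomeless,
      rate_nonhomeless = rr$rate_nonhomeless,
      rate_ratio = rr$rate_ratio,
      ci_low = rr$ci_low,
      ci_high = rr$ci_high
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rate_comparison_set", class(out))
  out
}
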