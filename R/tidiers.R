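#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted homelessness classification model
#'
#' One row per model term with the Wald summary statistics, in the usual
#' broom column layout.
#'
#' @param x A `homeless_model` from [fit_logistic()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @exportS3Method generics::tidy
tidy.homeless_model <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' One-row summary of a fitted homelessness classification model
#'
#' @param x A `homeless_model`.
#' @param ... Unused.
#' @return Tibble with `n`, `n_predictors`, `converged`, `separation`,
#'   `n_iter`, `logLik`, `AIC`, `deviance`.
#' @exportS3Method generics::glance
glance.homeless_model <- function(x, ...) {
  ll <- tail(x$loglik, 1)
  k <- length(x$coefficients)
  tibble::tibble(
    n = x$n,
    n_predictors = length(x$feature_names),
    converged = x$converged,
    separation = x$separation,
    n_iter = x$n_iter,
    logLik = ll,
    AIC = 2 * k - 2 * ll,
    deviance = -2 * ll
  )
}
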