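#' @importFrom rlang %||% abort warn arg_match .data
#' @importFrom stats plogis qlogis rbinom runif setNames quantile
#' @importFrom utils head tail
NULL

# round-half-up at `digits` decimal places; base round() is half-to-even
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Normalize a postal address for exact matching
#'
#' Upper-cases, strips punctuation, and collapses runs of whitespace so that
#' trivially different renderings of the same address ("123 Main St." vs
#' "123  MAIN ST") compare equal. No fuzzy matching is attempted.
#'
#' @param address Character vector of addresses.
#' @return Character vector of normalized addresses.
#' @export
#' @examples
#' normalize_address("123  Main St.")
normalize_address <- function(address) {
  x <- toupper(address)
  x <- gsub("[^A-Z0-9 ]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

is_prob <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0 & x <= 1)

check_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != trunc(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}
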