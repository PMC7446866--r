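#' Stratified development/validation split
#'
#' Randomly assigns a fixed fraction of each label stratum to the
#' development partition and the remainder to validation, so both
#' partitions carry equal proportions of known cases. The development count
#' in each stratum is `dev_fraction x stratum size` rounded half-up (so
#' strata of 41,457 and 5,009,182 at 75% give 31,093 + 3,756,887 =
#' 3,787,980 development members).
#'
#' @param ids Vector of person ids.
#' @param labels Logical vector (known case or not), aligned with `ids`.
#' @param dev_fraction Development fraction, strictly between 0 and 1.
#' @param seed Integer seed; the assignment is deterministic given the
#'   seed.
#' @return Tibble with `person_id`, `stratum` (`"known_homeless"` /
#'   `"not_known_homeless"`), `partition` (`"development"` /
#'   `"validation"`).
#' @export
stratified_split <- function(ids, labels, dev_fraction = 0.75, seed) {
  stopifnot(length(ids) == length(labels), is.logical(labels), !anyNA(labels))
  if (!is.numeric(dev_fraction) || length(dev_fraction) != 1 ||
      dev_fraction <= 0 || dev_fraction >= 1) {
    abort("`dev_fraction` must be strictly between 0 and 1.")
  }
  seed <- check_scalar_count(seed, "seed", min = -.Machine$integer.max)
  partition <- character(length(ids))
  withr_seed(seed, {
    for (lab in c(TRUE, FALSE)) {
      idx <- which(labels == lab)
      n_dev <- round_half_up(dev_fraction * length(idx))
      partition[idx] <- "validation"
      if (n_dev > 0) {
        partition[idx[sample.int(length(idx), n_dev)]] <- "development"
      }
    }
  })
  tibble::tibble(
    person_id = ids,
    stratum = ifelse(labels, "known_homeless", "not_known_homeless"),
    partition = partition
  )
}

#' Downsample the majority class to a balanced development set
#'
#' Retains every minority-class member and a uniformly drawn
#' without-replacement subsample of the majority class of equal size, the
#' standard downsampling remedy for severe class imbalance before model
#' fitting.
#'
#' @param ids Vector of development-sample ids.
#' @param labels Logical vector aligned with `ids`; `TRUE` marks the
#'   (minority) positive class.
#' @param seed Integer seed.
#' @return Vector of retained ids (all positives plus the negative
#'   subsample), in original order.
#' @export
downsample_majority <- function(ids, labels, seed) {
  stopifnot(length(ids) == length(labels), is.logical(labels), !anyNA(labels))
  seed <- check_scalar_count(seed, "seed", min = -.Machine$integer.max)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present in the development sample.")
  }
  if (n_pos > n_neg) {
    abort("positive class is larger than the negative class; downsampling assumes the reverse.")
  }
  neg_idx <- which(!labels)
  keep_neg <- withr_seed(seed, neg_idx[sample.int(n_neg, n_pos)])
  keep <- sort(c(which(labels), keep_neg))
  ids[keep]
}

#' Fit a binary logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression with an explicit IRLS loop:
#' Newton steps with step-halving (so the log-likelihood never decreases),
#' convergence when the largest absolute coefficient change falls below
#' `tol`, and a tiny ridge penalty applied only when complete or
#' quasi-complete separation is detected (diverging coefficients or a
#' singular weighted cross-product), in which case the fit is flagged
#' rather than silently accepted. Predictors constant across all rows are
#' dropped with a warning.
#'
#' @param features Data frame or matrix of numeric (typically 0/1)
#'   predictors; a `person_id` column, if present, is ignored.
#' @param labels Logical or 0/1 outcome vector.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the coefficient change.
#' @param ridge Ridge penalty used only under separation.
#' @return An object of class `homeless_model`: named `coefficients`
#'   (including `(Intercept)`), `converged`, `separation`, `n_iter`,
#'   `loglik` (per-iteration trace), `vcov`, `n`, `feature_names`,
#'   `dropped`.
#' @export
#' @examples
#' x <- data.frame(exposed = c(rep(1, 25), rep(0, 50)))
#' y <- c(rep(TRUE, 20), rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 40))
#' coef(fit_logistic(x, y))
fit_logistic <- function(features, labels, max_iter = 100, tol = 1e-8,
                         ridge = 1e-6) {
  x <- as.data.frame(features)
  x$person_id <- NULL
  if (is.logical(labels)) labels <- as.numeric(labels)
  stopifnot(is.numeric(labels), all(labels %in% c(0, 1)),
            nrow(x) == length(labels))
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  constant <- apply(X, 2, function(col) length(unique(col)) == 1)
  dropped <- colnames(X)[constant]
  if (length(dropped) > 0) {
    warn(paste0("dropping constant predictor(s): ",
                paste(dropped, collapse = ", ")))
    X <- X[, !constant, drop = FALSE]
  }
  if (nrow(X) < ncol(X) + 1) {
    abort("need at least one more observation than predictors.")
  }
  X <- cbind(`(Intercept)` = 1, X)
  y <- labels
  p <- ncol(X)

  loglik_at <- function(beta) {
    eta <- drop(X %*% beta)
    # numerically stable log(1 + exp(eta))
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }

  beta <- numeric(p)
  ll <- loglik_at(beta)
  trace <- ll
  converged <- FALSE
  separation <- FALSE
  lambda <- 0
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    mu <- plogis(drop(X %*% beta))
    w <- mu * (1 - mu)
    XtWX <- crossprod(X * w, X)
    if (lambda > 0) XtWX <- XtWX + diag(lambda, p)
    score <- crossprod(X, y - mu)
    if (lambda > 0) score <- score - lambda * beta
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step)) {
      separation <- TRUE
      lambda <- ridge
      XtWX <- crossprod(X * w, X) + diag(lambda, p)
      step <- solve(XtWX, crossprod(X, y - mu) - lambda * beta)
    }
    # step-halving keeps the (penalized) log-likelihood non-decreasing
    pen <- function(b, l) loglik_at(b) - l / 2 * sum(b^2)
    target <- pen(beta, lambda)
    scale <- 1
    repeat {
      candidate <- beta + scale * drop(step)
      if (pen(candidate, lambda) >= target - 1e-12 || scale < 1e-8) break
      scale <- scale / 2
    }
    delta <- max(abs(candidate - beta))
    beta <- candidate
    trace <- c(trace, loglik_at(beta))
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (lambda == 0 && max(abs(beta)) > 30) {
      # diverging coefficients: (quasi-)complete separation
      separation <- TRUE
      lambda <- ridge
    }
  }
  if (!converged) {
    warn("IRLS did not converge within `max_iter` iterations.")
  }
  mu <- plogis(drop(X %*% beta))
  w <- mu * (1 - mu)
  vcov <- tryCatch(solve(crossprod(X * w, X) + diag(lambda, p)),
                   error = function(e) matrix(NA_real_, p, p))
  dimnames(vcov) <- list(colnames(X), colnames(X))

  structure(
    list(
      coefficients = setNames(drop(beta), colnames(X)),
      converged = converged,
      separation = separation,
      n_iter = iter,
      loglik = trace,
      vcov = vcov,
      n = nrow(X),
      feature_names = colnames(X)[-1],
      dropped = dropped
    ),
    class = "homeless_model"
  )
}

#' @export
coef.homeless_model <- function(object, ...) object$coefficients

#' @export
print.homeless_model <- function(x, ...) {
  cat("<homeless_model> logistic regression,", length(x$feature_names),
      "predictors, n =", format(x$n, big.mark = ","), "\n")
  cat("  converged:", x$converged, " iterations:", x$n_iter,
      " log-likelihood:", round(tail(x$loglik, 1), 2), "\n")
  if (x$separation) cat("  note: separation detected; ridge fallback used\n")
  if (length(x$dropped) > 0) {
    cat("  dropped constant predictors:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predicted probabilities of homelessness
#'
#' Applies a fitted model's coefficients to new data on the logistic
#' scale. Feature columns must exactly cover the model's predictors (a
#' `person_id` column is carried through to the output).
#'
#' @param model A `homeless_model`.
#' @param features Data frame of predictor values, optionally with a
#'   `person_id` column.
#' @return Tibble with `person_id` (row number if absent) and
#'   `probability` in `[0, 1]`.
#' @export
predict_probability <- function(model, features) {
  stopifnot(inherits(model, "homeless_model"))
  x <- as.data.frame(features)
  ids <- if ("person_id" %in% names(x)) x$person_id else seq_len(nrow(x))
  x$person_id <- NULL
  missing <- setdiff(model$feature_names, names(x))
  if (length(missing) > 0) {
    abort(paste0("features missing from new data: ",
                 paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(x), c(model$feature_names, model$dropped))
  if (length(unknown) > 0) {
    abort(paste0("unknown feature name(s): ", paste(unknown, collapse = ", ")))
  }
  X <- as.matrix(x[model$feature_names])
  eta <- unname(model$coefficients[1]) + drop(X %*% model$coefficients[-1])
  tibble::tibble(person_id = ids, probability = plogis(eta))
}
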