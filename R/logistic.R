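# Maximum-likelihood logistic regression by iteratively reweighted least
# squares, with explicit separation detection and a ridge-stabilized
# fallback.  Kept in-package so the convergence contract (tolerance 1e-8,
# cap 100 iterations, ridge 1e-6 on separation) is under our control;
# stats::glm() is used as an independent cross-check in the tests.

.irls_logistic <- function(X, y, ridge = 0, tol = 1e-8, max_iter = 100L) {
  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    H <- XtW %*% X + diag(ridge, p)
    beta_new <- tryCatch(drop(solve(H, XtW %*% z)),
                         error = function(e) beta + NA)
    if (anyNA(beta_new)) break
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(beta = beta, converged = converged, iterations = iter)
}

.fit_logistic <- function(X, y, term_names) {
  if (length(unique(y)) < 2)
    stop("outcome has a single class; cannot fit a logistic model")
  if (min(table(y)) < 2)
    stop("need at least 2 records per outcome class")
  # constant (zero-variance) predictors carry no information: they are
  # dropped from the design and reported with coefficient exactly 0
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                        function(col) stats::sd(col) > 0))
  X_full <- X
  X <- X[, keep, drop = FALSE]
  fit <- .irls_logistic(X, y)
  eta <- drop(X %*% fit$beta)
  # complete/quasi-complete separation: the unpenalized MLE diverges, which
  # shows up as non-convergence with fitted probabilities pinned at 0/1
  separation <- !fit$converged && all((eta > 0) == (y == 1) | eta == 0) ||
    (max(abs(fit$beta)) > 1e6)
  if (separation || !fit$converged) {
    fit <- .irls_logistic(X, y, ridge = 1e-6)
    separation <- TRUE
  }
  beta <- rep(0, ncol(X_full))
  beta[keep] <- fit$beta
  names(beta) <- term_names
  X <- X_full
  mu <- stats::plogis(drop(X %*% beta))
  structure(list(intercept = beta[[1]], coefficients = beta[-1],
                 all_coefficients = beta, fitted = mu,
                 converged = fit$converged, iterations = fit$iterations,
                 separation = separation, n = length(y)),
            class = "petscore_logit")
}

#' @export
print.petscore_logit <- function(x, ...) {
  cat("Logistic model (IRLS", if (x$separation) ", ridge-stabilized: separation detected" else "",
      ")\n", sep = "")
  print(round(x$all_coefficients, 6))
  cat("converged:", x$converged, "after", x$iterations, "iterations\n")
  invisible(x)
}

#' Predict probabilities from a fitted logistic model
#'
#' @param object A `petscore_logit` fit.
#' @param newdata Optional data.frame (for [fit_additive_logistic()] fits) or
#'   numeric score vector (for [probability_curve()] fits); when missing,
#'   fitted probabilities are returned.
#' @param ... Unused.
#' @export
predict.petscore_logit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (is.data.frame(newdata)) {
    X <- cbind(1, as.matrix(newdata[, names(object$coefficients),
                                    drop = FALSE]))
  } else {
    X <- cbind(1, as.numeric(newdata))
  }
  stats::plogis(drop(X %*% object$all_coefficients))
}

#' Additive logistic comparator model
#'
#' Fits transformation status on the linear additive terms SUV-max, TLG and
#' LDH elevation (unknown LDH treated as not elevated, as in the score).
#' This is the comparator the multiplicative score is benchmarked against.
#'
#' @param records Cohort data.frame with columns `suvmax`, `tlg_cc`,
#'   `ldh_elevated`.
#' @param outcome Logical (or 0/1) vector, `TRUE` = transformed.
#' @return A `petscore_logit` with coefficients, fitted probabilities and
#'   `converged` / `separation` flags.
#' @export
fit_additive_logistic <- function(records, outcome) {
  stopifnot(all(c("suvmax", "tlg_cc", "ldh_elevated") %in% names(records)),
            nrow(records) == length(outcome))
  y <- as.integer(as.logical(outcome))
  ldh <- as.numeric(ldh_factor(records$ldh_elevated) == 2L)
  X <- cbind(1, records$suvmax, records$tlg_cc, ldh)
  .fit_logistic(X, y, c("(Intercept)", "suvmax", "tlg_cc", "ldh_elevated"))
}

#' Logistic probability-of-transformation curve over the score
#'
#' Single-predictor logistic fit of transformation status on the
#' transformation score, giving an estimated probability of transformation
#' as a function of the score.
#'
#' @param scores Numeric transformation scores.
#' @param outcome Logical (or 0/1), `TRUE` = transformed.
#' @return A `petscore_logit`; use `predict(fit, newdata = score_grid)` to
#'   evaluate the curve.
#' @export
probability_curve <- function(scores, outcome) {
  stopifnot(length(scores) == length(outcome))
  y <- as.integer(as.logical(outcome))
  .fit_logistic(cbind(1, as.numeric(scores)), y, c("(Intercept)", "score"))
}
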