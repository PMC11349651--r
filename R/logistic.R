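#' Binary logistic regression for amyloid positivity
#'
#' Fits a maximum-likelihood logistic model (iteratively reweighted least
#' squares, as in `stats::glm`) of a binary outcome on a feature matrix,
#' with Wald z tests per coefficient. Perfect or quasi-perfect separation
#' is detected (fitted probabilities collapsing to 0/1) and flagged; the
#' coefficients are then reported as non-converged rather than trusted.
#'
#' @param features Numeric matrix or data frame of predictors (no
#'   intercept column; one is added). No feature may be constant.
#' @param outcome Binary outcome: logical, 0/1 or
#'   `"positive"`/`"negative"`.
#' @param epsilon IRLS convergence tolerance on the deviance (default
#'   1e-8, tighter than the `glm` default).
#'
#' @return A list with class `logistic_fit`: `coefficients` (data frame
#'   with term, estimate, std_error, z, p_value), `log_likelihood`,
#'   `converged`, `separation_detected`, `n`.
#' @export
fit_logistic <- function(features, outcome, epsilon = 1e-8) {
  X <- as.matrix(as.data.frame(features))
  if (!is.numeric(X)) caps_validation_error("features must be numeric")
  y <- as_binary_labels(outcome)
  if (nrow(X) != length(y)) caps_validation_error("features/outcome length mismatch")
  if (nrow(X) <= ncol(X) + 1L) {
    caps_validation_error("need more observations than coefficients")
  }
  if (any(apply(X, 2L, function(v) length(unique(v)) == 1L))) {
    caps_validation_error("constant feature(s) present; drop before fitting")
  }
  if (length(unique(y)) < 2L) caps_validation_error("outcome has a single class")
  df <- data.frame(X)
  df$.y <- y
  fit <- suppressWarnings(
    glm(.y ~ ., data = df, family = binomial(),
        control = list(epsilon = epsilon, maxit = 100)))
  mu <- fit$fitted.values
  separation <- any(mu < 1e-8 | mu > 1 - 1e-8)
  s <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(s),
                      estimate = s[, 1L], std_error = s[, 2L],
                      z = s[, 3L], p_value = s[, 4L],
                      row.names = NULL)
  structure(list(coefficients = coefs,
                 log_likelihood = as.numeric(logLik(fit)),
                 converged = fit$converged && !separation,
                 separation_detected = separation,
                 n = length(y)),
            class = "logistic_fit")
}

# Bernoulli log-likelihood at arbitrary coefficients; shared by the fit
# diagnostics and the grid-search oracle used in the tests.
logistic_loglik <- function(beta, X, y) {
  eta <- cbind(1, X) %*% beta
  sum(y * eta - log1p(exp(eta)))
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n=%d, logLik %.4f, converged=%s%s\n", x$n,
              x$log_likelihood, x$converged,
              if (x$separation_detected) " (separation detected)" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}
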