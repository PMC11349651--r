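#' ROC analysis with AUC and 95% confidence interval
#'
#' Builds the empirical ROC curve of a score against a binary reference
#' label and computes the c-statistic (AUC). The AUC is computed by the
#' rank (Mann-Whitney) formula — the probability that a randomly chosen
#' positive subject outscores a randomly chosen negative one, ties
#' counting one half — which equals the trapezoidal area under the
#' empirical curve. The 95% CI uses DeLong's method by default
#' (via \pkg{pROC}), with Hanley-McNeil selectable.
#'
#' @param scores Numeric score per subject (higher = more disease-like).
#' @param labels Binary reference labels: logical, 0/1, or
#'   `"positive"`/`"negative"`. Both classes must be present.
#' @param ci_method `"delong"` (default) or `"hanley_mcneil"`.
#'
#' @return A list with class `roc_result`: `thresholds` (descending score
#'   cutpoints, prediction positive when score >= cutpoint), `tpr`, `fpr`
#'   (step curve from (0,0) to (1,1)), `auc`, `auc_ci_95`, `method`,
#'   `n_positive`, `n_negative`.
#' @export
roc_analysis <- function(scores, labels, ci_method = c("delong", "hanley_mcneil")) {
  ci_method <- match.arg(ci_method)
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) {
    caps_validation_error("`scores` and `labels` must have equal length")
  }
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    caps_validation_error("`scores` must be finite numerics")
  }
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    caps_validation_error("ROC analysis needs both classes present")
  }
  # Mann-Whitney/rank form of the c-statistic (midranks handle ties as 1/2)
  r <- rank(scores)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  cuts <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(cuts, function(c) sum(scores >= c & y == 1L) / n1, numeric(1))
  fpr <- vapply(cuts, function(c) sum(scores >= c & y == 0L) / n0, numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr); cuts <- c(Inf, cuts)
  if (tpr[length(tpr)] < 1 || fpr[length(fpr)] < 1) {
    tpr <- c(tpr, 1); fpr <- c(fpr, 1); cuts <- c(cuts, -Inf)
  }

  ci <- if (ci_method == "delong") {
    r <- suppressMessages(pROC::roc(response = y, predictor = scores,
                                    levels = c(0, 1), direction = "<", quiet = TRUE))
    # perfect separation gives the degenerate but valid interval [1, 1];
    # pROC warns about it, which is noise in simulation loops
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))[c(1L, 3L)])
  } else {
    # Hanley & McNeil (1982) SE with the exponential approximation
    q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                  (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
    auc + c(-1, 1) * qnorm(0.975) * se
  }
  ci <- pmin(1, pmax(0, ci))

  structure(list(thresholds = cuts, tpr = tpr, fpr = fpr,
                 auc = auc, auc_ci_95 = ci, method = ci_method,
                 n_positive = n1, n_negative = n0),
            class = "roc_result")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(as.integer(labels))
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (all(labels %in% c("positive", "negative"))) {
      return(as.integer(labels == "positive"))
    }
  }
  caps_validation_error(
    "labels must be logical, 0/1, or 'positive'/'negative'")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f, %s), %d positive vs %d negative\n",
              x$auc, x$auc_ci_95[1], x$auc_ci_95[2], x$method,
              x$n_positive, x$n_negative))
  invisible(x)
}
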