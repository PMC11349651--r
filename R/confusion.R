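#' Construct a 2x2 confusion table
#'
#' @param tp,fp,tn,fn Non-negative integer cell counts (reference status
#'   in columns, predicted status in rows); at least one must be positive.
#' @return A list with class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, tn, fn) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  for (nm in names(cells)) assert_scalar_int(cells[[nm]], nm, lo = 0)
  if (sum(cells) == 0) caps_validation_error("confusion table must contain at least one subject")
  structure(as.list(as.integer(cells)) |> setNames(names(cells)),
            class = "confusion_table")
}

#' Operating characteristics of a confusion table
#'
#' Derives sensitivity, specificity, positive and negative predictive
#' values and the two likelihood ratios from the 2x2 cell counts. Each
#' metric is reported as `NA` (undefined), never coerced to 0, when its
#' denominator is zero. Cell counts are integers so the quotients are
#' exact up to floating point; rounding is left to the caller.
#'
#' @param table A [confusion_table()].
#' @return A list with class `operating_characteristics`: `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `lr_positive`, `lr_negative`, plus `n`.
#' @examples
#' m <- confusion_metrics(confusion_table(tp = 25, fp = 4, tn = 16, fn = 3))
#' round(100 * c(m$sensitivity, m$specificity, m$ppv, m$npv), 1)
#' @export
confusion_metrics <- function(table) {
  if (!inherits(table, "confusion_table")) {
    caps_validation_error("`table` must be a confusion_table")
  }
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- frac(table$tp, table$tp + table$fn)
  spec <- frac(table$tn, table$tn + table$fp)
  lr_pos <- if (!is.na(sens) && !is.na(spec) && spec < 1) sens / (1 - spec) else NA_real_
  lr_neg <- if (!is.na(sens) && !is.na(spec) && spec > 0) (1 - sens) / spec else NA_real_
  structure(list(
    sensitivity = sens, specificity = spec,
    ppv = frac(table$tp, table$tp + table$fp),
    npv = frac(table$tn, table$tn + table$fn),
    lr_positive = lr_pos, lr_negative = lr_neg,
    n = table$tp + table$fp + table$tn + table$fn
  ), class = "operating_characteristics")
}

#' Predictive values at a given prevalence
#'
#' PPV and NPV are post-test probabilities and depend on pre-test
#' prevalence via Bayes' theorem; with sensitivity and specificity held
#' fixed, PPV rises and NPV falls as prevalence increases. This is why a
#' clinical score calibrated in a memory clinic (high amyloid prevalence)
#' carries different predictive values in, say, a primary-care population.
#'
#' @param sensitivity,specificity Proportions in (0, 1].
#' @param prevalence Pre-test probability(ies) of disease in (0, 1);
#'   vectorised.
#' @return Data frame with columns `prevalence`, `ppv`, `npv`.
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            all(prevalence > 0), all(prevalence < 1))
  ppv <- sensitivity * prevalence /
    (sensitivity * prevalence + (1 - specificity) * (1 - prevalence))
  npv <- specificity * (1 - prevalence) /
    (specificity * (1 - prevalence) + (1 - sensitivity) * prevalence)
  data.frame(prevalence = prevalence, ppv = ppv, npv = npv)
}

#' @export
print.operating_characteristics <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("<operating_characteristics> n=%d | sens %s, spec %s, PPV %s, NPV %s, LR+ %s, LR- %s\n",
              x$n, pct(x$sensitivity), pct(x$specificity), pct(x$ppv), pct(x$npv),
              ifelse(is.na(x$lr_positive), "undefined", sprintf("%.2f", x$lr_positive)),
              ifelse(is.na(x$lr_negative), "undefined", sprintf("%.2f", x$lr_negative))))
  invisible(x)
}
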