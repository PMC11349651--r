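#' Evaluate CAPS or CAPS-MT on a cohort
#'
#' Scores every subject, compares the predicted class against the
#' reference amyloid status, and returns the 2x2 confusion table, its
#' operating characteristics, an ROC analysis of the raw totals, and the
#' per-subject score table. Subjects that cannot be scored (missing
#' components) or that lack a reference label are dropped with a logged
#' count, mirroring how incomplete records are excluded from an accuracy
#' analysis.
#'
#' @param cohort List of `caps_subject` records.
#' @param score `"caps"` (default) or `"caps_mt"`.
#' @param threshold Positivity threshold (default 3).
#' @param npiq_mode,decline_method Passed to [compute_caps()].
#'
#' @return A list with class `score_evaluation`: `confusion`
#'   ([confusion_table()]), `metrics` ([confusion_metrics()]), `roc`
#'   ([roc_analysis()]), `scores` (per-subject data frame), `n_scored`,
#'   `n_dropped`, `dropped` (ids with reasons).
#' @export
evaluate_score <- function(cohort, score = c("caps", "caps_mt"), threshold = 3L,
                           npiq_mode = "total", decline_method = "first_last") {
  score <- match.arg(score)
  scorer <- if (score == "caps") compute_caps else compute_caps_mt
  rows <- list(); dropped <- list()
  for (s in cohort) {
    if (!identical(s$amyloid_status_reference, "positive") &&
        !identical(s$amyloid_status_reference, "negative")) {
      dropped[[s$id]] <- "no reference amyloid status"
      next
    }
    res <- tryCatch(scorer(s, threshold = threshold, npiq_mode = npiq_mode,
                           decline_method = decline_method),
                    capscore_error = function(e) e)
    if (inherits(res, "error")) {
      dropped[[s$id]] <- conditionMessage(res)
      next
    }
    total <- if (score == "caps") res$caps_total else res$caps_mt_total
    rows[[s$id]] <- data.frame(
      id = s$id,
      npiq_points = res$npiq_points, decline_points = res$decline_points,
      fazekas_points = res$fazekas_points,
      mtla_points = res$mtla_points %||% NA_integer_,
      total = total, predicted_status = res$predicted_status,
      reference_status = s$amyloid_status_reference,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) caps_error("no scoreable subjects in cohort",
                                "capscore_no_scoreable_subjects")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (length(dropped)) {
    message(sprintf("evaluate_score: dropped %d unscoreable subject(s): %s",
                    length(dropped), paste(names(dropped), collapse = ", ")))
  }
  ref_pos <- tab$reference_status == "positive"
  pred_pos <- tab$predicted_status == "positive"
  conf <- confusion_table(tp = sum(pred_pos & ref_pos),
                          fp = sum(pred_pos & !ref_pos),
                          tn = sum(!pred_pos & !ref_pos),
                          fn = sum(!pred_pos & ref_pos))
  roc <- if (any(ref_pos) && any(!ref_pos)) {
    roc_analysis(tab$total, tab$reference_status)
  } else NULL
  structure(list(confusion = conf, metrics = confusion_metrics(conf),
                 roc = roc, scores = tab,
                 n_scored = nrow(tab), n_dropped = length(dropped),
                 dropped = dropped,
                 score = score, threshold = as.integer(threshold)),
            class = "score_evaluation")
}

#' @export
print.score_evaluation <- function(x, ...) {
  cat(sprintf("<score_evaluation> %s at threshold %d: %d scored, %d dropped\n",
              toupper(gsub("_mt", "-MT", x$score)), x$threshold,
              x$n_scored, x$n_dropped))
  cat(sprintf("  confusion: tp=%d fp=%d tn=%d fn=%d\n",
              x$confusion$tp, x$confusion$fp, x$confusion$tn, x$confusion$fn))
  print(x$metrics)
  if (!is.null(x$roc)) print(x$roc)
  invisible(x)
}
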