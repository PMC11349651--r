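#' CAPS points for the NPI-Q component
#'
#' Neuropsychiatric symptom burden contributes 0, 1 or 2 points: a total
#' NPI-Q score of 0 gives 0 points, exactly 1 gives 1 point, and 2 or more
#' gives 2 points.
#'
#' @param total_npiq_score Non-negative integer NPI-Q total.
#' @return Integer points in `{0,1,2}`.
#' @export
npiq_points <- function(total_npiq_score) {
  total_npiq_score <- assert_scalar_int(total_npiq_score, "NPI-Q total", lo = 0)
  if (total_npiq_score >= 2L) 2L else as.integer(total_npiq_score)
}

#' CAPS points for the white-matter (Fazekas) component
#'
#' Little or no white matter microangiopathy (Fazekas 0 or 1) argues for
#' an amyloid rather than a vascular aetiology and scores 1 point; a
#' Fazekas rating of 2 or more scores 0.
#'
#' @param fazekas Integer Fazekas rating 0-3.
#' @return Integer points in `{0,1}`.
#' @export
fazekas_points <- function(fazekas) {
  fazekas <- assert_scalar_int(fazekas, "fazekas", lo = 0, hi = 3)
  if (fazekas <= 1L) 1L else 0L
}

#' CAPS-MT points for the medial temporal atrophy component
#'
#' A Scheltens (MTLA) rating above 2 scores 1 point in the CAPS-MT
#' extension; 2 or less scores 0.
#'
#' @param scheltens_mtla Integer Scheltens rating 0-4.
#' @return Integer points in `{0,1}`.
#' @export
mtla_points <- function(scheltens_mtla) {
  scheltens_mtla <- assert_scalar_int(scheltens_mtla, "scheltens_mtla", lo = 0, hi = 4)
  if (scheltens_mtla > 2L) 1L else 0L
}

#' Classify a point score against a positivity threshold
#'
#' @param score Integer CAPS or CAPS-MT total.
#' @param threshold Positivity threshold; scores at or above it predict
#'   amyloid positivity. Default 3 ("a score of 3 or 4").
#' @return `"positive"` or `"negative"`.
#' @export
classify <- function(score, threshold = 3L) {
  score <- assert_scalar_int(score, "score", lo = 0)
  threshold <- assert_scalar_int(threshold, "threshold", lo = 0)
  if (score >= threshold) "positive" else "negative"
}

#' Compute the CAPS score for a subject
#'
#' CAPS is the sum of three components: NPI-Q points (0/1/2 via
#' [npiq_points()]), a rapid-decline point (1 if the subject lost more
#' than 2 MMSE points per year, via [annualized_decline()]), and a
#' white-matter point (1 if Fazekas < 2, via [fazekas_points()]). The
#' total ranges 0-4 and a total at or above `threshold` (default 3)
#' predicts amyloid positivity.
#'
#' Subjects missing any of the three components (no NPI-Q, fewer than two
#' dated cognitive scores, no Fazekas rating) raise a classed error
#' (`capscore_incomplete_subject`) naming the missing component.
#'
#' @param subj A `caps_subject` (see [subject()]).
#' @param threshold Positivity threshold, default 3.
#' @param npiq_mode `"total"` (default; the total NPI-Q severity score
#'   drives the points) or `"count"` (the symptom count does; sensitivity
#'   analysis only).
#' @param decline_method Passed to [annualized_decline()].
#'
#' @return A list with class `caps_result`: per-component points,
#'   `caps_total` (0-4), `predicted_status`, `threshold_used`, and the
#'   underlying `decline` result.
#' @export
compute_caps <- function(subj, threshold = 3L,
                         npiq_mode = c("total", "count"),
                         decline_method = c("first_last", "lsq")) {
  npiq_mode <- match.arg(npiq_mode)
  decline_method <- match.arg(decline_method)
  if (!inherits(subj, "caps_subject")) {
    caps_validation_error("`subj` must be a caps_subject")
  }
  if (is.null(subj$npiq)) {
    caps_error(sprintf("subject %s: cannot score CAPS, NPI-Q profile missing", subj$id),
               "capscore_incomplete_subject")
  }
  if (nrow(subj$cognitive_scores) < 2L) {
    caps_error(sprintf(
      "subject %s: cannot score CAPS, fewer than two dated cognitive scores", subj$id),
      "capscore_incomplete_subject")
  }
  if (is.null(subj$fazekas)) {
    caps_error(sprintf("subject %s: cannot score CAPS, Fazekas rating missing", subj$id),
               "capscore_incomplete_subject")
  }
  np <- npiq_summary(subj$npiq)
  npiq_input <- if (npiq_mode == "total") np$total_score else np$symptom_count
  dec <- annualized_decline(subj, method = decline_method)
  pts_np <- npiq_points(npiq_input)
  pts_dec <- if (dec$rapid) 1L else 0L
  pts_faz <- fazekas_points(subj$fazekas)
  total <- pts_np + pts_dec + pts_faz
  structure(list(
    id = subj$id,
    npiq_points = pts_np, decline_points = pts_dec, fazekas_points = pts_faz,
    caps_total = total,
    mtla_points = NULL, caps_mt_total = NULL,
    predicted_status = classify(total, threshold),
    threshold_used = as.integer(threshold),
    decline = dec
  ), class = "caps_result")
}

#' Compute CAPS-MT (CAPS plus medial temporal atrophy)
#'
#' Extends [compute_caps()] with a fourth component: 1 point when the
#' Scheltens MTLA rating exceeds 2 ([mtla_points()]), giving a 0-5 total.
#' The positivity threshold is kept at 3 by default; because the MTLA
#' point is purely additive, the CAPS-MT decision at a given threshold is
#' never less positive than the CAPS decision. The additive form and the
#' retained threshold are this package's reading of the extension (the
#' rule was introduced as an additional binary input); both are exposed
#' so users can vary them.
#'
#' @inheritParams compute_caps
#' @return A `caps_result` with `mtla_points` and `caps_mt_total` filled
#'   in; `predicted_status` classifies `caps_mt_total` against `threshold`.
#' @export
compute_caps_mt <- function(subj, threshold = 3L,
                            npiq_mode = c("total", "count"),
                            decline_method = c("first_last", "lsq")) {
  if (!inherits(subj, "caps_subject")) {
    caps_validation_error("`subj` must be a caps_subject")
  }
  if (is.null(subj$scheltens_mtla)) {
    caps_error(sprintf(
      "subject %s: cannot score CAPS-MT, Scheltens rating missing", subj$id),
      "capscore_incomplete_subject")
  }
  res <- compute_caps(subj, threshold = threshold, npiq_mode = npiq_mode,
                      decline_method = decline_method)
  res$mtla_points <- mtla_points(subj$scheltens_mtla)
  res$caps_mt_total <- res$caps_total + res$mtla_points
  res$predicted_status <- classify(res$caps_mt_total, threshold)
  res
}

#' @export
print.caps_result <- function(x, ...) {
  mt <- if (!is.null(x$caps_mt_total)) {
    sprintf(" | MTLA %d -> CAPS-MT %d", x$mtla_points, x$caps_mt_total)
  } else ""
  cat(sprintf("<caps_result> %s: NPI-Q %d + decline %d + Fazekas %d = CAPS %d%s => %s (threshold %d)\n",
              x$id %||% "?", x$npiq_points, x$decline_points, x$fazekas_points,
              x$caps_total, mt, x$predicted_status, x$threshold_used))
  invisible(x)
}
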