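#' Is a decline rate "rapid"?
#'
#' Rapid decline is a loss of strictly more than 2 MMSE points per year.
#' A rate of exactly 2.0 is not rapid; negative rates (improvement) are
#' never rapid.
#'
#' @param rate Annualized MMSE loss in points/year (positive = decline).
#' @return Logical.
#' @export
is_rapid <- function(rate) {
  if (!is.numeric(rate) || anyNA(rate) || any(!is.finite(rate))) {
    caps_validation_error("decline rate must be finite")
  }
  rate > 2.0
}

#' Annualized MMSE decline
#'
#' Computes the rate of cognitive decline from longitudinal MMSE scores as
#' the score difference between the first and last available visit divided
#' by the intervening time (years = days / 365.25), so that a positive
#' rate means decline. Subjects without at least two dated scores cannot
#' have a rate and raise a classed error (`capscore_insufficient_scores`),
#' mirroring how such subjects are excluded from any analysis that uses
#' rapid decline as a variable.
#'
#' An alternative `method = "lsq"` fits a least-squares slope through all
#' visits; the default first-vs-last maximises the observation span and
#' matches the two-time-point definition of the rule.
#'
#' @param scores Data frame with columns `date` and `mmse` (integer,
#'   already MoCA-converted where needed), or a `caps_subject` (its
#'   [mmse_series()] is used). `date` may be a `Date` (years are
#'   days/365.25) or a plain numeric time in years.
#' @param method `"first_last"` (default) or `"lsq"`.
#'
#' @return A list with class `decline_result`: `rate` (points/year),
#'   `rapid` (logical, rate > 2), `n_timepoints`, `span_years`.
#' @examples
#' d <- data.frame(date = as.Date(c("2022-01-01", "2023-01-01")),
#'                 mmse = c(26L, 22L))
#' annualized_decline(d)$rate # 4.0 (roughly; 365.25-day year)
#' @export
annualized_decline <- function(scores, method = c("first_last", "lsq")) {
  method <- match.arg(method)
  if (inherits(scores, "caps_subject")) scores <- mmse_series(scores)
  if (!is.data.frame(scores) || !all(c("date", "mmse") %in% names(scores))) {
    caps_validation_error("`scores` must have columns date and mmse")
  }
  if (nrow(scores) < 2L) {
    caps_error(sprintf(
      "annualized decline needs at least two dated scores (got %d); subject excluded",
      nrow(scores)), "capscore_insufficient_scores")
  }
  t_years <- if (inherits(scores$date, "Date") || is.character(scores$date)) {
    d <- as.Date(scores$date)
    as.numeric(d - min(d)) / 365.25
  } else if (is.numeric(scores$date)) {
    scores$date - min(scores$date)
  } else {
    caps_validation_error("`date` must be a Date, ISO-8601 string or numeric years")
  }
  scores <- scores[order(t_years), ]
  t_years <- sort(t_years)
  n <- nrow(scores)
  span_years <- t_years[n] - t_years[1L]
  if (span_years <= 0) {
    caps_error("cognitive scores span zero time; decline rate undefined",
               "capscore_zero_span")
  }
  rate <- if (method == "first_last") {
    (scores$mmse[1L] - scores$mmse[n]) / span_years
  } else {
    # negative LS slope of mmse over time = rate of loss
    -unname(coef(stats::lm(scores$mmse ~ t_years))[2L])
  }
  structure(list(rate = rate, rapid = is_rapid(rate),
                 n_timepoints = n, span_years = span_years),
            class = "decline_result")
}
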