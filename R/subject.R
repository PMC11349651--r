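#' Construct a memory-clinic subject record
#'
#' Bundles every clinical observation the scoring pipeline consumes into a
#' validated record: demographics, longitudinal cognitive scores, the
#' NPI-Q profile, vascular and functional scales, MRI visual ratings, an
#' optional CSF panel, and the reference amyloid status against which the
#' score is evaluated.
#'
#' @param id Subject identifier (non-empty string).
#' @param age Age in years (> 0).
#' @param sex `"female"` or `"male"`.
#' @param cognitive_scores Data frame with columns `date` (coercible to
#'   `Date`), `instrument` (`"MMSE"` or `"MoCA"`) and `raw` (integer 0-30).
#'   Rows are sorted by date on construction.
#' @param npiq An [npiq_profile()] (or named severity vector).
#' @param fazekas Integer white-matter hyperintensity rating 0-3.
#' @param scheltens_mtla Optional integer medial temporal atrophy rating 0-4.
#' @param duration_of_illness Optional illness duration at presentation, years.
#' @param hachinski Optional integer Hachinski score 0-18.
#' @param lawton_brody Optional integer Lawton-Brody ADL total 0-23.
#' @param csf Optional [csf_panel()].
#' @param amyloid_status_reference `"positive"`, `"negative"` or `"unknown"`;
#'   the ground-truth label used by all evaluation operations.
#' @param reference_modality `"CSF"`, `"PET"`, `"both"` or `"none"`.
#'
#' @return A list with class `caps_subject`.
#' @export
subject <- function(id, age, sex, cognitive_scores, npiq, fazekas,
                    scheltens_mtla = NULL, duration_of_illness = NULL,
                    hachinski = NULL, lawton_brody = NULL, csf = NULL,
                    amyloid_status_reference = "unknown",
                    reference_modality = "none") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    caps_validation_error("subject `id` must be a non-empty string")
  }
  if (!is_scalar_number(age) || age <= 0) {
    caps_validation_error(sprintf("subject %s: age must be > 0", id))
  }
  sex <- match.arg(sex, c("female", "male"))
  amyloid_status_reference <- match.arg(amyloid_status_reference,
                                        c("positive", "negative", "unknown"))
  reference_modality <- match.arg(reference_modality,
                                  c("CSF", "PET", "both", "none"))
  cs <- validate_cognitive_scores(cognitive_scores, id)
  npiq <- validate_npiq(npiq)
  fazekas <- assert_scalar_int(fazekas, "fazekas", lo = 0, hi = 3)
  if (!is.null(scheltens_mtla)) {
    scheltens_mtla <- assert_scalar_int(scheltens_mtla, "scheltens_mtla",
                                        lo = 0, hi = 4)
  }
  if (!is.null(hachinski)) {
    hachinski <- assert_scalar_int(hachinski, "hachinski", lo = 0, hi = 18)
  }
  if (!is.null(lawton_brody)) {
    lawton_brody <- assert_scalar_int(lawton_brody, "lawton_brody", lo = 0, hi = 23)
  }
  if (!is.null(duration_of_illness) &&
      (!is_scalar_number(duration_of_illness) || duration_of_illness < 0)) {
    caps_validation_error(sprintf("subject %s: duration_of_illness must be >= 0", id))
  }
  if (!is.null(csf) && !inherits(csf, "csf_panel")) {
    csf <- do.call(csf_panel, as.list(csf))
  }
  structure(list(
    id = id, age = as.numeric(age), sex = sex,
    duration_of_illness = duration_of_illness,
    cognitive_scores = cs, npiq = npiq,
    hachinski = hachinski, lawton_brody = lawton_brody,
    fazekas = fazekas, scheltens_mtla = scheltens_mtla,
    csf = csf,
    amyloid_status_reference = amyloid_status_reference,
    reference_modality = reference_modality
  ), class = "caps_subject")
}

validate_cognitive_scores <- function(cs, id = "?") {
  if (is.null(cs) || (is.data.frame(cs) && nrow(cs) == 0L)) {
    return(data.frame(date = as.Date(character()), instrument = character(),
                      raw = integer()))
  }
  if (!is.data.frame(cs) || !all(c("date", "instrument", "raw") %in% names(cs))) {
    caps_validation_error(sprintf(
      "subject %s: cognitive_scores needs columns date, instrument, raw", id))
  }
  cs$date <- as.Date(cs$date)
  if (anyNA(cs$date)) {
    caps_validation_error(sprintf("subject %s: cognitive score dates must parse", id))
  }
  if (!all(cs$instrument %in% c("MMSE", "MoCA"))) {
    caps_validation_error(sprintf("subject %s: instrument must be MMSE or MoCA", id))
  }
  if (anyNA(cs$raw) || any(cs$raw != round(cs$raw)) ||
      any(cs$raw < 0) || any(cs$raw > 30)) {
    caps_validation_error(sprintf("subject %s: raw scores must be integers 0-30", id))
  }
  cs <- cs[order(cs$date), c("date", "instrument", "raw")]
  cs$raw <- as.integer(cs$raw)
  rownames(cs) <- NULL
  cs
}

#' @export
print.caps_subject <- function(x, ...) {
  cat(sprintf("<caps_subject> %s: %s, %g y, %d visit(s), NPI-Q total %d, Fazekas %d, reference %s\n",
              x$id, x$sex, x$age, nrow(x$cognitive_scores),
              npiq_summary(x$npiq)$total_score, x$fazekas,
              x$amyloid_status_reference))
  invisible(x)
}

#' MMSE-equivalent longitudinal scores for a subject
#'
#' Returns the subject's cognitive scores on the MMSE scale, converting
#' any MoCA scores via [moca_to_mmse()]. Only MMSE-equivalent scores feed
#' the decline computation.
#'
#' @param subj A `caps_subject`.
#' @return Data frame with columns `date` and `mmse`, sorted by date.
#' @export
mmse_series <- function(subj) {
  cs <- subj$cognitive_scores
  mmse <- ifelse(cs$instrument == "MoCA", moca_to_mmse(cs$raw), cs$raw)
  data.frame(date = cs$date, mmse = as.integer(mmse))
}

#' Flatten a cohort into a subject-level table
#'
#' One row per subject with the derived quantities the statistical battery
#' uses: baseline MMSE (first visit, MoCA-converted), NPI-Q total and
#' symptom count, decline rate and rapid-decline flag (NA when fewer than
#' two dated scores are available), imaging ratings and the reference label.
#'
#' @param cohort List of `caps_subject` records.
#' @return A data frame, one row per subject.
#' @export
cohort_table <- function(cohort) {
  stopifnot(length(cohort) > 0L)
  rows <- lapply(cohort, function(s) {
    ser <- mmse_series(s)
    dec <- tryCatch(annualized_decline(ser), capscore_error = function(e) NULL)
    np <- npiq_summary(s$npiq)
    data.frame(
      id = s$id, age = s$age, sex = s$sex,
      duration_of_illness = s$duration_of_illness %||% NA_real_,
      baseline_mmse = if (nrow(ser)) ser$mmse[1L] else NA_integer_,
      npiq_total = np$total_score, npiq_count = np$symptom_count,
      hachinski = s$hachinski %||% NA_integer_,
      lawton_brody = s$lawton_brody %||% NA_integer_,
      fazekas = s$fazekas,
      scheltens_mtla = s$scheltens_mtla %||% NA_integer_,
      decline_rate = if (is.null(dec)) NA_real_ else dec$rate,
      rapid_decline = if (is.null(dec)) NA else dec$rapid,
      amyloid_status_reference = s$amyloid_status_reference,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
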