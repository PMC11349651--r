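# Long-format CSV dialect: one row per subject-visit. Subject-constant
# fields are repeated on every row of that subject; per-visit fields are
# visit_date (ISO-8601), instrument (MMSE/MoCA) and cognitive_score.
# Optional fields may be empty/NA.
cohort_csv_columns <- function() {
  c("subject_id", "visit_date", "instrument", "cognitive_score",
    "age", "sex", "duration_of_illness",
    paste0("npiq_", npiq_domains()),
    "hachinski", "lawton_brody", "fazekas", "scheltens_mtla",
    "csf_abeta42", "csf_ptau", "csf_ttau",
    "csf_ptau_abeta42_ratio", "csf_ttau_abeta42_ratio",
    "amyloid_status_reference", "reference_modality")
}

na_null <- function(x) if (length(x) == 0L || is.na(x[1L])) NULL else x[1L]

#' Read a cohort from long-format CSV
#'
#' Expects one row per subject-visit (see [write_cohort_csv()] for the
#' column dialect); subject-level fields are taken from each subject's
#' first row. Dates must be ISO-8601 (`YYYY-MM-DD`).
#'
#' @param path Path to a CSV file.
#' @return List of `caps_subject` records, in first-appearance order.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) caps_validation_error(sprintf("input not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) caps_validation_error(sprintf("input is empty: %s", path))
  missing_cols <- setdiff(c("subject_id", "visit_date", "instrument",
                            "cognitive_score", "age", "sex",
                            paste0("npiq_", npiq_domains()), "fazekas"),
                          names(df))
  if (length(missing_cols)) {
    caps_validation_error(paste0("cohort CSV is missing column(s): ",
                                 paste(missing_cols, collapse = ", ")))
  }
  opt <- function(row, col) if (col %in% names(df)) na_null(row[[col]]) else NULL
  ids <- unique(df$subject_id)
  lapply(ids, function(id) {
    rows <- df[df$subject_id == id, , drop = FALSE]
    first <- rows[1L, , drop = FALSE]
    sev <- setNames(as.integer(first[paste0("npiq_", npiq_domains())]),
                    npiq_domains())
    csf_fields <- list(abeta42 = opt(first, "csf_abeta42"),
                       ptau = opt(first, "csf_ptau"),
                       ttau = opt(first, "csf_ttau"),
                       ptau_abeta42_ratio = opt(first, "csf_ptau_abeta42_ratio"),
                       ttau_abeta42_ratio = opt(first, "csf_ttau_abeta42_ratio"))
    has_csf <- any(!vapply(csf_fields, is.null, logical(1)))
    visits <- rows[!is.na(rows$visit_date) & !is.na(rows$cognitive_score), ]
    subject(
      id = as.character(id),
      age = first$age,
      sex = first$sex,
      duration_of_illness = opt(first, "duration_of_illness"),
      cognitive_scores = data.frame(date = as.Date(visits$visit_date),
                                    instrument = visits$instrument,
                                    raw = as.integer(visits$cognitive_score)),
      npiq = npiq_profile(severities = sev),
      hachinski = opt(first, "hachinski"),
      lawton_brody = opt(first, "lawton_brody"),
      fazekas = first$fazekas,
      scheltens_mtla = opt(first, "scheltens_mtla"),
      csf = if (has_csf) do.call(csf_panel, csf_fields) else NULL,
      amyloid_status_reference = opt(first, "amyloid_status_reference") %||% "unknown",
      reference_modality = opt(first, "reference_modality") %||% "none")
  })
}

#' Write a cohort to long-format CSV
#'
#' @param cohort List of `caps_subject` records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  rows <- lapply(cohort, function(s) {
    nv <- max(1L, nrow(s$cognitive_scores))
    base <- data.frame(
      subject_id = s$id,
      visit_date = if (nrow(s$cognitive_scores)) as.character(s$cognitive_scores$date) else NA,
      instrument = if (nrow(s$cognitive_scores)) s$cognitive_scores$instrument else NA,
      cognitive_score = if (nrow(s$cognitive_scores)) s$cognitive_scores$raw else NA,
      age = s$age, sex = s$sex,
      duration_of_illness = s$duration_of_illness %||% NA,
      stringsAsFactors = FALSE)
    for (d in npiq_domains()) base[[paste0("npiq_", d)]] <- s$npiq[[d]]
    base$hachinski <- s$hachinski %||% NA
    base$lawton_brody <- s$lawton_brody %||% NA
    base$fazekas <- s$fazekas
    base$scheltens_mtla <- s$scheltens_mtla %||% NA
    base$csf_abeta42 <- (s$csf %||% list())$abeta42 %||% NA
    base$csf_ptau <- (s$csf %||% list())$ptau %||% NA
    base$csf_ttau <- (s$csf %||% list())$ttau %||% NA
    base$csf_ptau_abeta42_ratio <- (s$csf %||% list())$ptau_abeta42_ratio %||% NA
    base$csf_ttau_abeta42_ratio <- (s$csf %||% list())$ttau_abeta42_ratio %||% NA
    base$amyloid_status_reference <- s$amyloid_status_reference
    base$reference_modality <- s$reference_modality
    base[rep(seq_len(nrow(base)), length.out = nv), cohort_csv_columns()]
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from nested JSON
#'
#' Accepts an array of per-subject objects with the same field names as
#' the CSV dialect, but with `cognitive_scores` nested as an array of
#' `{date, instrument, raw}` objects, `npiq` as a domain-to-severity
#' object, and `csf` as a nested object.
#'
#' @param path Path to a JSON file.
#' @return List of `caps_subject` records.
#' @export
read_cohort_json <- function(path) {
  if (!file.exists(path)) caps_validation_error(sprintf("input not found: %s", path))
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!length(recs)) caps_validation_error(sprintf("input is empty: %s", path))
  lapply(recs, function(r) {
    cs <- do.call(rbind, lapply(r$cognitive_scores, function(v) {
      data.frame(date = v$date, instrument = v$instrument, raw = v$raw)
    }))
    subject(
      id = r$id, age = r$age, sex = r$sex,
      duration_of_illness = r$duration_of_illness,
      cognitive_scores = cs,
      npiq = npiq_profile(severities = unlist(r$npiq)),
      hachinski = r$hachinski, lawton_brody = r$lawton_brody,
      fazekas = r$fazekas, scheltens_mtla = r$scheltens_mtla,
      csf = if (!is.null(r$csf)) do.call(csf_panel, r$csf) else NULL,
      amyloid_status_reference = r$amyloid_status_reference %||% "unknown",
      reference_modality = r$reference_modality %||% "none")
  })
}

#' Write a cohort to nested JSON
#'
#' @param cohort List of `caps_subject` records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_json <- function(cohort, path) {
  recs <- lapply(cohort, function(s) {
    list(id = s$id, age = s$age, sex = s$sex,
         duration_of_illness = s$duration_of_illness,
         cognitive_scores = lapply(seq_len(nrow(s$cognitive_scores)), function(i) {
           list(date = as.character(s$cognitive_scores$date[i]),
                instrument = s$cognitive_scores$instrument[i],
                raw = s$cognitive_scores$raw[i])
         }),
         npiq = as.list(unclass(s$npiq)),
         hachinski = s$hachinski, lawton_brody = s$lawton_brody,
         fazekas = s$fazekas, scheltens_mtla = s$scheltens_mtla,
         csf = if (!is.null(s$csf)) Filter(Negate(is.null), unclass(s$csf)) else NULL,
         amyloid_status_reference = s$amyloid_status_reference,
         reference_modality = s$reference_modality)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
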