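#' NPI-Q domain names
#'
#' The twelve symptom domains of the Neuropsychiatric Inventory
#' Questionnaire, each rated for severity 0 (absent) to 3 (severe).
#'
#' @return Character vector of the 12 canonical domain names.
#' @export
npiq_domains <- function() {
  c("delusions", "hallucinations", "agitation", "apathy", "anxiety",
    "depression", "euphoria", "disinhibition", "irritability",
    "aberrant_motor_behavior", "sleeping_disorder", "appetite_disturbance")
}

#' Construct an NPI-Q severity profile
#'
#' Builds a validated 12-domain severity profile. Domains not supplied are
#' recorded as 0 (symptom absent), mirroring how untriggered NPI-Q items
#' are scored in practice.
#'
#' @param ... Named integer severities in `{0,1,2,3}`, names drawn from
#'   [npiq_domains()] (e.g. `depression = 2, irritability = 1`).
#' @param severities Alternatively, a named numeric vector of severities;
#'   overrides `...` when supplied.
#'
#' @return A named integer vector of length 12 with class `npiq_profile`.
#' @examples
#' p <- npiq_profile(depression = 1, irritability = 1)
#' npiq_summary(p)
#' @export
npiq_profile <- function(..., severities = NULL) {
  vals <- severities %||% unlist(list(...))
  out <- setNames(integer(12L), npiq_domains())
  if (length(vals)) {
    if (is.null(names(vals)) || any(!nzchar(names(vals)))) {
      caps_validation_error("NPI-Q severities must be named by domain")
    }
    bad <- setdiff(names(vals), npiq_domains())
    if (length(bad)) {
      caps_validation_error(paste0("unknown NPI-Q domain(s): ",
                                   paste(bad, collapse = ", ")))
    }
    for (d in names(vals)) {
      out[[d]] <- assert_scalar_int(vals[[d]], paste0("severity of '", d, "'"),
                                    lo = 0, hi = 3)
    }
  }
  structure(out, class = "npiq_profile")
}

validate_npiq <- function(profile) {
  if (inherits(profile, "npiq_profile")) {
    x <- unclass(profile)
  } else if (is.numeric(profile) && !is.null(names(profile))) {
    x <- profile
  } else {
    caps_validation_error("NPI-Q profile must be an `npiq_profile` or a named numeric vector")
  }
  if (length(x) != 12L || !setequal(names(x), npiq_domains())) {
    caps_validation_error("NPI-Q profile must cover exactly the 12 canonical domains")
  }
  x <- x[npiq_domains()]
  for (d in names(x)) {
    if (!is_scalar_number(x[[d]]) || x[[d]] != round(x[[d]]) ||
        x[[d]] < 0 || x[[d]] > 3) {
      caps_validation_error(sprintf(
        "NPI-Q severity for domain '%s' must be an integer in 0-3 (got %s)",
        d, format(x[[d]])))
    }
  }
  structure(setNames(as.integer(x), names(x)), class = "npiq_profile")
}

#' Summarise an NPI-Q profile
#'
#' Derives the two aggregate quantities used throughout the pipeline: the
#' total severity score (sum over the 12 domains, range 0-36) and the
#' symptom count (number of domains with severity above 0, range 0-12).
#'
#' @param profile An [npiq_profile()] or named severity vector.
#'
#' @return A list with integer elements `total_score` and `symptom_count`.
#' @export
npiq_summary <- function(profile) {
  x <- validate_npiq(profile)
  list(total_score = as.integer(sum(x)),
       symptom_count = as.integer(sum(x > 0L)))
}
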