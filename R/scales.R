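# MoCA -> MMSE crosswalk anchors (de-duplicated, sorted). These are the
# weighted-mean equivalences for the score range seen clinically; between
# anchors the conversion is linear, below the lowest anchor it extrapolates
# the first segment's slope (floored at 0), and 30 maps to 30.
.moca_anchors <- data.frame(
  moca = c(11L, 12L, 13L, 14L, 15L, 18L, 21L, 24L, 25L, 26L, 28L, 30L),
  mmse = c(18L, 19L, 20L, 20L, 21L, 24L, 26L, 28L, 28L, 29L, 29L, 30L)
)

round_half_up <- function(x) floor(x + 0.5)

#' Convert a MoCA score to its MMSE equivalent
#'
#' Maps a Montreal Cognitive Assessment score (0-30) onto the MMSE scale
#' using a weighted-mean crosswalk: anchor scores are reproduced exactly,
#' scores between anchors are linearly interpolated, scores below the
#' lowest anchor are extrapolated with the first segment's slope (floored
#' at 0), and the result is rounded half-up to the nearest integer. The
#' conversion is monotone non-decreasing over the whole 0-30 range.
#'
#' @param moca Integer MoCA score(s) in 0-30 (vectorised).
#'
#' @return Integer MMSE equivalent(s) in 0-30.
#' @examples
#' moca_to_mmse(15) # 21
#' moca_to_mmse(16) # 22, interpolated
#' @export
moca_to_mmse <- function(moca) {
  if (!is.numeric(moca) || anyNA(moca) || any(moca != round(moca)) ||
      any(moca < 0) || any(moca > 30)) {
    caps_validation_error("MoCA score must be an integer in 0-30")
  }
  a <- .moca_anchors
  slope0 <- (a$mmse[2L] - a$mmse[1L]) / (a$moca[2L] - a$moca[1L])
  out <- vapply(as.integer(moca), function(m) {
    hit <- match(m, a$moca)
    if (!is.na(hit)) return(as.numeric(a$mmse[hit]))
    if (m < a$moca[1L]) {
      return(max(0, a$mmse[1L] - slope0 * (a$moca[1L] - m)))
    }
    i <- findInterval(m, a$moca)
    a$mmse[i] + (m - a$moca[i]) *
      (a$mmse[i + 1L] - a$mmse[i]) / (a$moca[i + 1L] - a$moca[i])
  }, numeric(1))
  as.integer(pmin(30, round_half_up(out)))
}

#' Classify a Hachinski Ischemic Score
#'
#' A Hachinski score above 4 suggests vascular dementia; 4 or less favours
#' a primary degenerative (non-vascular) aetiology.
#'
#' @param score Non-negative integer Hachinski score (0-18).
#' @return `"vascular"` or `"non_vascular"`.
#' @export
hachinski_class <- function(score) {
  score <- assert_scalar_int(score, "hachinski", lo = 0, hi = 18)
  if (score > 4L) "vascular" else "non_vascular"
}

#' Stage disease severity from the Lawton-Brody ADL total
#'
#' Full independence in activities of daily living (23/23) is taken as the
#' prodromal (MCI) stage; any documented restriction classifies the
#' presentation as clinical dementia stage.
#'
#' @param lawton_total Integer Lawton-Brody total in 0-23.
#' @return `"prodromal"` or `"dementia"`.
#' @export
adl_stage <- function(lawton_total) {
  lawton_total <- assert_scalar_int(lawton_total, "lawton_brody", lo = 0, hi = 23)
  if (lawton_total == 23L) "prodromal" else "dementia"
}

# CSF cut-offs (ng/L for absolutes; ratios dimensionless). Values on the
# abnormal side of the printed normal bounds classify as amyloid positive.
.csf_cutoffs <- list(abeta42_low = 1030, ptau_ratio = 0.024, ttau_ratio = 0.29)

#' Build a CSF biomarker panel
#'
#' @param abeta42,ptau,ttau Concentrations in ng/L (optional, positive).
#' @param ptau_abeta42_ratio,ttau_abeta42_ratio Precomputed ratios
#'   (optional). When a ratio and both of its inputs are present they must
#'   agree with element-wise division within 5% relative tolerance.
#' @return A list with class `csf_panel`.
#' @export
csf_panel <- function(abeta42 = NULL, ptau = NULL, ttau = NULL,
                      ptau_abeta42_ratio = NULL, ttau_abeta42_ratio = NULL) {
  p <- list(abeta42 = abeta42, ptau = ptau, ttau = ttau,
            ptau_abeta42_ratio = ptau_abeta42_ratio,
            ttau_abeta42_ratio = ttau_abeta42_ratio)
  for (nm in c("abeta42", "ptau", "ttau")) {
    if (!is.null(p[[nm]])) {
      if (!is_scalar_number(p[[nm]]) || p[[nm]] <= 0) {
        caps_validation_error(sprintf("CSF %s must be a positive concentration", nm))
      }
    }
  }
  check_ratio <- function(ratio, num, name) {
    if (is.null(ratio)) return(invisible())
    if (!is_scalar_number(ratio) || ratio <= 0) {
      caps_validation_error(sprintf("CSF %s must be positive", name))
    }
    if (!is.null(num) && !is.null(p$abeta42)) {
      implied <- num / p$abeta42
      if (abs(ratio - implied) > 0.05 * implied) {
        caps_validation_error(sprintf(
          "CSF %s (%.4f) inconsistent with analyte quotient (%.4f)",
          name, ratio, implied))
      }
    }
  }
  check_ratio(p$ptau_abeta42_ratio, p$ptau, "ptau_abeta42_ratio")
  check_ratio(p$ttau_abeta42_ratio, p$ttau, "ttau_abeta42_ratio")
  structure(p, class = "csf_panel")
}

#' Determine amyloid status from a CSF panel
#'
#' Applies the biomarker cut-offs with ratio precedence: if a tau/Abeta42
#' ratio is available (given directly or computable from the analytes),
#' the subject is positive when ptau/Abeta42 >= 0.024 or
#' ttau/Abeta42 >= 0.29. Only when no ratio is available does the absolute
#' rule apply: positive when Abeta42 <= 1030 ng/L. Borderline equality
#' counts as positive. The rule that decided is recorded in `basis`.
#'
#' @param panel A [csf_panel()].
#' @return A list with class `amyloid_status`: `status`
#'   (`"positive"`/`"negative"`) and `basis` (`"csf_ratio"`/`"csf_absolute"`).
#' @export
csf_amyloid_status <- function(panel) {
  if (!inherits(panel, "csf_panel")) panel <- do.call(csf_panel, as.list(panel))
  pr <- panel$ptau_abeta42_ratio
  tr <- panel$ttau_abeta42_ratio
  if (is.null(pr) && !is.null(panel$ptau) && !is.null(panel$abeta42)) {
    pr <- panel$ptau / panel$abeta42
  }
  if (is.null(tr) && !is.null(panel$ttau) && !is.null(panel$abeta42)) {
    tr <- panel$ttau / panel$abeta42
  }
  if (!is.null(pr) || !is.null(tr)) {
    pos <- (!is.null(pr) && pr >= .csf_cutoffs$ptau_ratio) ||
           (!is.null(tr) && tr >= .csf_cutoffs$ttau_ratio)
    return(structure(list(status = if (pos) "positive" else "negative",
                          basis = "csf_ratio"), class = "amyloid_status"))
  }
  if (!is.null(panel$abeta42)) {
    pos <- panel$abeta42 <= .csf_cutoffs$abeta42_low
    return(structure(list(status = if (pos) "positive" else "negative",
                          basis = "csf_absolute"), class = "amyloid_status"))
  }
  caps_error("CSF panel has no usable analyte; amyloid status indeterminate",
             "capscore_indeterminate_csf")
}
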