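#' Two-group comparison with a normality gate
#'
#' Reproduces the usual clinical-cohort comparison battery. Continuous
#' variables are first screened for normality in each group with the
#' Lilliefors-corrected Kolmogorov-Smirnov test (mean and SD estimated
#' from the data, alpha = 0.05 per group); if both groups pass, the
#' groups are compared with an independent-samples t-test, otherwise with
#' the Mann-Whitney (Wilcoxon rank-sum) test. Categorical variables are
#' compared with a chi-square test of independence (Yates continuity
#' correction off by default for 2x2 tables).
#'
#' @param cohort Either a list of `caps_subject` records (the variable is
#'   looked up in [cohort_table()] and groups are the reference amyloid
#'   labels) or a data frame with a `group` column and the variable column.
#' @param variable Name of the variable to compare (e.g. `"baseline_mmse"`,
#'   `"npiq_total"`, `"age"`, `"sex"`).
#' @param type `"auto"` (numeric -> continuous, otherwise categorical),
#'   `"continuous"` or `"categorical"`.
#' @param alpha_normality Per-group alpha for the normality gate.
#' @param yates Use Yates continuity correction in the chi-square test.
#'
#' @return A list with class `group_comparison`: `variable`, `test`
#'   (`"t"`, `"mann_whitney"` or `"chi_square"`), `statistic`, `p_value`,
#'   per-group `summary` (mean/sd/n or proportions), and
#'   `normality_p` for the gated path.
#' @export
compare_groups <- function(cohort, variable,
                           type = c("auto", "continuous", "categorical"),
                           alpha_normality = 0.05, yates = FALSE) {
  type <- match.arg(type)
  if (is.data.frame(cohort)) {
    df <- cohort
    if (!"group" %in% names(df)) {
      caps_validation_error("data-frame input needs a `group` column")
    }
  } else {
    df <- cohort_table(cohort)
    df$group <- df$amyloid_status_reference
  }
  if (!variable %in% names(df)) {
    caps_validation_error(sprintf("variable '%s' not found", variable))
  }
  keep <- !is.na(df[[variable]]) & !is.na(df$group)
  x <- df[[variable]][keep]
  g <- as.character(df$group)[keep]
  lev <- sort(unique(g))
  if (length(lev) != 2L) {
    caps_validation_error("compare_groups needs exactly two groups")
  }
  xs <- split(x, factor(g, levels = lev))
  if (any(vapply(xs, length, integer(1)) < 2L)) {
    caps_validation_error("each group needs at least two observations")
  }
  if (type == "auto") {
    type <- if (is.numeric(x) && length(unique(x)) > 2L) "continuous" else "categorical"
  }

  if (type == "continuous") {
    if (!is.numeric(x)) caps_validation_error("continuous comparison needs numeric data")
    if (any(vapply(xs, function(v) sd(v) == 0, logical(1)))) {
      caps_error("a group has zero variance; t-test path degenerate",
                 "capscore_degenerate_variance")
    }
    norm_p <- vapply(xs, function(v) {
      if (length(v) < 4L) return(NA_real_)  # Lilliefors needs n >= 4
      nortest::lillie.test(v)$p.value
    }, numeric(1))
    gaussian <- all(!is.na(norm_p) & norm_p > alpha_normality)
    if (gaussian) {
      ht <- t.test(xs[[1L]], xs[[2L]])
      test <- "t"
    } else {
      ht <- suppressWarnings(wilcox.test(xs[[1L]], xs[[2L]], exact = FALSE))
      test <- "mann_whitney"
    }
    summ <- lapply(xs, function(v) list(mean = mean(v), sd = sd(v), n = length(v)))
  } else {
    tab <- table(factor(g, levels = lev), x)
    if (ncol(tab) < 2L) {
      # identical composition in both groups: no association by construction
      return(structure(list(variable = variable, test = "chi_square",
                            statistic = 0, p_value = 1,
                            summary = lapply(xs, table), normality_p = NULL),
                       class = "group_comparison"))
    }
    ht <- suppressWarnings(chisq.test(tab, correct = yates))
    test <- "chi_square"
    summ <- lapply(xs, function(v) as.list(prop.table(table(v))))
    norm_p <- NULL
  }
  structure(list(variable = variable, test = test,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 summary = setNames(summ, lev),
                 normality_p = if (type == "continuous") norm_p else NULL),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s test, statistic %.3f, p = %.4g\n",
              x$variable, x$test, x$statistic, x$p_value))
  invisible(x)
}
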