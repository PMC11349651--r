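#' Pipeline run configuration
#'
#' @param input Path to a cohort file (`.csv` long format or `.json`
#'   nested; see [read_cohort_csv()] / [read_cohort_json()]).
#' @param score `"caps"` or `"caps_mt"`.
#' @param threshold Positivity threshold (default 3).
#' @param npiq_mode `"total"` or `"count"` (see [compute_caps()]).
#' @param decline_method `"first_last"` or `"lsq"`.
#' @param seed Integer seed recorded in the report (the scoring pipeline
#'   itself is deterministic; the seed matters when the input cohort is
#'   generated on the fly).
#' @param output Optional path for the JSON report.
#' @param scored_output Optional path for the per-subject scored CSV.
#' @param config_file Optional YAML file whose top-level keys override
#'   the defaults above (explicit arguments win over the file).
#'
#' @return A list with class `run_config`.
#' @export
run_config <- function(input, score = "caps", threshold = 3L,
                       npiq_mode = "total", decline_method = "first_last",
                       seed = 1L, output = NULL, scored_output = NULL,
                       config_file = NULL) {
  cfg <- list(input = input, score = score, threshold = threshold,
              npiq_mode = npiq_mode, decline_method = decline_method,
              seed = seed, output = output, scored_output = scored_output)
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      caps_validation_error(sprintf("config file not found: %s", config_file))
    }
    file_cfg <- yaml::read_yaml(config_file)
    supplied <- names(as.list(match.call())[-1])
    for (k in intersect(names(file_cfg), names(cfg))) {
      if (!k %in% supplied) cfg[[k]] <- file_cfg[[k]]
    }
  }
  cfg$score <- match.arg(cfg$score, c("caps", "caps_mt"))
  cfg$npiq_mode <- match.arg(cfg$npiq_mode, c("total", "count"))
  cfg$decline_method <- match.arg(cfg$decline_method, c("first_last", "lsq"))
  cfg$threshold <- assert_scalar_int(cfg$threshold, "threshold", lo = 0)
  cfg$seed <- assert_scalar_int(cfg$seed, "seed")
  if (!is.character(cfg$input) || !file.exists(cfg$input)) {
    caps_validation_error(sprintf("input not resolvable: %s", cfg$input))
  }
  structure(cfg, class = "run_config")
}

read_cohort <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    read_cohort_json(path)
  } else {
    read_cohort_csv(path)
  }
}

#' Run the end-to-end scoring pipeline
#'
#' Reads a cohort, validates it, computes MMSE-equivalent series and
#' decline, scores CAPS (or CAPS-MT), evaluates the score against the
#' reference amyloid status, and assembles a machine-readable report:
#' package version, configuration echo (including the seed), per-subject
#' component points and totals, excluded subjects with reasons, the
#' confusion table, operating characteristics and ROC summary. The report
#' is checked against the shipped report schema before it is returned or
#' written. Runs are idempotent for a fixed input and configuration.
#'
#' @param config A [run_config()].
#' @return The report, invisibly as a list (also written to
#'   `config$output` as JSON and `config$scored_output` as CSV when set).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) caps_validation_error("need a run_config")
  cohort <- read_cohort(config$input)
  ev <- evaluate_score(cohort, score = config$score,
                       threshold = config$threshold,
                       npiq_mode = config$npiq_mode,
                       decline_method = config$decline_method)
  roc_summary <- if (!is.null(ev$roc)) {
    list(auc = ev$roc$auc, auc_ci_95 = ev$roc$auc_ci_95,
         method = ev$roc$method,
         points = data.frame(threshold = ev$roc$thresholds,
                             tpr = ev$roc$tpr, fpr = ev$roc$fpr))
  } else NULL
  report <- list(
    package = "capscore",
    version = as.character(packageVersion("capscore")),
    schema_version = report_schema()$version,
    config = list(input = config$input, score = config$score,
                  threshold = config$threshold, npiq_mode = config$npiq_mode,
                  decline_method = config$decline_method, seed = config$seed),
    n_subjects = length(cohort),
    n_scored = ev$n_scored,
    excluded = lapply(names(ev$dropped), function(id) {
      list(id = id, reason = ev$dropped[[id]])
    }),
    subject_scores = ev$scores,
    confusion = unclass(ev$confusion)[c("tp", "fp", "tn", "fn")],
    metrics = unclass(ev$metrics)[c("sensitivity", "specificity", "ppv",
                                    "npv", "lr_positive", "lr_negative")],
    roc = roc_summary)
  validate_report(report)
  if (!is.null(config$output)) {
    jsonlite::write_json(report, config$output, auto_unbox = TRUE,
                         digits = NA, na = "null", null = "null",
                         dataframe = "rows")
  }
  if (!is.null(config$scored_output)) {
    write.csv(ev$scores, config$scored_output, row.names = FALSE)
  }
  invisible(report)
}

report_schema <- function() {
  path <- system.file("schema", "report.schema.json", package = "capscore")
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

# Structural validation of a pipeline report against the shipped schema:
# required keys must be present and of the declared primitive type.
validate_report <- function(report) {
  schema <- report_schema()
  check_node <- function(node, obj, where) {
    for (key in names(node$required)) {
      spec <- node$required[[key]]
      if (!key %in% names(obj) ||
          (is.null(obj[[key]]) && !isTRUE(spec$nullable))) {
        caps_error(sprintf("report missing required field %s.%s", where, key),
                   "capscore_report_schema_error")
      }
      val <- obj[[key]]
      if (is.null(val)) next
      ok <- switch(spec$type,
                   string = is.character(val),
                   integer = is.numeric(val) && all(val == round(val)),
                   number = is.numeric(val),
                   object = is.list(val),
                   array = is.list(val) || is.data.frame(val),
                   TRUE)
      if (!ok) {
        caps_error(sprintf("report field %s.%s is not of type %s",
                           where, key, spec$type),
                   "capscore_report_schema_error")
      }
      if (!is.null(spec$required)) check_node(spec, val, paste0(where, ".", key))
    }
  }
  check_node(schema, report, "report")
  invisible(TRUE)
}
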