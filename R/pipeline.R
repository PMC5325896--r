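# End-to-end validation pipeline: simulate/load -> classify -> evaluate
# -> report.  The bundle mirrors the full assessment battery: baseline
# summary, screening characteristics with CIs, ROC/AUC, calibration, and
# Brier score with decomposition.

REPORT_SCHEMA_VERSION <- "1"

#' Pipeline run configuration
#'
#' @param input `"fixture"`, `"stochastic"`, or a path to a cohort CSV.
#' @param seed integer seed driving any simulation.
#' @param rule_variant bundled rule name (`"tirc-table2"`,
#'   `"tirc-methods"`) or a `tirc_rule` object.
#' @param ci a [ci_config()].
#' @param score_kind ROC score: `"binary"` (the rule decision) or
#'   `"count"` (number of firing criteria, mandatory-only positives
#'   scored 1 so that thresholding at >= 1 reproduces the rule).
#' @param prediction_kind probability construction for Brier/calibration:
#'   `"stratum_rate"` (observed injury rate of the patient's rule
#'   stratum; the construction a checklist rule supports) or
#'   `"binary_label"` (the 0/1 decision itself).
#' @param spec a [cohort_spec()] for simulated inputs.
#' @param output_dir optional directory for the report bundle files.
#' @return a `run_config` object.
#' @export
run_config <- function(input = "fixture", seed = 1L,
                       rule_variant = "tirc-table2",
                       ci = ci_config(),
                       score_kind = c("binary", "count"),
                       prediction_kind = c("stratum_rate", "binary_label"),
                       spec = NULL,
                       output_dir = NULL) {
  score_kind <- match.arg(score_kind)
  prediction_kind <- match.arg(prediction_kind)
  rule <- if (inherits(rule_variant, "tirc_rule")) rule_variant
          else tirc_rule(rule_variant)
  if (!input %in% c("fixture", "stochastic") && !file.exists(input))
    abort_config(sprintf("input must be 'fixture', 'stochastic' or an existing file; got '%s'", input))
  structure(list(input = input, seed = as.integer(seed), rule = rule,
                 ci = ci, score_kind = score_kind,
                 prediction_kind = prediction_kind, spec = spec,
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full validation pipeline
#'
#' Obtains a cohort (simulated or from file), classifies it with the
#' configured rule, and evaluates discrimination, calibration and overall
#' performance.  Identical config and seed give an identical bundle; when
#' `output_dir` is set, a versioned JSON report (full-precision values
#' plus display-rounded twins), ROC and calibration point CSVs, the
#' cohort CSV and a run log are written there.
#'
#' @param config a [run_config()].
#' @return a `tirc_report_bundle` list: `cohort_summary`, `confusion`,
#'   `screening`, `roc`, `auc`, `brier`, `calibration`, `triage`,
#'   `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- "input"
  bundle <- tryCatch({
    cohort <- switch(config$input,
      fixture = generate_fixture(config$spec %||% cohort_spec(),
                                 seed = config$seed),
      stochastic = generate_stochastic(
        config$spec %||% cohort_spec(mode = "stochastic"),
        seed = config$seed),
      read_cohort(config$input))

    stage <- "classify"
    triage <- classify_cohort(cohort, config$rule)
    ct <- confusion_table(triage, cohort)

    stage <- "screening"
    screening <- screening_report(ct, config$ci)

    stage <- "discrimination"
    scores <- if (config$score_kind == "binary")
      as.integer(triage$rule_positive)
    else pmax(triage$criteria_count, as.integer(triage$rule_positive))
    roc <- roc_from_scores(scores, cohort$cxr_positive,
                           score_kind = if (config$score_kind == "binary")
                             "binary_rule" else "criteria_count")

    stage <- "overall_performance"
    predictions <- if (config$prediction_kind == "stratum_rate")
      stratum_predictions(triage, cohort,
                          by = if (config$score_kind == "binary") "rule"
                               else "count")
    else as.numeric(triage$rule_positive)
    brier <- brier_score(predictions, cohort$cxr_positive,
                         prediction_kind = config$prediction_kind)

    stage <- "calibration"
    strata <- calibration_strata(predictions, cohort$cxr_positive)
    calibration <- calibration_fit(strata,
                                   config$ci$confidence_level)

    stage <- "summary"
    structure(list(cohort_summary = describe_cohort(cohort),
                   confusion = ct, screening = screening, roc = roc,
                   auc = auc(roc), brier = brier,
                   calibration = calibration, triage = triage,
                   config = config),
              class = "tirc_report_bundle")
  }, tircval_error = function(e) {
    tirc_error(sprintf("[stage %s] %s", stage, conditionMessage(e)),
               sub("^tircval_(.*)_error$", "\\1", class(e)[1]))
  })
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

round_list <- function(x, digits = 1) lapply(x, round_half_up, digits)

bundle_as_json_list <- function(bundle) {
  ct <- bundle$confusion
  est <- bundle$screening$estimates
  full <- setNames(lapply(seq_len(nrow(est)), function(i)
    list(estimate = est$estimate[i], lower = est$lower[i],
         upper = est$upper[i])), est$metric)
  display <- setNames(lapply(seq_len(nrow(est)), function(i)
    round_list(list(estimate = est$estimate[i], lower = est$lower[i],
                    upper = est$upper[i]))), est$metric)
  list(schema_version = REPORT_SCHEMA_VERSION,
       package_version = as.character(utils::packageVersion("tircval")),
       config = list(input = bundle$config$input, seed = bundle$config$seed,
                     rule_variant = bundle$config$rule$variant,
                     score_kind = bundle$config$score_kind,
                     prediction_kind = bundle$config$prediction_kind,
                     confidence_level = bundle$config$ci$confidence_level,
                     proportion_ci_method = bundle$config$ci$proportion_method),
       confusion = list(tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn),
       screening = full,
       screening_display = display,
       auc = bundle$auc,
       brier = bundle$brier[c("brier", "reliability", "resolution",
                              "uncertainty", "scaled_reliability")],
       calibration = list(method = bundle$calibration$method,
                          intercept = bundle$calibration$intercept,
                          slope = bundle$calibration$slope))
}

write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    abort_io(sprintf("cannot create output directory '%s'", dir))
  jsonlite::write_json(bundle_as_json_list(bundle),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(as.data.frame(bundle$roc), file.path(dir, "roc_points.csv"),
            row.names = FALSE)
  write.csv(bundle$calibration$strata,
            file.path(dir, "calibration_points.csv"), row.names = FALSE)
  cfg_json <- jsonlite::toJSON(bundle_as_json_list(bundle)$config,
                               auto_unbox = TRUE)
  log_lines <- c(
    sprintf("tircval %s | R %s", utils::packageVersion("tircval"),
            getRversion()),
    sprintf("seed: %d", bundle$config$seed),
    sprintf("config: %s", cfg_json),
    sprintf("cohort: n = %d", bundle$cohort_summary$n),
    sprintf("confusion: tp=%d fp=%d fn=%d tn=%d", bundle$confusion$tp,
            bundle$confusion$fp, bundle$confusion$fn, bundle$confusion$tn))
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.tirc_report_bundle <- function(x, ...) {
  cat("== TIRC validation report ==\n")
  print(x$screening)
  cat(sprintf("AUC (%s score): %.4f\n", x$config$score_kind, x$auc))
  print(x$brier)
  print(x$calibration)
  invisible(x)
}
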