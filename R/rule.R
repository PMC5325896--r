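# The TIRC decision rule.
#
# TIRC flags a blunt-trauma patient for chest radiography when either a
# mandatory condition holds (unstable hemodynamics, loss of consciousness)
# or any one of a checklist of exam/history criteria is present.  Two
# published criterion lists circulate: the list that generated the
# published screening table ("tirc-table2", 8 items) and a shorter list
# from the model description ("tirc-methods", 5 items + the mandatory
# pair).  Both ship; "tirc-table2" is the default.

CRITERIA_TABLE2 <- c("age_over_60", "crepitation", "loss_of_consciousness",
                     "decreased_pulmonary_sounds", "chest_wall_pain",
                     "chest_wall_tenderness", "dyspnea",
                     "thoracic_skin_abrasion")

CRITERIA_METHODS <- c("age_over_60", "crepitation",
                      "decreased_pulmonary_sounds", "thoracic_skin_abrasion",
                      "dyspnea")

#' Define a TIRC rule
#'
#' @param variant bundled criterion list: `"tirc-table2"` (default; the
#'   8-item list behind the published screening characteristics) or
#'   `"tirc-methods"` (the shorter model-description list).  Ignored when
#'   `any_of_criteria` is supplied.
#' @param any_of_criteria character vector of criterion names; each must
#'   be a logical patient field or the derived predicate `age_over_60`.
#' @param mandatory_conditions predicates that mandate imaging regardless
#'   of the checklist.
#' @param age_threshold age cut-point in years for the age criterion.
#' @param age_comparison `"greater_or_equal"` (default; the published
#'   cohort bins age at "< 60 / >= 60") or `"strictly_greater"`.
#' @return a `tirc_rule` object.
#' @export
#' @examples
#' rule <- tirc_rule()
#' rule$any_of_criteria
tirc_rule <- function(variant = c("tirc-table2", "tirc-methods"),
                      any_of_criteria = NULL,
                      mandatory_conditions = c("hemodynamic_unstable",
                                               "loss_of_consciousness"),
                      age_threshold = 60,
                      age_comparison = c("greater_or_equal",
                                         "strictly_greater")) {
  if (is.null(any_of_criteria)) {
    variant <- tryCatch(match.arg(variant),
                        error = function(e) abort_config(sprintf(
                          "unknown rule variant '%s'; available: tirc-table2, tirc-methods",
                          variant[1])))
    any_of_criteria <- switch(variant,
                              "tirc-table2" = CRITERIA_TABLE2,
                              "tirc-methods" = CRITERIA_METHODS)
  } else {
    variant <- "custom"
  }
  if (length(any_of_criteria) == 0)
    abort_config("any_of_criteria must be non-empty")
  age_comparison <- match.arg(age_comparison)
  known <- c(BOOL_COLUMNS[BOOL_COLUMNS != "cxr_positive"], "age_over_60")
  bad <- setdiff(c(any_of_criteria, mandatory_conditions), known)
  if (length(bad))
    abort_config(sprintf("criterion name(s) not resolvable: %s",
                         paste(bad, collapse = ", ")))
  structure(list(variant = variant,
                 mandatory_conditions = mandatory_conditions,
                 any_of_criteria = any_of_criteria,
                 age_threshold = age_threshold,
                 age_comparison = age_comparison),
            class = "tirc_rule")
}

#' Load a rule definition from a JSON config file
#'
#' The file may give either `variant` or explicit `any_of_criteria`, plus
#' optional `mandatory_conditions`, `age_threshold`, `age_comparison`.
#'
#' @param path JSON file path.
#' @return a `tirc_rule`.
#' @export
read_rule <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(cfg$variant)) args$variant <- cfg$variant
  for (f in c("any_of_criteria", "mandatory_conditions", "age_threshold",
              "age_comparison"))
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  do.call(tirc_rule, args)
}

#' @export
print.tirc_rule <- function(x, ...) {
  cat(sprintf("<tirc_rule> variant: %s\n", x$variant))
  cat("  mandatory:", paste(x$mandatory_conditions, collapse = ", "), "\n")
  cat("  any of:   ", paste(x$any_of_criteria, collapse = ", "), "\n")
  cat(sprintf("  age criterion: age %s %d\n",
              if (x$age_comparison == "greater_or_equal") ">=" else ">",
              x$age_threshold))
  invisible(x)
}

# Logical matrix, one column per predicate, evaluated over the cohort.
criterion_matrix <- function(cohort, predicates, rule) {
  m <- vapply(predicates, function(p) {
    if (p == "age_over_60") {
      if (rule$age_comparison == "greater_or_equal")
        cohort$age >= rule$age_threshold
      else cohort$age > rule$age_threshold
    } else cohort[[p]]
  }, logical(nrow(cohort)))
  matrix(m, nrow = nrow(cohort), dimnames = list(NULL, predicates))
}

#' Classify a cohort with a TIRC rule
#'
#' Pure function: each patient is rule-positive iff a mandatory condition
#' holds or at least one checklist criterion fires.
#'
#' @param cohort a valid `tirc_cohort`.
#' @param rule a `tirc_rule` (default rule if omitted).
#' @return a `tirc_triage` data.frame, one row per patient in cohort
#'   order: `patient_id`, `rule_positive`, `mandatory_branch`,
#'   `criteria_count` (number of checklist criteria firing; usable as an
#'   ordinal ROC score), `fired_criteria` (semicolon-joined names).
#' @export
classify_cohort <- function(cohort, rule = tirc_rule()) {
  validate_cohort(cohort)
  stopifnot(inherits(rule, "tirc_rule"))
  crit <- criterion_matrix(cohort, rule$any_of_criteria, rule)
  mand <- criterion_matrix(cohort, rule$mandatory_conditions, rule)
  count <- as.integer(rowSums(crit))
  mandatory_branch <- rowSums(mand) > 0
  fired <- apply(crit, 1, function(r)
    paste(rule$any_of_criteria[r], collapse = ";"))
  structure(data.frame(patient_id = cohort$patient_id,
                       rule_positive = mandatory_branch | count > 0,
                       mandatory_branch = mandatory_branch,
                       criteria_count = count,
                       fired_criteria = fired,
                       row.names = NULL),
            class = c("tirc_triage", "data.frame"),
            rule = rule)
}

#' Evaluate the rule on a single patient record
#'
#' @param record a one-row data.frame (or coercible list) with the cohort
#'   schema fields.
#' @param rule a `tirc_rule`.
#' @return a list: `patient_id`, `rule_positive`, `mandatory_branch`,
#'   `criteria_count`, `fired_criteria` (character vector).
#' @export
evaluate_rule <- function(record, rule = tirc_rule()) {
  df <- as.data.frame(record, stringsAsFactors = FALSE)
  if (nrow(df) != 1) abort_validation("record must be a single patient row")
  tri <- classify_cohort(new_cohort(df), rule)
  list(patient_id = tri$patient_id,
       rule_positive = tri$rule_positive,
       mandatory_branch = tri$mandatory_branch,
       criteria_count = tri$criteria_count,
       fired_criteria = if (nzchar(tri$fired_criteria))
         strsplit(tri$fired_criteria, ";", fixed = TRUE)[[1]] else character(0))
}
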