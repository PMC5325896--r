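# Patient data model and CSV input/output.
#
# A cohort is a plain data.frame (class "tirc_cohort") with one row per
# patient and the fixed column set returned by cohort_schema().  Booleans
# are stored as logical in memory and serialised 0/1 in CSV; the
# injury_types column is a semicolon-joined token string ("" = no injury).

INJURY_TYPES <- c("hemothorax", "pneumothorax", "rib_fracture",
                  "sternum_fracture", "scapula_fracture", "clavicle_fracture",
                  "widened_mediastinum", "lung_contusion")

MECHANISMS <- c("motor_vehicle_collision", "fall", "other")

BOOL_COLUMNS <- c("hemodynamic_unstable", "loss_of_consciousness", "dyspnea",
                  "distracting_pain", "thoracic_skin_abrasion",
                  "chest_deformity", "chest_wall_tenderness", "chest_wall_pain",
                  "crepitation", "abdominal_tenderness",
                  "decreased_pulmonary_sounds", "cxr_positive")

#' Cohort column schema
#'
#' Names and types of the patient-level columns every cohort must carry.
#' The outcome `cxr_positive` is TRUE iff at least one traumatic
#' intra-thoracic injury was seen on the chest radiograph, in which case
#' `injury_types` lists the findings (semicolon-separated; one of
#' hemothorax, pneumothorax, rib/sternum/scapula/clavicle fracture,
#' widened mediastinum, lung contusion).
#'
#' @param schema_version schema label; only `"1"` is defined.
#' @return named character vector mapping column name to storage type.
#' @export
cohort_schema <- function(schema_version = "1") {
  if (!identical(schema_version, "1"))
    abort_config(sprintf("unknown schema_version '%s'", schema_version))
  c(patient_id = "character", age = "integer", sex = "character",
    mechanism = "character", sbp = "numeric", dbp = "numeric",
    spo2 = "numeric", resp_rate = "numeric", gcs = "integer",
    setNames(rep("logical", length(BOOL_COLUMNS)), BOOL_COLUMNS),
    injury_types = "character")
}

new_cohort <- function(df, provenance = list(source = "memory")) {
  structure(df, class = c("tirc_cohort", "data.frame"),
            provenance = provenance)
}

#' Cohort provenance
#'
#' @param cohort a `tirc_cohort`.
#' @return list with at least `source` (`"file"`, `"fixture"`,
#'   `"stochastic"` or `"memory"`) and, where applicable, `seed` and `path`.
#' @export
cohort_provenance <- function(cohort) attr(cohort, "provenance")

#' Validate a cohort against the schema invariants
#'
#' Checks column presence and types, completeness (no missing values:
#' analyses are complete-case, blanks are rejected rather than imputed),
#' physiologic ranges (age >= 15, GCS 3-15, 0 < SpO2 <= 100, positive
#' pressures and respiratory rate), level sets for sex/mechanism/injury
#' tokens, uniqueness of `patient_id`, and the outcome consistency rule
#' `cxr_positive == (injury_types != "")`.
#'
#' @param cohort data.frame to validate.
#' @return the cohort, invisibly, with class `tirc_cohort`.
#' @export
validate_cohort <- function(cohort) {
  schema <- cohort_schema()
  missing_cols <- setdiff(names(schema), names(cohort))
  if (length(missing_cols))
    abort_schema(sprintf("cohort is missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  if (nrow(cohort) == 0)
    abort_validation("cohort must contain at least one patient record")
  if (anyNA(cohort[names(schema)]) ||
      !all(complete.cases(cohort[names(schema)])))
    abort_validation("cohort contains missing values; complete cases are required")
  if (anyDuplicated(cohort$patient_id))
    abort_validation(sprintf(
      "duplicated patient_id(s): %s",
      paste(unique(cohort$patient_id[duplicated(cohort$patient_id)]),
            collapse = ", ")))

  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      abort_validation(sprintf("%s for patient_id(s): %s", what,
                               paste(cohort$patient_id[idx], collapse = ", ")))
  }
  bad(cohort$age < 15, "age below 15")
  bad(cohort$gcs < 3 | cohort$gcs > 15, "gcs outside 3-15")
  bad(cohort$spo2 <= 0 | cohort$spo2 > 100, "spo2 outside (0, 100]")
  bad(cohort$sbp <= 0 | cohort$dbp <= 0 | cohort$resp_rate <= 0,
      "non-positive vital sign")
  bad(!cohort$sex %in% c("male", "female"), "unknown sex level")
  bad(!cohort$mechanism %in% MECHANISMS, "unknown mechanism level")

  tokens <- strsplit(cohort$injury_types, ";", fixed = TRUE)
  bad(vapply(tokens, function(t) any(!t %in% INJURY_TYPES), logical(1)),
      "unknown injury_types token")
  bad(cohort$cxr_positive != (vapply(tokens, length, integer(1)) > 0),
      "cxr_positive inconsistent with injury_types")

  if (!inherits(cohort, "tirc_cohort"))
    cohort <- new_cohort(cohort)
  invisible(cohort)
}

#' Read a cohort from CSV
#'
#' Expects the exact column set of [cohort_schema()], comma-separated,
#' UTF-8, header row required, booleans encoded 0/1, no missing values.
#'
#' @param path CSV file path.
#' @param schema_version schema label (only `"1"`).
#' @return a validated `tirc_cohort` with file provenance; row order is
#'   preserved.
#' @export
read_cohort <- function(path, schema_version = "1") {
  schema <- cohort_schema(schema_version)
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols))
    abort_schema(sprintf("CSV %s is missing required column(s): %s",
                         path, paste(missing_cols, collapse = ", ")))
  raw <- raw[names(schema)]

  parse_col <- function(x, type, col) {
    switch(type,
      character = x,
      integer = {
        v <- suppressWarnings(as.integer(x))
        if (anyNA(v) & !anyNA(x))
          abort_parse(sprintf("non-integer value in column '%s' at row %d",
                              col, which(is.na(v))[1]))
        v
      },
      numeric = {
        v <- suppressWarnings(as.numeric(x))
        if (anyNA(v) & !anyNA(x))
          abort_parse(sprintf("non-numeric value in column '%s' at row %d",
                              col, which(is.na(v))[1]))
        v
      },
      logical = {
        ok <- x %in% c("0", "1")
        if (!all(ok))
          abort_parse(sprintf("non-boolean value '%s' in column '%s' at row %d",
                              x[!ok][1], col, which(!ok)[1]))
        x == "1"
      })
  }
  for (col in names(schema))
    raw[[col]] <- parse_col(raw[[col]], schema[[col]], col)

  cohort <- new_cohort(raw, provenance = list(source = "file", path = path,
                                              schema_version = schema_version))
  validate_cohort(cohort)
  cohort
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: booleans as 0/1, injury types
#' semicolon-joined, full numeric precision, so that reading the file back
#' reproduces the cohort field-for-field.
#'
#' @param cohort a valid `tirc_cohort`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- as.data.frame(cohort)[names(cohort_schema())]
  for (col in BOOL_COLUMNS) out[[col]] <- as.integer(out[[col]])
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("cannot write cohort to '%s'", path))
  invisible(path)
}

#' Summarise a cohort (baseline characteristics table)
#'
#' Per-variable counts and percentages for the categorical/binary fields
#' (age banded at 60, GCS banded at 15) and mean +/- SD for age and the
#' vital signs, mirroring the layout of a baseline-characteristics table.
#'
#' @param cohort a valid `tirc_cohort`.
#' @return a `cohort_summary` list with elements `n`, `categorical`
#'   (data.frame: variable, level, count, percent) and `continuous`
#'   (data.frame: variable, mean, sd).
#' @export
describe_cohort <- function(cohort) {
  validate_cohort(cohort)
  n <- nrow(cohort)

  cat_var <- function(variable, values, levels) {
    counts <- vapply(levels, function(l) sum(values == l), integer(1))
    data.frame(variable = variable, level = levels, count = counts,
               percent = 100 * counts / n, row.names = NULL)
  }
  cats <- list(
    cat_var("age_band", ifelse(cohort$age >= 60, ">=60", "<60"),
            c("<60", ">=60")),
    cat_var("sex", cohort$sex, c("male", "female")),
    cat_var("mechanism", cohort$mechanism, MECHANISMS),
    cat_var("gcs_band", ifelse(cohort$gcs == 15, "15", "<15"),
            c("15", "<15"))
  )
  for (col in BOOL_COLUMNS)
    cats <- c(cats, list(cat_var(col, cohort[[col]], c(TRUE, FALSE))))
  categorical <- do.call(rbind, cats)
  categorical$level <- as.character(categorical$level)

  cont_vars <- c("age", "sbp", "dbp", "spo2", "resp_rate")
  continuous <- data.frame(
    variable = cont_vars,
    mean = vapply(cont_vars, function(v) mean(cohort[[v]]), numeric(1)),
    sd = vapply(cont_vars, function(v) stats::sd(cohort[[v]]), numeric(1)),
    row.names = NULL)

  structure(list(n = n, categorical = categorical, continuous = continuous),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (n = %d)\n", x$n))
  df <- x$categorical
  df$percent <- sprintf("%.1f", round_half_up(df$percent, 1))
  print(df, row.names = FALSE)
  cf <- x$continuous
  cf$mean <- sprintf("%.2f", cf$mean); cf$sd <- sprintf("%.2f", cf$sd)
  print(cf, row.names = FALSE)
  invisible(x)
}

#' @export
print.tirc_cohort <- function(x, ...) {
  prov <- cohort_provenance(x)
  cat(sprintf("<tirc_cohort> %d patients (source: %s%s)\n", nrow(x),
              prov$source %||% "memory",
              if (!is.null(prov$seed)) sprintf(", seed %d", prov$seed) else ""))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}
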