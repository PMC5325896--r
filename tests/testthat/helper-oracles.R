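# Independent brute-force oracles and small in-code fixtures.

# Four-way tally by an explicit per-record loop (oracle for confusion_table).
brute_confusion <- function(rule_positive, cxr_positive) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(rule_positive)) {
    if (rule_positive[i] && cxr_positive[i]) tp <- tp + 1L
    else if (rule_positive[i] && !cxr_positive[i]) fp <- fp + 1L
    else if (!rule_positive[i] && cxr_positive[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Pairwise Mann-Whitney probability, ties counting one half
# (oracle for trapezoidal AUC).
brute_auc <- function(scores, outcomes) {
  pos <- scores[outcomes]
  neg <- scores[!outcomes]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# One fully-specified valid patient row; override any field by name.
make_record <- function(patient_id = "P1", ...) {
  rec <- list(patient_id = patient_id, age = 30L, sex = "male",
              mechanism = "motor_vehicle_collision", sbp = 120, dbp = 80,
              spo2 = 98, resp_rate = 14, gcs = 15L,
              hemodynamic_unstable = FALSE, loss_of_consciousness = FALSE,
              dyspnea = FALSE, distracting_pain = FALSE,
              thoracic_skin_abrasion = FALSE, chest_deformity = FALSE,
              chest_wall_tenderness = FALSE, chest_wall_pain = FALSE,
              crepitation = FALSE, abdominal_tenderness = FALSE,
              decreased_pulmonary_sounds = FALSE, cxr_positive = FALSE,
              injury_types = "")
  dots <- list(...)
  rec[names(dots)] <- dots
  as.data.frame(rec, stringsAsFactors = FALSE)
}

# Random valid cohort built record-by-record, independent of the package
# generator (for round-trip and tally properties).
make_random_cohort <- function(n, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    injured <- runif(1) < 0.3
    make_record(
      patient_id = sprintf("R%03d", i),
      age = sample(15:90, 1),
      sex = sample(c("male", "female"), 1),
      mechanism = sample(c("motor_vehicle_collision", "fall", "other"), 1),
      sbp = round(runif(1, 90, 180), 1),
      dbp = round(runif(1, 50, 110), 1),
      spo2 = round(runif(1, 85, 100), 1),
      resp_rate = round(runif(1, 10, 30), 1),
      gcs = sample(3:15, 1),
      loss_of_consciousness = runif(1) < 0.1,
      dyspnea = runif(1) < 0.1,
      distracting_pain = runif(1) < 0.2,
      thoracic_skin_abrasion = runif(1) < 0.1,
      chest_wall_tenderness = runif(1) < 0.1,
      chest_wall_pain = runif(1) < 0.1,
      crepitation = runif(1) < 0.05,
      decreased_pulmonary_sounds = runif(1) < 0.05,
      cxr_positive = injured,
      injury_types = if (injured)
        paste(sample(c("rib_fracture", "pneumothorax", "hemothorax"),
                     sample(1:2, 1)), collapse = ";") else "")
  })
  validate_cohort(do.call(rbind, rows))
}

# Default-spec fixture cohort shared across tests (generated once).
table2_cohort <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- generate_fixture(cohort_spec(), seed = 42)
    cached
  }
})
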