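# Discrimination, calibration and overall performance.
#
# Discrimination: empirical ROC over distinct score thresholds and
# trapezoidal AUC (equal to the tie-corrected Mann-Whitney statistic; for
# a binary rule, exactly (sensitivity + specificity) / 2).
# Overall performance: Brier score with the Murphy decomposition
# (reliability - resolution + uncertainty), grouping by distinct
# prediction values.
# Calibration: count-weighted least-squares line through per-stratum
# (predicted, observed) points; logistic recalibration as an alternate.

#' Empirical ROC curve from ordinal scores
#'
#' One operating point per distinct score value (ties grouped), thresholds
#' swept from high to low, endpoints (0,0) and (1,1) included.
#'
#' @param scores per-patient ordinal risk scores (higher = riskier); for
#'   TIRC either the binary rule decision or the count of firing criteria.
#' @param outcomes per-patient logical outcomes.
#' @param score_kind label stored on the curve (`"binary_rule"`,
#'   `"criteria_count"`, or free text).
#' @return a `roc_curve`: data.frame of (`threshold`, `fpr`, `tpr`) sorted
#'   by FPR, with attribute `score_kind`.
#' @export
roc_from_scores <- function(scores, outcomes, score_kind = "custom") {
  if (length(scores) != length(outcomes))
    abort_validation("scores and outcomes must have equal length")
  outcomes <- as.logical(outcomes)
  npos <- sum(outcomes); nneg <- sum(!outcomes)
  if (npos == 0 || nneg == 0)
    abort_undefined("ROC undefined: need at least one positive and one negative outcome")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(outcomes & scores >= t) / npos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(!outcomes & scores >= t) / nneg,
                numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1)
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  structure(pts, class = c("roc_curve", "data.frame"),
            score_kind = score_kind)
}

#' Area under an ROC curve (trapezoidal)
#'
#' For a single binary rule this equals (sensitivity + specificity) / 2
#' exactly; in general it equals the Mann-Whitney probability that a
#' random injured patient outscores a random uninjured one, ties counting
#' one half.
#'
#' @param curve a `roc_curve`.
#' @return area in `[0, 1]`.
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  x <- curve$fpr; y <- curve$tpr
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points (score: %s), AUC = %.4f\n",
              nrow(x), attr(x, "score_kind"), auc(x)))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Brier score with Murphy decomposition
#'
#' Mean squared difference between predicted probability and binary
#' outcome, decomposed over the strata defined by distinct prediction
#' values: `brier = reliability - resolution + uncertainty` where
#' `reliability = sum n_k (p_k - o_k)^2 / N`,
#' `resolution = sum n_k (o_k - o_bar)^2 / N`, and
#' `uncertainty = o_bar (1 - o_bar)`.  `scaled_reliability` is
#' reliability / uncertainty.
#'
#' @param predictions per-patient probabilities in `[0, 1]`.
#' @param outcomes per-patient logical outcomes.
#' @param prediction_kind label: `"stratum_rate"`, `"binary_label"` or
#'   `"custom"`.
#' @return a `brier_result` list: `brier`, `reliability`, `resolution`,
#'   `uncertainty`, `scaled_reliability`, `n`, `prediction_kind`.
#' @export
brier_score <- function(predictions, outcomes, prediction_kind = "custom") {
  n <- length(predictions)
  if (n == 0) abort_validation("empty input")
  if (length(outcomes) != n)
    abort_validation("predictions and outcomes must have equal length")
  if (any(predictions < 0 | predictions > 1))
    abort_validation("predictions must lie in [0, 1]")
  y <- as.numeric(as.logical(outcomes))
  brier <- mean((predictions - y)^2)
  obar <- mean(y)
  groups <- split(y, predictions)
  nk <- vapply(groups, length, integer(1))
  ok <- vapply(groups, mean, numeric(1))
  pk <- as.numeric(names(groups))
  reliability <- sum(nk * (pk - ok)^2) / n
  resolution <- sum(nk * (ok - obar)^2) / n
  uncertainty <- obar * (1 - obar)
  structure(list(brier = brier, reliability = reliability,
                 resolution = resolution, uncertainty = uncertainty,
                 scaled_reliability = if (uncertainty > 0)
                   reliability / uncertainty else NA_real_,
                 n = n, prediction_kind = prediction_kind),
            class = "brier_result")
}

#' @export
print.brier_result <- function(x, ...) {
  cat(sprintf("Brier score: %.4f  (n = %d, predictions: %s)\n", x$brier,
              x$n, x$prediction_kind))
  cat(sprintf("  reliability %.6f - resolution %.6f + uncertainty %.6f\n",
              x$reliability, x$resolution, x$uncertainty))
  cat(sprintf("  scaled reliability: %.6f\n", x$scaled_reliability))
  invisible(x)
}

#' Stratum-rate predicted probabilities
#'
#' Assigns each patient the observed injury rate of their stratum: by
#' default the binary rule stratum (rule-positive patients get the
#' positive-stratum injury rate, rule-negative the negative-stratum rate),
#' or the criteria-count stratum.  This is the prediction construction a
#' checklist rule supports without a fitted model.
#'
#' @param triage a `tirc_triage`.
#' @param cohort the matching cohort.
#' @param by `"rule"` (two strata) or `"count"` (one stratum per distinct
#'   criteria count, mandatory-only positives pooled with count 1).
#' @return numeric vector of predicted probabilities, cohort order.
#' @export
stratum_predictions <- function(triage, cohort, by = c("rule", "count")) {
  by <- match.arg(by)
  if (!identical(as.character(triage$patient_id),
                 as.character(cohort$patient_id)))
    abort_alignment("triage results are not aligned 1:1 with the cohort by patient_id")
  key <- if (by == "rule") triage$rule_positive
         else pmax(triage$criteria_count, as.integer(triage$rule_positive))
  rates <- tapply(cohort$cxr_positive, key, mean)
  as.numeric(rates[as.character(key)])
}

#' Calibration strata from patient-level predictions
#'
#' @param predictions per-patient probabilities.
#' @param outcomes per-patient logical outcomes.
#' @return data.frame (`predicted`, `observed`, `n`), one row per distinct
#'   prediction value, sorted by `predicted`.
#' @export
calibration_strata <- function(predictions, outcomes) {
  if (length(predictions) != length(outcomes))
    abort_validation("predictions and outcomes must have equal length")
  y <- as.numeric(as.logical(outcomes))
  groups <- split(y, predictions)
  out <- data.frame(predicted = as.numeric(names(groups)),
                    observed = vapply(groups, mean, numeric(1)),
                    n = vapply(groups, length, integer(1)),
                    row.names = NULL)
  out[order(out$predicted), , drop = FALSE]
}

#' Fit a calibration line through stratum points
#'
#' Count-weighted least squares of observed outcome rate on predicted
#' probability across strata.  Perfect calibration is intercept 0, slope
#' 1.  Confidence intervals come from the weighted regression's standard
#' errors (t-based); with exactly two strata the fit is saturated and the
#' CIs are `NA`.
#'
#' @param strata data.frame (`predicted`, `observed`, `n`) as from
#'   [calibration_strata()].
#' @param confidence_level two-sided coverage for the CIs.
#' @return a `calibration_fit` list: `intercept`, `slope`, `ci` (2x2
#'   matrix, rows intercept/slope), `strata`, `method = "wls"`.
#' @export
calibration_fit <- function(strata, confidence_level = 0.95) {
  if (length(unique(strata$predicted)) < 2)
    abort_undefined("calibration line underdetermined: need >= 2 distinct predicted probabilities")
  fit <- lm(observed ~ predicted, data = strata, weights = n)
  est <- coef(fit)
  ci <- if (stats::df.residual(fit) > 0)
    suppressWarnings(confint(fit, level = confidence_level))
  else matrix(NA_real_, 2, 2)
  dimnames(ci) <- list(c("intercept", "slope"), c("lower", "upper"))
  structure(list(intercept = unname(est[1]), slope = unname(est[2]),
                 ci = ci, strata = strata, method = "wls",
                 confidence_level = confidence_level),
            class = "calibration_fit")
}

#' Logistic recalibration (alternate calibration mode)
#'
#' Patient-level logistic regression of the outcome on the logit of the
#' predicted probability (predictions clamped away from 0/1).  This is
#' the model-based alternative to the stratum-level line of
#' [calibration_fit()]; its intercept/slope live on the logit scale and
#' are not comparable to the weighted-least-squares line.
#'
#' @param predictions per-patient probabilities.
#' @param outcomes per-patient logical outcomes.
#' @param confidence_level two-sided coverage.
#' @return a `calibration_fit` with `method = "logistic"`.
#' @export
calibration_logistic <- function(predictions, outcomes,
                                 confidence_level = 0.95) {
  eps <- 1e-8
  lp <- qlogis(pmin(pmax(predictions, eps), 1 - eps))
  y <- as.numeric(as.logical(outcomes))
  fit <- suppressWarnings(glm(y ~ lp, family = binomial()))
  est <- coef(fit)
  ci <- tryCatch(suppressWarnings(suppressMessages(
    stats::confint.default(fit, level = confidence_level))),
    error = function(e) matrix(NA_real_, 2, 2))
  dimnames(ci) <- list(c("intercept", "slope"), c("lower", "upper"))
  structure(list(intercept = unname(est[1]), slope = unname(est[2]),
                 ci = ci, strata = calibration_strata(predictions, outcomes),
                 method = "logistic", confidence_level = confidence_level),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration line (%s): intercept %.3f, slope %.3f\n",
              x$method, x$intercept, x$slope))
  if (!anyNA(x$ci))
    cat(sprintf("  %g%% CI: intercept (%.3f, %.3f), slope (%.3f, %.3f)\n",
                100 * x$confidence_level, x$ci[1, 1], x$ci[1, 2],
                x$ci[2, 1], x$ci[2, 2]))
  invisible(x)
}
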