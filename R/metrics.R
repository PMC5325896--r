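# Screening performance: confusion table, point estimates, confidence
# intervals, and the design-stage sample-size formula.
#
# Proportion CIs default to the continuity-corrected Wilson (Newcombe)
# score interval, which reproduces the published screening table's
# intervals exactly; plain Wilson and Clopper-Pearson are available.
# Likelihood-ratio CIs use the standard log method (Simel).

#' Construct a confusion table from counts
#'
#' @param tp,fp,fn,tn non-negative integer counts of rule decision versus
#'   radiographic outcome.
#' @return a `confusion_table` object.
#' @export
#' @examples
#' new_confusion_table(33, 295, 0, 1190)
new_confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    abort_validation("confusion counts must be non-negative integers")
  structure(as.list(setNames(as.integer(counts), names(counts))),
            class = "confusion_table")
}

#' Cross-classify triage decisions against radiographic outcomes
#'
#' @param triage a `tirc_triage` from [classify_cohort()].
#' @param cohort the cohort the triage was computed on.
#' @return a `confusion_table`: `tp` counts rule-positive and injured,
#'   `fp` rule-positive and uninjured, `fn` rule-negative and injured,
#'   `tn` rule-negative and uninjured.
#' @export
confusion_table <- function(triage, cohort) {
  if (nrow(triage) != nrow(cohort) ||
      !identical(as.character(triage$patient_id),
                 as.character(cohort$patient_id)))
    abort_alignment("triage results are not aligned 1:1 with the cohort by patient_id")
  pos <- triage$rule_positive
  out <- cohort$cxr_positive
  new_confusion_table(tp = sum(pos & out), fp = sum(pos & !out),
                      fn = sum(!pos & out), tn = sum(!pos & !out))
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("rule+", "rule-"), c("injury+", "injury-")))
  print(m)
  invisible(x)
}

ct_total <- function(ct) ct$tp + ct$fp + ct$fn + ct$tn

#' Confidence interval configuration
#'
#' @param confidence_level two-sided coverage, in (0, 1).
#' @param proportion_method `"wilson_cc"` (continuity-corrected Wilson,
#'   default), `"wilson"`, or `"clopper_pearson"`.
#' @return a `ci_config` object carrying the implied two-sided standard
#'   normal quantile `z_quantile`.
#' @export
ci_config <- function(confidence_level = 0.95,
                      proportion_method = c("wilson_cc", "wilson",
                                            "clopper_pearson")) {
  if (!is.numeric(confidence_level) || confidence_level <= 0 ||
      confidence_level >= 1)
    abort_config("confidence_level must be in (0, 1)")
  structure(list(confidence_level = confidence_level,
                 proportion_method = match.arg(proportion_method),
                 z_quantile = qnorm(1 - (1 - confidence_level) / 2)),
            class = "ci_config")
}

#' Binomial proportion confidence interval (percent scale)
#'
#' Continuity-corrected Wilson (Newcombe 1998) by default, with the
#' conventional truncation at the 0 and 100 boundaries; score Wilson and
#' exact Clopper-Pearson as alternatives.
#'
#' @param x numerator count.
#' @param n denominator count (> 0).
#' @param config a [ci_config()].
#' @return named numeric `c(lower, upper)` in percent, full precision.
#' @export
#' @examples
#' proportion_ci(33, 33)       # sensitivity bound when 33/33 are detected
#' proportion_ci(1190, 1485)   # specificity
proportion_ci <- function(x, n, config = ci_config()) {
  if (n <= 0) abort_undefined("proportion CI undefined for denominator 0")
  if (x < 0 || x > n) abort_validation("need 0 <= x <= n")
  z <- config$z_quantile
  p <- x / n
  ci <- switch(config$proportion_method,
    wilson_cc = {
      lo <- (2 * n * p + z^2 - 1 -
               z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
            (2 * (n + z^2))
      hi <- (2 * n * p + z^2 + 1 +
               z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
            (2 * (n + z^2))
      if (x == 0) lo <- 0
      if (x == n) hi <- 1
      c(lo, hi)
    },
    wilson = {
      centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      c(centre - half, centre + half)
    },
    clopper_pearson =
      as.numeric(binom.test(x, n,
                            conf.level = config$confidence_level)$conf.int)
  )
  c(lower = max(0, ci[1]) * 100, upper = min(1, ci[2]) * 100)
}

lr_point <- function(ct, which) {
  sens <- ct$tp / (ct$tp + ct$fn)
  spec <- ct$tn / (ct$tn + ct$fp)
  if (which == "plr") {
    if (spec == 1) Inf else sens / (1 - spec)
  } else {
    if (spec == 0) abort_undefined("NLR undefined when specificity is 0")
    (1 - sens) / spec
  }
}

#' Likelihood-ratio confidence interval (log method)
#'
#' `exp(log(LR) +/- z * SE)` with `SE_PLR = sqrt((1-sens)/tp + spec/fp)`
#' and `SE_NLR = sqrt(sens/fn + (1-spec)/tn)`.  When the point estimate is
#' exactly 0 (a rule with no false negatives has NLR 0) the log method is
#' undefined and the degenerate interval (0, 0) is returned with a
#' warning.
#'
#' @param ct a `confusion_table`.
#' @param which `"plr"` or `"nlr"`.
#' @param config a [ci_config()].
#' @return named numeric `c(lower, upper)` on the ratio scale.
#' @export
lr_ci <- function(ct, which = c("plr", "nlr"), config = ci_config()) {
  which <- match.arg(which)
  if (ct$tp + ct$fn == 0 || ct$tn + ct$fp == 0)
    abort_undefined("likelihood ratio undefined: empty outcome margin")
  point <- lr_point(ct, which)
  if (point == 0) {
    warning("likelihood ratio point estimate is 0; log-method CI undefined, returning degenerate (0, 0)",
            call. = FALSE)
    return(c(lower = 0, upper = 0))
  }
  if (!is.finite(point))
    abort_undefined(sprintf("%s is infinite; log-method CI undefined",
                            toupper(which)))
  sens <- ct$tp / (ct$tp + ct$fn)
  spec <- ct$tn / (ct$tn + ct$fp)
  se <- if (which == "plr") {
    if (ct$tp == 0) abort_undefined("PLR SE undefined when tp = 0")
    sqrt((1 - sens) / ct$tp + spec / ct$fp)
  } else {
    if (ct$tn == 0) abort_undefined("NLR SE undefined when tn = 0")
    sqrt(sens / ct$fn + (1 - spec) / ct$tn)
  }
  z <- config$z_quantile
  c(lower = exp(log(point) - z * se), upper = exp(log(point) + z * se))
}

#' Screening point estimates from a confusion table
#'
#' @param ct a `confusion_table`.
#' @return named list, percent scale for proportions
#'   (sensitivity, specificity, ppv, npv, prevalence, rule_positive_rate,
#'   accuracy) and ratio scale for plr/nlr (`plr` is `Inf` when
#'   specificity is 1).
#' @export
screening_metrics <- function(ct) {
  n <- ct_total(ct)
  if (ct$tp + ct$fn == 0)
    abort_undefined("sensitivity undefined: no positive outcomes (tp + fn = 0)")
  if (ct$tn + ct$fp == 0)
    abort_undefined("specificity undefined: no negative outcomes (tn + fp = 0)")
  if (ct$tp + ct$fp == 0)
    abort_undefined("ppv undefined: no rule-positive patients (tp + fp = 0)")
  if (ct$tn + ct$fn == 0)
    abort_undefined("npv undefined: no rule-negative patients (tn + fn = 0)")
  list(sensitivity = 100 * ct$tp / (ct$tp + ct$fn),
       specificity = 100 * ct$tn / (ct$tn + ct$fp),
       ppv = 100 * ct$tp / (ct$tp + ct$fp),
       npv = 100 * ct$tn / (ct$tn + ct$fn),
       prevalence = 100 * (ct$tp + ct$fn) / n,
       rule_positive_rate = 100 * (ct$tp + ct$fp) / n,
       accuracy = 100 * (ct$tp + ct$tn) / n,
       plr = lr_point(ct, "plr"),
       nlr = lr_point(ct, "nlr"))
}

#' Full screening report with confidence intervals
#'
#' Point estimates and CIs for every screening characteristic, mirroring
#' the rows of a diagnostic-accuracy table: sensitivity, specificity,
#' PPV, NPV, prevalence, rule-positive rate, accuracy (percent; proportion
#' CI per `config`), and PLR/NLR (ratio; log-method CI).
#'
#' @param ct a `confusion_table`.
#' @param config a [ci_config()].
#' @return a `screening_report` list: `estimates` (data.frame with metric,
#'   estimate, lower, upper at full precision), `confusion`, `ci_config`.
#' @export
screening_report <- function(ct, config = ci_config()) {
  pm <- screening_metrics(ct)
  n <- ct_total(ct)
  prop_ci <- function(x, d) proportion_ci(x, d, config)
  cis <- rbind(
    sensitivity = prop_ci(ct$tp, ct$tp + ct$fn),
    specificity = prop_ci(ct$tn, ct$tn + ct$fp),
    ppv = prop_ci(ct$tp, ct$tp + ct$fp),
    npv = prop_ci(ct$tn, ct$tn + ct$fn),
    prevalence = prop_ci(ct$tp + ct$fn, n),
    rule_positive_rate = prop_ci(ct$tp + ct$fp, n),
    accuracy = prop_ci(ct$tp + ct$tn, n),
    plr = if (is.finite(pm$plr)) lr_ci(ct, "plr", config) else c(NA, NA),
    nlr = suppressWarnings(lr_ci(ct, "nlr", config)))
  estimates <- data.frame(metric = rownames(cis),
                          estimate = unlist(pm[rownames(cis)]),
                          lower = cis[, 1], upper = cis[, 2],
                          row.names = NULL)
  structure(list(estimates = estimates, confusion = ct, ci_config = config),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Screening performance (%s%% CI, %s)\n",
              format(100 * x$ci_config$confidence_level),
              x$ci_config$proportion_method))
  df <- x$estimates
  fmt <- function(v) sprintf("%.1f", round_half_up(v, 1))
  df$display <- sprintf("%s (%s - %s)", fmt(df$estimate), fmt(df$lower),
                        fmt(df$upper))
  print(df[, c("metric", "display")], row.names = FALSE)
  ct <- x$confusion
  cat(sprintf("TP %d  FP %d  FN %d  TN %d  (n = %d)\n",
              ct$tp, ct$fp, ct$fn, ct$tn, ct_total(ct)))
  invisible(x)
}

#' Sample size for estimating a proportion to a given precision
#'
#' The single-proportion precision formula
#' `ceiling(z^2 * p * (1 - p) / d^2)`.
#'
#' @param p expected prevalence (fraction in (0, 1)).
#' @param d absolute precision (half-width of the CI, fraction in (0, 1)).
#' @param confidence_level two-sided coverage.
#' @return minimum sample size (integer).
#' @export
#' @examples
#' sample_size_proportion(0.065, 0.015)   # 1038
sample_size_proportion <- function(p, d, confidence_level = 0.95) {
  if (p <= 0 || p >= 1) abort_config("p must be in (0, 1)")
  if (d <= 0 || d >= 1) abort_config("d must be in (0, 1)")
  z <- qnorm(1 - (1 - confidence_level) / 2)
  as.integer(ceiling(z^2 * p * (1 - p) / d^2))
}
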