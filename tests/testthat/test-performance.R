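test_that("binary-rule ROC has three points through (FPR, 1) and the analytic AUC", {
  # counts from the published 2x2: 33/295/0/1190
  scores <- c(rep(1, 328), rep(0, 1190))
  outcomes <- c(rep(TRUE, 33), rep(FALSE, 295), rep(FALSE, 1190))
  curve <- roc_from_scores(scores, outcomes, "binary_rule")
  expect_equal(nrow(curve), 3L)
  expect_equal(curve$fpr, c(0, 295 / 1485, 1))
  expect_equal(curve$tpr, c(0, 1, 1))
  expect_equal(auc(curve), (1 + 1190 / 1485) / 2, tolerance = 1e-12)
})

test_that("perfect and constant scores give the boundary curves", {
  out <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  perfect <- roc_from_scores(as.numeric(out), out)
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
  expect_equal(auc(perfect), 1)
  # constant scores degrade to the diagonal
  flat <- roc_from_scores(rep(2, 5), out)
  expect_equal(auc(flat), 0.5)
  expect_error(roc_from_scores(1:4, rep(TRUE, 4)),
               class = "tircval_undefined_error")
  expect_error(roc_from_scores(1:3, c(TRUE, FALSE)),
               class = "tircval_validation_error")
})

test_that("trapezoidal AUC equals the brute-force pairwise U statistic", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    outcomes <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    scores <- sample(0:5, n, replace = TRUE)   # heavy ties
    expect_equal(auc(roc_from_scores(scores, outcomes)),
                 brute_auc(scores, outcomes), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  outcomes <- runif(200) < 0.3
  outcomes[1:2] <- c(TRUE, FALSE)
  scores <- rnorm(200) + outcomes
  expect_equal(auc(roc_from_scores(scores, outcomes)),
               as.numeric(pROC::auc(pROC::roc(outcomes, scores,
                                              quiet = TRUE, direction = "<"))),
               tolerance = 1e-10)
})

test_that("binary-rule AUC identity (sens + spec) / 2 on random tables", {
  set.seed(43)
  for (i in 1:15) {
    tp <- sample(1:30, 1); fp <- sample(0:30, 1)
    fn <- sample(0:30, 1); tn <- sample(1:30, 1)
    scores <- c(rep(1, tp + fp), rep(0, fn + tn))
    outcomes <- c(rep(TRUE, tp), rep(FALSE, fp), rep(TRUE, fn),
                  rep(FALSE, tn))
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    expect_equal(auc(roc_from_scores(scores, outcomes)), (sens + spec) / 2,
                 tolerance = 1e-12)
  }
})

test_that("random scores independent of outcome give AUC near 1/2", {
  set.seed(44)
  outcomes <- runif(4000) < 0.3
  scores <- rnorm(4000)
  expect_equal(auc(roc_from_scores(scores, outcomes)), 0.5,
               tolerance = 0.03)
})

test_that("Murphy decomposition identity holds to 1e-12", {
  set.seed(45)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    predictions <- sample(round(runif(6), 2), n, replace = TRUE)
    outcomes <- runif(n) < predictions
    b <- brier_score(predictions, outcomes)
    expect_equal(b$brier, b$reliability - b$resolution + b$uncertainty,
                 tolerance = 1e-12)
    expect_true(b$reliability >= 0 && b$resolution >= 0)
    expect_lte(b$resolution, b$uncertainty + 1e-12)
    expect_equal(b$uncertainty, mean(outcomes) * (1 - mean(outcomes)),
                 tolerance = 1e-12)
  }
})

test_that("Brier limits: perfect, constant-prevalence, and binary predictions", {
  out <- c(rep(TRUE, 7), rep(FALSE, 13))
  perfect <- brier_score(as.numeric(out), out)
  expect_equal(perfect$brier, 0)
  expect_equal(perfect$reliability, 0)

  prev <- mean(out)
  flat <- brier_score(rep(prev, 20), out)
  expect_equal(flat$brier, flat$uncertainty, tolerance = 1e-12)
  expect_equal(flat$resolution, 0)

  # binary 0/1 predictions score (fp + fn) / N
  co <- make_random_cohort(50, seed = 46)
  tri <- classify_cohort(co)
  ct <- confusion_table(tri, co)
  b <- brier_score(as.numeric(tri$rule_positive), co$cxr_positive,
                   "binary_label")
  expect_equal(b$brier, (ct$fp + ct$fn) / nrow(co), tolerance = 1e-12)

  expect_error(brier_score(numeric(0), logical(0)),
               class = "tircval_validation_error")
  expect_error(brier_score(c(0.5, 1.2), c(TRUE, FALSE)),
               class = "tircval_validation_error")
})

test_that("stratum-rate predictions equal per-stratum observed rates", {
  co <- make_random_cohort(80, seed = 47)
  tri <- classify_cohort(co)
  p <- stratum_predictions(tri, co)
  pos_rate <- mean(co$cxr_positive[tri$rule_positive])
  neg_rate <- mean(co$cxr_positive[!tri$rule_positive])
  expect_equal(unique(p[tri$rule_positive]), pos_rate)
  expect_equal(unique(p[!tri$rule_positive]), neg_rate)
  # by construction the stratum-rate reliability term vanishes
  b <- brier_score(p, co$cxr_positive, "stratum_rate")
  expect_equal(b$reliability, 0, tolerance = 1e-12)
})

test_that("calibration line: diagonal and two-point cases", {
  diag <- data.frame(predicted = c(0.1, 0.3, 0.6),
                     observed = c(0.1, 0.3, 0.6), n = c(10, 20, 30))
  fit <- calibration_fit(diag)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$slope, 1, tolerance = 1e-12)

  two <- data.frame(predicted = c(0, 0.5), observed = c(0, 1),
                    n = c(25, 25))
  fit2 <- calibration_fit(two)
  expect_equal(fit2$slope, 2, tolerance = 1e-12)
  expect_equal(fit2$intercept, 0, tolerance = 1e-12)
  expect_true(all(is.na(fit2$ci)))   # saturated fit

  expect_error(calibration_fit(data.frame(predicted = 0.2, observed = 0.3,
                                          n = 10)),
               class = "tircval_undefined_error")
})

test_that("weighted fit recovers injected miscalibration within its CI", {
  # five strata, injected intercept 0.05 / slope 1.2, binomial sampling
  predicted <- c(0.05, 0.1, 0.2, 0.3, 0.5)
  nk <- rep(400L, 5)
  a <- 0.05; b <- 1.2
  hits <- 0
  set.seed(48)
  for (r in 1:100) {
    observed <- rbinom(5, nk, pmin(a + b * predicted, 1)) / nk
    fit <- calibration_fit(data.frame(predicted = predicted,
                                      observed = observed, n = nk))
    covered <- fit$ci["intercept", 1] <= a & a <= fit$ci["intercept", 2] &
      fit$ci["slope", 1] <= b & b <= fit$ci["slope", 2]
    hits <- hits + covered
  }
  expect_gte(hits, 90)
})

test_that("logistic recalibration recovers slope 1 / intercept 0 in the limit", {
  set.seed(49)
  p <- runif(4000, 0.05, 0.95)
  y <- runif(4000) < p
  fit <- calibration_logistic(p, y)
  expect_equal(fit$method, "logistic")
  expect_lt(abs(fit$intercept), 0.15)
  expect_lt(abs(fit$slope - 1), 0.1)
})
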