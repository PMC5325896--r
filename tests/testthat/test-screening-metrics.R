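table2_ct <- new_confusion_table(33, 295, 0, 1190)

test_that("confusion table equals the brute-force four-way tally", {
  co <- make_random_cohort(50, seed = 21)
  tri <- classify_cohort(co)
  ct <- confusion_table(tri, co)
  oracle <- brute_confusion(tri$rule_positive, co$cxr_positive)
  expect_equal(unlist(ct[c("tp", "fp", "fn", "tn")]), oracle)
  expect_equal(ct$tp + ct$fp + ct$fn + ct$tn, nrow(co))

  one <- validate_cohort(make_record(dyspnea = TRUE, cxr_positive = TRUE,
                                     injury_types = "pneumothorax"))
  ct1 <- confusion_table(classify_cohort(one), one)
  expect_equal(unlist(ct1), c(tp = 1L, fp = 0L, fn = 0L, tn = 0L))
})

test_that("misaligned triage and cohort raise an alignment error", {
  co <- make_random_cohort(10, seed = 22)
  tri <- classify_cohort(co)
  expect_error(confusion_table(tri[c(2:10, 1), ], co),
               class = "tircval_alignment_error")
  expect_error(confusion_table(tri[1:9, ], co),
               class = "tircval_alignment_error")
})

test_that("point estimates reproduce the published screening table", {
  m <- screening_metrics(table2_ct)
  expect_equal(round_half_up(m$sensitivity, 1), 100.0)
  expect_equal(round_half_up(m$specificity, 1), 80.1)
  expect_equal(round_half_up(m$ppv, 1), 10.1)
  expect_equal(round_half_up(m$npv, 1), 100.0)
  expect_equal(round_half_up(m$plr, 1), 5.0)
  expect_equal(round_half_up(m$nlr, 1), 0.0)
  expect_equal(round_half_up(m$prevalence, 1), 2.2)
  expect_equal(round_half_up(m$rule_positive_rate, 1), 21.6)

  perfect <- screening_metrics(new_confusion_table(1, 0, 0, 1))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$nlr, 0)
  expect_true(is.infinite(perfect$plr))
})

test_that("degenerate margins raise undefined-metric errors naming the metric", {
  expect_error(screening_metrics(new_confusion_table(0, 5, 0, 5)),
               "sensitivity", class = "tircval_undefined_error")
  expect_error(screening_metrics(new_confusion_table(5, 0, 5, 0)),
               "specificity", class = "tircval_undefined_error")
  expect_error(proportion_ci(3, 0), class = "tircval_undefined_error")
})

test_that("continuity-corrected Wilson reproduces the published intervals", {
  expect_equal(round_half_up(proportion_ci(33, 33), 1),
               c(lower = 87.0, upper = 100.0))
  expect_equal(round_half_up(proportion_ci(1190, 1485), 1),
               c(lower = 78.0, upper = 82.1))
  expect_equal(round_half_up(proportion_ci(33, 328), 1),
               c(lower = 7.1, upper = 14.0))
  expect_equal(round_half_up(proportion_ci(1190, 1190), 1),
               c(lower = 99.6, upper = 100.0))
  expect_equal(unname(proportion_ci(0, 50)[1]), 0)
})

test_that("CI methods agree with their reference implementations", {
  cases <- list(c(33, 33), c(1190, 1485), c(7, 80), c(0, 20), c(19, 20))
  for (cs in cases) {
    x <- cs[1]; n <- cs[2]
    expect_equal(unname(proportion_ci(x, n, ci_config())),
                 100 * as.numeric(prop.test(x, n, correct = TRUE)$conf.int),
                 tolerance = 1e-10)
    expect_equal(
      unname(proportion_ci(x, n, ci_config(proportion_method = "wilson"))),
      100 * as.numeric(prop.test(x, n, correct = FALSE)$conf.int),
      tolerance = 1e-10)
    expect_equal(
      unname(proportion_ci(x, n,
                           ci_config(proportion_method = "clopper_pearson"))),
      100 * as.numeric(binom.test(x, n)$conf.int), tolerance = 1e-10)
  }
})

test_that("CI properties: containment, convergence, width monotone in n", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:500, 1)
    x <- sample(0:n, 1)
    p <- 100 * x / n
    for (m in c("wilson_cc", "wilson", "clopper_pearson")) {
      ci <- proportion_ci(x, n, ci_config(proportion_method = m))
      expect_true(ci["lower"] <= p + 1e-9 && p <= ci["upper"] + 1e-9)
      expect_true(ci["lower"] >= 0 && ci["upper"] <= 100)
    }
    cc <- proportion_ci(x, n, ci_config())
    w <- proportion_ci(x, n, ci_config(proportion_method = "wilson"))
    expect_true(cc["lower"] <= w["lower"] + 1e-9 &&
                  cc["upper"] >= w["upper"] - 1e-9)
  }
  # convergence of the three methods at fixed proportion
  gaps <- sapply(c(50, 500, 50000), function(n) {
    cis <- sapply(c("wilson_cc", "wilson", "clopper_pearson"), function(m)
      proportion_ci(round(0.3 * n), n, ci_config(proportion_method = m)))
    max(apply(cis, 1, function(r) diff(range(r))))
  })
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.05)
  # width shrinks with the denominator at fixed proportion
  widths <- sapply(c(20, 100, 1000, 10000), function(n)
    diff(proportion_ci(round(0.2 * n), n)))
  expect_true(all(diff(widths) < 0))
})

test_that("Bayes consistency ties PPV to sensitivity, specificity, prevalence", {
  set.seed(33)
  for (i in 1:25) {
    ct <- new_confusion_table(sample(1:50, 1), sample(1:50, 1),
                              sample(1:50, 1), sample(1:50, 1))
    m <- screening_metrics(ct)
    sens <- m$sensitivity / 100; spec <- m$specificity / 100
    prev <- m$prevalence / 100
    expect_equal(m$ppv / 100,
                 sens * prev / (sens * prev + (1 - spec) * (1 - prev)),
                 tolerance = 1e-12)
  }
})

test_that("log-method LR intervals reproduce the published values", {
  expect_equal(round_half_up(lr_ci(table2_ct, "plr"), 1),
               c(lower = 4.5, upper = 5.6))
  expect_warning(nlr <- lr_ci(table2_ct, "nlr"), "degenerate")
  expect_equal(nlr, c(lower = 0, upper = 0))
  # uninformative test: PLR point 1, interval straddles 1
  even <- new_confusion_table(50, 50, 50, 50)
  expect_equal(screening_metrics(even)$plr, 1)
  ci <- lr_ci(even, "plr")
  expect_true(ci["lower"] < 1 && ci["upper"] > 1)
})

test_that("the full report holds its point estimates inside their CIs", {
  rep <- screening_report(table2_ct)
  est <- rep$estimates
  expect_true(all(est$lower <= est$estimate + 1e-9 &
                    est$estimate <= est$upper + 1e-9))
  props <- est[!est$metric %in% c("plr", "nlr"), ]
  expect_true(all(props$lower >= 0 & props$upper <= 100))
})

test_that("sample-size formula matches the closed form", {
  expect_equal(sample_size_proportion(0.065, 0.015), 1038L)
  expect_equal(sample_size_proportion(0.5, 0.05), 385L)
  expect_equal(sample_size_proportion(0.5, 0.5), 4L)
  expect_error(sample_size_proportion(0, 0.05),
               class = "tircval_config_error")
})
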