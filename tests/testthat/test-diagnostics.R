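test_that("2x2 construction counts cells and validates input", {
  t <- two_by_two(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(unlist(t[c("tp", "tn", "fp", "fn")]), c(tp = 1, tn = 1, fp = 0, fn = 0))
  t2 <- two_by_two(rep(FALSE, 5), rep(TRUE, 5))
  expect_equal(t2$fn, 5)
  expect_equal(t2$tp + t2$fp + t2$tn, 0)
  expect_error(two_by_two(TRUE, c(TRUE, FALSE)), "length")
  expect_error(two_by_two(logical(0), logical(0)), "at least one")
  expect_equal(sum(tidy(two_by_two(c(TRUE, FALSE), c(FALSE, TRUE)))$n), 2)
})

test_that("metrics reproduce the published operating characteristics from their 2x2 tables", {
  m1 <- dx_metrics(structure(list(tp = 52, fp = 23, fn = 32, tn = 445),
                             class = "two_by_two"))
  sens <- m1$estimate[m1$metric == "sensitivity"]
  spec <- m1$estimate[m1$metric == "specificity"]
  expect_equal(sens, 52 / 84)
  expect_equal(percent_half_up(sens), 62L)
  expect_equal(percent_half_up(spec), 95L)

  bifasc <- dx_metrics(structure(list(tp = 14, fp = 0, fn = 70, tn = 89),
                                 class = "two_by_two"))
  expect_equal(percent_half_up(bifasc$estimate[bifasc$metric == "sensitivity"]), 17L)
  expect_equal(bifasc$estimate[bifasc$metric == "specificity"], 1.0)

  perfect <- dx_metrics(two_by_two(c(TRUE, FALSE), c(TRUE, FALSE)))
  expect_true(all(perfect$estimate == 1))

  # zero denominator reported as NA, never 0/0
  degenerate <- dx_metrics(two_by_two(c(FALSE, FALSE), c(FALSE, FALSE)))
  expect_true(is.na(degenerate$estimate[degenerate$metric == "sensitivity"]))

  # label symmetry: swapping tp<->tn and fp<->fn exchanges sens and spec
  a <- structure(list(tp = 11, fp = 4, fn = 7, tn = 30), class = "two_by_two")
  b <- structure(list(tp = 30, fp = 7, fn = 4, tn = 11), class = "two_by_two")
  ma <- dx_metrics(a); mb <- dx_metrics(b)
  expect_equal(ma$estimate[ma$metric == "sensitivity"],
               mb$estimate[mb$metric == "specificity"])
  expect_equal(ma$estimate[ma$metric == "specificity"],
               mb$estimate[mb$metric == "sensitivity"])
})

test_that("Wilson intervals bracket the point estimate and cover at the nominal rate", {
  expect_equal(wilson_ci(0, 10)[["lo"]], 0)
  expect_equal(wilson_ci(10, 10)[["hi"]], 1)
  ci <- wilson_ci(52, 84)
  expect_lte(ci[["lo"]], 52 / 84)
  expect_gte(ci[["hi"]], 52 / 84)
  expect_error(wilson_ci(5, 4), "successes")
  expect_error(wilson_ci(2, 10, 1.2), "conf_level")

  # exact-coverage sweep by binomial enumeration: coverage never more than
  # 3 points below nominal on the central-p grid
  for (n in c(10, 25, 50, 100)) {
    for (p in seq(0.1, 0.9, 0.1)) {
      coverage <- sum(vapply(0:n, function(k) {
        ci <- wilson_ci(k, n)
        if (ci[["lo"]] <= p && p <= ci[["hi"]]) stats::dbinom(k, n, p) else 0
      }, 0))
      expect_gte(coverage, 0.92)
    }
  }
})

test_that("chi-square matches the textbook statistic and falls back to Fisher when sparse", {
  even <- matrix(c(10, 10, 10, 10), 2)
  out <- chi_square_test(even)
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 1)

  # in-hospital mortality, left-main occlusion vs subtotal occlusion
  mort <- matrix(c(37, 10, 47, 79), 2)
  out2 <- chi_square_test(mort)
  expect_equal(out2$method, "pearson_chi_square")
  expect_equal(out2$statistic, pearson_stat(mort))
  expect_equal(out2$df, 1)
  expect_lt(out2$p.value, 0.001)

  sparse <- matrix(c(2, 3, 3, 50), 2)
  expect_equal(chi_square_test(sparse)$method, "fisher_exact")
  expect_error(chi_square_test(matrix(c(0, 0, 3, 5), 2, byrow = TRUE)), "margin")
  # larger-than-2x2 tables stay Pearson
  m6 <- matrix(c(37, 10, 8, 4, 1, 1, 47, 79, 77, 94, 90, 104), ncol = 2)
  expect_equal(chi_square_test(m6)$df, 5)
})

test_that("one-way ANOVA detects the published QRS group separation", {
  same <- rep(c(1, 2, 3), 2)
  out <- one_way_anova(same, rep(c("a", "b"), each = 3))
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 1)
  expect_error(one_way_anova(1:3, c("a", "a", "b")), "at least two")

  # Monte-Carlo at the published group means/SDs: the group effect is
  # detected at p < 0.001 in at least 95% of replicates
  spec <- cohort_spec()$groups
  withr::local_seed(99)
  hits <- vapply(1:200, function(i) {
    q <- rnorm(sum(spec$n), rep(spec$qrs_mean, spec$n), rep(spec$qrs_sd, spec$n))
    one_way_anova(q, rep(spec$group, spec$n))$p.value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("trapezoidal AUC equals the pair-counting statistic to 1e-12", {
  withr::local_seed(31)
  for (i in 1:25) {
    n <- sample(10:500, 1)
    # coarse rounding forces heavy ties
    scores <- round(rnorm(n, 0, 2), sample(0:1, 1))
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, pair_count_auc(scores, labels), tolerance = 1e-12)
    expect_true(all(diff(r$curve$tpr) >= 0))
    expect_true(all(diff(r$curve$fpr) >= 0))
  }
  # degenerate and limiting cases
  expect_equal(roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_curve(rep(5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_curve(1:3, rep(TRUE, 3)), "Both classes")
  withr::local_seed(8)
  big <- roc_curve(rnorm(4000), runif(4000) < 0.5)
  expect_equal(big$auc, 0.5, tolerance = 0.05)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(13)
  scores <- round(rnorm(200), 1)
  labels <- runif(200) < 0.5
  ours <- roc_curve(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    direction = "<", quiet = TRUE
  )))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("Youden cutoff maximises tpr - fpr with ties broken toward the lower threshold", {
  # thresholds 5 and 3 both attain J = 0.5; the lower one wins (it has the
  # higher sensitivity)
  scores <- c(5, 3, 3, 1)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  r <- roc_curve(scores, labels)
  expect_equal(max(r$curve$tpr - r$curve$fpr), 0.5)
  expect_equal(r$youden_cutoff, 3)
  expect_equal(r$sens_at_cutoff, 1)
  # unique-maximum case
  r2 <- roc_curve(c(1, 2, 3, 4), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(r2$youden_cutoff, 2)
  expect_equal(r2$sens_at_cutoff, 1)
  expect_equal(r2$spec_at_cutoff, 1)
})

test_that("empirical AUC converges to the binormal closed form", {
  expect_equal(binormal_auc(0, 1, 0, 1), 0.5)
  expect_gt(binormal_auc(100, 1, 0, 1), 0.999999)
  expect_error(binormal_auc(1, 0, 0, 1), "positive")
  expect_equal(binormal_auc(117, 23, 97.1, 16.5), 0.759, tolerance = 0.001)

  withr::local_seed(77)
  n <- 50000
  pos <- rnorm(n, 117, 23)
  neg <- rnorm(n, 97.1, 16.5)
  emp <- roc_curve(c(pos, neg), rep(c(TRUE, FALSE), each = n))$auc
  expect_equal(emp, binormal_auc(117, 23, 97.1, 16.5), tolerance = 0.01)
})

test_that("evaluation with explicit control sets reproduces the single-criterion figures", {
  cohort <- simulate_cohort(seed = 21)
  ev <- evaluate_criteria(cohort, c("ste_avr_avl", "bifascicular"),
                          controls = "lm_subocclusion")
  aa <- ev[ev$criterion == "ste_avr_avl", ]
  expect_equal(c(aa$tp, aa$fp, aa$fn, aa$tn), c(23, 4, 61, 85))
  expect_equal(percent_half_up(aa$specificity), 96L)
  expect_equal(percent_half_up(aa$sensitivity), 27L)
  bf <- ev[ev$criterion == "bifascicular", ]
  expect_equal(bf$specificity, 1.0)
  expect_equal(percent_half_up(bf$sensitivity), 17L)
  expect_error(
    evaluate_criteria(cohort, "model1", controls = c("lm_occlusion", "rca")),
    "must not"
  )
})
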