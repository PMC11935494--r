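ar_stable_frame <- function(seed = 11) {
  ds <- simulate_cohort(cohort_config(), seed = seed)
  labs <- assign_cohorts(ds)
  list(
    df = dplyr::inner_join(ds$samples,
                           dplyr::select(labs, "sample_id", "label"),
                           by = "sample_id"),
    prevalence = study_prevalence(labs)
  )
}

test_that("independent subsampling keeps gap-or-different-diagnosis pairs", {
  two_close <- data.frame(days_post_transplant = c(0, 30),
                          label = c("STABLE", "STABLE"))
  set.seed(1)
  expect_equal(nrow(select_independent_subset(two_close)), 1)

  mixed <- data.frame(days_post_transplant = c(0, 30),
                      label = c("STABLE", "AR"))
  expect_equal(nrow(select_independent_subset(mixed)), 2)

  single <- data.frame(days_post_transplant = 5, label = "AR")
  expect_identical(select_independent_subset(single), single)

  spaced <- data.frame(days_post_transplant = c(0, 91, 182),
                       label = rep("STABLE", 3))
  expect_equal(nrow(select_independent_subset(spaced)), 3)
  # the gap predicate is strict: exactly 90 days is still dependent
  boundary <- data.frame(days_post_transplant = c(0, 90),
                         label = rep("STABLE", 2))
  expect_equal(nrow(select_independent_subset(boundary)), 1)
})

test_that("every emitted subset satisfies the independence predicate", {
  set.seed(40)
  for (i in 1:200) {
    n <- sample(1:8, 1)
    df <- data.frame(days_post_transplant = sample(0:400, n),
                     label = sample(c("AR", "STABLE"), n, replace = TRUE))
    sub <- select_independent_subset(df)
    if (nrow(sub) > 1) {
      pairs <- utils::combn(nrow(sub), 2)
      ok <- apply(pairs, 2, function(ij) {
        abs(sub$days_post_transplant[ij[1]] -
              sub$days_post_transplant[ij[2]]) > 90 ||
          sub$label[ij[1]] != sub$label[ij[2]]
      })
      expect_true(all(ok))
    }
    # maximality: no rejected row could have been added back
    left_out <- df[!rownames(df) %in% rownames(sub), , drop = FALSE]
    if (nrow(left_out)) {
      addable <- apply(left_out, 1, function(row) {
        all(abs(as.numeric(row[["days_post_transplant"]]) -
                  sub$days_post_transplant) > 90 |
              row[["label"]] != sub$label)
      })
      expect_false(any(addable))
    }
  }
})

test_that("confusion metrics reproduce hand counts and the printed point estimates", {
  cm <- confusion_metrics(c(1.8, 0.5, 0.4, 1.2),
                          c("AR", "AR", "STABLE", "STABLE"))
  expect_equal(unname(cm[c("sensitivity", "specificity")]), c(0.5, 0.5))

  # 14 of 18 AR at or above threshold; 11 of 13 STABLE below
  ar_vals <- c(rep(1.5, 14), rep(0.5, 4))
  st_vals <- c(rep(0.5, 11), rep(1.5, 2))
  cm <- confusion_metrics(c(ar_vals, st_vals),
                          rep(c("AR", "STABLE"), c(18, 13)))
  expect_equal(round(unname(cm["sensitivity"]), 4), 0.7778)
  expect_equal(round(unname(cm["specificity"]), 4), 0.8462)

  expect_null(confusion_metrics(c(1, 2), c("AR", "AR")))
})

test_that("likelihood ratios match the published arithmetic", {
  lr <- likelihood_ratios(0.7778, 0.8462)
  expect_equal(round(unname(lr["lr_neg"]), 2), 0.26)
  expect_equal(unname(lr["lr_pos"]), 0.7778 / (1 - 0.8462))
  lr <- likelihood_ratios(1, 1)
  expect_equal(unname(lr["lr_pos"]), Inf)
  expect_equal(unname(lr["lr_neg"]), 0)
})

test_that("predictive values follow Bayes' rule at fixed prevalence", {
  pv <- predictive_values(0.7778, 0.8462, 0.1101)
  expect_equal(unname(pv["ppv"]), 0.385, tolerance = 0.002)
  expect_equal(unname(pv["npv"]), 0.968, tolerance = 0.002)
  pv <- predictive_values(0.8, 0.9, 1e-9)
  expect_lt(unname(pv["ppv"]), 1e-6)
  expect_gt(unname(pv["npv"]), 1 - 1e-6)
  expect_equal(unname(predictive_values(0.5, 0.5, 0.5)), c(0.5, 0.5))
})

test_that("empirical AUROC equals the pair-enumeration oracle", {
  expect_equal(empirical_auroc(c(2, 3), c(0, 1)), 1)
  expect_equal(empirical_auroc(c(1, 2), c(1, 2)), 0.5)
  expect_equal(empirical_auroc(c(1.8, 0.9, 2.5), c(0.4, 1.0, 0.7)), 8 / 9)

  set.seed(13)
  for (i in 1:1000) {
    pos <- round(rlnorm(sample(1:8, 1), 0.6, 0.9), 2)
    neg <- round(rlnorm(sample(1:8, 1), -0.8, 0.9), 2)
    expect_equal(empirical_auroc(pos, neg), auroc_oracle(pos, neg),
                 tolerance = 1e-12)
  }
  expect_error(empirical_auroc(numeric(0), 1:3), "non-empty")
})

test_that("empirical AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  pos <- rlnorm(40, 0.59, 0.91)
  neg <- rlnorm(120, -0.78, 0.95)
  ours <- empirical_auroc(pos, neg)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(1, 0), c(40, 120)), predictor = c(pos, neg),
    quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("raising the threshold never raises sensitivity nor lowers specificity", {
  set.seed(55)
  vals <- rlnorm(60, 0, 1)
  labs <- rep(c("AR", "STABLE"), 30)
  thresholds <- seq(0.2, 3, by = 0.2)
  cms <- vapply(thresholds,
                function(t) confusion_metrics(vals, labs, t)[1:2],
                numeric(2))
  expect_true(all(diff(cms[1, ]) <= 1e-12))
  expect_true(all(diff(cms[2, ]) >= -1e-12))
})

test_that("study prevalence uses the post-treatment-window denominator", {
  labels <- tibble::tibble(
    label = rep(c("AR", "STABLE", "EXCLUDED", "EXCLUDED"), c(25, 197, 30, 5)),
    exclusion_reason = rep(c("none", "none", "post_treatment_window",
                             "suspected_ar_unconfirmed"), c(25, 197, 30, 5))
  )
  expect_equal(study_prevalence(labels), 25 / 227)
  expect_equal(round(100 * study_prevalence(labels), 2), 11.01)
  expect_equal(study_prevalence(labels, denominator = "analyzed"), 25 / 222)
  none <- tibble::tibble(label = rep("STABLE", 3),
                         exclusion_reason = rep("none", 3))
  expect_equal(study_prevalence(none), 0)
  all_ar <- tibble::tibble(label = rep("AR", 3),
                           exclusion_reason = rep("none", 3))
  expect_equal(study_prevalence(all_ar), 1)
})

test_that("the estimator is deterministic under a fixed seed", {
  fx <- ar_stable_frame()
  cfg <- resampling_config(iterations = 25, prevalence = fx$prevalence)
  a <- estimate_performance(fx$df, cfg, seed = 99)
  b <- estimate_performance(fx$df, cfg, seed = 99)
  expect_identical(a$summary, b$summary)
  expect_identical(a$iterations, b$iterations)
  one <- estimate_performance(fx$df, resampling_config(iterations = 1,
                                                       prevalence = 0.11),
                              seed = 5)
  two <- estimate_performance(fx$df, resampling_config(iterations = 1,
                                                       prevalence = 0.11),
                              seed = 5)
  expect_identical(one$iterations, two$iterations)
})

test_that("perfect separation is invariant under resampling", {
  df <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:30),
    days_post_transplant = seq(10, 3000, length.out = 30),
    corrected_fraction_pct = rep(c(5, 0.5), 15),
    label = rep(c("AR", "STABLE"), 15)
  )
  perf <- estimate_performance(df, resampling_config(iterations = 200,
                                                     prevalence = 0.5),
                               seed = 3)
  s <- perf$summary
  for (m in c("sensitivity", "specificity", "auroc")) {
    expect_equal(s$point[s$metric == m], 1)
    expect_equal(s$ci_low[s$metric == m], 1)
    expect_equal(s$ci_high[s$metric == m], 1)
  }
})

test_that("per-iteration internal relations hold", {
  fx <- ar_stable_frame()
  perf <- estimate_performance(
    fx$df, resampling_config(iterations = 300, prevalence = fx$prevalence),
    seed = 8)
  it <- perf$iterations
  ok_spec <- it[, "specificity"] < 1
  expect_equal(it[ok_spec, "lr_pos"],
               it[ok_spec, "sensitivity"] / (1 - it[ok_spec, "specificity"]))
  expect_true(all(it[, c("sensitivity", "specificity", "ppv", "npv",
                         "auroc")] >= 0 &
                    it[, c("sensitivity", "specificity", "ppv", "npv",
                           "auroc")] <= 1))
  s <- perf$summary
  expect_true(all(s$ci_low <= s$point & s$point <= s$ci_high))
  roc <- perf$roc
  expect_true(all(diff(roc$tpr) >= -1e-12))
  expect_equal(roc$fpr[1], 0)
})

test_that("percentile intervals for sensitivity cover the truth at a plausible rate", {
  # known truth: P(AR fraction >= 1.0) under the calibrated AR lognormal
  par <- calibrate_lognormal(1.80, 1.04, 3.56)
  true_sens <- 1 - plnorm(1.0, par["meanlog"], par["sdlog"])
  set.seed(60)
  covered <- vapply(1:60, function(i) {
    df <- tibble::tibble(
      patient_id = sprintf("P%03d", 1:120),
      days_post_transplant = sample(30:2000, 120),
      corrected_fraction_pct = c(rlnorm(25, par["meanlog"], par["sdlog"]),
                                 rlnorm(95, log(0.46), 0.9496)),
      label = rep(c("AR", "STABLE"), c(25, 95))
    )
    perf <- estimate_performance(df, resampling_config(iterations = 400,
                                                       prevalence = 0.11),
                                 seed = 1000 + i)
    s <- perf$summary[perf$summary$metric == "sensitivity", ]
    s$ci_low <= true_sens && true_sens <= s$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.995)
})

test_that("tidy, glance and autoplot work on a performance summary", {
  fx <- ar_stable_frame()
  perf <- estimate_performance(fx$df,
                               resampling_config(iterations = 30,
                                                 prevalence = fx$prevalence),
                               seed = 2)
  td <- tidy(perf)
  expect_equal(td$term, c("sensitivity", "specificity", "ppv", "npv",
                          "lr_pos", "lr_neg", "auroc"))
  g <- glance(perf)
  expect_equal(g$iterations, 30)
  expect_equal(g$prevalence, fx$prevalence)
  p <- ggplot2::autoplot(perf)
  expect_s3_class(p, "ggplot")
})
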