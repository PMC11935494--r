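test_that("post-event look-back excludes draws after treated infection or treatment", {
  # treated infection 30 days before the draw
  ev <- make_event("2022-05-02", "infection", treated = TRUE)
  out <- assign_cohort(one_sample("2022-06-01"), ev)
  expect_equal(out$label, "EXCLUDED")
  expect_equal(out$exclusion_reason, "post_treatment_window")

  # 42 days is still inside; 43 is outside
  out <- assign_cohort(one_sample("2022-06-01"),
                       make_event("2022-04-20", "treatment_start"))
  expect_equal(out$label, "EXCLUDED")
  out <- assign_cohort(one_sample("2022-06-01"),
                       make_event("2022-04-19", "treatment_start"))
  expect_equal(out$label, "STABLE")

  # biopsy gets its own reason, regardless of result
  out <- assign_cohort(one_sample("2022-06-01"),
                       make_event("2022-05-20", "biopsy"))
  expect_equal(out$exclusion_reason, "post_biopsy")
})

test_that("an event on the draw date is associative, not exclusionary", {
  ev <- make_event("2022-06-01", "acr", grade = "A2", histology = TRUE,
                   treated = TRUE)
  expect_equal(assign_cohort(one_sample("2022-06-01"), ev)$label, "AR")
})

test_that("suspected AR without histology excludes the draw", {
  ev <- make_event("2022-06-10", "suspected_ar")
  out <- assign_cohort(one_sample("2022-06-01"), ev)
  expect_equal(out$label, "EXCLUDED")
  expect_equal(out$exclusion_reason, "suspected_ar_unconfirmed")
})

test_that("cohort association covers detection up to six weeks after the draw", {
  # histology-confirmed A2 ten days after the draw
  ev <- make_event("2022-06-11", "acr", grade = "A2", histology = TRUE)
  expect_equal(assign_cohort(one_sample("2022-06-01"), ev)$label, "AR")
  # unconfirmed ACR does not make the AR cohort under the default policy
  ev <- make_event("2022-06-11", "acr", grade = "A2", histology = FALSE)
  expect_equal(assign_cohort(one_sample("2022-06-01"), ev)$label, "STABLE")
  expect_equal(assign_cohort(one_sample("2022-06-01"), ev,
                             assignment_policy(require_histology_for_ar = FALSE))$label,
               "AR")
  # treated AMR counts as AR; untreated does not
  ev <- make_event("2022-06-20", "amr", histology = TRUE, treated = TRUE)
  expect_equal(assign_cohort(one_sample("2022-06-01"), ev)$label, "AR")
  ev <- make_event("2022-06-20", "amr", histology = TRUE, treated = FALSE)
  expect_equal(assign_cohort(one_sample("2022-06-01"), ev)$label, "STABLE")
  # beyond the window nothing associates
  ev <- make_event("2022-07-14", "acr", grade = "A1", histology = TRUE)
  expect_equal(assign_cohort(one_sample("2022-06-01"), ev)$label, "STABLE")
})

test_that("no events within the window means STABLE", {
  expect_equal(assign_cohort(one_sample(), no_events())$label, "STABLE")
})

test_that("CLAD is persistent from onset; other injury is windowed", {
  onset <- make_event("2022-01-15", "clad_onset")
  expect_equal(assign_cohort(one_sample("2022-06-01"), onset)$label, "CLAD")
  expect_equal(assign_cohort(one_sample("2022-01-01"), onset)$label, "STABLE")
  inj <- make_event("2022-06-10", "other_injury")
  expect_equal(assign_cohort(one_sample("2022-06-01"), inj)$label, "OTHER")
})

test_that("same-window rejection and infection resolve by precedence with a flag", {
  ev <- dplyr::bind_rows(
    make_event("2022-06-05", "acr", grade = "A1", histology = TRUE),
    make_event("2022-06-05", "infection", treated = TRUE)
  )
  out <- assign_cohort(one_sample("2022-06-01"), ev)
  expect_equal(out$label, "AR")
  expect_true(out$ambiguous)
})

test_that("every sample gets exactly one label and the accounting reconciles", {
  ds <- simulate_cohort(cohort_config(), seed = 6)
  labs <- assign_cohorts(ds)
  expect_equal(nrow(labs), nrow(ds$samples))
  expect_equal(sort(labs$sample_id), sort(ds$samples$sample_id))
  rep <- attr(labs, "report")
  expect_equal(rep$n_analyzed + rep$n_excluded, rep$n_samples)
  expect_equal(sum(rep$label_counts), rep$n_samples)
  expect_equal(sum(rep$exclusion_counts), rep$n_excluded)
  expect_equal((labs$exclusion_reason == "none"), (labs$label != "EXCLUDED"))
})

test_that("an empty event table labels every non-excluded sample STABLE", {
  ds <- tiny_dataset()
  ds$events <- ds$events[0, ]
  labs <- assign_cohorts(ds)
  expect_equal(labs$label, rep("STABLE", 3))
})

test_that("a flagged patient contributes only excluded samples", {
  p <- tiny_patients()
  p$excluded_patient[1] <- TRUE
  ds <- validate_dataset(p, tiny_samples(), tiny_events())
  labs <- assign_cohorts(ds)
  expect_equal(labs$label[labs$patient_id == "P1"], rep("EXCLUDED", 2))
  expect_equal(labs$exclusion_reason[labs$patient_id == "P1"],
               rep("patient_excluded", 2))
  expect_equal(labs$label[labs$patient_id == "P2"], "STABLE")
})

test_that("adding a look-back treatment can only move a label to EXCLUDED", {
  set.seed(31)
  for (i in 1:25) {
    type <- sample(c("acr", "infection", "other_injury", "none"), 1)
    ev <- switch(type,
      acr = make_event("2022-06-10", "acr", grade = "A1", histology = TRUE),
      infection = make_event("2022-06-10", "infection", treated = TRUE),
      other_injury = make_event("2022-06-10", "other_injury"),
      none = no_events()
    )
    before <- assign_cohort(one_sample("2022-06-01"), ev)
    ev2 <- dplyr::bind_rows(ev, make_event(
      as.character(as.Date("2022-06-01") - sample(1:42, 1)),
      "treatment_start"))
    after <- assign_cohort(one_sample("2022-06-01"), ev2)
    expect_equal(after$label, "EXCLUDED")
    expect_true(before$label %in% c("AR", "INFXN", "OTHER", "STABLE"))
  }
})

test_that("assigned labels recover the generator's ground truth across seeds", {
  for (s in 1:20) {
    ds <- simulate_cohort(cohort_config(), seed = s)
    labs <- assign_cohorts(ds)
    merged <- dplyr::inner_join(
      ds$truth,
      dplyr::select(labs, "sample_id", assigned = "label",
                    reason = "exclusion_reason"),
      by = "sample_id")
    expect_equal(merged$assigned, merged$label)
    expect_equal(merged$reason, merged$exclusion_reason)
  }
})
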