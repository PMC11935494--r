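# tiny hand-built datasets used across test files

tiny_patients <- function() {
  tibble::tibble(
    patient_id = c("P1", "P2"),
    transplant_date = as.Date(c("2022-01-01", "2022-02-01")),
    laterality = c("left", "right"),
    excluded_patient = c(FALSE, FALSE),
    exclusion_note = c("", "")
  )
}

tiny_samples <- function() {
  tibble::tibble(
    sample_id = c("S1", "S2", "S3"),
    patient_id = c("P1", "P1", "P2"),
    draw_date = as.Date(c("2022-06-01", "2022-10-01", "2022-08-01")),
    raw_fraction_pct = c(0.23, 0.90, 0.10)
  )
}

tiny_events <- function() {
  tibble::tibble(
    event_id = "E1",
    patient_id = "P1",
    event_date = as.Date("2022-10-10"),
    event_type = "acr",
    acr_grade = "A2",
    histology_confirmed = TRUE,
    treated = TRUE
  )
}

tiny_dataset <- function() {
  validate_dataset(tiny_patients(), tiny_samples(), tiny_events())
}

# one sample + surrounding events, for assignment-rule checks
one_sample <- function(draw = "2022-06-01") {
  tibble::tibble(sample_id = "S1", patient_id = "P1",
                 draw_date = as.Date(draw))
}

make_event <- function(date, type, grade = "none", histology = FALSE,
                       treated = FALSE) {
  tibble::tibble(event_id = paste0("E", seq_along(date)), patient_id = "P1",
                 event_date = as.Date(date), event_type = type,
                 acr_grade = grade, histology_confirmed = histology,
                 treated = treated)
}

no_events <- function() make_event(character(0), character(0))

# brute-force pair-enumeration AUROC oracle (independent of the rank path)
auroc_oracle <- function(pos, neg) {
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}
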