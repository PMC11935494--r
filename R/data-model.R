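#' Double a raw single-lung dd-cfDNA fraction
#'
#' Single lung transplant (SLT) recipients carry roughly half the donor lung
#' mass of double-lung recipients, so the raw donor-derived cell-free DNA
#' fraction is multiplied by 2 before comparison against the 1.0% positivity
#' threshold developed in double-lung cohorts.
#'
#' @param raw_fraction_pct Numeric vector of raw dd-cfDNA fractions in percent
#'   (0.46 means 0.46%). Must be finite and non-negative.
#' @return Numeric vector of corrected fractions, `2 * raw_fraction_pct`.
#' @examples
#' correct_for_slt(c(0.23, 0.90))
#' @export
correct_for_slt <- function(raw_fraction_pct) {
  if (!is.numeric(raw_fraction_pct)) {
    stop("`raw_fraction_pct` must be numeric.", call. = FALSE)
  }
  bad <- !is.finite(raw_fraction_pct) | raw_fraction_pct < 0
  if (any(bad)) {
    stop(
      "`raw_fraction_pct` must be finite and >= 0; offending value(s): ",
      paste(utils::head(raw_fraction_pct[bad], 5), collapse = ", "),
      call. = FALSE
    )
  }
  2 * raw_fraction_pct
}

#' Classify a corrected dd-cfDNA fraction against a positivity threshold
#'
#' The threshold comparison is inclusive: a fraction exactly at the threshold
#' is called positive, matching the clinical rule "dd-cfDNA >= 1.0%".
#'
#' @param corrected_fraction_pct Numeric vector of SLT-corrected fractions (%).
#' @param threshold_pct Positivity threshold in percent; default 1.0.
#' @return Character vector, `"positive"` or `"negative"`.
#' @examples
#' classify_threshold(c(0.999, 1.0, 1.8))
#' @export
classify_threshold <- function(corrected_fraction_pct, threshold_pct = 1.0) {
  stopifnot(is.numeric(corrected_fraction_pct), is.numeric(threshold_pct),
            length(threshold_pct) == 1L, is.finite(threshold_pct))
  if (any(!is.finite(corrected_fraction_pct))) {
    stop("`corrected_fraction_pct` must be finite.", call. = FALSE)
  }
  ifelse(corrected_fraction_pct >= threshold_pct, "positive", "negative")
}

cohort_levels <- function() c("STABLE", "AR", "INFXN", "CLAD", "OTHER")
label_levels <- function() c(cohort_levels(), "EXCLUDED")
exclusion_reasons <- function() {
  c("post_treatment_window", "post_biopsy", "suspected_ar_unconfirmed",
    "patient_excluded", "none")
}
event_types <- function() {
  c("biopsy", "acr", "amr", "infection", "clad_onset", "other_injury",
    "suspected_ar", "treatment_start")
}
acr_grades <- function() c("A1", "A2", "A3", "A4", "unspecified", "none")

stop_rows <- function(msg, ids) {
  stop(msg, ": ", paste(utils::head(ids, 5), collapse = ", "),
       if (length(ids) > 5) sprintf(" (and %d more)", length(ids) - 5),
       call. = FALSE)
}

#' Validate a patients / samples / events dataset
#'
#' Checks column presence, value domains, referential integrity (every sample
#' and event points to a known patient), date sanity, and non-negative finite
#' dd-cfDNA fractions. Derives `days_post_transplant` and
#' `corrected_fraction_pct` when absent.
#'
#' @param patients Data frame with columns `patient_id`, `transplant_date`,
#'   `laterality` (left/right/unknown), `excluded_patient` (logical),
#'   `exclusion_note`.
#' @param samples Data frame with columns `sample_id`, `patient_id`,
#'   `draw_date`, `raw_fraction_pct`; `corrected_fraction_pct` and
#'   `days_post_transplant` are recomputed if missing.
#' @param events Data frame with columns `event_id`, `patient_id`,
#'   `event_date`, `event_type`, `acr_grade`, `histology_confirmed`, `treated`.
#' @return A list with tibbles `patients`, `samples`, `events` (class
#'   `slt_dataset`).
#' @export
validate_dataset <- function(patients, samples, events) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop("Missing column(s) in ", what, ": ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  need(patients, c("patient_id", "transplant_date", "laterality",
                   "excluded_patient"), "patients")
  need(samples, c("sample_id", "patient_id", "draw_date", "raw_fraction_pct"),
       "samples")
  need(events, c("event_id", "patient_id", "event_date", "event_type",
                 "acr_grade", "histology_confirmed", "treated"), "events")

  patients <- tibble::as_tibble(patients)
  samples <- tibble::as_tibble(samples)
  events <- tibble::as_tibble(events)

  as_date_checked <- function(x, what) {
    out <- as.Date(x, format = "%Y-%m-%d")
    if (inherits(x, "Date")) out <- x
    if (any(is.na(out) & !is.na(x))) {
      stop_rows(paste0("Unparseable ISO-8601 date in ", what),
                as.character(x)[is.na(out) & !is.na(x)])
    }
    if (any(is.na(out))) stop("Missing date in ", what, call. = FALSE)
    out
  }
  patients$transplant_date <- as_date_checked(patients$transplant_date,
                                              "patients$transplant_date")
  samples$draw_date <- as_date_checked(samples$draw_date, "samples$draw_date")
  events$event_date <- as_date_checked(events$event_date, "events$event_date")

  if (anyDuplicated(patients$patient_id)) {
    stop_rows("Duplicated patient_id",
              patients$patient_id[duplicated(patients$patient_id)])
  }
  if (anyDuplicated(samples$sample_id)) {
    stop_rows("Duplicated sample_id",
              samples$sample_id[duplicated(samples$sample_id)])
  }
  if (!"exclusion_note" %in% names(patients)) patients$exclusion_note <- ""
  patients$exclusion_note[is.na(patients$exclusion_note)] <- ""
  patients$excluded_patient <- as.logical(patients$excluded_patient)
  bad_lat <- !patients$laterality %in% c("left", "right", "unknown")
  if (any(bad_lat)) stop_rows("Invalid laterality", patients$patient_id[bad_lat])

  orphan <- !samples$patient_id %in% patients$patient_id
  if (any(orphan)) {
    stop_rows("Sample(s) reference unknown patient_id",
              samples$sample_id[orphan])
  }
  orphan_e <- !events$patient_id %in% patients$patient_id
  if (any(orphan_e)) {
    stop_rows("Event(s) reference unknown patient_id", events$event_id[orphan_e])
  }

  bad_frac <- !is.finite(samples$raw_fraction_pct) | samples$raw_fraction_pct < 0
  if (any(bad_frac)) {
    stop_rows("raw_fraction_pct must be finite and >= 0 for sample(s)",
              samples$sample_id[bad_frac])
  }
  if (!"corrected_fraction_pct" %in% names(samples)) {
    samples$corrected_fraction_pct <- correct_for_slt(samples$raw_fraction_pct)
  } else {
    off <- abs(samples$corrected_fraction_pct -
                 2 * samples$raw_fraction_pct) > 1e-8
    if (any(off)) {
      stop_rows("corrected_fraction_pct != 2 * raw_fraction_pct for sample(s)",
                samples$sample_id[off])
    }
  }

  tx <- patients$transplant_date[match(samples$patient_id, patients$patient_id)]
  dpt <- as.integer(samples$draw_date - tx)
  if (any(dpt < 0)) {
    stop_rows("draw_date precedes transplant_date for sample(s)",
              samples$sample_id[dpt < 0])
  }
  samples$days_post_transplant <- dpt

  bad_type <- !events$event_type %in% event_types()
  if (any(bad_type)) stop_rows("Invalid event_type", events$event_id[bad_type])
  bad_grade <- !events$acr_grade %in% acr_grades()
  if (any(bad_grade)) stop_rows("Invalid acr_grade", events$event_id[bad_grade])
  grade_mismatch <- events$acr_grade != "none" & events$event_type != "acr"
  if (any(grade_mismatch)) {
    stop_rows("acr_grade set on non-ACR event(s)", events$event_id[grade_mismatch])
  }

  structure(list(patients = patients, samples = samples, events = events),
            class = "slt_dataset")
}

#' Read a patients / samples / events dataset from CSV
#'
#' @param patients_path,samples_path,events_path Paths to the three CSV files.
#' @return A validated `slt_dataset` list of tibbles (see
#'   [validate_dataset()]).
#' @export
read_dataset <- function(patients_path, samples_path, events_path) {
  rd <- function(p) readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  validate_dataset(rd(patients_path), rd(samples_path), rd(events_path))
}

#' Write a dataset to CSV files
#'
#' Writes `patients.csv`, `samples.csv` and `events.csv` (and
#' `truth_labels.csv` when the dataset carries a `truth` element) into `dir`.
#'
#' @param dataset An `slt_dataset` (or compatible list of data frames).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  parts <- c("patients", "samples", "events")
  if (!is.null(dataset$truth)) parts <- c(parts, "truth")
  paths <- character(0)
  for (p in parts) {
    file <- file.path(dir, paste0(if (p == "truth") "truth_labels" else p, ".csv"))
    readr::write_csv(dataset[[p]], file, progress = FALSE)
    paths[p] <- file
  }
  invisible(paths)
}
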