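#' Calibrate a lognormal to a printed median and interquartile range
#'
#' Fits the two-parameter lognormal whose median equals `median_pct` exactly
#' and whose log-scale IQR width equals `log(q75) - log(q25)` exactly:
#' `meanlog = log(median)`, `sdlog = (log(q75) - log(q25)) / (2 * qnorm(0.75))`.
#' Quartile asymmetry about the median (mild in published dd-cfDNA tables) is
#' not preserved — two printed constraints, two parameters.
#'
#' @param median_pct,q25_pct,q75_pct Median and quartiles in percent; all > 0,
#'   `q25 < q75`, median within `[q25, q75]`.
#' @return Named numeric vector `c(meanlog, sdlog)` usable with [stats::rlnorm()].
#' @examples
#' calibrate_lognormal(0.46, 0.20, 0.72)
#' @export
calibrate_lognormal <- function(median_pct, q25_pct, q75_pct) {
  stopifnot(is.numeric(median_pct), is.numeric(q25_pct), is.numeric(q75_pct))
  if (any(c(median_pct, q25_pct, q75_pct) <= 0)) {
    stop("Quantiles must be strictly positive.", call. = FALSE)
  }
  if (q25_pct >= q75_pct) stop("Need q25 < q75.", call. = FALSE)
  if (median_pct < q25_pct || median_pct > q75_pct) {
    stop("Median must lie within [q25, q75].", call. = FALSE)
  }
  c(meanlog = log(median_pct),
    sdlog = (log(q75_pct) - log(q25_pct)) / (2 * stats::qnorm(0.75)))
}

#' Published per-cohort dd-cfDNA and draw-time calibration table
#'
#' Medians and interquartile ranges of the SLT-corrected dd-cfDNA fraction and
#' of the draw time post-transplant, with analyzed sample counts, for the five
#' diagnostic cohorts of the multicenter SLT surveillance study. These are the
#' defaults the synthetic generator is calibrated to. OTHER has no published
#' draw-time distribution, so the all-cohort 233 (96-489) days is used for it
#' (and for planted excluded samples).
#'
#' @return A tibble with one row per cohort: `label`, `n_samples`,
#'   `median_pct`, `q25_pct`, `q75_pct`, `time_median_d`, `time_q25_d`,
#'   `time_q75_d`.
#' @export
cohort_reference <- function() {
  tibble::tribble(
    ~label,   ~n_samples, ~median_pct, ~q25_pct, ~q75_pct, ~time_median_d, ~time_q25_d, ~time_q75_d,
    "STABLE", 137L,       0.46,        0.20,     0.72,     230,            130,         334,
    "AR",     25L,        1.80,        1.04,     3.56,     456,            153,         570,
    "INFXN",  41L,        1.10,        0.52,     1.74,     264,            129,         503,
    "CLAD",   7L,         0.96,        0.75,     1.06,     720,            419.5,       1617,
    "OTHER",  12L,        2.01,        1.28,     3.31,     233,            96,          489
  )
}

#' Configuration for the synthetic SLT surveillance cohort generator
#'
#' Defaults reproduce the published study's accounting: 103 patients (102
#' analyzed plus one fully excluded), 257 samples of which 222 are analyzed
#' (STABLE 137, AR 25, INFXN 41, CLAD 7, OTHER 12), 30 samples excluded inside
#' the 42-day post-treatment window (including all samples from the excluded
#' patient) and 5 excluded as suspected-but-unconfirmed acute rejection.
#'
#' @param cohort_specs Tibble as returned by [cohort_reference()]; per-cohort
#'   dd-cfDNA and draw-time calibration plus analyzed sample counts.
#' @param n_patients Number of analyzed patients (the excluded patient is
#'   added on top).
#' @param laterality_probs Probabilities for left / right / unknown allograft
#'   side; must sum to 1. The published proportions 52.9 / 44.1 / 2.9 sum to
#'   99.9 (rounding), so the default carries the residual on `unknown`.
#' @param n_excluded_treatment_window Total samples planted with a qualifying
#'   treatment 1-42 days before the draw, `n_excluded_patient_samples` of
#'   which sit on the flagged excluded patient.
#' @param n_excluded_suspected_ar Samples planted with a suspected AR event
#'   lacking histologic confirmation.
#' @param n_excluded_patient_samples Samples carried by the one excluded
#'   patient (counted inside `n_excluded_treatment_window`).
#' @param acr_grade_counts Named counts of ACR samples by ISHLT grade within
#'   the AR cohort; the remainder of the AR cohort is treated AMR.
#' @param min_gap_event_days,min_gap_stable_days Minimum spacing between two
#'   draws of one patient when either draw carries clinical events
#'   (respectively when both are event-free STABLE draws). The event-side
#'   default of 100 days keeps any +/-42-day event window from leaking into a
#'   neighbouring sample's window; the STABLE-side default of 30 days lets
#'   within-patient pairs violate the 90-day independence gap so the
#'   subsampling stage has real work to do.
#' @param max_samples_per_patient Upper bound on draws per patient.
#' @param first_transplant_date Earliest transplant date in the cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(cohort_specs = cohort_reference(),
                          n_patients = 102L,
                          laterality_probs = c(left = 0.529, right = 0.441,
                                               unknown = 0.030),
                          n_excluded_treatment_window = 30L,
                          n_excluded_suspected_ar = 5L,
                          n_excluded_patient_samples = 3L,
                          acr_grade_counts = c(A1 = 8L, A2 = 5L, A3 = 0L,
                                               A4 = 1L, unspecified = 7L),
                          min_gap_event_days = 100L,
                          min_gap_stable_days = 30L,
                          max_samples_per_patient = 6L,
                          first_transplant_date = as.Date("2019-06-01")) {
  stopifnot(all(c("label", "n_samples", "median_pct", "q25_pct", "q75_pct")
                %in% names(cohort_specs)))
  if (abs(sum(laterality_probs) - 1) > 1e-9) {
    stop("laterality_probs must sum to 1.", call. = FALSE)
  }
  counts <- c(n_patients, n_excluded_treatment_window, n_excluded_suspected_ar,
              n_excluded_patient_samples, cohort_specs$n_samples)
  if (any(counts < 0)) stop("Counts must be non-negative.", call. = FALSE)
  if (n_excluded_patient_samples > n_excluded_treatment_window) {
    stop("Excluded patient's samples are counted inside the treatment-window ",
         "exclusions.", call. = FALSE)
  }
  n_ar <- cohort_specs$n_samples[cohort_specs$label == "AR"]
  if (length(n_ar) == 1 && sum(acr_grade_counts) > n_ar) {
    stop("ACR grade counts exceed the AR cohort size.", call. = FALSE)
  }
  structure(
    list(cohort_specs = tibble::as_tibble(cohort_specs),
         n_patients = as.integer(n_patients),
         laterality_probs = laterality_probs,
         n_excluded_treatment_window = as.integer(n_excluded_treatment_window),
         n_excluded_suspected_ar = as.integer(n_excluded_suspected_ar),
         n_excluded_patient_samples = as.integer(n_excluded_patient_samples),
         acr_grade_counts = acr_grade_counts,
         min_gap_event_days = as.integer(min_gap_event_days),
         min_gap_stable_days = as.integer(min_gap_stable_days),
         max_samples_per_patient = as.integer(max_samples_per_patient),
         first_transplant_date = first_transplant_date),
    class = "cohort_config"
  )
}

# days post-transplant for n slots from the cohort's calibrated lognormal,
# clamped away from implausibly early/late draws
draw_days <- function(spec_row, n) {
  par <- calibrate_lognormal(spec_row$time_median_d, spec_row$time_q25_d,
                             spec_row$time_q75_d)
  pmin(pmax(round(stats::rlnorm(n, par["meanlog"], par["sdlog"])), 21), 2400)
}

# integer partition of n_slots into n_patients counts within [1, max_k]
partition_slots <- function(n_slots, n_patients, max_k) {
  if (n_slots < n_patients || n_slots > n_patients * max_k) {
    stop("Infeasible configuration: ", n_slots, " samples cannot be spread ",
         "over ", n_patients, " patients at 1-", max_k, " samples each.",
         call. = FALSE)
  }
  prob <- c(0.34, 0.26, 0.16, 0.10, 0.08, 0.06)
  prob <- if (max_k <= 6) prob[seq_len(max_k)] else c(prob, rep(0.01, max_k - 6))
  k <- sample(seq_len(max_k), n_patients, replace = TRUE, prob = prob)
  while (sum(k) != n_slots) {
    i <- sample.int(n_patients, 1)
    if (sum(k) > n_slots && k[i] > 1L) k[i] <- k[i] - 1L
    if (sum(k) < n_slots && k[i] < max_k) k[i] <- k[i] + 1L
  }
  k
}

# order one patient's slots (CLAD last, persistent state) and push draws
# apart so no event window can leak into a neighbouring draw's window
space_patient_slots <- function(df, gap_event, gap_stable) {
  df <- df[order(df$cohort == "CLAD", df$days), , drop = FALSE]
  is_clad <- df$cohort == "CLAD"
  if (any(is_clad) && any(!is_clad)) {
    non_clad_max <- max(df$days[!is_clad])
    first_clad <- which(is_clad)[1]
    if (df$days[first_clad] <= non_clad_max) {
      df$days[is_clad] <- df$days[is_clad] +
        (non_clad_max - df$days[first_clad]) + 150
    }
  }
  if (nrow(df) > 1) {
    eventful <- df$cohort != "STABLE"
    for (i in 2:nrow(df)) {
      gap_needed <- if (eventful[i] || eventful[i - 1]) gap_event else gap_stable
      if (df$days[i] - df$days[i - 1] < gap_needed) {
        df$days[i] <- df$days[i - 1] + gap_needed
      }
    }
  }
  df
}

#' Generate a synthetic SLT dd-cfDNA surveillance dataset
#'
#' Produces a longitudinal patient / sample / clinical-event dataset in which
#' each analyzed sample's corrected dd-cfDNA fraction is drawn from its
#' cohort's quantile-calibrated lognormal, clinical events are planted so that
#' [assign_cohorts()] recovers the intended label for every sample, the
#' configured numbers of excluded samples carry qualifying event histories
#' (a treatment 1-42 days before the draw; a suspected AR without histologic
#' confirmation), and one extra patient is flagged excluded with all of their
#' samples. Ground-truth labels are returned for verification.
#'
#' Diagnostic events (ACR/AMR/infection/other injury) are planted on or up to
#' 42 days after their sample's draw — consistent with dd-cfDNA elevation
#' preceding clinical detection — so they associate with the draw without
#' triggering the post-event exclusion look-back. CLAD onset is placed before
#' a patient's first CLAD draw and CLAD draws are the patient's last, since
#' CLAD is persistent. Samples within a cohort are independent draws: no
#' within-patient autocorrelation or treatment-response kinetics are
#' simulated.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   it.
#' @return An `slt_dataset` list with tibbles `patients`, `samples`, `events`,
#'   and `truth` (`sample_id`, `label`, `exclusion_reason`).
#' @examples
#' ds <- simulate_cohort(seed = 1)
#' nrow(ds$samples)
#' @export
simulate_cohort <- function(config = cohort_config(), seed) {
  if (missing(seed) || is.null(seed)) {
    stop("A `seed` is required for reproducible generation.", call. = FALSE)
  }
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  specs <- config$cohort_specs
  n_excl_regular <- config$n_excluded_treatment_window -
    config$n_excluded_patient_samples

  # --- slots on regular patients (analyzed + planted exclusions) -------------
  slot_cohort <- c(rep(specs$label, specs$n_samples),
                   rep(".EXCL_TREAT", n_excl_regular),
                   rep(".EXCL_SUSP", config$n_excluded_suspected_ar))
  slot_cohort <- sample(slot_cohort)
  k <- partition_slots(length(slot_cohort), config$n_patients,
                       config$max_samples_per_patient)
  slots <- tibble::tibble(
    cohort = slot_cohort,
    patient_idx = rep(seq_len(config$n_patients), times = k)
  )

  # excluded patient's slots appended (always .EXCL_TREAT-style histories)
  if (config$n_excluded_patient_samples > 0) {
    slots <- dplyr::bind_rows(slots, tibble::tibble(
      cohort = rep(".EXCL_TREAT", config$n_excluded_patient_samples),
      patient_idx = config$n_patients + 1L
    ))
  }
  n_total_patients <- config$n_patients +
    as.integer(config$n_excluded_patient_samples > 0)

  # --- dd-cfDNA fractions and draw times per slot ----------------------------
  value_cohort <- dplyr::case_match(slots$cohort,
                                    ".EXCL_TREAT" ~ "STABLE",
                                    ".EXCL_SUSP" ~ "AR",
                                    .default = slots$cohort)
  time_cohort <- dplyr::case_match(slots$cohort,
                                   ".EXCL_TREAT" ~ "OTHER",
                                   ".EXCL_SUSP" ~ "AR",
                                   .default = slots$cohort)
  corrected <- numeric(nrow(slots))
  days <- numeric(nrow(slots))
  for (lab in unique(value_cohort)) {
    idx <- which(value_cohort == lab)
    row <- specs[specs$label == lab, ]
    par <- calibrate_lognormal(row$median_pct, row$q25_pct, row$q75_pct)
    corrected[idx] <- stats::rlnorm(length(idx), par["meanlog"], par["sdlog"])
  }
  for (lab in unique(time_cohort)) {
    idx <- which(time_cohort == lab)
    days[idx] <- draw_days(specs[specs$label == lab, ], length(idx))
  }
  slots$raw_fraction_pct <- round(corrected / 2, 4)
  slots$days <- days

  slots <- slots |>
    dplyr::group_by(.data$patient_idx) |>
    dplyr::group_modify(~ space_patient_slots(.x, config$min_gap_event_days,
                                              config$min_gap_stable_days)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$patient_idx, .data$days)

  # --- patients --------------------------------------------------------------
  patients <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n_total_patients)),
    transplant_date = config$first_transplant_date +
      sample.int(540, n_total_patients, replace = TRUE) - 1L,
    laterality = sample(names(config$laterality_probs), n_total_patients,
                        replace = TRUE, prob = config$laterality_probs),
    excluded_patient = FALSE,
    exclusion_note = ""
  )
  if (config$n_excluded_patient_samples > 0) {
    patients$excluded_patient[n_total_patients] <- TRUE
    patients$exclusion_note[n_total_patients] <-
      "active malignancy (synthetic)"
  }

  # --- samples ---------------------------------------------------------------
  slots$patient_id <- patients$patient_id[slots$patient_idx]
  slots$sample_id <- sprintf("S%04d", seq_len(nrow(slots)))
  slots$draw_date <- patients$transplant_date[slots$patient_idx] + slots$days
  samples <- tibble::tibble(
    sample_id = slots$sample_id,
    patient_id = slots$patient_id,
    draw_date = slots$draw_date,
    raw_fraction_pct = slots$raw_fraction_pct,
    corrected_fraction_pct = 2 * slots$raw_fraction_pct,
    days_post_transplant = as.integer(slots$days)
  )

  # --- events planted per slot ----------------------------------------------
  ar_idx <- which(slots$cohort == "AR")
  ar_idx <- sample(ar_idx)  # random grade assignment within the AR cohort
  grade_vec <- rep(names(config$acr_grade_counts), config$acr_grade_counts)
  n_acr <- length(grade_vec)
  acr_idx <- ar_idx[seq_len(min(n_acr, length(ar_idx)))]
  amr_idx <- setdiff(ar_idx, acr_idx)

  ev <- list()
  add_events <- function(idx, type, offset, grade = "none",
                         histology = FALSE, treated = FALSE) {
    if (!length(idx)) return(NULL)
    tibble::tibble(
      patient_id = slots$patient_id[idx],
      event_date = slots$draw_date[idx] + offset,
      event_type = type, acr_grade = grade,
      histology_confirmed = histology, treated = treated
    )
  }
  ev$acr <- add_events(acr_idx, "acr",
                       sample(0:42, length(acr_idx), replace = TRUE),
                       grade = grade_vec[seq_along(acr_idx)],
                       histology = TRUE, treated = TRUE)
  ev$amr <- add_events(amr_idx, "amr",
                       sample(0:42, length(amr_idx), replace = TRUE),
                       histology = TRUE, treated = TRUE)
  inf_idx <- which(slots$cohort == "INFXN")
  ev$infxn <- add_events(inf_idx, "infection",
                         sample(0:42, length(inf_idx), replace = TRUE),
                         treated = TRUE)
  oth_idx <- which(slots$cohort == "OTHER")
  ev$other <- add_events(oth_idx, "other_injury",
                         sample(0:42, length(oth_idx), replace = TRUE))
  tw_idx <- which(slots$cohort == ".EXCL_TREAT")
  ev$treat <- add_events(tw_idx, "treatment_start",
                         -sample(1:42, length(tw_idx), replace = TRUE),
                         treated = TRUE)
  susp_idx <- which(slots$cohort == ".EXCL_SUSP")
  ev$susp <- add_events(susp_idx, "suspected_ar",
                        sample(0:42, length(susp_idx), replace = TRUE))
  # one persistent CLAD onset per patient with CLAD draws, before the first
  clad <- slots[slots$cohort == "CLAD", ]
  if (nrow(clad)) {
    onset <- clad |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(first_draw = min(.data$draw_date), .groups = "drop")
    ev$clad <- tibble::tibble(
      patient_id = onset$patient_id,
      event_date = onset$first_draw -
        sample(1:30, nrow(onset), replace = TRUE),
      event_type = "clad_onset", acr_grade = "none",
      histology_confirmed = FALSE, treated = FALSE
    )
  }
  events <- dplyr::bind_rows(ev)
  if (nrow(events)) {
    events <- events[sample.int(nrow(events)), , drop = FALSE]
    events$event_id <- sprintf("E%04d", seq_len(nrow(events)))
    events <- dplyr::select(events, "event_id", dplyr::everything())
  } else {
    events <- tibble::tibble(event_id = character(), patient_id = character(),
                             event_date = as.Date(character()),
                             event_type = character(), acr_grade = character(),
                             histology_confirmed = logical(),
                             treated = logical())
  }

  # --- ground truth ----------------------------------------------------------
  truth <- tibble::tibble(
    sample_id = slots$sample_id,
    label = dplyr::case_match(slots$cohort,
                              ".EXCL_TREAT" ~ "EXCLUDED",
                              ".EXCL_SUSP" ~ "EXCLUDED",
                              .default = slots$cohort),
    exclusion_reason = dplyr::case_when(
      slots$patient_idx == config$n_patients + 1L ~ "patient_excluded",
      slots$cohort == ".EXCL_TREAT" ~ "post_treatment_window",
      slots$cohort == ".EXCL_SUSP" ~ "suspected_ar_unconfirmed",
      .default = "none"
    )
  ) |> dplyr::arrange(.data$sample_id)

  validate_dataset(patients, samples, events) |>
    (\(d) {
      d$truth <- truth
      d
    })()
}

#' Empirical quantiles of a generated cohort against its calibration target
#'
#' Generator self-check: computes the sample median and quartiles of the
#' corrected dd-cfDNA fraction for one cohort label and returns them beside
#' the calibration target.
#'
#' @param samples Samples tibble with `sample_id` and `corrected_fraction_pct`.
#' @param labels Labels tibble with `sample_id` and `label` (e.g. the
#'   generator's `truth` or [assign_cohorts()] output).
#' @param label Cohort label to check.
#' @param spec Calibration table, default [cohort_reference()].
#' @param min_n Minimum samples required (quantiles of fewer are too noisy to
#'   certify calibration).
#' @return One-row tibble: `label`, `n`, observed `median`/`q25`/`q75`, target
#'   `median_target`/`q25_target`/`q75_target`.
#' @export
empirical_quantile_check <- function(samples, labels, label,
                                     spec = cohort_reference(), min_n = 20) {
  vals <- dplyr::inner_join(samples, labels, by = "sample_id") |>
    dplyr::filter(.data$label == !!label) |>
    dplyr::pull("corrected_fraction_pct")
  if (length(vals) < min_n) {
    stop("Only ", length(vals), " samples labelled ", label,
         "; need at least ", min_n, " for a quantile check.", call. = FALSE)
  }
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  target <- spec[spec$label == label, ]
  tibble::tibble(label = label, n = length(vals),
                 median = q[2], q25 = q[1], q75 = q[3],
                 median_target = target$median_pct,
                 q25_target = target$q25_pct, q75_target = target$q75_pct)
}
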