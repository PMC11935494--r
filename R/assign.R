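#' Cohort-assignment policy
#'
#' Window lengths and histology requirements governing how each blood draw is
#' matched to clinical events. Diagnostic association uses events within
#' `association_window_days` of the draw (±6 weeks by default). Exclusion
#' uses a half-open look-back: an acute event (biopsy, confirmed ACR/AMR,
#' infection, treatment start) strictly before the draw and within
#' `post_event_exclusion_days` excludes the sample; an event on the draw date
#' itself is associative, not exclusionary, so a draw that prompts detection
#' of rejection or infection still enters its cohort while draws taken during
#' or shortly after treatment do not.
#'
#' @param association_window_days Days either side of the draw within which
#'   an event is considered related (default 42).
#' @param post_event_exclusion_days Length of the post-event exclusion
#'   look-back in days (default 42).
#' @param require_histology_for_ar Must ACR/AMR events be
#'   histology-confirmed to enter the AR cohort (default `TRUE`)?
#' @return A list of class `assignment_policy`.
#' @export
assignment_policy <- function(association_window_days = 42L,
                              post_event_exclusion_days = 42L,
                              require_histology_for_ar = TRUE) {
  stopifnot(association_window_days > 0, post_event_exclusion_days > 0)
  structure(
    list(association_window_days = as.integer(association_window_days),
         post_event_exclusion_days = as.integer(post_event_exclusion_days),
         require_histology_for_ar = isTRUE(require_histology_for_ar)),
    class = "assignment_policy"
  )
}

# label one sample from its patient's events; returns list(label, reason,
# ambiguous)
assign_one <- function(draw_date, events, policy, patient_excluded) {
  if (isTRUE(patient_excluded)) {
    return(list(label = "EXCLUDED", reason = "patient_excluded",
                ambiguous = FALSE))
  }
  w <- policy$association_window_days
  lb <- policy$post_event_exclusion_days
  delta <- as.numeric(draw_date - events$event_date)  # >0: event before draw

  # post-event exclusion: acute event strictly before the draw, within the
  # look-back window
  acute <- events$event_type %in%
    c("biopsy", "acr", "amr", "infection", "treatment_start")
  in_lookback <- acute & delta > 0 & delta <= lb
  if (any(in_lookback)) {
    reason <- if (all(events$event_type[in_lookback] == "biopsy")) {
      "post_biopsy"
    } else {
      "post_treatment_window"
    }
    return(list(label = "EXCLUDED", reason = reason, ambiguous = FALSE))
  }

  in_window <- abs(delta) <= w
  if (any(in_window & events$event_type == "suspected_ar" &
            !events$histology_confirmed)) {
    return(list(label = "EXCLUDED", reason = "suspected_ar_unconfirmed",
                ambiguous = FALSE))
  }

  histo_ok <- if (policy$require_histology_for_ar) {
    events$histology_confirmed
  } else {
    rep(TRUE, nrow(events))
  }
  is_ar <- in_window &
    ((events$event_type == "acr" & histo_ok) |
       (events$event_type == "amr" & histo_ok & events$treated))
  is_infxn <- in_window & events$event_type == "infection" & events$treated
  is_clad <- events$event_type == "clad_onset" & delta >= 0  # persistent state
  is_other <- in_window & events$event_type == "other_injury"

  hits <- c(AR = any(is_ar), INFXN = any(is_infxn), CLAD = any(is_clad),
            OTHER = any(is_other))
  if (!any(hits)) {
    return(list(label = "STABLE", reason = "none", ambiguous = FALSE))
  }
  # fixed precedence: rejection is the study focus, then infection, then the
  # chronic state, then other injury
  label <- names(hits)[which(hits)[1]]
  list(label = label, reason = "none", ambiguous = sum(hits) > 1)
}

#' Assign one sample to a diagnostic cohort or exclusion
#'
#' Applies, in order of precedence: patient-level exclusion; post-event
#' exclusion (acute event in the 42-day look-back before the draw — biopsy
#' gives reason `post_biopsy`, any treated/confirmed rejection, infection or
#' treatment gives `post_treatment_window`); suspected-AR-without-histology
#' exclusion; then cohort association within ±`association_window_days`:
#' AR (histology-confirmed ACR grade A1-A4/unspecified, or treated AMR) >
#' INFXN (treated infection) > CLAD (onset on or before the draw; persistent)
#' > OTHER (other graft injury) > STABLE.
#'
#' @param sample One-row data frame (or list) with `draw_date`.
#' @param patient_events Events of the sample's patient.
#' @param policy An [assignment_policy()].
#' @param patient_excluded Is the sample's patient flagged excluded?
#' @return One-row tibble: `label`, `exclusion_reason`, `ambiguous`.
#' @export
assign_cohort <- function(sample, patient_events,
                          policy = assignment_policy(),
                          patient_excluded = FALSE) {
  res <- assign_one(as.Date(sample$draw_date), patient_events, policy,
                    patient_excluded)
  tibble::tibble(label = res$label, exclusion_reason = res$reason,
                 ambiguous = res$ambiguous)
}

#' Assign every sample in a dataset to a cohort or exclusion
#'
#' Vectorised [assign_cohort()] over a full dataset. The result carries an
#' accounting report (`attr(., "report")` or [assignment_report()]): counts
#' per label and per exclusion reason, which always reconcile — analyzed +
#' excluded = total samples. Samples with qualifying events of more than one
#' diagnostic category in the window are labelled by precedence and flagged
#' `ambiguous` (and listed in the report), never silently.
#'
#' @param samples,events,patients Tibbles as in a validated `slt_dataset`; a
#'   single `slt_dataset` may be passed as `samples` instead.
#' @param policy An [assignment_policy()].
#' @return Tibble with one row per sample: `sample_id`, `patient_id`, `label`,
#'   `exclusion_reason`, `ambiguous`; report in `attr(., "report")`.
#' @examples
#' ds <- simulate_cohort(seed = 1)
#' labels <- assign_cohorts(ds)
#' attr(labels, "report")$label_counts
#' @export
assign_cohorts <- function(samples, events = NULL, patients = NULL,
                           policy = assignment_policy()) {
  if (inherits(samples, "slt_dataset") ||
        (is.list(samples) && !is.data.frame(samples) &&
           all(c("samples", "events", "patients") %in% names(samples)))) {
    ds <- samples
    samples <- ds$samples
    events <- ds$events
    patients <- ds$patients
  }
  stopifnot(is.data.frame(samples), is.data.frame(events),
            is.data.frame(patients), inherits(policy, "assignment_policy"))

  excluded_pat <- patients$patient_id[patients$excluded_patient]
  ev_by_pat <- split(events, events$patient_id)
  empty_ev <- events[0, , drop = FALSE]

  res <- purrr::pmap(
    list(samples$draw_date, samples$patient_id),
    function(draw_date, patient_id) {
      pe <- ev_by_pat[[patient_id]]
      if (is.null(pe)) pe <- empty_ev
      assign_one(draw_date, pe, policy, patient_id %in% excluded_pat)
    }
  )
  labels <- tibble::tibble(
    sample_id = samples$sample_id,
    patient_id = samples$patient_id,
    label = purrr::map_chr(res, "label"),
    exclusion_reason = purrr::map_chr(res, "reason"),
    ambiguous = purrr::map_lgl(res, "ambiguous")
  )
  attr(labels, "report") <- assignment_report(labels)
  labels
}

#' Accounting report for a set of cohort labels
#'
#' @param labels Output of [assign_cohorts()].
#' @return A list: `n_samples`, `n_analyzed`, `n_excluded`, `label_counts`
#'   (named, all six labels), `exclusion_counts` (named, by reason),
#'   `ambiguous_sample_ids`.
#' @export
assignment_report <- function(labels) {
  lc <- table(factor(labels$label, levels = label_levels()))
  ec <- table(factor(
    labels$exclusion_reason[labels$label == "EXCLUDED"],
    levels = setdiff(exclusion_reasons(), "none")
  ))
  list(
    n_samples = nrow(labels),
    n_analyzed = sum(labels$label != "EXCLUDED"),
    n_excluded = sum(labels$label == "EXCLUDED"),
    label_counts = c(lc),
    exclusion_counts = c(ec),
    ambiguous_sample_ids =
      labels$sample_id[labels$ambiguous %||% rep(FALSE, nrow(labels))]
  )
}
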