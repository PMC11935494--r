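#' Run the full surveillance analysis pipeline
#'
#' Orchestrates simulate (or read) -> assign -> cohort/laterality/time
#' comparisons -> time trend -> performance estimation, writing every
#' intermediate artifact plus a manifest to `output_dir`. Identical
#' configuration and seed produce identical outputs: the master seed fans out
#' to stage seeds by fixed offsets so stages can be rerun in isolation.
#'
#' @param output_dir Directory for run artifacts (created if needed).
#' @param seed Master integer seed.
#' @param generator A [cohort_config()]; ignored when `dataset` is supplied.
#' @param policy An [assignment_policy()].
#' @param resampling A [resampling_config()].
#' @param dataset Optional pre-built `slt_dataset` (e.g. from
#'   [read_dataset()]); when `NULL` a synthetic cohort is generated.
#' @return Invisibly, the run manifest (list): seeds, per-stage row counts,
#'   accounting report, prevalence, and paths of the files written.
#' @export
run_pipeline <- function(output_dir, seed,
                         generator = cohort_config(),
                         policy = assignment_policy(),
                         resampling = resampling_config(),
                         dataset = NULL) {
  if (missing(seed) || is.null(seed)) stop("A `seed` is required.", call. = FALSE)
  seed <- as.integer(seed)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(output_dir, paste0(name, ".csv"))
    readr::write_csv(df, p, progress = FALSE)
    paths[name] <<- p
    p
  }

  # stage 1: data
  if (is.null(dataset)) dataset <- simulate_cohort(generator, seed = seed)
  written <- write_dataset(dataset, output_dir)
  paths[names(written)] <- written

  # stage 2: cohort assignment
  labels <- assign_cohorts(dataset, policy = policy)
  report <- attr(labels, "report")
  emit(labels, "labels")
  jsonlite::write_json(report, file.path(output_dir, "assignment_report.json"),
                       auto_unbox = TRUE, digits = NA)
  paths["assignment_report"] <- file.path(output_dir, "assignment_report.json")

  # stage 3: group statistics
  emit(compare_cohorts(dataset$samples, labels), "cohort_table")
  lat <- compare_laterality(dataset$samples, labels, dataset$patients)
  if (nrow(lat)) emit(lat, "laterality_table")
  emit(compare_draw_times(dataset$samples, labels), "time_table")

  stable <- dataset$samples |>
    dplyr::inner_join(dplyr::select(labels, "sample_id", "label"),
                      by = "sample_id") |>
    dplyr::filter(.data$label == "STABLE")
  trend <- fit_time_trend(stable)

  # stage 4: diagnostic performance (fixed study prevalence unless overridden)
  prevalence <- resampling$prevalence %||% study_prevalence(labels)
  resampling$prevalence <- prevalence
  perf_df <- dataset$samples |>
    dplyr::inner_join(dplyr::select(labels, "sample_id", "label"),
                      by = "sample_id")
  perf <- estimate_performance(perf_df, resampling, seed = seed + 1L)
  emit(tidy(perf), "performance_summary")
  emit(perf$roc, "roc_curve")

  manifest <- list(
    seed = seed, stage_seeds = list(generate = seed, performance = seed + 1L),
    n_patients = nrow(dataset$patients),
    n_samples = nrow(dataset$samples),
    n_events = nrow(dataset$events),
    n_analyzed = report$n_analyzed,
    n_excluded = report$n_excluded,
    label_counts = as.list(report$label_counts),
    exclusion_counts = as.list(report$exclusion_counts),
    prevalence = prevalence,
    iterations = perf$iterations_used,
    degenerate_redraws = perf$n_redraws,
    reduced_iterations = perf$iterations_used < 10000L,
    time_trend = list(slope = trend$slope, r_squared = trend$r_squared,
                      p_slope = trend$p_slope, n = trend$n),
    outputs = as.list(paths)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Render report tables from a completed pipeline run
#'
#' Re-reads a run directory and emits the three report tables with the
#' presentation rounding used in clinical dd-cfDNA reports (fractions and
#' percentages to 2 decimals, ratios to 2 decimals, AUROC to 3), plus the
#' sample-accounting summary.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return A list of tibbles: `cohorts`, `laterality` (may be empty),
#'   `performance`, and the `accounting` list.
#' @export
render_report <- function(run_dir) {
  need <- file.path(run_dir, c("cohort_table.csv", "performance_summary.csv",
                               "assignment_report.json"))
  missing_f <- need[!file.exists(need)]
  if (length(missing_f)) {
    stop("Missing stage output(s): ", paste(basename(missing_f),
                                            collapse = ", "), call. = FALSE)
  }
  rd <- function(name) {
    p <- file.path(run_dir, paste0(name, ".csv"))
    if (file.exists(p)) {
      readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
    } else {
      tibble::tibble()
    }
  }
  cohorts <- rd("cohort_table") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with(c("median", "q25", "q75")),
                                ~ round(.x, 2)),
                  dplyr::across(dplyr::starts_with("p_"), ~ signif(.x, 3)))
  lat <- rd("laterality_table")
  if (nrow(lat)) {
    lat <- lat |>
      dplyr::mutate(dplyr::across(dplyr::starts_with(c("median", "q25", "q75")),
                                  ~ round(.x, 2)),
                    dplyr::across(dplyr::starts_with("p_"), ~ signif(.x, 3)))
  } else {
    warning("Laterality table absent or empty for this run.")
  }
  perf <- rd("performance_summary")
  pct <- perf$term %in% c("sensitivity", "specificity", "ppv", "npv")
  num <- c("estimate", "conf.low", "conf.high")
  perf[pct, num] <- round(perf[pct, num] * 100, 2)
  perf[perf$term == "auroc", num] <- round(perf[perf$term == "auroc", num], 3)
  perf[perf$term %in% c("lr_pos", "lr_neg"), num] <-
    round(perf[perf$term %in% c("lr_pos", "lr_neg"), num], 2)
  accounting <- jsonlite::read_json(
    file.path(run_dir, "assignment_report.json"), simplifyVector = TRUE)
  list(cohorts = cohorts, laterality = lat, performance = perf,
       accounting = accounting)
}
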