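#' Median and interquartile range
#'
#' Quantiles use linear interpolation between order statistics (the "type 7"
#' convention of [stats::quantile()]), the fixed rule used throughout the
#' package's tables.
#'
#' @param values Numeric vector, length >= 1.
#' @return Named numeric vector `c(median, q25, q75)`.
#' @examples
#' median_iqr(c(8.18, 5.90, 2.32, 4.72))
#' @export
median_iqr <- function(values) {
  if (!length(values)) stop("Empty input.", call. = FALSE)
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q25 = q[2], q75 = q[3])
}

#' Two-sided Mann-Whitney U test
#'
#' U is computed by rank sums with midranks for ties. The p-value uses the
#' exact distribution when both groups have at most `exact_max` observations
#' and the pooled values are tie-free, and otherwise the normal approximation
#' with tie correction and continuity correction — a reproducible switch
#' chosen so the smallest cohort sizes in dd-cfDNA tables get exact p-values.
#'
#' @param values_a,values_b Numeric vectors, each non-empty.
#' @param exact_max Largest per-group n for which the exact null distribution
#'   is used (default 20).
#' @return One-row tibble: `n_a`, `n_b`, `u_statistic` (U of group a),
#'   `p_raw`.
#' @export
mann_whitney_two_sided <- function(values_a, values_b, exact_max = 20L) {
  if (!length(values_a) || !length(values_b)) {
    stop("Both groups must be non-empty.", call. = FALSE)
  }
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  use_exact <- length(values_a) <= exact_max && length(values_b) <= exact_max &&
    !ties
  ht <- stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                           exact = use_exact, correct = TRUE)
  tibble::tibble(n_a = length(values_a), n_b = length(values_b),
                 u_statistic = unname(ht$statistic), p_raw = ht$p.value)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: sort ascending, multiply the i-th p-value by m/i,
#' enforce monotone non-decreasing from the largest rank down, cap at 1, and
#' return in input order (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.5889, 0.8208, 0.5981, 0.3850, 0.7237, 0.4102))
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    stop("All p-values must lie in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Linear regression of dd-cfDNA fraction on time post-transplant
#'
#' Ordinary least squares of the corrected fraction on days post-transplant,
#' used to assess whether the stable-allograft baseline drifts across early
#' versus late epochs. The p-value is the two-sided t-test of the slope.
#'
#' @param data Data frame with the two columns named below.
#' @param fraction_col,days_col Column names (strings) of the corrected
#'   fraction (%) and days post-transplant.
#' @return An object of class `time_trend` with elements `slope` (% per day),
#'   `intercept` (%), `r_squared`, `p_slope`, `n`, and the underlying `fit`.
#'   Supports [generics::tidy()] and [generics::glance()].
#' @export
fit_time_trend <- function(data, fraction_col = "corrected_fraction_pct",
                           days_col = "days_post_transplant") {
  stopifnot(is.data.frame(data),
            all(c(fraction_col, days_col) %in% names(data)))
  y <- data[[fraction_col]]
  x <- data[[days_col]]
  if (length(y) < 3) stop("Need at least 3 observations.", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("Days post-transplant have zero variance.", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an exactly flat or exactly linear response; both are
  # legitimate degenerate inputs handled below
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  p_slope <- if (nrow(sm$coefficients) < 2 || is.na(sm$coefficients[2, 4])) {
    NA_real_
  } else {
    sm$coefficients[2, 4]
  }
  if (stats::var(y) == 0) {  # flat response: no trend, nothing to explain
    r2 <- 0
    p_slope <- 1
  }
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, p_slope = p_slope, n = length(y),
         fit = fit),
    class = "time_trend"
  )
}

#' @export
print.time_trend <- function(x, ...) {
  cat(sprintf(
    "dd-cfDNA vs time post-transplant (n = %d): slope = %.3g %%/day, R^2 = %.4g, p = %.3g\n",
    x$n, x$slope, x$r_squared, x$p_slope))
  invisible(x)
}

# shared engine for the per-table comparison families: each row is one
# Mann-Whitney test of `cohort` against `reference`, BH-adjusted within the
# call (each printed table is its own FDR family)
compare_family <- function(groups, reference) {
  ref_vals <- groups$values[[match(reference, groups$group)]]
  if (is.null(ref_vals) || !length(ref_vals)) {
    stop("Reference group '", reference, "' is empty or absent.", call. = FALSE)
  }
  others <- groups[groups$group != reference, , drop = FALSE]
  rows <- purrr::map2_dfr(others$group, others$values, function(g, v) {
    mw <- mann_whitney_two_sided(v, ref_vals)
    mi_a <- median_iqr(v)
    mi_b <- median_iqr(ref_vals)
    tibble::tibble(
      cohort_a = g, cohort_b = reference,
      n_a = length(v), n_b = length(ref_vals),
      median_a = mi_a["median"], q25_a = mi_a["q25"], q75_a = mi_a["q75"],
      median_b = mi_b["median"], q25_b = mi_b["q25"], q75_b = mi_b["q75"],
      u_statistic = mw$u_statistic, p_raw = mw$p_raw
    )
  })
  rows$p_fdr <- bh_adjust(rows$p_raw)
  rows
}

#' Compare each diagnostic cohort's dd-cfDNA against the stable baseline
#'
#' One two-sided Mann-Whitney U test per non-reference cohort, with
#' Benjamini-Hochberg adjustment across the comparisons in this call (the
#' table is its own FDR family).
#'
#' @param samples Samples tibble (needs `sample_id`,
#'   `corrected_fraction_pct`).
#' @param labels Labels tibble from [assign_cohorts()] (or the generator's
#'   truth); `EXCLUDED` samples are dropped.
#' @param reference Reference cohort, default `"STABLE"`.
#' @return Tibble, one row per comparison: cohort medians/IQRs, U, `p_raw`,
#'   `p_fdr`.
#' @export
compare_cohorts <- function(samples, labels, reference = "STABLE") {
  df <- dplyr::inner_join(samples,
                          dplyr::select(labels, "sample_id", "label"),
                          by = "sample_id") |>
    dplyr::filter(.data$label != "EXCLUDED")
  groups <- df |>
    dplyr::group_by(group = .data$label) |>
    dplyr::summarise(values = list(.data$corrected_fraction_pct),
                     .groups = "drop")
  out <- compare_family(groups, reference)
  # stable ordering: cohort display order
  out[order(match(out$cohort_a, cohort_levels())), , drop = FALSE]
}

#' Compare left- versus right-side allografts within each cohort
#'
#' For the overall analyzed set and for each cohort, tests left versus right
#' dd-cfDNA by two-sided Mann-Whitney, BH-adjusted across all rows of the
#' table. Samples with unknown laterality are dropped from this analysis
#' (they remain in every cohort-level analysis).
#'
#' @param samples,labels As in [compare_cohorts()].
#' @param patients Patients tibble (supplies `laterality`).
#' @return Tibble with one row per cohort plus `"Overall"`: per-side n and
#'   median/IQR, `p_raw`, `p_fdr`. Cohorts lacking samples on either side are
#'   omitted.
#' @export
compare_laterality <- function(samples, labels, patients) {
  df <- samples |>
    dplyr::inner_join(dplyr::select(labels, "sample_id", "label"),
                      by = "sample_id") |>
    dplyr::filter(.data$label != "EXCLUDED") |>
    dplyr::left_join(dplyr::select(patients, "patient_id", "laterality"),
                     by = "patient_id") |>
    dplyr::filter(.data$laterality %in% c("left", "right"))
  rows <- purrr::map_dfr(c("Overall", cohort_levels()), function(coh) {
    sub <- if (coh == "Overall") df else df[df$label == coh, , drop = FALSE]
    l <- sub$corrected_fraction_pct[sub$laterality == "left"]
    r <- sub$corrected_fraction_pct[sub$laterality == "right"]
    if (!length(l) || !length(r)) return(NULL)
    mw <- mann_whitney_two_sided(l, r)
    mi_l <- median_iqr(l)
    mi_r <- median_iqr(r)
    tibble::tibble(
      cohort = coh, n_left = length(l), n_right = length(r),
      median_left = mi_l["median"], q25_left = mi_l["q25"],
      q75_left = mi_l["q75"],
      median_right = mi_r["median"], q25_right = mi_r["q25"],
      q75_right = mi_r["q75"],
      u_statistic = mw$u_statistic, p_raw = mw$p_raw
    )
  })
  if (is.null(rows) || !nrow(rows)) {
    warning("No samples with known laterality; laterality table is empty.")
    return(tibble::tibble())
  }
  rows$p_fdr <- bh_adjust(rows$p_raw)
  rows
}

#' Compare draw time post-transplant across cohorts
#'
#' Tests each cohort's days-post-transplant distribution against the
#' reference cohort's by two-sided Mann-Whitney, BH-adjusted within the call.
#'
#' @param samples,labels,reference As in [compare_cohorts()]; `samples` needs
#'   `days_post_transplant`.
#' @return Tibble, one row per comparison, same shape as [compare_cohorts()].
#' @export
compare_draw_times <- function(samples, labels, reference = "STABLE") {
  df <- dplyr::inner_join(samples,
                          dplyr::select(labels, "sample_id", "label"),
                          by = "sample_id") |>
    dplyr::filter(.data$label != "EXCLUDED")
  groups <- df |>
    dplyr::group_by(group = .data$label) |>
    dplyr::summarise(values = list(as.numeric(.data$days_post_transplant)),
                     .groups = "drop")
  out <- compare_family(groups, reference)
  out[order(match(out$cohort_a, cohort_levels())), , drop = FALSE]
}
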