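#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a performance summary
#'
#' @param x A `performance_summary` from [estimate_performance()].
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `conf.low`, `conf.high`
#'   (median and 2.5th/97.5th percentiles across iterations).
#' @method tidy performance_summary
#' @export
tidy.performance_summary <- function(x, ...) {
  tibble::tibble(term = x$summary$metric, estimate = x$summary$point,
                 conf.low = x$summary$ci_low, conf.high = x$summary$ci_high)
}

#' One-row summary of a performance estimate
#'
#' @param x A `performance_summary`.
#' @param ... Unused.
#' @return One-row tibble: `auroc`, `sensitivity`, `specificity`,
#'   `prevalence`, `threshold_pct`, `iterations`, `degenerate_redraws`.
#' @method glance performance_summary
#' @export
glance.performance_summary <- function(x, ...) {
  pt <- stats::setNames(x$summary$point, x$summary$metric)
  tibble::tibble(auroc = pt[["auroc"]], sensitivity = pt[["sensitivity"]],
                 specificity = pt[["specificity"]],
                 prevalence = x$prevalence_used,
                 threshold_pct = x$threshold_pct,
                 iterations = x$iterations_used,
                 degenerate_redraws = x$n_redraws)
}

#' Tidy a dd-cfDNA time-trend fit
#'
#' @param x A `time_trend` from [fit_time_trend()].
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy time_trend
#' @export
tidy.time_trend <- function(x, ...) {
  co <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = c("(Intercept)", "days_post_transplant"),
                 estimate = co[, 1], std.error = co[, 2],
                 statistic = co[, 3], p.value = co[, 4])
}

#' One-row summary of a time-trend fit
#'
#' @param x A `time_trend`.
#' @param ... Unused.
#' @return One-row tibble: `r.squared`, `p.value` (slope), `slope`,
#'   `intercept`, `nobs`.
#' @method glance time_trend
#' @export
glance.time_trend <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, p.value = x$p_slope,
                 slope = x$slope, intercept = x$intercept, nobs = x$n)
}
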