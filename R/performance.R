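#' Randomly subsample one patient's draws to an independent set
#'
#' Two draws from the same patient are treated as independent when they are
#' more than `gap_days` apart (strictly) or carry different diagnostic
#' labels. The rows are shuffled and each is greedily accepted if compatible
#' with every draw already accepted, so which of two close same-label draws
#' survives is random.
#'
#' @param patient_samples Data frame of one patient's draws with columns
#'   `days_post_transplant` and `label`.
#' @param gap_days Independence gap in days (default 90; the predicate is
#'   `> gap_days`, so 90 days apart exactly is still dependent).
#' @return A subset of the input rows in which every pair satisfies the
#'   independence predicate.
#' @examples
#' df <- data.frame(days_post_transplant = c(0, 30, 150),
#'                  label = c("STABLE", "STABLE", "STABLE"))
#' nrow(select_independent_subset(df))  # 2: the 0/30-day pair conflicts
#' @export
select_independent_subset <- function(patient_samples, gap_days = 90) {
  n <- nrow(patient_samples)
  if (n <= 1) return(patient_samples)
  days <- patient_samples$days_post_transplant
  lab <- patient_samples$label
  ord <- sample.int(n)
  keep <- integer(0)
  for (i in ord) {
    ok <- all(abs(days[i] - days[keep]) > gap_days | lab[i] != lab[keep])
    if (ok) keep <- c(keep, i)
  }
  patient_samples[sort(keep), , drop = FALSE]
}

#' Sensitivity and specificity of the dd-cfDNA threshold on a labelled set
#'
#' @param values Corrected dd-cfDNA fractions (%).
#' @param labels Character vector with the positive class `"AR"` and negative
#'   class `"STABLE"`; other labels are ignored.
#' @param threshold_pct Positivity threshold (inclusive), default 1.0.
#' @return Named numeric vector `c(sensitivity, specificity, n_pos, n_neg)`,
#'   or `NULL` when either class is absent (a degenerate draw the caller
#'   should reject and redraw).
#' @export
confusion_metrics <- function(values, labels, threshold_pct = 1.0) {
  pos <- values[labels == "AR"]
  neg <- values[labels == "STABLE"]
  if (!length(pos) || !length(neg)) return(NULL)
  c(sensitivity = mean(pos >= threshold_pct),
    specificity = mean(neg < threshold_pct),
    n_pos = length(pos), n_neg = length(neg))
}

#' Positive and negative likelihood ratios
#'
#' `+LR = sens / (1 - spec)`; `-LR = (1 - sens) / spec`. A perfect
#' specificity gives `+LR = Inf` (flagged, not an error).
#'
#' @param sensitivity,specificity Probabilities in `[0, 1]`.
#' @return Named numeric vector `c(lr_pos, lr_neg)`.
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  lr_pos <- if (specificity < 1) sensitivity / (1 - specificity) else Inf
  lr_neg <- if (specificity > 0) (1 - sensitivity) / specificity else Inf
  c(lr_pos = lr_pos, lr_neg = lr_neg)
}

#' Predictive values at a fixed disease prevalence
#'
#' Bayes' rule: `PPV = sens p / (sens p + (1 - spec)(1 - p))`;
#' `NPV = spec (1 - p) / ((1 - sens) p + spec (1 - p))`.
#'
#' @param sensitivity,specificity Probabilities in `[0, 1]`.
#' @param prevalence Disease prevalence in `(0, 1)`.
#' @return Named numeric vector `c(ppv, npv)`.
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  stopifnot(prevalence > 0, prevalence < 1)
  p <- prevalence
  ppv_den <- sensitivity * p + (1 - specificity) * (1 - p)
  npv_den <- (1 - sensitivity) * p + specificity * (1 - p)
  c(ppv = if (ppv_den > 0) sensitivity * p / ppv_den else 0,
    npv = if (npv_den > 0) specificity * (1 - p) / npv_den else 0)
}

#' Empirical AUROC by the probability-of-correct-ranking estimator
#'
#' The fraction of (positive, negative) pairs in which the positive value
#' exceeds the negative, ties counted one half — identical to the trapezoidal
#' area under the empirical ROC curve. Computed via midranks, so it is exact
#' and O(n log n).
#'
#' @param positive_values,negative_values Numeric vectors, both non-empty.
#' @return The AUROC in `[0, 1]`.
#' @examples
#' empirical_auroc(c(1.8, 0.9, 2.5), c(0.4, 1.0, 0.7))  # 8/9
#' @export
empirical_auroc <- function(positive_values, negative_values) {
  n_pos <- length(positive_values)
  n_neg <- length(negative_values)
  if (!n_pos || !n_neg) stop("Both groups must be non-empty.", call. = FALSE)
  r <- rank(c(positive_values, negative_values), ties.method = "average")
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Study prevalence of acute rejection
#'
#' AR samples over the samples surviving the post-treatment-window exclusion.
#' Suspected-but-unconfirmed AR exclusions stay in the denominator by default
#' (`denominator = "post_treatment_survivors"`), reproducing the published
#' accounting (25 / (257 - 30) = 11.01%); `denominator = "analyzed"` restricts
#' to analyzed samples only.
#'
#' @param labels Labels tibble from [assign_cohorts()] (needs `label` and
#'   `exclusion_reason`).
#' @param denominator `"post_treatment_survivors"` (default) or `"analyzed"`.
#' @return Prevalence as a proportion in `[0, 1]`.
#' @export
study_prevalence <- function(labels,
                             denominator = c("post_treatment_survivors",
                                             "analyzed")) {
  denominator <- match.arg(denominator)
  n_ar <- sum(labels$label == "AR")
  keep <- labels$label != "EXCLUDED"
  if (denominator == "post_treatment_survivors") {
    keep <- keep | labels$exclusion_reason == "suspected_ar_unconfirmed"
  }
  n_den <- sum(keep)
  if (n_den == 0) stop("Empty denominator.", call. = FALSE)
  n_ar / n_den
}

#' Resampling configuration for the performance estimator
#'
#' @param iterations Number of subsample + bootstrap iterations (default
#'   10,000).
#' @param gap_days Within-patient independence gap in days (strict `>`,
#'   default 90).
#' @param threshold_pct Positivity threshold in percent (default 1.0).
#' @param prevalence Fixed study prevalence used for PPV/NPV; `NULL` (default)
#'   computes it from the labels passed to [estimate_performance()].
#' @param redraw_subset_each_iteration Redraw the independent subset every
#'   iteration (default `TRUE`, so subset-selection variance propagates into
#'   the CI); `FALSE` fixes one subset and bootstraps only.
#' @param fpr_grid False-positive-rate grid on which the per-iteration ROC is
#'   evaluated for the median ROC curve.
#' @param max_redraws Cap on redraws of degenerate bootstrap draws (a class
#'   absent) per iteration.
#' @return A list of class `resampling_config`.
#' @export
resampling_config <- function(iterations = 10000L, gap_days = 90,
                              threshold_pct = 1.0, prevalence = NULL,
                              redraw_subset_each_iteration = TRUE,
                              fpr_grid = seq(0, 1, by = 0.02),
                              max_redraws = 1000L) {
  stopifnot(iterations >= 1, gap_days >= 0, threshold_pct > 0)
  if (!is.null(prevalence)) stopifnot(prevalence > 0, prevalence < 1)
  structure(
    list(iterations = as.integer(iterations), gap_days = gap_days,
         threshold_pct = threshold_pct, prevalence = prevalence,
         redraw_subset_each_iteration = isTRUE(redraw_subset_each_iteration),
         fpr_grid = fpr_grid, max_redraws = as.integer(max_redraws)),
    class = "resampling_config"
  )
}

metric_names <- function() {
  c("sensitivity", "specificity", "ppv", "npv", "lr_pos", "lr_neg", "auroc")
}

# tpr of the empirical ROC at given fpr values (step interpolation): the ROC
# point at fpr f uses the threshold equal to the (1 - f) empirical quantile
# (type 1) of the negatives; tpr = P(pos >= threshold)
roc_tpr_at <- function(pos, neg, fpr) {
  thr <- stats::quantile(neg, 1 - fpr, type = 1, names = FALSE)
  thr[fpr == 0] <- Inf  # fpr 0 needs a threshold above every negative
  vapply(thr, function(t) mean(pos >= t), numeric(1))
}

#' Estimate dd-cfDNA diagnostic performance by subsampling and bootstrap
#'
#' The clustered resampling estimator for AR-vs-STABLE discrimination. Each
#' iteration (1) draws a fresh random independent subset within every patient
#' (draws kept only if more than `gap_days` apart or differently labelled),
#' (2) bootstrap-resamples the pooled subset with replacement at the same
#' size, and (3) computes sensitivity and specificity at the threshold, PPV
#' and NPV at the fixed study prevalence, likelihood ratios, and the
#' empirical AUROC. Degenerate bootstrap draws with a class absent are
#' rejected and redrawn (counted). The point estimate and 95% CI of every
#' metric are the median and 2.5th/97.5th percentiles across iterations; a
#' median ROC curve is assembled pointwise on a false-positive-rate grid.
#'
#' @param data Data frame with columns `patient_id`, `days_post_transplant`,
#'   `corrected_fraction_pct`, and `label`; only `"AR"` and `"STABLE"` rows
#'   are used. Typically `samples` joined with [assign_cohorts()] output.
#' @param config A [resampling_config()].
#' @param seed Integer seed driving all randomness of the estimator.
#' @return An object of class `performance_summary`: `summary` tibble
#'   (metric, point, ci_low, ci_high), `roc` tibble (fpr, tpr of the median
#'   curve), `prevalence_used`, `iterations_used`, `n_redraws`,
#'   `threshold_pct`, and the per-iteration `iterations` matrix. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' ds <- simulate_cohort(seed = 1)
#' labels <- assign_cohorts(ds)
#' df <- dplyr::inner_join(ds$samples,
#'                         dplyr::select(labels, "sample_id", "label"),
#'                         by = "sample_id")
#' perf <- estimate_performance(df, resampling_config(iterations = 50,
#'                                                    prevalence = 0.1101),
#'                              seed = 7)
#' tidy(perf)
#' @export
estimate_performance <- function(data, config = resampling_config(), seed) {
  if (missing(seed) || is.null(seed)) {
    stop("A `seed` is required.", call. = FALSE)
  }
  stopifnot(inherits(config, "resampling_config"),
            all(c("patient_id", "days_post_transplant",
                  "corrected_fraction_pct", "label") %in% names(data)))
  set.seed(as.integer(seed))

  prevalence <- config$prevalence
  if (is.null(prevalence)) {
    if (!"exclusion_reason" %in% names(data)) data$exclusion_reason <- "none"
    prevalence <- study_prevalence(data)
  }

  df <- data[data$label %in% c("AR", "STABLE"),
             c("patient_id", "days_post_transplant",
               "corrected_fraction_pct", "label")]
  if (length(unique(df$label)) < 2) {
    stop("Need both AR and STABLE samples.", call. = FALSE)
  }

  by_pat <- split(seq_len(nrow(df)), df$patient_id)
  days <- df$days_post_transplant
  lab <- df$label
  vals <- df$corrected_fraction_pct
  # patients whose draws are already pairwise independent never change under
  # subsampling; only "conflicted" patients need the per-iteration shuffle
  conflicted <- vapply(by_pat, function(idx) {
    if (length(idx) <= 1) return(FALSE)
    d <- days[idx]
    l <- lab[idx]
    for (i in seq_along(idx)[-1]) {
      if (any(abs(d[i] - d[seq_len(i - 1)]) <= config$gap_days &
                l[i] == l[seq_len(i - 1)])) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  fixed_idx <- unlist(by_pat[!conflicted], use.names = FALSE)
  confl_pats <- by_pat[conflicted]

  greedy_subset <- function(idx) {
    ord <- idx[sample.int(length(idx))]
    keep <- integer(0)
    for (i in ord) {
      if (all(abs(days[i] - days[keep]) > config$gap_days |
                lab[i] != lab[keep])) {
        keep <- c(keep, i)
      }
    }
    keep
  }
  draw_subset <- function() {
    c(fixed_idx, unlist(lapply(confl_pats, greedy_subset), use.names = FALSE))
  }

  iters <- config$iterations
  out <- matrix(NA_real_, nrow = iters, ncol = length(metric_names()),
                dimnames = list(NULL, metric_names()))
  n_grid <- length(config$fpr_grid)
  tpr_mat <- matrix(NA_real_, nrow = iters, ncol = n_grid)
  n_redraws <- 0L
  subset_idx <- if (!config$redraw_subset_each_iteration) draw_subset()

  for (it in seq_len(iters)) {
    repeat {
      if (config$redraw_subset_each_iteration) subset_idx <- draw_subset()
      boot <- subset_idx[sample.int(length(subset_idx),
                                    length(subset_idx), replace = TRUE)]
      cm <- confusion_metrics(vals[boot], lab[boot], config$threshold_pct)
      if (!is.null(cm)) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > config$max_redraws * iters) {
        stop("Too many degenerate bootstrap draws.", call. = FALSE)
      }
    }
    pos <- vals[boot][lab[boot] == "AR"]
    neg <- vals[boot][lab[boot] == "STABLE"]
    lr <- likelihood_ratios(cm["sensitivity"], cm["specificity"])
    pv <- predictive_values(cm["sensitivity"], cm["specificity"], prevalence)
    out[it, ] <- c(cm["sensitivity"], cm["specificity"], pv, lr,
                   empirical_auroc(pos, neg))
    tpr_mat[it, ] <- roc_tpr_at(pos, neg, config$fpr_grid)
  }

  qs <- apply(out, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
              type = 7, names = FALSE)
  summary <- tibble::tibble(
    metric = metric_names(),
    point = unname(qs[1, ]), ci_low = unname(qs[2, ]),
    ci_high = unname(qs[3, ])
  )
  roc <- tibble::tibble(
    fpr = config$fpr_grid,
    tpr = apply(tpr_mat, 2, stats::median)
  )
  structure(
    list(summary = summary, roc = roc, prevalence_used = prevalence,
         iterations_used = iters, n_redraws = n_redraws,
         threshold_pct = config$threshold_pct, iterations = out),
    class = "performance_summary"
  )
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf(
    "dd-cfDNA diagnostic performance, AR vs STABLE (threshold %.2f%%, %d iterations, prevalence %.2f%%)\n",
    x$threshold_pct, x$iterations_used, 100 * x$prevalence_used))
  s <- x$summary
  pct <- s$metric %in% c("sensitivity", "specificity", "ppv", "npv")
  disp <- s
  disp[pct, c("point", "ci_low", "ci_high")] <-
    round(s[pct, c("point", "ci_low", "ci_high")] * 100, 2)
  disp[!pct, c("point", "ci_low", "ci_high")] <-
    round(s[!pct, c("point", "ci_low", "ci_high")], 3)
  for (i in seq_len(nrow(disp))) {
    cat(sprintf("  %-12s %s (%s-%s)%s\n", disp$metric[i], disp$point[i],
                disp$ci_low[i], disp$ci_high[i], if (pct[i]) " %" else ""))
  }
  if (x$n_redraws > 0) {
    cat("  (", x$n_redraws, " degenerate bootstrap draws redrawn)\n", sep = "")
  }
  invisible(x)
}
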