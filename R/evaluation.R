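#' Signed bias of discrepancy estimates
#'
#' Mean of `estimates - truth` over all supplied values (dyads and, when the
#' inputs are stacked, replications). Kept signed — the published tables name
#' it "absolute bias" but print signed values — with an absolute-value
#' variant by argument.
#'
#' @param estimates,truth Aligned numeric vectors (or matrices).
#' @param absolute If `TRUE`, return `|mean(estimates - truth)|`.
#' @return A single number.
#' @export
bias_discrepancy <- function(estimates, truth, absolute = FALSE) {
  if (length(estimates) == 0) abort("empty input", class = "dyadsim_domain_error")
  if (length(estimates) != length(truth)) {
    abort("`estimates` and `truth` must be aligned", class = "dyadsim_domain_error")
  }
  b <- mean(estimates - truth)
  if (absolute) abs(b) else b
}

#' Reliability metric of a replication's discrepancy estimates
#'
#' `Var(truth) / Var(estimates)` within one replication: 1 is ideal; values
#' below 1 mean the estimates are noisier than the true discrepancies
#' (classical unreliability); values above 1 mean the estimates are less
#' variable than the truth (shrinkage). A zero estimate variance (total
#' shrinkage) returns `Inf` as a sentinel, which aggregation excludes and
#' counts.
#'
#' @param truth,estimates Per-dyad numeric vectors from one replication.
#' @return A positive ratio, possibly `Inf`.
#' @export
reliability_metric <- function(truth, estimates) {
  if (length(truth) < 2) abort("need at least 2 dyads", class = "dyadsim_domain_error")
  if (length(truth) != length(estimates)) {
    abort("`truth` and `estimates` must be aligned", class = "dyadsim_domain_error")
  }
  ve <- var(estimates)
  if (ve == 0) return(Inf)
  var(truth) / ve
}

#' Standard-error bias across replications
#'
#' Mean of the reported standard errors minus the empirical standard
#' deviation of the coefficient estimates across replications. Zero means the
#' standard errors are calibrated.
#'
#' @param se_estimates Per-replication standard errors.
#' @param coef_estimates Per-replication coefficient estimates.
#' @return A single number.
#' @export
se_bias <- function(se_estimates, coef_estimates) {
  keep <- !is.na(se_estimates) & !is.na(coef_estimates)
  if (sum(keep) < 2) abort("need at least 2 replications", class = "dyadsim_domain_error")
  mean(se_estimates[keep]) - sd(coef_estimates[keep])
}

#' Power and coverage of regression slopes across replications
#'
#' Power is the fraction of replications with a two-sided p-value below
#' `alpha`; coverage is the fraction whose confidence interval contains the
#' generating slope. Inestimable terms are excluded from the denominators and
#' counted.
#'
#' @param results List of `outcome_regression` objects (one per replication).
#' @param true_slopes Named generating slopes, by default
#'   `c(discrepancy = 0.8, direction = 0.5, interaction = 0.2)`.
#' @param alpha Significance level.
#' @return A tibble with one row per slope term: `power`, `coverage`,
#'   `n_used`, `n_inestimable`.
#' @export
power_and_coverage <- function(results,
                               true_slopes = c(discrepancy = 0.8,
                                               direction = 0.5,
                                               interaction = 0.2),
                               alpha = 0.05) {
  if (!length(results)) abort("empty result list", class = "dyadsim_domain_error")
  tab <- dplyr::bind_rows(lapply(results, function(r) r$coefficients))
  tab <- dplyr::filter(tab, .data$term %in% names(true_slopes))
  tab$true <- true_slopes[tab$term]
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$term),
    power = mean(.data$p_value[!.data$inestimable] < alpha),
    coverage = mean(.data$conf_low[!.data$inestimable] <= .data$true[!.data$inestimable] &
                      .data$true[!.data$inestimable] <= .data$conf_high[!.data$inestimable]),
    n_used = sum(!.data$inestimable),
    n_inestimable = sum(.data$inestimable),
    .groups = "drop"
  )
  out[match(intersect(names(true_slopes), out$term), out$term), ]
}

#' R-squared bias relative to the true-score benchmark
#'
#' `mean(r2_est) - mean(r2_true)` over aligned replications.
#'
#' @param r2_est,r2_true Per-replication R-squared values (or lists of
#'   `outcome_regression` objects).
#' @return A single number.
#' @export
r2_bias <- function(r2_est, r2_true) {
  grab <- function(x) {
    if (is.list(x) && length(x) && inherits(x[[1]], "outcome_regression")) {
      vapply(x, function(r) r$r_squared, numeric(1))
    } else as.numeric(x)
  }
  a <- grab(r2_est); b <- grab(r2_true)
  if (!length(a) || length(a) != length(b)) {
    abort("aligned, non-empty replication lists required", class = "dyadsim_domain_error")
  }
  mean(a) - mean(b)
}

#' Aggregate replication records into per-cell metrics
#'
#' Collapses the replication-level records produced by [run_study()] into one
#' row per condition x method: discrepancy bias, mean reliability ratio
#' (infinite sentinels excluded and counted), slope biases, standard-error
#' biases, power and coverage per coefficient, R-squared bias and power, and
#' the replication accounting.
#'
#' @param rep_records Replication-level tibble (see [run_study()]).
#' @param true_slopes Generating slopes for bias/coverage.
#' @param alpha Significance level for power.
#' @return A tibble, one row per condition x method.
#' @export
cell_metrics <- function(rep_records,
                         true_slopes = c(discrepancy = 0.8, direction = 0.5,
                                         interaction = 0.2),
                         alpha = 0.05) {
  cover <- function(lo, hi, tr) ifelse(is.na(lo), NA, lo <= tr & tr <= hi)
  dplyr::summarise(
    dplyr::group_by(rep_records, .data$condition, .data$method),
    bias_discrepancy = mean(.data$bias_disc),
    reliability = mean(.data$rel_ratio[is.finite(.data$rel_ratio)]),
    reliability_sd = sd(.data$rel_ratio[is.finite(.data$rel_ratio)]),
    n_infinite_reliability = sum(is.infinite(.data$rel_ratio)),
    slope_bias_discrepancy = mean(.data$b1, na.rm = TRUE) - true_slopes[["discrepancy"]],
    slope_bias_direction = mean(.data$b2, na.rm = TRUE) - true_slopes[["direction"]],
    slope_bias_interaction = mean(.data$b3, na.rm = TRUE) - true_slopes[["interaction"]],
    se_bias_discrepancy = se_bias(.data$se1, .data$b1),
    se_bias_direction = if (sum(!is.na(.data$se2)) >= 2) se_bias(.data$se2, .data$b2) else NA_real_,
    se_bias_interaction = if (sum(!is.na(.data$se3)) >= 2) se_bias(.data$se3, .data$b3) else NA_real_,
    power_discrepancy = mean(.data$p1 < alpha, na.rm = TRUE),
    power_direction = mean(.data$p2 < alpha, na.rm = TRUE),
    power_interaction = mean(.data$p3 < alpha, na.rm = TRUE),
    coverage_discrepancy = mean(cover(.data$cl1, .data$ch1, true_slopes[["discrepancy"]]), na.rm = TRUE),
    coverage_direction = mean(cover(.data$cl2, .data$ch2, true_slopes[["direction"]]), na.rm = TRUE),
    coverage_interaction = mean(cover(.data$cl3, .data$ch3, true_slopes[["interaction"]]), na.rm = TRUE),
    r2_bias = mean(.data$r2 - .data$r2_true),
    r2_power = mean(.data$r2_p < alpha),
    n_reps_used = dplyr::n(),
    n_not_converged = sum(!.data$converged),
    n_boundary = sum(.data$boundary),
    n_inestimable_direction = sum(is.na(.data$b2)),
    .groups = "drop"
  )
}

#' Flag EBD cells or replications with outlying discrepancy-slope bias
#'
#' An EBD value counts as an outlier when it falls outside the observed
#' `[min, max]` range of the pooled RSD and SEM values for the same metric
#' (the published post-hoc diagnosis of over-shrinkage). Fixed bounds can be
#' supplied instead. The result cross-tabulates outlier fractions by ICC and
#' number of dyads, where over-shrinkage concentrates.
#'
#' @param metrics Tibble with columns `method`, the metric column, and the
#'   design columns `icc`, `n_dyads` (cell metrics joined with conditions, or
#'   replication records).
#' @param metric Name of the metric column to screen (default
#'   `"slope_bias_discrepancy"`).
#' @param bounds Optional fixed `c(lower, upper)`.
#' @return A list of class `ebd_outliers`: the bounds used, the flagged rows,
#'   counts/fractions, and the ICC x n_dyads cross-tab.
#' @export
flag_ebd_outliers <- function(metrics, metric = "slope_bias_discrepancy",
                              bounds = NULL) {
  stopifnot(metric %in% names(metrics), "method" %in% names(metrics))
  if (!all(c("rsd", "ebd", "sem") %in% unique(metrics$method))) {
    abort("all three methods must be present", class = "dyadsim_config_error")
  }
  ref <- metrics[[metric]][metrics$method %in% c("rsd", "sem")]
  ref <- ref[is.finite(ref)]
  if (is.null(bounds)) bounds <- range(ref)
  ebd <- dplyr::filter(metrics, .data$method == "ebd")
  ebd$outlier <- !is.na(ebd[[metric]]) &
    (ebd[[metric]] < bounds[1] | ebd[[metric]] > bounds[2])
  crosstab <- NULL
  if (all(c("icc", "n_dyads") %in% names(ebd))) {
    crosstab <- dplyr::summarise(
      dplyr::group_by(ebd, .data$icc, .data$n_dyads),
      n = dplyr::n(), n_outliers = sum(.data$outlier),
      fraction = mean(.data$outlier), .groups = "drop"
    )
  }
  structure(
    list(metric = metric, bounds = bounds,
         flagged = dplyr::filter(ebd, .data$outlier),
         n = nrow(ebd), n_outliers = sum(ebd$outlier),
         fraction = mean(ebd$outlier), crosstab = crosstab),
    class = "ebd_outliers"
  )
}

#' @export
print.ebd_outliers <- function(x, ...) {
  cat(sprintf("<ebd_outliers> %d / %d EBD values (%.1f%%) outside [%.3g, %.3g] of RSD+SEM %s\n",
              x$n_outliers, x$n, 100 * x$fraction, x$bounds[1], x$bounds[2],
              x$metric))
  if (!is.null(x$crosstab)) print(x$crosstab, n = Inf)
  invisible(x)
}
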