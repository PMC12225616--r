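#' Run the full factorial simulation study
#'
#' For every condition and replication: generate a dyad dataset and outcome,
#' estimate the discrepancy with all three methods (RSD, EBD, SEM), fit the
#' outcome-prediction regression per method plus the true-score benchmark,
#' and record everything the metric battery needs. Replication seeds are
#' derived from the master seed by a counter scheme over (condition index,
#' replication index), so results are identical however cells are ordered or
#' parallelised, and any single replication can be reproduced in isolation.
#'
#' Estimator failures are caught, counted in the manifest and excluded from
#' that replication's records; non-convergence and boundary (over-shrinkage)
#' solutions are retained and flagged, since over-shrinkage behaviour is a
#' finding, not noise.
#'
#' @param design Condition tibble from [design_grid()] (default: the full
#'   216-cell published design).
#' @param reps Replications per condition. The default 50 is the reduced
#'   desk-scale preset; the published protocol used 1000.
#' @param seed Master seed (integer).
#' @param model Generation model `"A"` or `"B"` (see [generate_dyads()]).
#' @param outcome_basis `"observed"` or `"true"` (see [generate_outcome()]).
#' @param direction_source Direction indicator used in the evaluation
#'   regressions (see [fit_outcome_regression()]).
#' @param me_mode Measurement-error mode for the model-based estimators:
#'   `"design"` (generating error variances) or `"data"` (estimated from the
#'   scores via the reliability formula).
#' @param sem_scoring SEM factor-score extraction (see [fit_sem_scores()]).
#' @param noise_sd Outcome noise SD.
#' @param total_true_var Total true-score variance.
#' @param workers Number of parallel workers (forked; results identical to
#'   `workers = 1`).
#' @param verbose Print per-condition progress to stderr.
#' @return A `dyad_study` object: `conditions`, replication-level
#'   `rep_records`, per-cell `cell_metrics` (joined with the design factors),
#'   `failures`, and the `config` manifest.
#' @examples
#' small <- design_grid(icc = 0.3, n_dyads = 50,
#'                      reliability = list(c(0.8, 0.8)),
#'                      effect_size = 0.5, es_var = 1)
#' st <- run_study(small, reps = 3, seed = 1)
#' st$cell_metrics
#' @export
run_study <- function(design = design_grid(), reps = 50, seed = 1,
                      model = c("A", "B"),
                      outcome_basis = c("observed", "true"),
                      direction_source = c("observed", "estimated", "true"),
                      me_mode = c("design", "data"),
                      sem_scoring = c("bartlett", "regression"),
                      noise_sd = 1, total_true_var = 1, workers = 1,
                      verbose = FALSE) {
  model <- match.arg(model)
  outcome_basis <- match.arg(outcome_basis)
  direction_source <- match.arg(direction_source)
  me_mode <- match.arg(me_mode)
  sem_scoring <- match.arg(sem_scoring)
  if (reps < 1) abort("`reps` must be at least 1", class = "dyadsim_config_error")
  conditions <- derive_variances(design, total_true_var = total_true_var)
  conditions$reliability_pair <- sprintf("%g/%g", conditions$alpha_a,
                                         conditions$alpha_b)
  run_cond <- function(i) {
    cond <- conditions[i, ]
    rows <- vector("list", reps)
    fails <- list()
    for (r in seq_len(reps)) {
      set.seed(replication_seed(seed, cond$condition, r))
      d <- generate_dyads(cond, seed = NULL, model = model)
      d <- generate_outcome(d, noise_sd = noise_sd, basis = outcome_basis)
      me <- if (me_mode == "design") measurement_error(d, "design")
            else measurement_error(d, "data", alpha = c(cond$alpha_a, cond$alpha_b))
      truth <- truth_regression(d)
      fits <- list(
        rsd = tryCatch(rsd(d), error = function(e) e),
        ebd = tryCatch(fit_mlm_ebd(d, me = me), error = function(e) e),
        sem = tryCatch(fit_sem_scores(d, me = me, scoring = sem_scoring),
                       error = function(e) e)
      )
      for (m in names(fits)) {
        f <- fits[[m]]
        if (inherits(f, "error")) {
          fails[[length(fails) + 1]] <- tibble::tibble(
            condition = cond$condition, rep = r, method = m,
            message = conditionMessage(f))
          next
        }
        reg <- tryCatch(
          fit_outcome_regression(d, f, direction_source = direction_source),
          error = function(e) e)
        if (inherits(reg, "error")) {
          fails[[length(fails) + 1]] <- tibble::tibble(
            condition = cond$condition, rep = r, method = m,
            message = conditionMessage(reg))
          next
        }
        rows[[length(rows) + 1]] <- c(
          condition = cond$condition, rep = r, method_id = match(m, c("rsd", "ebd", "sem")),
          bias_disc = mean(f$scores - d$d_true),
          rel_ratio = reliability_metric(d$d_true, f$scores),
          regression_stats(reg),
          r2_true = truth$r_squared,
          converged = as.numeric(isTRUE(f$converged)),
          boundary = as.numeric(isTRUE(f$boundary))
        )
      }
    }
    list(rows = rows, fails = fails)
  }
  idx <- seq_len(nrow(conditions))
  results <- if (workers > 1) {
    parallel::mclapply(idx, run_cond, mc.cores = workers)
  } else {
    lapply(idx, function(i) {
      if (verbose) message(sprintf("condition %d / %d", i, nrow(conditions)))
      run_cond(i)
    })
  }
  mat <- do.call(rbind, unlist(lapply(results, `[[`, "rows"), recursive = FALSE))
  rec <- tibble::as_tibble(mat)
  rec$method <- c("rsd", "ebd", "sem")[rec$method_id]
  rec$method_id <- NULL
  rec$converged <- rec$converged == 1
  rec$boundary <- rec$boundary == 1
  rec <- dplyr::left_join(
    rec,
    dplyr::select(conditions, "condition", "icc", "n_dyads",
                  "reliability_pair", "effect_size", "es_var"),
    by = "condition"
  )
  failures <- dplyr::bind_rows(unlist(lapply(results, `[[`, "fails"),
                                      recursive = FALSE))
  if (!nrow(failures)) {
    failures <- tibble::tibble(condition = integer(), rep = integer(),
                               method = character(), message = character())
  }
  cm <- cell_metrics(rec)
  cm <- dplyr::left_join(
    cm,
    dplyr::select(conditions, "condition", "icc", "n_dyads",
                  "reliability_pair", "effect_size", "es_var"),
    by = "condition"
  )
  structure(
    list(conditions = conditions, rep_records = rec, cell_metrics = cm,
         failures = failures,
         config = list(reps = reps, seed = seed, model = model,
                       outcome_basis = outcome_basis,
                       direction_source = direction_source, me_mode = me_mode,
                       sem_scoring = sem_scoring, noise_sd = noise_sd,
                       total_true_var = total_true_var,
                       n_conditions = nrow(conditions),
                       timestamp = format(Sys.time(), tz = "UTC"))),
    class = "dyad_study"
  )
}

# Counter-based per-replication seed: deterministic in (master, condition,
# replication) and independent of execution order. Stays below 2^31 - 1.
replication_seed <- function(master, condition, rep) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(condition) +
                as.numeric(rep)) %% 2147483587) + 1L
}

# Flatten one outcome_regression into the fixed-width numeric record used by
# the replication table (NA for terms absent or inestimable).
regression_stats <- function(reg) {
  tab <- reg$coefficients
  pull <- function(term, col) {
    i <- match(term, tab$term)
    if (is.na(i)) NA_real_ else tab[[col]][i]
  }
  c(b1 = pull("discrepancy", "estimate"),
    b2 = pull("direction", "estimate"),
    b3 = pull("interaction", "estimate"),
    se1 = pull("discrepancy", "std_error"),
    se2 = pull("direction", "std_error"),
    se3 = pull("interaction", "std_error"),
    p1 = pull("discrepancy", "p_value"),
    p2 = pull("direction", "p_value"),
    p3 = pull("interaction", "p_value"),
    cl1 = pull("discrepancy", "conf_low"),
    cl2 = pull("direction", "conf_low"),
    cl3 = pull("interaction", "conf_low"),
    ch1 = pull("discrepancy", "conf_high"),
    ch2 = pull("direction", "conf_high"),
    ch3 = pull("interaction", "conf_high"),
    r2 = reg$r_squared,
    r2_p = reg$r2_p_value)
}

#' Summarise a study across cells
#'
#' Grand mean and SD of every cell metric per method, mirroring the row
#' structure of the published summary table (bias and reliability of the
#' discrepancy estimates, then bias / SE bias / power / coverage per
#' regression slope, then R-squared bias and power).
#'
#' @param study A `dyad_study` (or its `cell_metrics` tibble).
#' @return Tidy tibble: `metric`, `method`, `mean`, `sd`.
#' @export
summarize_study <- function(study) {
  cm <- if (inherits(study, "dyad_study")) study$cell_metrics else study
  if (!nrow(cm)) abort("empty study", class = "dyadsim_domain_error")
  metrics <- c("bias_discrepancy", "reliability",
               "slope_bias_discrepancy", "se_bias_discrepancy",
               "power_discrepancy", "coverage_discrepancy",
               "slope_bias_direction", "se_bias_direction",
               "power_direction", "coverage_direction",
               "slope_bias_interaction", "se_bias_interaction",
               "power_interaction", "coverage_interaction",
               "r2_bias", "r2_power")
  long <- tidyr::pivot_longer(
    dplyr::select(cm, "condition", "method", dplyr::all_of(metrics)),
    cols = dplyr::all_of(metrics), names_to = "metric", values_to = "value"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$metric, .data$method),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
  out$metric <- factor(out$metric, levels = metrics)
  out$method <- factor(out$method, levels = c("rsd", "ebd", "sem"))
  dplyr::arrange(out, .data$metric, .data$method)
}

#' Six-way (or five-way) eta-squared ANOVA of study outcomes
#'
#' Decomposes a simulation outcome over the design factors, optionally with
#' method as an additional factor, at replication level (the default,
#' matching the published analysis) or cell-mean level.
#'
#' @param study A `dyad_study`.
#' @param outcome One of `"reliability"`, `"bias_discrepancy"`,
#'   `"slope_bias_discrepancy"`, `"slope_bias_direction"`,
#'   `"slope_bias_interaction"`, `"se_discrepancy"`, `"se_direction"`,
#'   `"se_interaction"`, `"r2_bias"`, or a column name of the record table.
#' @param include_method Add `method` as a factor (the six-way layout).
#' @param level `"replication"` or `"cell"`.
#' @return An `eta_squared_table`.
#' @export
study_anova <- function(study, outcome = "slope_bias_discrepancy",
                        include_method = TRUE,
                        level = c("replication", "cell")) {
  level <- match.arg(level)
  factors <- c(if (include_method) "method",
               "icc", "n_dyads", "reliability_pair", "effect_size", "es_var")
  if (level == "replication") {
    rec <- study$rep_records
    rec$.outcome <- outcome_column(rec, outcome)
  } else {
    rec <- study$cell_metrics
    col <- switch(outcome, se_discrepancy = "se_bias_discrepancy",
                  se_direction = "se_bias_direction",
                  se_interaction = "se_bias_interaction", outcome)
    if (!col %in% names(rec)) abort(paste("unknown cell metric:", outcome),
                                    class = "dyadsim_config_error")
    rec$.outcome <- rec[[col]]
  }
  eta_squared_anova(rec, ".outcome", factors)
}

#' @export
print.dyad_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<dyad_study> %d conditions x %d reps (model %s, outcome basis %s, seed %d)\n",
              cfg$n_conditions, cfg$reps, cfg$model, cfg$outcome_basis, cfg$seed))
  cat(sprintf("  %d replication records, %d failures\n",
              nrow(x$rep_records), nrow(x$failures)))
  invisible(x)
}

#' Write the per-cell metric table to CSV
#'
#' One row per condition x method, mirroring the published per-cell layout.
#'
#' @param study A `dyad_study`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_metrics <- function(study, path) {
  utils::write.csv(study$cell_metrics, path, row.names = FALSE)
  invisible(path)
}
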