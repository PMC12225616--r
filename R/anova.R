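#' Eta-squared ANOVA decomposition on a balanced factorial
#'
#' Classical sums-of-squares ANOVA of a simulation outcome on categorical
#' design factors, reporting `eta^2 = SS_effect / SS_total` for every main
#' effect and (optionally) every two-way interaction. On a balanced
#' full-factorial layout the effects are orthogonal, so the decomposition is
#' independent of factor entry order; higher-order variation folds into the
#' residual share.
#'
#' Non-finite outcome values (e.g. infinite reliability sentinels) are
#' removed with a warning and count; removal can leave the layout slightly
#' unbalanced, in which case sequential sums of squares are only
#' approximately order-independent. A layout that is unbalanced before
#' exclusions is an error.
#'
#' @param data Long tibble of outcome values keyed by factor levels.
#' @param outcome Name of the outcome column.
#' @param factors Character vector of factor column names.
#' @param interactions Include all two-way interactions (default `TRUE`).
#' @return An `eta_squared_table`: tibble of `term`, `df`, `ss`, `eta_sq`
#'   plus attributes `ss_total`, `ss_residual`, `n`, `n_dropped`.
#' @examples
#' df <- tidyr::expand_grid(a = c("l", "h"), b = c("l", "h"), rep = 1:2)
#' df$y <- c(0, 0, 1, 1, 1, 1, 2, 2)[order(order(seq_len(8)))]
#' @export
eta_squared_anova <- function(data, outcome, factors, interactions = TRUE) {
  stopifnot(outcome %in% names(data), all(factors %in% names(data)))
  df <- as.data.frame(data[c(outcome, factors)])
  names(df)[1] <- ".y"
  for (f in factors) df[[f]] <- factor(df[[f]])
  constant <- factors[vapply(df[factors], nlevels, 0L) < 2]
  if (length(constant)) {
    warn(paste("dropping single-level factors:", paste(constant, collapse = ", ")))
    factors <- setdiff(factors, constant)
    if (!length(factors)) abort("no factor has 2 or more levels",
                                class = "dyadsim_config_error")
  }
  counts <- table(df[factors])
  if (any(counts == 0)) abort("missing design cells", class = "dyadsim_config_error")
  if (length(unique(as.vector(counts))) != 1) {
    abort("unbalanced factorial layout", class = "dyadsim_config_error")
  }
  drop <- !is.finite(df$.y)
  n_dropped <- sum(drop)
  if (n_dropped > 0) {
    warn(sprintf("dropping %d non-finite outcome values before the ANOVA", n_dropped))
    df <- df[!drop, , drop = FALSE]
  }
  ss_total <- sum((df$.y - mean(df$.y))^2)
  rhs <- if (interactions && length(factors) > 1) {
    paste0("(", paste(factors, collapse = " + "), ")^2")
  } else {
    paste(factors, collapse = " + ")
  }
  if (ss_total == 0) {
    warn("outcome is constant; every eta-squared is defined as 0")
    # degenerate: constant outcome; define every eta^2 as 0
    terms <- attr(stats::terms(stats::as.formula(paste(".y ~", rhs))), "term.labels")
    tab <- tibble::tibble(term = terms, df = NA_integer_, ss = 0, eta_sq = 0)
    return(structure(tab, class = c("eta_squared_table", class(tab)),
                     ss_total = 0, ss_residual = 0, n = nrow(df),
                     n_dropped = n_dropped))
  }
  fit <- aov(stats::as.formula(paste(".y ~", rhs)), data = df)
  sm <- summary(fit)[[1]]
  term <- trimws(rownames(sm))
  keep <- term != "Residuals"
  tab <- tibble::tibble(
    term = term[keep],
    df = sm$Df[keep],
    ss = sm$`Sum Sq`[keep],
    eta_sq = sm$`Sum Sq`[keep] / ss_total
  )
  ss_res <- ss_total - sum(tab$ss)
  structure(tab, class = c("eta_squared_table", class(tab)),
            ss_total = ss_total, ss_residual = ss_res, n = nrow(df),
            n_dropped = n_dropped)
}

#' @export
print.eta_squared_table <- function(x, mask_below = NULL, ...) {
  cat(sprintf("<eta_squared_table> n = %d, SS_total = %.4g, residual share = %.3f\n",
              attr(x, "n"), attr(x, "ss_total"),
              if (attr(x, "ss_total") > 0)
                attr(x, "ss_residual") / attr(x, "ss_total") else 0))
  y <- tibble::as_tibble(x)
  if (!is.null(mask_below)) {
    y$eta_sq <- ifelse(y$eta_sq < mask_below, NA, y$eta_sq)
  }
  print(y, n = Inf)
  invisible(x)
}

#' Format an eta-squared table with small effects masked
#'
#' Mirrors the published table convention: effects below the threshold are
#' shown as dashes.
#'
#' @param x An `eta_squared_table`.
#' @param mask_below Masking threshold (the published tables use 0.01).
#' @param digits Rounding for display.
#' @return A tibble with a character `eta_sq` column.
#' @export
format_eta_table <- function(x, mask_below = 0.01, digits = 2) {
  tibble::tibble(
    term = x$term,
    eta_sq = ifelse(x$eta_sq < mask_below, "-",
                    formatC(round(x$eta_sq, digits), format = "f", digits = digits))
  )
}

# Map a friendly outcome name to a replication-record expression.
outcome_column <- function(records, outcome,
                           true_slopes = c(discrepancy = 0.8, direction = 0.5,
                                           interaction = 0.2)) {
  switch(outcome,
    reliability = records$rel_ratio,
    bias_discrepancy = records$bias_disc,
    slope_bias_discrepancy = records$b1 - true_slopes[["discrepancy"]],
    slope_bias_direction = records$b2 - true_slopes[["direction"]],
    slope_bias_interaction = records$b3 - true_slopes[["interaction"]],
    se_discrepancy = records$se1,
    se_direction = records$se2,
    se_interaction = records$se3,
    r2_bias = records$r2 - records$r2_true,
    if (outcome %in% names(records)) records[[outcome]] else
      abort(paste("unknown outcome:", outcome), class = "dyadsim_config_error")
  )
}

#' Post-hoc five-way ANOVAs per method
#'
#' Runs [eta_squared_anova()] of an outcome on the five design factors
#' separately for each estimation method, the layout used to interpret which
#' factors drive each method's behaviour.
#'
#' @param records Replication- or cell-level records containing `method`,
#'   the design-factor columns and the outcome.
#' @param outcome Outcome name (see [study_anova()] for the friendly names).
#' @param factors Design-factor columns.
#' @return Named list of `eta_squared_table`s, one per method.
#' @export
run_posthoc_anovas <- function(records, outcome = "reliability",
                               factors = c("icc", "n_dyads", "reliability_pair",
                                           "effect_size", "es_var")) {
  methods <- sort(unique(records$method))
  out <- lapply(methods, function(m) {
    sub <- dplyr::filter(records, .data$method == m)
    sub$.outcome <- outcome_column(sub, outcome)
    eta_squared_anova(sub, ".outcome", factors)
  })
  setNames(out, methods)
}
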