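#' Tidy a discrepancy fit into per-dyad scores
#'
#' @param x A `discrepancy_fit`.
#' @param ... Unused.
#' @return Tibble with `dyad_id`, `method`, `score`.
#' @method tidy discrepancy_fit
#' @export
tidy.discrepancy_fit <- function(x, ...) {
  tibble::tibble(dyad_id = x$dyad_id, method = x$method, score = x$scores)
}

#' One-row summary of a discrepancy fit
#'
#' @param x A `discrepancy_fit`.
#' @param ... Unused.
#' @return Tibble with the fixed effects, variance estimates, shrinkage
#'   weight and fit flags.
#' @method glance discrepancy_fit
#' @export
glance.discrepancy_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_dyads = x$n_dyads,
    gamma00_hat = x$gamma00_hat, gamma10_hat = x$gamma10_hat,
    tau00_hat = if (is.null(x$t_hat)) NA_real_ else x$t_hat[1, 1],
    tau01_hat = if (is.null(x$t_hat)) NA_real_ else x$t_hat[1, 2],
    tau11_hat = if (is.null(x$t_hat)) NA_real_ else x$t_hat[2, 2],
    sigma2_e_a = unname(x$sigma2_fixed["a"]),
    sigma2_e_b = unname(x$sigma2_fixed["b"]),
    lambda_bar = x$lambda_bar, converged = x$converged,
    boundary = x$boundary, loglik = x$loglik
  )
}

#' Tidy an outcome regression's coefficient table
#'
#' @param x An `outcome_regression`.
#' @param ... Unused.
#' @return The coefficient tibble (term, estimate, std_error, statistic,
#'   p_value, conf_low, conf_high, inestimable).
#' @method tidy outcome_regression
#' @export
tidy.outcome_regression <- function(x, ...) {
  x$coefficients
}

#' One-row summary of an outcome regression
#'
#' @param x An `outcome_regression`.
#' @param ... Unused.
#' @return Tibble with `r_squared`, the overall-F p-value, `n_obs`,
#'   `df_residual`, `kind` and `model_kind`.
#' @method glance outcome_regression
#' @export
glance.outcome_regression <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, r2_p_value = x$r2_p_value, n_obs = x$n_obs,
    df_residual = x$df_residual, kind = x$kind, model_kind = x$model_kind
  )
}

#' Tidy an eta-squared table
#'
#' @param x An `eta_squared_table`.
#' @param ... Unused.
#' @return A plain tibble of `term`, `df`, `ss`, `eta_sq`.
#' @method tidy eta_squared_table
#' @export
tidy.eta_squared_table <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("term", "df", "ss", "eta_sq")])
}
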