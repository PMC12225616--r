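#' Enumerate the factorial simulation design
#'
#' Builds the full Cartesian product of the design factors as one condition
#' per row, in deterministic lexicographic order (later arguments vary
#' fastest). The defaults reproduce the published study conditions: 3 levels
#' of conditional ICC x 4 numbers of dyads x 3 reliability pairs x 3
#' discrepancy effect sizes x 2 effect-size variances = 216 conditions.
#'
#' @param icc Conditional intraclass correlation levels, each in (0, 1): the
#'   share of true-score variance between dyads after conditioning on the
#'   reporter indicator.
#' @param n_dyads Numbers of dyads (clusters of size 2) per dataset.
#' @param reliability List of length-2 numeric vectors `c(alpha_a, alpha_b)`,
#'   the score reliabilities of members A and B. Each alpha must lie in
#'   (0, 1].
#' @param effect_size Cohen's d of the mean discrepancy, in true-score SD
#'   units (the grand discrepancy slope gamma10).
#' @param es_var Variance of the dyad-level discrepancy (tau11), in
#'   true-score variance units.
#' @param distinguishable Logical; whether dyad members carry a meaningful
#'   role distinction (affects outcome generation and the prediction model).
#'
#' @return A tibble with one row per condition and columns `condition`
#'   (integer id), `icc`, `n_dyads`, `alpha_a`, `alpha_b`, `effect_size`,
#'   `es_var`, `distinguishable`.
#' @examples
#' nrow(design_grid()) # 216
#' design_grid(icc = 0.3, n_dyads = 100, reliability = list(c(0.8, 0.8)),
#'             effect_size = 0.5, es_var = 1)
#' @export
design_grid <- function(icc = c(0.1, 0.3, 0.5),
                        n_dyads = c(50, 150, 250, 400),
                        reliability = list(c(0.7, 0.7), c(0.8, 0.8), c(0.7, 0.8)),
                        effect_size = c(0.2, 0.5, 0.8),
                        es_var = c(0.5, 1),
                        distinguishable = TRUE) {
  if (!is.list(reliability)) reliability <- list(reliability)
  lens <- c(length(icc), length(n_dyads), length(reliability),
            length(effect_size), length(es_var))
  if (any(lens == 0)) {
    abort("every design factor needs at least one level", class = "dyadsim_config_error")
  }
  if (any(icc <= 0 | icc >= 1)) {
    abort("`icc` levels must lie strictly between 0 and 1", class = "dyadsim_config_error")
  }
  if (any(n_dyads < 2)) {
    abort("`n_dyads` must be at least 2", class = "dyadsim_config_error")
  }
  alphas <- unlist(reliability)
  if (length(alphas) != 2 * length(reliability) ||
      any(alphas <= 0 | alphas > 1)) {
    abort("`reliability` must be pairs (alpha_a, alpha_b) with 0 < alpha <= 1",
          class = "dyadsim_config_error")
  }
  if (any(es_var < 0)) {
    abort("`es_var` must be non-negative", class = "dyadsim_config_error")
  }
  grid <- tidyr::expand_grid(
    icc = icc, n_dyads = as.integer(n_dyads), rel = seq_along(reliability),
    effect_size = effect_size, es_var = es_var
  )
  grid <- dplyr::mutate(
    grid,
    condition = dplyr::row_number(),
    alpha_a = purrr::map_dbl(.data$rel, ~ reliability[[.x]][1]),
    alpha_b = purrr::map_dbl(.data$rel, ~ reliability[[.x]][2]),
    distinguishable = distinguishable
  )
  dplyr::select(grid, "condition", "icc", "n_dyads", "alpha_a", "alpha_b",
                "effect_size", "es_var", "distinguishable")
}

#' Derive generating variance components for each condition
#'
#' Translates the design factors into the variance components of the
#' two-level generating model: between-dyad intercept variance
#' `tau00 = icc * total_true_var`, level-1 true residual variance
#' `sigma2_w = (1 - icc) * total_true_var` (entering the generated scores only
#' under generation model B), discrepancy variance `tau11 = es_var`,
#' intercept-slope covariance `tau01` (0 by default), measurement-error
#' variances `sigma2_e = (1 - alpha) / alpha * total_true_var` per member, and
#' fixed effects `gamma00` (grand mean, 0 by default) and
#' `gamma10 = effect_size * sqrt(total_true_var)`.
#'
#' The published design table lists the alpha = 0.7 and 0.8 error variances as
#' 0.43 and 0.25; those are the rounded values of (1 - alpha) / alpha with
#' unit true-score variance, and the exact values are used here.
#'
#' @param conditions Tibble of conditions from [design_grid()].
#' @param total_true_var Total true-score variance split between tau00 and
#'   sigma2_w; must be positive.
#' @param gamma00 Grand mean of the scores.
#' @param tau01 Generating intercept-slope covariance.
#' @return The input tibble with columns `tau00`, `sigma2_w`, `tau11`,
#'   `tau01`, `sigma2_e_a`, `sigma2_e_b`, `gamma00`, `gamma10` appended.
#' @examples
#' derive_variances(design_grid()[1, ])
#' @export
derive_variances <- function(conditions, total_true_var = 1, gamma00 = 0,
                             tau01 = 0) {
  if (total_true_var <= 0) {
    abort("`total_true_var` must be positive", class = "dyadsim_config_error")
  }
  if (any(conditions$alpha_a == 0) || any(conditions$alpha_b == 0)) {
    abort("reliability 0 implies infinite error variance", class = "dyadsim_config_error")
  }
  dplyr::mutate(
    conditions,
    tau00 = .data$icc * total_true_var,
    sigma2_w = (1 - .data$icc) * total_true_var,
    tau11 = .data$es_var,
    tau01 = tau01,
    sigma2_e_a = (1 - .data$alpha_a) / .data$alpha_a * total_true_var,
    sigma2_e_b = (1 - .data$alpha_b) / .data$alpha_b * total_true_var,
    gamma00 = gamma00,
    gamma10 = .data$effect_size * sqrt(total_true_var)
  )
}

#' Intraclass correlation from variance components
#'
#' `tau00 / (tau00 + sigma2)`: the proportion of score variance attributable
#' to the dyad level.
#'
#' @param tau00 Between-dyad variance (non-negative).
#' @param sigma2 Within-dyad (level-1 residual) variance (non-negative).
#' @return The ICC as a proportion.
#' @examples
#' icc(0.3, 0.7) # 0.3
#' @export
icc <- function(tau00, sigma2) {
  if (any(tau00 < 0) || any(sigma2 < 0)) {
    abort("variance components must be non-negative", class = "dyadsim_domain_error")
  }
  if (any(tau00 + sigma2 == 0)) {
    abort("ICC is undefined when both variance components are zero",
          class = "dyadsim_domain_error")
  }
  tau00 / (tau00 + sigma2)
}

#' Read design levels from a YAML or JSON config file
#'
#' The file may provide any of the fields `icc`, `n_dyads`, `reliability`
#' (a list of two-element vectors), `effect_size`, `es_var`,
#' `distinguishable`; missing fields fall back to the [design_grid()]
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A condition tibble, as from [design_grid()].
#' @export
read_design_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  known <- c("icc", "n_dyads", "reliability", "effect_size", "es_var",
             "distinguishable")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    warn(paste("ignoring unknown config fields:", paste(extra, collapse = ", ")))
  }
  args <- cfg[intersect(names(cfg), known)]
  if (!is.null(args$reliability)) {
    rel <- args$reliability
    if (is.matrix(rel)) rel <- asplit(rel, 1)
    if (is.data.frame(rel)) rel <- asplit(as.matrix(rel), 1)
    args$reliability <- lapply(rel, as.numeric)
  }
  do.call(design_grid, args)
}
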