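#' Generate one synthetic dyad dataset
#'
#' Simulates true and observed scores for `n_dyads` dyads under the two-level
#' random-coefficient model. Each dyad j draws an intercept deviation
#' `u0j ~ N(0, tau00)` and a discrepancy `beta1j = gamma10 + u1j`,
#' `u1j ~ N(0, tau11)`. With the reporter code -0.5 (member A) / +0.5
#' (member B), true scores are
#' `T_ij = gamma00 + u0j + beta1j * report_ij` (generation model A); model B
#' additionally adds independent member-level true residuals
#' `N(0, sigma2_w)`, so the conditional ICC of the true scores equals the
#' design label by construction. Observed scores add member-specific
#' measurement error `N(0, sigma2_e)` calibrated to the reliability levels.
#'
#' The signed true discrepancy is `d_true = true_b - true_a` (positive when
#' member B exceeds member A, matching the reporter coding, so the MLM slope,
#' the SEM slope factor, and the raw difference all estimate the same
#' quantity). The direction indicator `w_true` is 1 when member A's true
#' score is greater than or equal to member B's, 0 otherwise.
#'
#' @param condition One-row condition tibble from [design_grid()]; variance
#'   components are derived via [derive_variances()] if absent.
#' @param seed Optional integer seed. When `NULL` the current RNG stream is
#'   used, so a caller can place the draw inside its own seeding scheme.
#' @param model Generation model, `"A"` (default; the true discrepancy is
#'   exactly beta1j) or `"B"` (member-level true residuals included).
#' @param total_true_var Passed to [derive_variances()] when components are
#'   missing.
#' @return A tibble with one row per dyad: `dyad_id`, `true_a`, `true_b`,
#'   `obs_a`, `obs_b`, `beta1`, `d_true`, `w_true`, carrying the condition
#'   and model as attributes.
#' @examples
#' cond <- design_grid(icc = 0.3, n_dyads = 8, reliability = list(c(0.8, 0.8)),
#'                     effect_size = 0.5, es_var = 1)
#' generate_dyads(cond, seed = 1)
#' @export
generate_dyads <- function(condition, seed = NULL, model = c("A", "B"),
                           total_true_var = 1) {
  model <- match.arg(model)
  stopifnot(is.data.frame(condition), nrow(condition) == 1)
  if (!"tau00" %in% names(condition)) {
    condition <- derive_variances(condition, total_true_var = total_true_var)
  }
  c_ <- as.list(condition)
  if (c_$n_dyads < 2) abort("need at least 2 dyads", class = "dyadsim_domain_error")
  if (min(c_$tau00, c_$tau11, c_$sigma2_w, c_$sigma2_e_a, c_$sigma2_e_b) < 0) {
    abort("negative generating variance", class = "dyadsim_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  J <- c_$n_dyads
  u0 <- rnorm(J, 0, sqrt(c_$tau00))
  if (c_$tau01 != 0) {
    # draw (u0, u1) jointly from the 2x2 covariance [[tau00, tau01], [., tau11]]
    cond_var <- c_$tau11 - c_$tau01^2 / c_$tau00
    if (cond_var < 0) abort("tau matrix not PSD", class = "dyadsim_domain_error")
    u1 <- c_$tau01 / c_$tau00 * u0 + rnorm(J, 0, sqrt(cond_var))
  } else {
    u1 <- rnorm(J, 0, sqrt(c_$tau11))
  }
  beta1 <- c_$gamma10 + u1
  true_a <- c_$gamma00 + u0 - 0.5 * beta1
  true_b <- c_$gamma00 + u0 + 0.5 * beta1
  if (model == "B") {
    true_a <- true_a + rnorm(J, 0, sqrt(c_$sigma2_w))
    true_b <- true_b + rnorm(J, 0, sqrt(c_$sigma2_w))
  }
  obs_a <- true_a + rnorm(J, 0, sqrt(c_$sigma2_e_a))
  obs_b <- true_b + rnorm(J, 0, sqrt(c_$sigma2_e_b))
  out <- tibble::tibble(
    dyad_id = seq_len(J),
    true_a = true_a, true_b = true_b,
    obs_a = obs_a, obs_b = obs_b,
    beta1 = beta1,
    d_true = true_b - true_a,
    w_true = direction_indicator(true_a - true_b)
  )
  attr(out, "condition") <- condition
  attr(out, "model") <- model
  out
}

#' Direction indicator for a signed A-vs-B difference
#'
#' Returns 1 when member A's score is greater than or equal to member B's
#' (ties count as 1), 0 otherwise. The argument is the difference on the
#' A - B scale; pass `-score` for discrepancy scores oriented B - A.
#'
#' @param a_minus_b Numeric vector of A - B differences.
#' @return Integer vector of 0/1.
#' @export
direction_indicator <- function(a_minus_b) {
  as.integer(a_minus_b >= 0)
}

#' Attach the simulated outcome to a dyad dataset
#'
#' For indistinguishable dyads the outcome is
#' `z = 0.5 + 0.8 * |D| + e`; for distinguishable dyads
#' `z = 0.5 + 0.8 * |D| + 0.5 * W + 0.2 * |D| * W + e`, with
#' `e ~ N(0, noise_sd^2)`. `D` and `W` are the discrepancy and its direction
#' taken from the observed scores (`basis = "observed"`, the default: the
#' outcome model's X and Y are the recorded member scores) or from the true
#' scores (`basis = "true"`; with this basis the true-score regression of
#' [truth_regression()] is exactly the generating model, which is the regime
#' used to calibrate coverage).
#'
#' @param dyads Tibble from [generate_dyads()].
#' @param noise_sd Outcome noise standard deviation (default 1, a standard
#'   normal disturbance).
#' @param distinguishable Logical; defaults to the condition's flag.
#' @param basis `"observed"` or `"true"`.
#' @param seed Optional seed; when `NULL` the current RNG stream continues.
#' @return The input tibble with columns `z`, `d_gen`, `w_gen` (the
#'   discrepancy and direction actually used in generation) appended.
#' @examples
#' cond <- design_grid(icc = 0.3, n_dyads = 8, reliability = list(c(0.8, 0.8)),
#'                     effect_size = 0.5, es_var = 1)
#' generate_outcome(generate_dyads(cond, seed = 1))
#' @export
generate_outcome <- function(dyads, noise_sd = 1, distinguishable = NULL,
                             basis = c("observed", "true"), seed = NULL) {
  basis <- match.arg(basis)
  if (noise_sd < 0) abort("`noise_sd` must be non-negative", class = "dyadsim_domain_error")
  cond <- attr(dyads, "condition")
  if (is.null(distinguishable)) {
    distinguishable <- if (!is.null(cond)) isTRUE(cond$distinguishable) else TRUE
  }
  if (!is.null(seed)) set.seed(seed)
  if (basis == "observed") {
    d <- dyads$obs_b - dyads$obs_a
    w <- direction_indicator(dyads$obs_a - dyads$obs_b)
  } else {
    d <- dyads$d_true
    w <- dyads$w_true
  }
  e <- rnorm(nrow(dyads), 0, noise_sd)
  z <- if (distinguishable) {
    0.5 + 0.8 * abs(d) + 0.5 * w + 0.2 * abs(d) * w + e
  } else {
    0.5 + 0.8 * abs(d) + e
  }
  out <- dyads
  out$z <- z
  out$d_gen <- d
  out$w_gen <- w
  attr(out, "condition") <- cond
  attr(out, "model") <- attr(dyads, "model")
  attr(out, "outcome_basis") <- basis
  attr(out, "distinguishable") <- distinguishable
  out
}

#' Reshape a dyad dataset to one row per member
#'
#' @param dyads Tibble from [generate_dyads()].
#' @return Long tibble with columns `dyad_id`, `member` ("a"/"b"), `report`
#'   (-0.5/+0.5) and `score` (the observed score).
#' @export
dyads_long <- function(dyads) {
  long <- tidyr::pivot_longer(
    dplyr::select(dyads, "dyad_id", "obs_a", "obs_b"),
    cols = c("obs_a", "obs_b"), names_to = "member", names_prefix = "obs_",
    values_to = "score"
  )
  dplyr::mutate(long, report = ifelse(.data$member == "a", -0.5, 0.5),
                .before = "score")
}

#' Write a dyad dataset to CSV
#'
#' @param dyads Tibble from [generate_dyads()] (with or without outcome).
#' @param path Output file path.
#' @param format `"wide"` (one row per dyad: id, obs_a, obs_b and, when
#'   present, z and w_true) or `"long"` (one row per member).
#' @return `path`, invisibly.
#' @export
write_dyad_csv <- function(dyads, path, format = c("wide", "long")) {
  format <- match.arg(format)
  out <- if (format == "wide") {
    keep <- intersect(c("dyad_id", "obs_a", "obs_b", "z", "w_true"), names(dyads))
    dyads[keep]
  } else {
    dyads_long(dyads)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a wide dyad CSV
#'
#' Accepts user data with one row per dyad and columns `dyad_id` (or `id`),
#' `score_a`/`obs_a` and `score_b`/`obs_b`, plus optionally `z`.
#'
#' @param path CSV path.
#' @return A dyad tibble usable by the estimator functions (true-score
#'   columns are absent for user data).
#' @export
read_dyad_csv <- function(path) {
  raw <- utils::read.csv(path)
  names(raw) <- tolower(names(raw))
  pick <- function(...) {
    nm <- intersect(c(...), names(raw))
    if (!length(nm)) abort(paste0("missing column: one of ", paste(c(...), collapse = "/")),
                           class = "dyadsim_config_error")
    raw[[nm[1]]]
  }
  out <- tibble::tibble(
    dyad_id = pick("dyad_id", "id"),
    obs_a = as.numeric(pick("obs_a", "score_a")),
    obs_b = as.numeric(pick("obs_b", "score_b"))
  )
  if ("z" %in% names(raw)) out$z <- as.numeric(raw$z)
  out
}
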