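#' Raw score difference (RSD)
#'
#' The simplest idiographic discrepancy estimate: the elementwise difference
#' of the two members' observed scores, oriented so that positive values mean
#' member B exceeds member A (consistent with the -0.5/+0.5 reporter coding,
#' so the MLM slope and the SEM slope factor estimate the same signed
#' quantity).
#'
#' @param dyads Data frame with columns `obs_a` and `obs_b`.
#' @return A `discrepancy_fit` object; `tidy()` gives per-dyad scores.
#' @examples
#' tidy(rsd(tibble::tibble(obs_a = c(1, 2), obs_b = c(4, 1))))
#' @export
rsd <- function(dyads) {
  check_dyads(dyads)
  scores <- dyads$obs_b - dyads$obs_a
  new_discrepancy_fit(
    method = "rsd", scores = scores, dyad_id = dyads_id(dyads),
    gamma00_hat = mean((dyads$obs_a + dyads$obs_b) / 2),
    gamma10_hat = mean(scores),
    t_hat = NULL, sigma2_fixed = c(a = 0, b = 0), lambda_bar = 1,
    converged = TRUE, boundary = FALSE, loglik = NA_real_
  )
}

#' Measurement-error specification for the model-based estimators
#'
#' The random-coefficient MLM and the two-indicator SEM are identified only
#' when the level-1 residual (measurement-error) variances are supplied. In
#' `"design"` mode these are the generating error variances
#' `(1 - alpha) / alpha * total_true_var` carried by the dataset's condition.
#' In `"data"` mode they are estimated from the observed scores as
#' `(1 - mean(alpha)) * s2_w`, where `s2_w` is the pooled within-dyad sample
#' variance (one degree of freedom per dyad) and `alpha` the externally
#' supplied reliability.
#'
#' @param dyads Dyad tibble. `"design"` mode requires the condition attribute
#'   from [generate_dyads()] (or explicit `sigma2_e_a`/`sigma2_e_b`).
#' @param mode `"design"` or `"data"`.
#' @param alpha Reliability (scalar or `c(alpha_a, alpha_b)`), required in
#'   `"data"` mode.
#' @param sigma2_e_a,sigma2_e_b Explicit error variances, overriding the
#'   condition in `"design"` mode.
#' @return An object of class `me_spec`: mode, the two error variances, and
#'   the alpha used (data mode).
#' @examples
#' d <- tibble::tibble(obs_a = c(0, 1, 4), obs_b = c(2, 1, 0))
#' measurement_error(d, mode = "data", alpha = 0.5)
#' @export
measurement_error <- function(dyads, mode = c("design", "data"), alpha = NULL,
                              sigma2_e_a = NULL, sigma2_e_b = NULL) {
  mode <- match.arg(mode)
  if (mode == "design") {
    if (is.null(sigma2_e_a) || is.null(sigma2_e_b)) {
      cond <- attr(dyads, "condition")
      if (is.null(cond) || !"sigma2_e_a" %in% names(cond)) {
        abort("design mode needs a generated dataset or explicit error variances",
              class = "dyadsim_config_error")
      }
      sigma2_e_a <- cond$sigma2_e_a
      sigma2_e_b <- cond$sigma2_e_b
    }
    if (sigma2_e_a < 0 || sigma2_e_b < 0) {
      abort("error variances must be non-negative", class = "dyadsim_domain_error")
    }
    out <- list(mode = "design", sigma2_e_a = sigma2_e_a,
                sigma2_e_b = sigma2_e_b, alpha_used = NA_real_)
  } else {
    check_dyads(dyads)
    if (nrow(dyads) < 2) abort("data mode needs at least 2 dyads",
                               class = "dyadsim_domain_error")
    if (is.null(alpha)) abort("data mode needs `alpha`", class = "dyadsim_config_error")
    abar <- mean(alpha)
    if (abar <= 0 || abar > 1) abort("alpha must lie in (0, 1]",
                                     class = "dyadsim_domain_error")
    s2w <- mean((dyads$obs_a - dyads$obs_b)^2) / 2
    me <- (1 - abar) * s2w
    out <- list(mode = "data", sigma2_e_a = me, sigma2_e_b = me,
                alpha_used = abar)
  }
  structure(out, class = "me_spec")
}

#' @export
print.me_spec <- function(x, ...) {
  cat(sprintf("<me_spec %s> sigma2_e_a = %.4g, sigma2_e_b = %.4g\n",
              x$mode, x$sigma2_e_a, x$sigma2_e_b))
  invisible(x)
}

#' Empirical-Bayes discrepancy (EBD) from the random-coefficient MLM
#'
#' Fits, by maximum likelihood, the two-level model
#' `y_ij = gamma00 + gamma10 * report_ij + u0j + u1j * report_ij + e_ij`
#' with the level-1 residual variances FIXED at the supplied measurement
#' error (the model is otherwise unidentified with two observations per
#' dyad), and the 2x2 random-effect covariance `T` constrained positive
#' semi-definite via a Cholesky parameterization. Because every dyad shares
#' the design matrix `X = [[1, -0.5], [1, 0.5]]`, the fixed effects profile
#' out exactly (`gamma_hat = X^-1 ybar`) and the likelihood reduces to a
#' 2x2 covariance-matching problem with closed-form interior solution
#' `T0 = X^-1 (S - diag(ME)) X^-T`; numeric refinement runs only when `T0`
#' leaves the PSD cone, in which case the solution sits on its boundary
#' (over-shrinkage: the estimated discrepancy variance collapses).
#'
#' Per-dyad discrepancy estimates are the BLUPs
#' `gamma10_hat + [T X' V^-1 (y_j - X gamma_hat)]_2` with
#' `V = X T X' + diag(ME)`; with diagonal `T` and equal error variances this
#' is exactly the classical shrinkage form
#' `lambda * RSD_j + (1 - lambda) * gamma10_hat`,
#' `lambda = tau11 / (tau11 + 2 sigma2_e)`.
#'
#' @param dyads Dyad tibble (needs `obs_a`, `obs_b`).
#' @param me A [measurement_error()] spec; defaults to design mode.
#' @param tol Convergence tolerance on the scaled log-likelihood for the
#'   boundary search.
#' @param max_iter Iteration cap for the boundary search.
#' @return A `discrepancy_fit` with the BLUP `scores`, fixed-effect estimates,
#'   `t_hat`, the conditioning error variances, the implied average shrinkage
#'   weight `lambda_bar`, and `converged`/`boundary` flags.
#' @export
fit_mlm_ebd <- function(dyads, me = NULL, tol = 1e-8, max_iter = 500) {
  check_dyads(dyads)
  J <- nrow(dyads)
  if (J < 3) abort("EBD needs at least 3 dyads to estimate the covariance",
                   class = "dyadsim_domain_error")
  me <- me %||% measurement_error(dyads, "design")
  Th <- diag(c(me$sigma2_e_a, me$sigma2_e_b))
  X <- dyad_design_matrix()
  Xinv <- solve(X)
  Y <- cbind(dyads$obs_a, dyads$obs_b)
  ybar <- colMeans(Y)
  Yc <- sweep(Y, 2, ybar)
  S <- crossprod(Yc) / J
  gam <- drop(Xinv %*% ybar)
  T0 <- Xinv %*% (S - Th) %*% t(Xinv)
  T0 <- (T0 + t(T0)) / 2
  ev <- eigen(T0, symmetric = TRUE, only.values = TRUE)$values
  converged <- TRUE
  if (min(ev) >= 0) {
    That <- T0
  } else {
    neg2ll <- function(l) {
      L <- matrix(c(l[1], l[2], 0, l[3]), 2, 2)
      V <- X %*% tcrossprod(L) %*% t(X) + Th
      dv <- V[1, 1] * V[2, 2] - V[1, 2]^2
      if (!is.finite(dv) || dv <= 1e-300) return(.Machine$double.xmax / 2)
      Vi <- matrix(c(V[2, 2], -V[1, 2], -V[2, 1], V[1, 1]), 2, 2) / dv
      log(dv) + sum(Vi * S)
    }
    ed <- eigen(T0, symmetric = TRUE)
    Tp <- ed$vectors %*% diag(pmax(ed$values, 1e-8)) %*% t(ed$vectors)
    L0 <- t(chol(Tp + diag(1e-10, 2)))
    op <- optim(c(L0[1, 1], L0[2, 1], L0[2, 2]), neg2ll, method = "Nelder-Mead",
                control = list(maxit = max_iter, reltol = tol))
    op2 <- suppressWarnings(
      optim(op$par, neg2ll, method = "BFGS",
            control = list(maxit = max_iter, reltol = tol))
    )
    if (op2$value < op$value) op <- op2
    converged <- op$convergence == 0
    L <- matrix(c(op$par[1], op$par[2], 0, op$par[3]), 2, 2)
    That <- tcrossprod(L)
  }
  V <- X %*% That %*% t(X) + Th
  dv <- V[1, 1] * V[2, 2] - V[1, 2]^2
  if (dv <= 0) abort("singular marginal covariance; supply nonzero measurement error",
                     class = "dyadsim_numeric_error")
  Vi <- matrix(c(V[2, 2], -V[1, 2], -V[2, 1], V[1, 1]), 2, 2) / dv
  K <- That %*% t(X) %*% Vi
  scores <- gam[2] + drop(Yc %*% K[2, ])
  tau11 <- That[2, 2]
  lambda_bar <- tau11 / (tau11 + me$sigma2_e_a + me$sigma2_e_b)
  ll <- -J / 2 * (2 * log(2 * pi) + log(dv) + sum(Vi * S))
  new_discrepancy_fit(
    method = "ebd", scores = scores, dyad_id = dyads_id(dyads),
    gamma00_hat = gam[1], gamma10_hat = gam[2], t_hat = That,
    sigma2_fixed = c(a = me$sigma2_e_a, b = me$sigma2_e_b),
    lambda_bar = lambda_bar, converged = converged,
    boundary = min(eigen(That, symmetric = TRUE, only.values = TRUE)$values) < 1e-8,
    loglik = ll
  )
}

#' SEM latent-difference factor scores
#'
#' Fits the two-indicator latent intercept/slope model: loadings of the
#' intercept factor fixed to 1 for both members, loadings of the slope
#' (discrepancy) factor fixed to -0.5 and +0.5, residual variances fixed at
#' the measurement error (two observed indicators cannot identify free
#' residuals), latent means and the full symmetric latent covariance `Psi`
#' free. With a square loading matrix the ML solution is closed-form: the
#' implied covariance saturates the sample ML covariance.
#'
#' Two factor-score extractions are offered. `"bartlett"` (default) gives the
#' unshrunken weighted-ML scores, which with two indicators reduce to the raw
#' difference `obs_b - obs_a` for the slope factor; `"regression"` gives the
#' posterior-mean scores
#' `mu_hat + [Psi Lambda' Sigma^-1 (y - mu_y)]_2`, which coincide with the
#' EBD BLUPs whenever the unconstrained `Psi` estimate is PSD (identical
#' likelihood, identical scoring formula).
#'
#' @param dyads Dyad tibble.
#' @param me A [measurement_error()] spec; defaults to design mode.
#' @param scoring `"bartlett"` or `"regression"`.
#' @return A `discrepancy_fit`; its `t_hat` is the unconstrained `Psi`
#'   estimate (which may have negative eigenvalues; see `boundary` for the
#'   PSD check used in the EBD comparison).
#' @export
fit_sem_scores <- function(dyads, me = NULL,
                           scoring = c("bartlett", "regression")) {
  scoring <- match.arg(scoring)
  check_dyads(dyads)
  J <- nrow(dyads)
  if (J < 3) abort("SEM needs at least 3 dyads", class = "dyadsim_domain_error")
  me <- me %||% measurement_error(dyads, "design")
  Th <- diag(c(me$sigma2_e_a, me$sigma2_e_b))
  X <- dyad_design_matrix()
  Xinv <- solve(X)
  Y <- cbind(dyads$obs_a, dyads$obs_b)
  ybar <- colMeans(Y)
  Yc <- sweep(Y, 2, ybar)
  S <- crossprod(Yc) / J
  mu <- drop(Xinv %*% ybar)
  Psi <- Xinv %*% (S - Th) %*% t(Xinv)
  Psi <- (Psi + t(Psi)) / 2
  dS <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (scoring == "regression") {
    if (dS <= 1e-12 * max(1, S[1, 1] * S[2, 2])) {
      abort("implied covariance is singular; factor scores are undefined",
            class = "dyadsim_numeric_error")
    }
    Si <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2, 2) / dS
    K <- Psi %*% t(X) %*% Si
    scores <- mu[2] + drop(Yc %*% K[2, ])
  } else {
    # Bartlett weighted-ML scores; with invertible loadings these are X^-1 y
    scores <- drop(Y %*% Xinv[2, ])
  }
  tau11 <- Psi[2, 2]
  ll <- if (dS > 0) -J / 2 * (2 * log(2 * pi) + log(dS) + 2) else NA_real_
  new_discrepancy_fit(
    method = "sem", scores = scores, dyad_id = dyads_id(dyads),
    gamma00_hat = mu[1], gamma10_hat = mu[2], t_hat = Psi,
    sigma2_fixed = c(a = me$sigma2_e_a, b = me$sigma2_e_b),
    lambda_bar = if (scoring == "bartlett") 1 else
      max(0, min(1, tau11 / (tau11 + me$sigma2_e_a + me$sigma2_e_b))),
    converged = TRUE,
    boundary = min(eigen(Psi, symmetric = TRUE, only.values = TRUE)$values) < -1e-10,
    loglik = ll, scoring = scoring
  )
}

#' Fit a discrepancy estimator by name
#'
#' Data-frame-first dispatcher over [rsd()], [fit_mlm_ebd()] and
#' [fit_sem_scores()].
#'
#' @param dyads Dyad tibble.
#' @param method `"rsd"`, `"ebd"` or `"sem"`.
#' @param me Optional [measurement_error()] spec for the model-based methods.
#' @param ... Passed on to the method function.
#' @return A `discrepancy_fit`.
#' @export
fit_discrepancy <- function(dyads, method = c("rsd", "ebd", "sem"),
                            me = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         rsd = rsd(dyads),
         ebd = fit_mlm_ebd(dyads, me = me, ...),
         sem = fit_sem_scores(dyads, me = me, ...))
}

#' Closed-form reliability of a difference score
#'
#' Classical-test-theory reliability of `X - Y` allowing correlated errors:
#' \deqn{\rho_{DD'} = \frac{\rho_{XX'} V_X + \rho_{YY'} V_Y
#'   - 2\rho_{XY}\sigma_X\sigma_Y
#'   + 2\rho_{E}\sigma_X\sigma_Y\sqrt{(1-\rho_{XX'})(1-\rho_{YY'})}}
#'   {V_X + V_Y - 2\rho_{XY}\sigma_X\sigma_Y}}
#' Used as the analytic oracle for the simulated RSD reliability.
#'
#' @param rho_xx,rho_yy Reliabilities of the two component scores.
#' @param var_x,var_y Their observed variances (positive).
#' @param rho_xy Correlation between the observed scores.
#' @param rho_exy Correlation between the two error terms.
#' @return The difference-score reliability.
#' @examples
#' diff_score_reliability(0.8, 0.8, 1, 1, rho_xy = 0.5) # 0.6
#' @export
diff_score_reliability <- function(rho_xx, rho_yy, var_x = 1, var_y = 1,
                                   rho_xy = 0, rho_exy = 0) {
  if (var_x <= 0 || var_y <= 0) abort("variances must be positive",
                                      class = "dyadsim_domain_error")
  if (any(abs(c(rho_xx, rho_yy, rho_xy, rho_exy)) > 1)) {
    abort("correlations must lie in [-1, 1]", class = "dyadsim_domain_error")
  }
  sx <- sqrt(var_x); sy <- sqrt(var_y)
  den <- var_x + var_y - 2 * rho_xy * sx * sy
  if (abs(den) < 1e-12) abort("difference-score variance is zero; reliability undefined",
                              class = "dyadsim_domain_error")
  num <- rho_xx * var_x + rho_yy * var_y - 2 * rho_xy * sx * sy +
    2 * rho_exy * sx * sy * sqrt((1 - rho_xx) * (1 - rho_yy))
  num / den
}

# ---- internal ---------------------------------------------------------------

check_dyads <- function(dyads) {
  if (!is.data.frame(dyads) || !all(c("obs_a", "obs_b") %in% names(dyads))) {
    abort("expected a data frame with columns `obs_a` and `obs_b`",
          class = "dyadsim_config_error")
  }
  if (anyNA(dyads$obs_a) || anyNA(dyads$obs_b)) {
    abort("missing observed scores are not supported", class = "dyadsim_domain_error")
  }
  invisible(dyads)
}

dyads_id <- function(dyads) {
  if ("dyad_id" %in% names(dyads)) dyads$dyad_id else seq_len(nrow(dyads))
}

new_discrepancy_fit <- function(method, scores, dyad_id, gamma00_hat,
                                gamma10_hat, t_hat, sigma2_fixed, lambda_bar,
                                converged, boundary, loglik, scoring = NULL) {
  if (!is.null(t_hat)) dimnames(t_hat) <- NULL
  structure(
    list(method = method, scores = as.numeric(scores), dyad_id = dyad_id,
         gamma00_hat = unname(gamma00_hat), gamma10_hat = unname(gamma10_hat),
         t_hat = t_hat,
         sigma2_fixed = sigma2_fixed, lambda_bar = lambda_bar,
         converged = converged, boundary = boundary, loglik = loglik,
         scoring = scoring, n_dyads = length(scores)),
    class = "discrepancy_fit"
  )
}

#' @export
print.discrepancy_fit <- function(x, ...) {
  cat(sprintf("<discrepancy_fit %s> %d dyads; gamma10_hat = %.4g; lambda_bar = %.3g%s%s\n",
              toupper(x$method), x$n_dyads, x$gamma10_hat, x$lambda_bar,
              if (isTRUE(x$boundary)) "; boundary" else "",
              if (!isTRUE(x$converged)) "; NOT converged" else ""))
  invisible(x)
}
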