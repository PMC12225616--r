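# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no stored data.

one_condition <- function(icc = 0.3, n_dyads = 50, alpha = c(0.8, 0.8),
                          effect_size = 0.5, es_var = 1,
                          distinguishable = TRUE) {
  design_grid(icc = icc, n_dyads = n_dyads, reliability = list(alpha),
              effect_size = effect_size, es_var = es_var,
              distinguishable = distinguishable)
}

# Dyad tibble whose sample ML covariance of (obs_a, obs_b) EXACTLY equals
# `target` and whose member means exactly equal `mu_y`. Used to pin down the
# closed-form covariance-matching solutions of the model-based estimators.
moment_matched_dyads <- function(J, target, mu_y = c(0, 0), seed = 1) {
  set.seed(seed)
  repeat {
    Y <- matrix(rnorm(2 * J), J, 2)
    Yc <- sweep(Y, 2, colMeans(Y))
    S <- crossprod(Yc) / J
    if (det(S) > 1e-8) break
  }
  W <- solve(t(chol(S)))            # whitens: cov(Yc %*% t(W)) = I (ML)
  Yt <- Yc %*% t(W) %*% chol(target)
  Yt <- sweep(Yt, 2, mu_y, `+`)
  tibble::tibble(dyad_id = seq_len(J), obs_a = Yt[, 1], obs_b = Yt[, 2])
}

# Textbook normal-equations OLS oracle: coefficients and standard errors via
# solve(X'X) on an explicit design matrix.
ols_oracle <- function(z, ...) {
  X <- cbind(1, ...)
  XtXi <- solve(crossprod(X))
  b <- drop(XtXi %*% crossprod(X, z))
  res <- z - drop(X %*% b)
  s2 <- sum(res^2) / (length(z) - ncol(X))
  list(coef = b, se = sqrt(s2 * diag(XtXi)))
}

# Independent brute-force maximiser of the EBD marginal likelihood: optimises
# the FULL parameter vector (gamma00, gamma10, t00, t01, t11) with a PSD
# penalty from a coarse grid of starts, then applies the textbook BLUP
# formula dyad by dyad.
ebd_oracle <- function(dyads, me) {
  X <- matrix(c(1, 1, -0.5, 0.5), 2, 2)
  Th <- diag(c(me$sigma2_e_a, me$sigma2_e_b))
  Y <- cbind(dyads$obs_a, dyads$obs_b)
  J <- nrow(Y)
  nll <- function(par) {
    Tm <- matrix(c(par[3], par[4], par[4], par[5]), 2, 2)
    ev <- eigen(Tm, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 0) return(1e8 * (1 + sum(pmax(-ev, 0))))
    V <- X %*% Tm %*% t(X) + Th
    dv <- det(V)
    if (dv <= 1e-12) return(1e8)
    Vi <- solve(V)
    r <- sweep(Y, 2, drop(X %*% par[1:2]))
    0.5 * (J * log(dv) + sum((r %*% Vi) * r))
  }
  best <- NULL
  m0 <- mean((Y[, 1] + Y[, 2]) / 2)
  d0 <- mean(Y[, 2] - Y[, 1])
  for (t00 in c(0.05, 0.2, 0.5, 1)) {
    for (t11 in c(0.1, 0.5, 1, 2)) {
      op <- optim(c(m0, d0, t00, 0, t11), nll,
                  control = list(maxit = 5000, reltol = 1e-14))
      op <- optim(op$par, nll, control = list(maxit = 5000, reltol = 1e-15))
      if (is.null(best) || op$value < best$value) best <- op
    }
  }
  par <- best$par
  Tm <- matrix(c(par[3], par[4], par[4], par[5]), 2, 2)
  V <- X %*% Tm %*% t(X) + Th
  Vi <- solve(V)
  gam <- par[1:2]
  scores <- vapply(seq_len(J), function(j) {
    gam[2] + drop(Tm %*% t(X) %*% Vi %*% (Y[j, ] - drop(X %*% gam)))[2]
  }, numeric(1))
  list(scores = scores, gamma = gam, T = Tm, value = best$value)
}

# Hand Type-I sums of squares for a balanced two-factor design with
# interaction (the classical cell-mean decomposition).
eta_oracle_2way <- function(y, f1, f2) {
  g <- mean(y)
  ss_tot <- sum((y - g)^2)
  m1 <- tapply(y, f1, mean)
  m2 <- tapply(y, f2, mean)
  n1 <- tapply(y, f1, length)
  n2 <- tapply(y, f2, length)
  ss1 <- sum(n1 * (m1 - g)^2)
  ss2 <- sum(n2 * (m2 - g)^2)
  cell <- tapply(y, list(f1, f2), mean)
  ncell <- tapply(y, list(f1, f2), length)
  dev <- sweep(sweep(cell, 1, m1), 2, m2) + g
  ss12 <- sum(ncell * dev^2)
  c(f1 = ss1 / ss_tot, f2 = ss2 / ss_tot, inter = ss12 / ss_tot)
}
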