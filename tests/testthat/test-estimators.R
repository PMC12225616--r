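test_that("RSD is the elementwise observed difference, oriented B - A", {
  expect_equal(tidy(rsd(tibble::tibble(obs_a = 3, obs_b = 5)))$score, 2)
  d <- tibble::tibble(obs_a = c(1, 2), obs_b = c(4, 1))
  expect_equal(tidy(rsd(d))$score, c(3, -1))
  same <- tibble::tibble(obs_a = c(1.5, -2), obs_b = c(1.5, -2))
  expect_equal(tidy(rsd(same))$score, c(0, 0))   # 0 = no discrepancy
  expect_error(rsd(tibble::tibble(obs_a = 1:3)), class = "dyadsim_config_error")
})

test_that("measurement error: design mode returns the generating variances", {
  cond <- one_condition(alpha = c(0.7, 0.8))
  d <- generate_dyads(cond, seed = 1)
  me <- measurement_error(d, "design")
  expect_equal(me$sigma2_e_a, 0.3 / 0.7, tolerance = 1e-12)
  expect_equal(me$sigma2_e_b, 0.25)
})

test_that("measurement error: data mode matches the hand-pooled variance", {
  toy <- tibble::tibble(obs_a = c(0, 1, 4), obs_b = c(2, 1, 0))
  # within-dyad variances (1 df each): 2, 0, 8 -> pooled 10/3
  me <- measurement_error(toy, "data", alpha = 0.5)
  expect_equal(me$sigma2_e_a, 0.5 * 10 / 3, tolerance = 1e-12)
  expect_equal(measurement_error(toy, "data", alpha = 1)$sigma2_e_a, 0)
  expect_error(measurement_error(toy[1, ], "data", alpha = 0.5),
               class = "dyadsim_domain_error")
})

test_that("EBD reduces to RSD when measurement error vanishes", {
  d <- generate_dyads(one_condition(n_dyads = 40), seed = 3)
  me0 <- measurement_error(d, "design", sigma2_e_a = 0, sigma2_e_b = 0)
  fit <- fit_mlm_ebd(d, me = me0)
  expect_equal(fit$scores, d$obs_b - d$obs_a, tolerance = 1e-8)
  expect_equal(fit$lambda_bar, 1)
})

test_that("a zero-variance difference collapses EBD to the grand slope", {
  set.seed(4)
  d <- tibble::tibble(obs_a = rnorm(30), obs_b = NA_real_)
  d$obs_b <- d$obs_a + 2                  # constant observed difference
  me <- measurement_error(d, "design", sigma2_e_a = 0.4, sigma2_e_b = 0.4)
  fit <- fit_mlm_ebd(d, me = me)
  expect_true(fit$boundary)
  expect_equal(fit$gamma10_hat, 2)
  expect_lt(max(abs(fit$scores - fit$gamma10_hat)), 1e-3)
})

test_that("EBD matches a brute-force marginal-likelihood oracle", {
  for (s in c(12, 101)) {
    d <- generate_dyads(one_condition(n_dyads = 12, es_var = 1.5,
                                      icc = 0.5), seed = s)
    me <- measurement_error(d, "design")
    fit <- fit_mlm_ebd(d, me = me)
    orc <- ebd_oracle(d, me)
    expect_lt(max(abs(fit$scores - orc$scores)), 1e-6)
    expect_lt(abs(fit$gamma10_hat - orc$gamma[2]), 1e-6)
  }
})

test_that("with diagonal T and equal errors, EBD is the classical shrinkage", {
  Tm <- diag(c(0.4, 0.9))
  sig2 <- 0.25
  X <- matrix(c(1, 1, -0.5, 0.5), 2, 2)
  S <- X %*% Tm %*% t(X) + diag(sig2, 2)
  d <- moment_matched_dyads(60, S, mu_y = c(0.1, 0.6), seed = 5)
  me <- measurement_error(d, "design", sigma2_e_a = sig2, sigma2_e_b = sig2)
  fit <- fit_mlm_ebd(d, me = me)
  expect_equal(fit$t_hat, Tm, tolerance = 1e-8)
  lambda <- 0.9 / (0.9 + 2 * sig2)
  rsd_scores <- d$obs_b - d$obs_a
  expect_equal(fit$scores,
               lambda * rsd_scores + (1 - lambda) * fit$gamma10_hat,
               tolerance = 1e-8)
  expect_equal(fit$lambda_bar, lambda, tolerance = 1e-8)
  # shrinkage never inflates dispersion
  expect_lte(var(fit$scores), var(rsd_scores))
})

test_that("EBD needs enough dyads and positive definite structure", {
  d <- generate_dyads(one_condition(n_dyads = 4), seed = 1)[1:2, ]
  expect_error(fit_mlm_ebd(d), class = "dyadsim_domain_error")
})

test_that("SEM slope scores equal the raw difference when ME is zero", {
  d <- generate_dyads(one_condition(n_dyads = 25), seed = 6)
  me0 <- measurement_error(d, "design", sigma2_e_a = 0, sigma2_e_b = 0)
  for (sc in c("bartlett", "regression")) {
    fit <- fit_sem_scores(d, me = me0, scoring = sc)
    expect_equal(fit$scores, d$obs_b - d$obs_a, tolerance = 1e-8)
  }
})

test_that("regression-method SEM scores equal EBD on PSD-interior solutions", {
  n_boundary <- 0
  for (s in 1:5) {
    d <- generate_dyads(one_condition(n_dyads = 200), seed = 40 + s)
    me <- measurement_error(d, "design")
    sem <- fit_sem_scores(d, me = me, scoring = "regression")
    ebd <- fit_mlm_ebd(d, me = me)
    if (sem$boundary) {                 # Psi-hat outside the PSD cone
      n_boundary <- n_boundary + 1
      next
    }
    expect_lt(max(abs(sem$scores - ebd$scores)), 1e-6)
    expect_equal(sem$t_hat, ebd$t_hat, tolerance = 1e-8)
  }
  expect_lt(n_boundary, 5)              # interior solutions dominate at J = 200
})

test_that("regression factor scores match the hand matrix-algebra solution", {
  # Psi = I, Theta = 0.25 I: Sigma = [[1.5, .75], [.75, 1.5]], and the slope
  # score weight vector works out to (-2/3, +2/3); a centered (1, 2) dyad
  # scores mu_slope + 2/3.
  X <- matrix(c(1, 1, -0.5, 0.5), 2, 2)
  S <- X %*% diag(2) %*% t(X) + diag(0.25, 2)
  d <- moment_matched_dyads(40, S, mu_y = c(0.2, 0.7), seed = 8)
  me <- measurement_error(d, "design", sigma2_e_a = 0.25, sigma2_e_b = 0.25)
  fit <- fit_sem_scores(d, me = me, scoring = "regression")
  ya_c <- d$obs_a - mean(d$obs_a)
  yb_c <- d$obs_b - mean(d$obs_b)
  expect_equal(fit$scores,
               fit$gamma10_hat - (2 / 3) * ya_c + (2 / 3) * yb_c,
               tolerance = 1e-8)
})

test_that("bartlett SEM scores are the unshrunken slope for any fixed ME", {
  d <- generate_dyads(one_condition(n_dyads = 30), seed = 9)
  fit <- fit_sem_scores(d, scoring = "bartlett")
  expect_equal(fit$scores, d$obs_b - d$obs_a, tolerance = 1e-10)
  expect_equal(fit$lambda_bar, 1)
})

test_that("fit_discrepancy dispatches to the three methods", {
  d <- generate_dyads(one_condition(n_dyads = 30), seed = 10)
  expect_equal(fit_discrepancy(d, "rsd")$method, "rsd")
  expect_equal(fit_discrepancy(d, "ebd")$method, "ebd")
  expect_equal(fit_discrepancy(d, "sem")$method, "sem")
})

test_that("difference-score reliability follows its closed form", {
  expect_equal(diff_score_reliability(0.8, 0.8, 1, 1, rho_xy = 0), 0.8)
  expect_equal(diff_score_reliability(1, 1, 1, 1, rho_xy = 0.5), 1)
  expect_equal(diff_score_reliability(0.8, 0.8, 1, 1, rho_xy = 0.5), 0.6)
  expect_error(diff_score_reliability(0.8, 0.8, 1, 1, rho_xy = 1),
               class = "dyadsim_domain_error")
  expect_error(diff_score_reliability(0.8, 0.8, -1, 1),
               class = "dyadsim_domain_error")
})

test_that("closed-form reliability agrees with the generating moments", {
  # feed the population moments implied by the generator into the formula;
  # the result must equal tau11 / (tau11 + sigma2_e_a + sigma2_e_b)
  for (cond in list(one_condition(icc = 0.1, alpha = c(0.7, 0.7), es_var = 0.5),
                    one_condition(icc = 0.5, alpha = c(0.7, 0.8), es_var = 1))) {
    vc <- derive_variances(cond)
    var_ta <- vc$tau00 + vc$tau11 / 4
    cov_t <- vc$tau00 - vc$tau11 / 4
    var_x <- var_ta + vc$sigma2_e_a
    var_y <- var_ta + vc$sigma2_e_b
    rel <- diff_score_reliability(var_ta / var_x, var_ta / var_y,
                                  var_x, var_y,
                                  rho_xy = cov_t / sqrt(var_x * var_y))
    expect_equal(rel, vc$tau11 / (vc$tau11 + vc$sigma2_e_a + vc$sigma2_e_b),
                 tolerance = 1e-12)
  }
})

test_that("EBD recovers the grand discrepancy over replications", {
  cond <- one_condition(n_dyads = 400, effect_size = 0.5)
  g10 <- vapply(1:200, function(r) {
    d <- generate_dyads(cond, seed = 1000 + r)
    fit_mlm_ebd(d)$gamma10_hat
  }, numeric(1))
  mc_se <- sd(g10) / sqrt(length(g10))
  expect_lt(abs(mean(g10) - 0.5), 3 * mc_se + 1e-8)
})
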