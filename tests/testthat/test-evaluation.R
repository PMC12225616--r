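test_that("discrepancy bias is the signed mean error", {
  x <- c(1, 2, 3)
  expect_equal(bias_discrepancy(x, x), 0)
  expect_equal(bias_discrepancy(x + 0.5, x), 0.5)
  expect_equal(bias_discrepancy(x - 0.5, x, absolute = TRUE), 0.5)
  set.seed(1)
  noise <- rnorm(1e5)
  expect_lt(abs(bias_discrepancy(x[1] + noise, rep(x[1], 1e5))), 0.01)
  expect_error(bias_discrepancy(numeric(0), numeric(0)),
               class = "dyadsim_domain_error")
})

test_that("reliability metric is the variance ratio with an Inf sentinel", {
  set.seed(2)
  truth <- rnorm(5000)
  expect_equal(reliability_metric(truth, truth), 1)
  est <- truth + rnorm(5000, sd = sd(truth))
  expect_equal(reliability_metric(truth, est), 0.5, tolerance = 0.05)
  expect_equal(reliability_metric(truth, rep(2, 5000)), Inf)
  expect_error(reliability_metric(1, 1), class = "dyadsim_domain_error")
})

test_that("SE bias compares reported SEs to the empirical SD", {
  set.seed(3)
  b <- rnorm(200)
  expect_equal(se_bias(rep(sd(b), 200), b), 0, tolerance = 1e-12)
  expect_equal(se_bias(rep(2 * sd(b), 200), b), sd(b), tolerance = 1e-12)
  expect_error(se_bias(1, 1), class = "dyadsim_domain_error")
})

test_that("SE bias vanishes for a correctly specified OLS", {
  ses <- bs <- numeric(300)
  for (r in 1:300) {
    set.seed(4000 + r)
    x <- rnorm(80)
    d <- tibble::tibble(z = 1 + 0.5 * abs(x) + rnorm(80))
    tab <- tidy(fit_outcome_regression(d, x, kind = "indistinguishable"))
    i <- tab$term == "discrepancy"
    ses[r] <- tab$std_error[i]
    bs[r] <- tab$estimate[i]
  }
  expect_lt(abs(se_bias(ses, bs)), 0.02)
})

test_that("power and coverage count significant and covering intervals", {
  mk <- function(p, lo, hi) {
    structure(list(coefficients = tibble::tibble(
      term = "discrepancy", estimate = (lo + hi) / 2, std_error = 1,
      statistic = 1, p_value = p, conf_low = lo, conf_high = hi,
      inestimable = FALSE), r_squared = 0.5, r2_p_value = 0.01, n_obs = 10,
      df_residual = 8, kind = "indistinguishable",
      model_kind = "indistinguishable", conf_level = 0.95),
      class = "outcome_regression")
  }
  res <- list(mk(0.01, 0.7, 0.9), mk(0.5, 0.9, 1.1), mk(0.04, 0.75, 0.85))
  pc <- power_and_coverage(res, true_slopes = c(discrepancy = 0.8))
  expect_equal(pc$power, 2 / 3)
  expect_equal(pc$coverage, 2 / 3)
  expect_equal(pc$n_used, 3)
  expect_error(power_and_coverage(list()), class = "dyadsim_domain_error")
})

test_that("truth-regression coverage is calibrated at the nominal level", {
  hits <- vapply(1:400, function(r) {
    cond <- one_condition(n_dyads = 250)
    d <- generate_outcome(generate_dyads(cond, seed = 5000 + r),
                          basis = "true")
    tab <- tidy(truth_regression(d))
    i <- tab$term == "discrepancy"
    tab$conf_low[i] <= 0.8 && 0.8 <= tab$conf_high[i]
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.95), 0.03)
})

test_that("R-squared bias is a difference of means", {
  expect_equal(r2_bias(c(0.2, 0.4), c(0.5, 0.5)), -0.2)
  expect_equal(r2_bias(c(0.3, 0.3), c(0.3, 0.3)), 0)
  expect_error(r2_bias(numeric(0), numeric(0)), class = "dyadsim_domain_error")
})

test_that("metrics decompose over replication batches and ignore dyad order", {
  st <- run_study(one_condition(n_dyads = 60), reps = 6, seed = 9)
  rec <- st$rep_records
  half1 <- cell_metrics(dplyr::filter(rec, rep <= 3))
  half2 <- cell_metrics(dplyr::filter(rec, rep > 3))
  full <- cell_metrics(rec)
  for (col in c("bias_discrepancy", "reliability", "power_discrepancy",
                "coverage_discrepancy")) {
    expect_equal(full[[col]], (half1[[col]] + half2[[col]]) / 2,
                 tolerance = 1e-12)
  }
  # per-dyad permutation leaves every per-replication record unchanged
  d <- generate_outcome(generate_dyads(one_condition(n_dyads = 40), seed = 1))
  perm <- d[sample(nrow(d)), ]
  expect_equal(reliability_metric(perm$d_true, perm$obs_b - perm$obs_a),
               reliability_metric(d$d_true, d$obs_b - d$obs_a))
  expect_equal(bias_discrepancy(perm$obs_b - perm$obs_a, perm$d_true),
               bias_discrepancy(d$obs_b - d$obs_a, d$d_true))
})

test_that("EBD outlier flagging counts values outside the RSD+SEM range", {
  base <- tibble::tibble(
    method = rep(c("rsd", "sem", "ebd"), each = 10),
    slope_bias_discrepancy = c(seq(-1.4, -0.3, length.out = 10),
                               seq(-1.3, -0.4, length.out = 10),
                               c(seq(-1.2, -0.5, length.out = 8), 66.5, -27.1)),
    icc = rep(0.5, 30), n_dyads = rep(50, 30)
  )
  out <- flag_ebd_outliers(base)
  expect_equal(out$bounds, c(-1.4, -0.3))
  expect_equal(out$n_outliers, 2)
  expect_equal(out$fraction, 0.2)
  expect_equal(out$crosstab$fraction, 0.2)
  inside <- dplyr::mutate(base, slope_bias_discrepancy =
                            pmin(pmax(slope_bias_discrepancy, -1.4), -0.3))
  expect_equal(flag_ebd_outliers(inside)$n_outliers, 0)
  fixed <- flag_ebd_outliers(base, bounds = c(-100, 100))
  expect_equal(fixed$n_outliers, 0)
  expect_error(flag_ebd_outliers(base[base$method != "sem", ]),
               class = "dyadsim_config_error")
})
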