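test_that("null period/cohort structure yields zero drift and deviations", {
  tr <- small_truth(drift = 0, age_slope = 0.05, offset = 1e9)
  fit <- fit_apc(exact_lexis(tr))
  expect_lt(abs(fit$net_drift), 1e-6)
  expect_lt(max(abs(fit$period_dev)), 1e-6)
  expect_lt(max(abs(fit$cohort_dev)), 1e-6)
  expect_equal(fit$long_age_trend, 0.05, tolerance = 1e-6)
  efs <- estimable_functions(fit)
  expect_equal(efs$crr$estimate, rep(1, length(fit$lexis$cohorts)),
               tolerance = 1e-6)
  expect_equal(efs$prr$estimate, rep(1, length(fit$lexis$periods)),
               tolerance = 1e-6)
})

test_that("net drift is recovered within sampling error", {
  tr <- small_truth(drift = 0.01, offset = 1e6)
  fit <- fit_apc(generate_lexis(tr, seed = 31))
  se <- sqrt(fit$param_cov["net_drift", "net_drift"])
  expect_lt(abs(fit$net_drift - 0.01), 3 * se)
})

test_that("doubling the data halves the parameter covariance", {
  tr <- small_truth()
  lx <- generate_lexis(tr, seed = 5)
  lx2 <- lexis_diagram(2 * lx$cases, 2 * lx$offsets, lx$ages[1],
                       lx$periods[1], lx$delta)
  f1 <- fit_apc(lx); f2 <- fit_apc(lx2)
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-8)
  expect_equal(f2$param_cov, f1$param_cov / 2, tolerance = 1e-6)
})

test_that("age-cohort and age-period assemblies agree cell-for-cell", {
  for (seed in c(2, 9)) {
    fit <- fit_apc(generate_lexis(small_truth(period_quad = 0.05,
                                              cohort_quad = 0.1), seed = seed))
    f1 <- fitted_log_rates(fit, "age_cohort")$log_rates
    f2 <- fitted_log_rates(fit, "age_period")$log_rates
    expect_lt(max(abs(f1 - f2)), 1e-8)
  }
})

test_that("an exactly APC-generated surface is reproduced by the fit", {
  tr <- small_truth(age_quad = 0.3, period_quad = 0.1, cohort_quad = 0.2,
                    offset = 1e8)
  lx <- exact_lexis(tr)
  fit <- fit_apc(lx)
  truth_lr <- log(lx$cases / lx$offsets)
  expect_lt(max(abs(fitted_log_rates(fit)$log_rates - truth_lr)), 1e-6)
})

test_that("IRLS reproduces the total observed case count", {
  fit <- fit_apc(generate_lexis(small_truth(), seed = 3))
  expect_equal(sum(fitted(fit, "count")), sum(fit$lexis$cases),
               tolerance = 1e-8)
})

test_that("deviation vectors are orthogonal to constant, linear, quadratic", {
  fit <- fit_apc(generate_lexis(small_truth(cohort_quad = 0.2), seed = 11))
  for (axis in list(list(fit$age_dev, fit$lexis$ages),
                    list(fit$period_dev, fit$lexis$periods),
                    list(fit$cohort_dev, fit$lexis$cohorts))) {
    dev <- axis[[1]]; idx <- axis[[2]]
    expect_lt(abs(sum(dev)), 1e-9)
    expect_lt(abs(sum(dev * (idx - mean(idx)))), 1e-9)
  }
  # residual deviations additionally orthogonal to the quadratic
  pr <- partition_deviations(fit$cohort_dev, fit$lexis$cohorts)
  expect_lt(abs(sum(pr$resid * pr$q2)), 1e-9)
  expect_equal(pr$theta * pr$q2 + pr$resid, fit$cohort_dev, tolerance = 1e-12)
})

test_that("partition_deviations recovers planted quadratic amplitudes", {
  idx <- 1990:2019
  q2 <- partition_deviations(rnorm(30), idx)$q2   # basis only
  # wiggle orthogonal to {1, x, q2} via explicit projection
  set.seed(8)
  w <- rnorm(30)
  X <- cbind(1, idx - mean(idx), q2)
  w <- w - X %*% solve(crossprod(X), crossprod(X, w))
  dev <- 0.3 * q2 + as.vector(w)
  pr <- partition_deviations(dev, idx)
  expect_equal(pr$theta, 0.3, tolerance = 1e-10)
  expect_equal(pr$resid, as.vector(w), tolerance = 1e-10)
  # pure quadratic -> zero residual; pure wiggle -> zero theta
  expect_lt(max(abs(partition_deviations(0.5 * q2, idx)$resid)), 1e-12)
  expect_lt(abs(partition_deviations(as.vector(w), idx)$theta), 1e-12)
  expect_error(partition_deviations(c(1, -1)), "length >= 3")
})

test_that("estimable functions are normalized and reference-invariant", {
  fit <- fit_apc(generate_lexis(small_truth(cohort_quad = 0.15), seed = 13))
  efs <- estimable_functions(fit)
  expect_identical(efs$crr$estimate[efs$c0_idx], 1)
  expect_identical(efs$prr$estimate[efs$p0_idx], 1)
  expect_true(all(efs$long_age$estimate > 0))
  # changing c0 rescales CRR by a constant
  c_alt <- fit$lexis$cohorts[efs$c0_idx + 3]
  efs2 <- estimable_functions(fit, c0 = c_alt)
  ratio <- efs2$crr$estimate / efs$crr$estimate
  expect_lt(diff(range(ratio)), 1e-10)
  expect_error(estimable_functions(fit, c0 = 1700), "valid labels")
  expect_error(estimable_functions(fit, p0 = 1700), "valid labels")
})

test_that("drift-only fits give log-linear PRR with slope equal to drift", {
  tr <- small_truth(drift = 0.02, offset = 1e9)
  fit <- fit_apc(exact_lexis(tr))
  efs <- estimable_functions(fit)
  lp <- log(efs$prr$estimate)
  slopes <- diff(lp) / diff(efs$prr$period)
  expect_equal(slopes, rep(0.02, length(slopes)), tolerance = 1e-6)
})

test_that("quasipoisson dispersion scales the covariance and floors at 1", {
  lx <- generate_lexis(small_truth(), seed = 17)
  f_p <- fit_apc(lx, family = "poisson")
  f_q <- fit_apc(lx, family = "quasipoisson")
  expect_gte(f_q$dispersion, 1)
  expect_equal(f_q$param_cov, f_p$param_cov * f_q$dispersion,
               tolerance = 1e-10)
  expect_equal(f_q$coefficients, f_p$coefficients)
})

test_that("wls engine agrees with IRLS at large counts", {
  tr <- small_truth(offset = 1e8)
  lx <- generate_lexis(tr, seed = 19)
  f_i <- fit_apc(lx, engine = "irls")
  f_w <- fit_apc(lx, engine = "wls")
  expect_equal(f_w$net_drift, f_i$net_drift, tolerance = 1e-4)
  expect_equal(f_w$mu, f_i$mu, tolerance = 1e-4)
})

test_that("aggregate_rates applies the linear operator correctly", {
  rates <- matrix(c(1, 2, 4, 2, 3, 5), 3, 2) * 1e-4
  offs <- matrix(c(10, 10, 20, 10, 30, 20), 3, 2)
  # single-age group returns the row unchanged
  g1 <- aggregate_rates(rates, NULL, list(top = 1), offs)
  expect_equal(g1$rate, rates[1, ])
  # equal offsets -> plain mean
  g2 <- aggregate_rates(rates[, 1, drop = FALSE], NULL, list(m = 1:2),
                        offs[, 1, drop = FALSE])
  expect_equal(g2$rate, mean(rates[1:2, 1]))
  # brute-force w' Sigma w on a 3-age toy with correlated cells
  S <- matrix(c(4, 1, 0.5, 1, 3, 0.2, 0.5, 0.2, 2), 3, 3) * 1e-10
  w <- offs[, 1] / sum(offs[, 1])
  manual <- drop(t(w) %*% S %*% w)
  full_cov <- matrix(0, 6, 6); full_cov[1:3, 1:3] <- S
  g3 <- aggregate_rates(rates, full_cov, list(all = 1:3), offs)
  expect_equal(g3$var[1], manual)
  expect_error(aggregate_rates(rates, NULL, list(bad = integer(0)), offs),
               "empty")
})

test_that("degenerate grids are rejected", {
  expect_error(fit_apc(lexis_diagram(matrix(1, 2, 5), matrix(10, 2, 5),
                                     40, 2000)), "at least 3")
})
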