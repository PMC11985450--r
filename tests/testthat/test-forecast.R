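test_that("zero-horizon forecasts reproduce the fitted surface", {
  fit <- fit_apc(generate_lexis(small_truth(), seed = 1))
  fc <- forecast_incidence(fit, h_fwd = 0, h_back = 0)
  expect_identical(unique(as.vector(fc$mask)), "observed-fitted")
  expect_equal(fc$log_rates, fitted_log_rates(fit)$log_rates,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("drift-only truth gives the closed-form forecast under both forms", {
  tr <- small_truth(drift = 0.012, offset = 1e9)
  fit <- fit_apc(exact_lexis(tr))
  fc_ac <- forecast_incidence(fit, h_fwd = 8, h_back = 8, form = "AC",
                              third = "none")
  fc_ap <- forecast_incidence(fit, h_fwd = 8, h_back = 8, form = "AP",
                              third = "none")
  A <- length(fc_ac$ages); Pe <- length(fc_ac$periods)
  closed <- matrix(truth_log_rate(tr, rep(tr$ages, Pe),
                                  rep(fc_ac$periods, each = A)), A, Pe)
  expect_lt(max(abs(fc_ac$log_rates - closed)), 1e-6)
  expect_lt(max(abs(fc_ap$log_rates - closed)), 1e-6)
  expect_lt(max(abs(fc_ac$log_rates - fc_ap$log_rates)), 1e-6)
})

test_that("partially observed cohorts keep their fitted rate ratio", {
  fit <- fit_apc(generate_lexis(small_truth(cohort_quad = 0.1), seed = 21))
  efs <- estimable_functions(fit)
  fc <- forecast_incidence(fit, efs, h_fwd = 1, h_back = 0, form = "AC",
                           third = "none")
  jnew <- length(fc$periods)
  pnew <- fc$periods[jnew]
  for (ai in seq_along(fc$ages)) {
    ci <- match(pnew - fc$ages[ai], fit$lexis$cohorts)
    if (is.na(ci)) next   # unobserved cohort
    expect_equal(fc$rates[ai, jnew],
                 efs$long_age$estimate[ai] * efs$crr$estimate[ci],
                 tolerance = 1e-10)
    expect_identical(fc$mask[ai, jnew], "forecast-partial-cohort")
  }
})

test_that("the model-set taxonomy has 4 basic and 12 full members", {
  fit <- fit_apc(generate_lexis(small_truth(period_quad = 0.05), seed = 2))
  efs <- estimable_functions(fit)
  m4 <- enumerate_model_set(fit, efs, h_fwd = 5, which = "four_basic")
  expect_length(m4, 4)
  expect_length(unique(names(m4)), 4)
  m12 <- enumerate_model_set(fit, efs, h_fwd = 5, which = "twelve_full")
  expect_length(m12, 12)
  expect_length(unique(names(m12)), 12)
  groups <- vapply(m12, function(f) f$provenance$group, character(1))
  expect_equal(unname(table(groups)[c("both", "period-only", "cohort-only",
                                      "neither")]),
               c(4L, 3L, 3L, 2L), ignore_attr = TRUE)
  # all members agree on observed-period cells
  obs <- m12[[1]]$mask == "observed-fitted"
  for (f in m12[-1]) expect_equal(f$rates[obs], m12[[1]]$rates[obs])
  # distinct models genuinely differ somewhere in the forecast region
  sig <- vapply(m12, function(f) sum(f$rates[!obs]), numeric(1))
  expect_length(unique(round(sig, 10)), 12)
})

test_that("model averaging is the cell-wise mean with the stated CI modes", {
  fit <- fit_apc(generate_lexis(small_truth(), seed = 3))
  fc <- forecast_incidence(fit, h_fwd = 4)
  # averaging copies returns the member unchanged
  av <- average_models(list(fc, fc, fc))
  expect_equal(av$rates, fc$rates)
  expect_equal(av$log_var, fc$log_var)
  # hand-built members: rates 2 and 4 -> mean 3; span CI is the union
  f1 <- fc; f2 <- fc
  f1$rates[] <- 2; f1$log_rates[] <- log(2); f1$log_var[] <- 0.01
  f2$rates[] <- 4; f2$log_rates[] <- log(4); f2$log_var[] <- 0.04
  avm <- average_models(list(f1, f2))
  expect_true(all(avm$rates == 3))
  expect_true(all(abs(avm$log_var - 0.025) < 1e-12))
  avs <- average_models(list(f1, f2), ci_mode = "span")
  z <- qnorm(0.975)
  expect_equal(avs$ci_lower[1, 1], min(2 * exp(-z * 0.1), 4 * exp(-z * 0.2)))
  expect_equal(avs$ci_upper[1, 1], max(2 * exp(z * 0.1), 4 * exp(z * 0.2)))
  # grid mismatch rejected
  fc2 <- forecast_incidence(fit, h_fwd = 2)
  expect_error(average_models(list(fc, fc2)), "different grids")
})

test_that("longer horizons extend rather than alter shorter ones", {
  fit <- fit_apc(generate_lexis(small_truth(cohort_quad = 0.1,
                                            period_quad = 0.05), seed = 4))
  efs <- estimable_functions(fit)
  for (form in c("AC", "AP")) {
    f5 <- forecast_incidence(fit, efs, h_fwd = 5, h_back = 3, form = form,
                             third = "linear")
    f10 <- forecast_incidence(fit, efs, h_fwd = 10, h_back = 6, form = form,
                              third = "linear")
    cols <- match(f5$periods, f10$periods)
    expect_equal(f10$rates[, cols], f5$rates, tolerance = 1e-12)
    expect_equal(f10$mask[, cols], f5$mask)
  }
})

test_that("counterfactual slope scaling is coherent", {
  fit <- fit_apc(generate_lexis(small_truth(cohort_quad = 0.08), seed = 5))
  efs <- estimable_functions(fit)
  fc <- forecast_incidence(fit, efs, h_fwd = 6, form = "AC")
  # scaling the trend by 1 changes nothing
  fc1 <- forecast_incidence(fit, efs, h_fwd = 6, form = "AC",
                            crr_trend = scale_slope(fc$trend, 1))
  expect_equal(fc1$rates, fc$rates)
  # rr_extrap = "horizontal" equals a flattened trend
  fc_h <- forecast_incidence(fit, efs, h_fwd = 6, form = "AC",
                             rr_extrap = "horizontal")
  fc_f <- forecast_incidence(fit, efs, h_fwd = 6, form = "AC",
                             crr_trend = flatten_tail(fc$trend, side = "both"))
  expect_equal(fc_h$rates, fc_f$rates)
})

test_that("third-variable treatments behave as documented", {
  tr <- small_truth(period_quad = 0.2, offset = 1e9)
  fit <- fit_apc(exact_lexis(tr))
  efs <- estimable_functions(fit)
  fc_n <- forecast_incidence(fit, efs, h_fwd = 5, form = "AC", third = "none")
  fc_h <- forecast_incidence(fit, efs, h_fwd = 5, form = "AC",
                             third = "horizontal")
  fc_l <- forecast_incidence(fit, efs, h_fwd = 5, form = "AC", third = "linear")
  fc_q <- forecast_incidence(fit, efs, h_fwd = 5, form = "AC",
                             third = "quadratic")
  # horizontal coincides with none under the boundary-anchored factor
  expect_equal(fc_h$rates, fc_n$rates)
  # linear compounds the boundary slope of theta * q2 per projected step
  q2 <- fit$basis$q2_period
  pP <- max(fit$lexis$periods)
  slope <- fit$theta_period * q2$deriv(pP)
  j <- length(fc_l$periods)   # furthest horizon, 5 steps out
  expect_equal(fc_l$log_rates[, j] - fc_n$log_rates[, j],
               rep(5 * slope, length(fc_l$ages)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # quadratic continues the full curve relative to its boundary value
  pnew <- fc_q$periods[j]
  expect_equal(fc_q$log_rates[, j] - fc_n$log_rates[, j],
               rep(fit$theta_period * (q2$eval(pnew) - q2$eval(pP)),
                   length(fc_q$ages)), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("forecast export writes the long-format CSV", {
  fit <- fit_apc(generate_lexis(small_truth(), seed = 6))
  fc <- forecast_incidence(fit, h_fwd = 2, h_back = 1)
  p <- withr::local_tempfile(fileext = ".csv")
  write_forecast(fc, p)
  df <- read.csv(p)
  expect_equal(nrow(df), length(fc$ages) * length(fc$periods))
  expect_named(df, c("age", "period", "rate", "log_var", "mask", "form",
                     "third"))
  expect_equal(sum(df$mask == "back-cast"), length(fc$ages))
})
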