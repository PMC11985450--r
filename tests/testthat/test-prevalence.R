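pipeline_forecast <- function(truth, seed = 1, h_back = 10, third = "none") {
  fit <- fit_apc(generate_lexis(truth, seed = seed))
  forecast_incidence(fit, h_fwd = 0, h_back = h_back, form = "AC",
                     third = third)
}

test_that("zero hazard reduces prevalence to the diagonal incidence sum", {
  tr <- small_truth()
  fc <- pipeline_forecast(tr, seed = 41)
  t_max <- 10
  prev <- prevalence_rates(fc, constant_hazard(0), t_max = t_max)
  lam <- fc$rates
  A <- length(fc$ages); P <- length(fc$periods)
  manual <- matrix(0, A, P)
  for (a in seq_len(A)) for (j in seq_len(P))
    for (i in 0:min(t_max, a - 1, j - 1))   # same accumulation order: exact
      manual[a, j] <- manual[a, j] + lam[a - i, j - i]
  expect_identical(unname(prev$xi), manual)
  # back-cast horizon = t_max: every cell over the original window complete
  obs <- match(tr$periods, fc$periods)
  expect_true(all(prev$complete_mask[, obs]))
  # early extended columns are flagged incomplete for old ages
  expect_false(prev$complete_mask[A, 1])
})

test_that("a single-term window multiplies incidence by same-period survival", {
  tr <- small_truth(offset = 1e5)
  fc <- pipeline_forecast(tr, seed = 42, h_back = 0)
  rec <- generate_case_listing(tr, seed = 43)
  sv <- tabulate_survivorship(rec, age_starts = seq(40, 55, 5),
                              periods = tr$periods, t_max = 10)
  hz <- fit_hazard(sv)
  prev <- prevalence_rates(fc, hz, t_max = 0)
  A <- length(fc$ages)
  h0 <- matrix(hazard_at(hz, rep(fc$ages, length(fc$periods)),
                         rep(fc$periods, each = A), 0), A)
  expect_equal(prev$xi, fc$rates * (1 - h0), ignore_attr = TRUE)
  expect_true(all(prev$complete_mask))
})

test_that("prevalence grows cell-wise with the survivorship window", {
  tr <- small_truth()
  fc <- pipeline_forecast(tr, seed = 44)
  hz <- constant_hazard(0.1)
  xi_prev <- NULL
  for (tm in c(0, 3, 7, 10)) {
    xi <- prevalence_rates(fc, hz, t_max = tm)$xi
    if (!is.null(xi_prev)) expect_true(all(xi >= xi_prev - 1e-15))
    xi_prev <- xi
  }
})

test_that("window and grid mismatches are rejected", {
  tr <- small_truth(offset = 2e4)
  fc <- pipeline_forecast(tr, seed = 45, h_back = 0)
  rec <- generate_case_listing(tr, seed = 46)
  sv <- tabulate_survivorship(rec, age_starts = seq(40, 55, 5),
                              periods = tr$periods, t_max = 4)
  hz <- fit_hazard(sv)
  expect_error(prevalence_rates(fc, hz, t_max = 10), "exceeds the fitted")
})

test_that("bootstrap replication is seeded and reproducible", {
  tr <- small_truth()
  fc <- pipeline_forecast(tr, seed = 47)
  O <- matrix(1e6, length(fc$ages), length(fc$periods))
  b1 <- bootstrap_covariance(fc, O, constant_hazard(0.1), t_max = 5,
                             B = 50, seed = 9)
  b2 <- bootstrap_covariance(fc, O, constant_hazard(0.1), t_max = 5,
                             B = 50, seed = 9)
  expect_identical(b1$cell_var, b2$cell_var)
  expect_identical(b1$cov, b2$cov)
  b3 <- bootstrap_covariance(fc, O, constant_hazard(0.1), t_max = 5,
                             B = 50, seed = 10)
  expect_false(identical(b1$cell_var, b3$cell_var))
})

test_that("bootstrap variance matches the analytic Poisson rate variance", {
  # single cell, zero hazard, t_max = 0: xi* = lambda*, var = lambda / O
  lam <- matrix(2e-4, 1, 1, dimnames = list(50, 2000))
  O <- matrix(5e5, 1, 1)
  bs <- bootstrap_covariance(lam, O, constant_hazard(0), t_max = 0,
                             B = 2000, seed = 12)
  expect_lt(abs(bs$cell_var[1, 1] / (2e-4 / 5e5) - 1), 0.10)
  # scaling offsets by 100 shrinks the variance about 100-fold
  bs2 <- bootstrap_covariance(lam, O * 100, constant_hazard(0), t_max = 0,
                              B = 2000, seed = 12)
  expect_lt(abs(bs2$cell_var[1, 1] / (bs$cell_var[1, 1] / 100) - 1), 0.15)
})

test_that("bootstrap covariance is consistent with the convolution structure", {
  tr <- small_truth(ages = 40:45, periods = 2001:2006)
  fc <- pipeline_forecast(tr, seed = 48, h_back = 2)
  O <- matrix(1e6, 6, length(fc$periods))
  bs <- bootstrap_covariance(fc, O, constant_hazard(0.2), t_max = 2,
                             B = 1500, seed = 13)
  expect_equal(dim(bs$cov), c(6 * 8, 6 * 8))
  expect_equal(as.vector(diag(bs$cov)), as.vector(bs$cell_var))
  # a cell and its within-diagonal successor share incidence terms:
  # correlation must be clearly positive
  i1 <- 3 + 6 * 4; i2 <- 4 + 6 * 5   # (age 3, period 5) and (age 4, period 6)
  rho <- bs$cov[i1, i2] / sqrt(bs$cov[i1, i1] * bs$cov[i2, i2])
  expect_gt(rho, 0.3)
})

test_that("delta-method variances track the bootstrap on a fitted pipeline", {
  tr <- small_truth(offset = 1e6)
  fit <- fit_apc(generate_lexis(tr, seed = 49))
  fc <- forecast_incidence(fit, h_fwd = 0, h_back = 10, form = "AC")
  rec <- generate_case_listing(tr, seed = 50)
  sv <- tabulate_survivorship(rec, age_starts = seq(40, 55, 5),
                              periods = tr$periods, t_max = 10)
  hz <- fit_hazard(sv)
  dv <- prevalence_delta_var(fc, hz, t_max = 10)
  expect_true(all(dv$inc_var >= 0))
  expect_true(all(dv$surv_var >= 0))
  expect_equal(dv$total, dv$inc_var + dv$surv_var)
  # the incidence part is close to the bootstrap variance (which resamples
  # raw rates: comparable scale, not smaller than the smoothed-fit part)
  O <- matrix(1e6, length(fc$ages), length(fc$periods))
  bs <- bootstrap_covariance(fc, O, hz, t_max = 10, B = 800, seed = 14,
                             full_cov = FALSE)
  obs <- match(tr$periods, fc$periods)
  ratio <- dv$inc_var[, obs] / bs$cell_var[, obs]
  expect_lt(median(ratio), 1.5)
})
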