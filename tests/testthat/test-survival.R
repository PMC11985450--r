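make_surv <- function(truth, seed = 5, t_max = 10) {
  rec <- generate_case_listing(truth, seed = seed)
  w <- truth$surv_age_width / truth$delta
  tabulate_survivorship(rec,
                        age_starts = truth$ages[seq(1, length(truth$ages), w)],
                        periods = truth$periods, t_max = t_max)
}

test_that("constant-hazard data give flat components and the right level", {
  tr <- small_truth(offset = 3e5,
                    hazard = list(log_h0 = log(0.05), t_slope = 0,
                                  a_slope = 0, p_slope = 0))
  hz <- fit_hazard(make_surv(tr, seed = 81))
  expect_lt(abs(hz$nu0 - log(0.05)) /
              sqrt(hz$coef_cov[1, 1]), 3)
  for (comp in c("time", "age", "period")) {
    ts <- hazard_terminal_slope(hz, comp)
    expect_lt(abs(ts["slope"]), 3 * ts["se"] + 1e-12)
  }
})

test_that("a planted period trend in the log hazard is recovered", {
  tr <- small_truth(offset = 8e5)   # ~ 1e5 diagnosed subjects
  hz <- fit_hazard(make_surv(tr, seed = 82))
  ts <- hazard_terminal_slope(hz, "period")
  expect_lt(abs(ts["slope"] - tr$hazard$p_slope), 3 * ts["se"])
})

test_that("scaling all counts leaves the hazard estimates unchanged", {
  tr <- small_truth(offset = 5e4)
  sv <- make_surv(tr, seed = 83)
  sv2 <- sv
  sv2$at_risk <- 2 * sv$at_risk
  sv2$deaths <- 2 * sv$deaths
  f1 <- fit_hazard(sv); f2 <- fit_hazard(sv2)
  expect_equal(f2$coef, f1$coef, tolerance = 1e-8)
})

test_that("hazard_at honours the fitted grid and the extrapolation contract", {
  tr <- small_truth(offset = 2e5)
  sv <- make_surv(tr, seed = 84)
  hz <- fit_hazard(sv)
  # grid reproduction: exp of the fitted linear predictor
  mid <- hz$age_eval_points[2]
  p0 <- hz$axes$p[3]
  lp <- hz$nu0 +
    apcprev:::component_value(hz$t_component, 4) +
    apcprev:::component_value(hz$a_component, mid) +
    apcprev:::component_value(hz$p_component, p0)
  expect_equal(hazard_at(hz, mid, p0, 4), exp(lp), tolerance = 1e-12)
  # beyond the data the log hazard is linear in p with the terminal slope
  pmax_ <- max(hz$axes$p)
  lh <- log(hazard_at(hz, mid, pmax_ + 1:4, 2))
  expect_lt(max(abs(diff(diff(lh)))), 1e-10)
  expect_equal(diff(lh)[1], unname(hazard_terminal_slope(hz, "period")["slope"]),
               tolerance = 1e-6)
  # flattened period tail freezes the hazard beyond the boundary
  hzf <- flatten_tail(hz, component = "period", side = "upper")
  expect_equal(hazard_at(hzf, mid, pmax_ + 7, 2),
               hazard_at(hzf, mid, pmax_, 2), tolerance = 1e-12)
  # t beyond the survivorship window is an error
  expect_error(hazard_at(hz, mid, p0, 11), "survivorship window")
})

test_that("survival curves follow the discrete product form", {
  expect_equal(survival_curve(constant_hazard(0), 50, 2000, 0:5), rep(1, 6))
  expect_equal(survival_curve(constant_hazard(0.1), 50, 2000, 2), 0.9^3)
  # near-certain death at t = 0 leaves the truncation floor
  h1 <- function(a, p, t) rep(1, length(t))
  expect_equal(survival_curve(h1, 50, 2000, 0), 1e-6)
  # monotone non-increasing for a fitted hazard
  tr <- small_truth(offset = 1e5)
  hz <- fit_hazard(make_surv(tr, seed = 85))
  S <- survival_curve(hz, 47, 2008, 0:10)
  expect_true(all(diff(S) <= 0))
  expect_true(all(S > 0 & S <= 1))
  # continuous-time approximation is close for small hazards
  Se <- survival_curve(hz, 47, 2008, 0:10, method = "exp")
  expect_lt(max(abs(Se - S) / S), 0.05)
})

test_that("joinpoint and B-spline hazard fits are concordant on linear truth", {
  tr <- small_truth(offset = 3e7,     # ~1.1M subjects so both methods stabilize
                    hazard = list(log_h0 = -2.5, t_slope = -0.08,
                                  a_slope = 0.02, p_slope = -0.02,
                                  t_kink = list(at = 4, slope_change = 0.05)))
  sv <- make_surv(tr, seed = 86)
  hj <- fit_hazard(sv, "joinpoint")
  hb <- fit_hazard(sv, "bspline")
  aa <- rep(hj$age_eval_points, each = length(hj$axes$p))
  pp <- rep(hj$axes$p, times = length(hj$age_eval_points))
  for (t in c(0, 3, 7)) {
    r <- hazard_at(hj, aa, pp, t) / hazard_at(hb, aa, pp, t)
    expect_lt(max(abs(r - 1)), 0.02)
  }
})

test_that("tabulated empirical hazards are reproduced on saturated grids", {
  tr <- small_truth(offset = 1e6)
  sv <- make_surv(tr, seed = 87)
  hz <- fit_hazard(sv)
  emp <- sv$deaths / pmax(sv$at_risk, 1)
  mid <- hz$age_eval_points
  worst <- 0
  for (gi in seq_along(mid)) for (t in c(0, 5)) {
    pj <- 3   # a well-populated early period
    fitted_h <- hazard_at(hz, mid[gi], sv$periods[pj], t)
    M <- sv$at_risk[gi, pj, t + 1]
    se <- sqrt(fitted_h * (1 - fitted_h) / M)
    worst <- max(worst, abs(fitted_h - emp[gi, pj, t + 1]) / se)
  }
  expect_lt(worst, 4)
})

test_that("degenerate survivorship axes are rejected by name", {
  rec <- data.frame(age_group_start = 50, age_group_width = 5,
                    diag_year = rep(2000:2004, each = 4),
                    exit_time = rep(0:3, 5), died = rep(c(1, 0), 10))
  sv <- tabulate_survivorship(rec, age_starts = 50, periods = 2000:2004,
                              t_max = 3)
  expect_error(fit_hazard(sv), "age")
})
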