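# Synthetic Lexis diagrams, survival case listings, and an individual-level
# microsimulation oracle, all driven by a single truth specification.  The
# generators exist both to exercise the pipeline under known truth and to
# provide the independent oracle for the prevalence convolution: the
# microsimulation walks simulated individuals through the Lexis plane and
# counts survivors directly, with no reference to the convolution formula.

#' Truth specification for the synthetic generators
#'
#' Defines a known incidence surface and survival hazard on a study grid.
#' The incidence log rate is
#' `mu + age_slope * (a - abar) + drift * (c - cbar)` plus optional
#' curvature/deviation generators; the hazard log is
#' `log_h0 + t_slope * t + a_slope * (a - a_min) + p_slope * (p - p_min)`
#' plus optional kinks, capped below 1.  Defaults emulate a large
#' registry-style surveillance setting: single-year bins over ages 30-84 and
#' periods 1992-2019, one million person-years per cell, baseline log rate
#' -9 with age slope 0.04/yr and net drift 0.01/yr, and good survival
#' (hazard about 0.08 in the diagnosis period) improving by 2% per calendar
#' year with an age gradient.
#'
#' @param ages,periods grid labels (equally spaced, common bin width).
#' @param offset person-years per cell (scalar or ages x periods matrix).
#' @param mu grand mean log rate.
#' @param age_slope longitudinal age trend of the log rate, per year.
#' @param drift net drift of the log rate, per year.
#' @param age_quad,period_quad,cohort_quad curvature amplitudes multiplying
#'   the unit-norm orthogonal quadratic of each axis.
#' @param cohort_kink optional `list(at =, slope_change =)`: adds
#'   `slope_change * (c - at)_+` to the log rate (a joinpoint in the cohort
#'   trend).
#' @param age_wiggle amplitude of a high-frequency sinusoid in age (a
#'   higher-order deviation generator).
#' @param hazard list with `log_h0`, `t_slope`, `a_slope`, `p_slope` and
#'   optional `t_kink` / `p_kink` (`list(at =, slope_change =)`).
#' @param surv_age_width width (years) of the survival age groups the case
#'   listing is reported in (default 5, as registries typically provide).
#' @param t_max survivorship window used by the generators.
#' @return object of class `truth_spec`.
#' @export
truth_spec <- function(ages = 30:84, periods = 1992:2019, offset = 1e6,
                       mu = -9, age_slope = 0.04, drift = 0.01,
                       age_quad = 0, period_quad = 0, cohort_quad = 0,
                       cohort_kink = NULL, age_wiggle = 0,
                       hazard = list(log_h0 = -2.5, t_slope = -0.10,
                                     a_slope = 0.02, p_slope = -0.02),
                       surv_age_width = 5, t_max = 10) {
  delta <- axis_step(ages, "age")
  dp <- axis_step(periods, "period")
  if (abs(delta - dp) > 1e-8)
    stop_("truth grid must have equal age and period bin widths")
  cohorts <- seq(periods[1] - ages[length(ages)],
                 periods[length(periods)] - ages[1], by = delta)
  hz <- utils::modifyList(list(log_h0 = -2.5, t_slope = -0.10,
                               a_slope = 0.02, p_slope = -0.02,
                               t_kink = NULL, p_kink = NULL), hazard)
  structure(list(ages = ages, periods = periods, cohorts = cohorts,
                 delta = delta, offset = offset, mu = mu,
                 age_slope = age_slope, drift = drift,
                 age_quad = age_quad, period_quad = period_quad,
                 cohort_quad = cohort_quad, cohort_kink = cohort_kink,
                 age_wiggle = age_wiggle, hazard = hz,
                 surv_age_width = surv_age_width, t_max = t_max,
                 q2 = list(age = ortho_quad(ages),
                           period = ortho_quad(periods),
                           cohort = ortho_quad(cohorts))),
            class = "truth_spec")
}

#' @export
print.truth_spec <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d ages x %d periods, offset %s/cell\n",
              length(x$ages), length(x$periods),
              format(mean(x$offset), big.mark = ",")))
  cat(sprintf("  log rate: mu %.2f, age slope %.3f/yr, net drift %.3f/yr\n",
              x$mu, x$age_slope, x$drift))
  if (!is.null(x$cohort_kink))
    cat(sprintf("  cohort trend kink at %g (slope change %+.3f)\n",
                x$cohort_kink$at, x$cohort_kink$slope_change))
  cat(sprintf("  hazard: h0 %.3f, t slope %+.3f, a slope %+.3f, p slope %+.3f\n",
              exp(x$hazard$log_h0), x$hazard$t_slope, x$hazard$a_slope,
              x$hazard$p_slope))
  invisible(x)
}

#' True log incidence rate of a truth specification
#'
#' Evaluates the generating log rate at arbitrary ages/periods (also beyond
#' the grid: quadratics continue as polynomials, kinks as hinge functions).
#'
#' @param truth a [truth_spec()].
#' @param a,p age and period values (vectorized, recycled).
#' @return numeric vector of log rates.
#' @export
truth_log_rate <- function(truth, a, p) {
  n <- max(length(a), length(p))
  a <- rep_len(a, n); p <- rep_len(p, n)
  cc <- p - a
  abar <- mean(truth$ages)
  cbar <- mean(truth$periods) - abar
  lr <- truth$mu + truth$age_slope * (a - abar) + truth$drift * (cc - cbar)
  if (truth$age_quad != 0) lr <- lr + truth$age_quad * truth$q2$age$eval(a)
  if (truth$period_quad != 0)
    lr <- lr + truth$period_quad * truth$q2$period$eval(p)
  if (truth$cohort_quad != 0)
    lr <- lr + truth$cohort_quad * truth$q2$cohort$eval(cc)
  if (!is.null(truth$cohort_kink))
    lr <- lr + truth$cohort_kink$slope_change * pmax(cc - truth$cohort_kink$at, 0)
  if (truth$age_wiggle != 0)
    lr <- lr + truth$age_wiggle * sin(2 * pi * (a - truth$ages[1]) / 5)
  lr
}

#' True discrete-time hazard of a truth specification
#'
#' @param truth a [truth_spec()].
#' @param a age at diagnosis (vectorized, recycled).
#' @param p period of diagnosis.
#' @param t follow-up time in periods.
#' @return per-period death probabilities, capped at `1 - 1e-6`.
#' @export
truth_hazard <- function(truth, a, p, t) {
  n <- max(length(a), length(p), length(t))
  a <- rep_len(a, n); p <- rep_len(p, n); t <- rep_len(t, n)
  hz <- truth$hazard
  lp <- hz$log_h0 + hz$t_slope * t + hz$a_slope * (a - truth$ages[1]) +
    hz$p_slope * (p - truth$periods[1])
  if (!is.null(hz$t_kink))
    lp <- lp + hz$t_kink$slope_change * pmax(t - hz$t_kink$at, 0)
  if (!is.null(hz$p_kink))
    lp <- lp + hz$p_kink$slope_change * pmax(p - hz$p_kink$at, 0)
  pmin(exp(lp), 1 - 1e-6)
}

offset_matrix <- function(truth, periods = truth$periods) {
  A <- length(truth$ages); P <- length(periods)
  if (length(truth$offset) == 1) return(matrix(truth$offset, A, P))
  o <- as.matrix(truth$offset)
  if (!identical(dim(o), c(A, length(truth$periods))))
    stop_("offset matrix shape does not match the truth grid")
  # extended axes reuse the nearest observed column (constant continuation)
  j <- pmin(pmax(findInterval(periods, truth$periods), 1L),
            length(truth$periods))
  o[, j, drop = FALSE]
}

#' Draw a synthetic Lexis diagram
#'
#' Samples case counts `Y[a, p] ~ Poisson(O * exp(true log rate))` on the
#' truth grid (or on an extended period axis).  Bit-reproducible given the
#' seed.
#'
#' @param truth a [truth_spec()].
#' @param seed integer seed.
#' @param periods optional replacement period axis (e.g. extended for
#'   back-cast validation); default the truth grid.
#' @return a [lexis_diagram()].
#' @export
generate_lexis <- function(truth, seed = 1, periods = NULL) {
  stopifnot(inherits(truth, "truth_spec"))
  periods <- periods %||% truth$periods
  O <- offset_matrix(truth, periods)
  if (any(O <= 0)) stop_("offsets must be strictly positive")
  A <- length(truth$ages); P <- length(periods)
  lr <- matrix(truth_log_rate(truth, rep(truth$ages, P),
                              rep(periods, each = A)), A, P)
  set.seed(seed)
  Y <- matrix(stats::rpois(A * P, O * exp(lr)), A, P)
  lexis_diagram(Y, O, truth$ages[1], periods[1], truth$delta)
}

# Death-time category probabilities for one diagnosis stratum: death at
# t = 0..t_hi, then survival beyond t_hi.
death_time_probs <- function(h) {
  S_prev <- c(1, cumprod(1 - h))
  c(S_prev[-length(S_prev)] * h, S_prev[length(S_prev)])
}

#' Draw a synthetic survival case listing
#'
#' For every diagnosed individual (cell counts from `diagnoses`, aggregated
#' to the survival age groups), draws a discrete survival time by sequential
#' per-period death probabilities from the truth hazard, evaluated at the
#' age-group midpoint.  Follow-up ends at the study-end period: survivors
#' are censored there.  Records are weighted (one row per distinct outcome
#' per stratum).
#'
#' @param truth a [truth_spec()].
#' @param diagnoses a [lexis_diagram()] of diagnosis counts; generated
#'   internally (with `seed + 1`) when omitted.
#' @param seed integer seed.
#' @return data frame of weighted case records with the columns expected by
#'   [tabulate_survivorship()].
#' @export
generate_case_listing <- function(truth, diagnoses = NULL, seed = 1) {
  stopifnot(inherits(truth, "truth_spec"))
  diagnoses <- diagnoses %||% generate_lexis(truth, seed + 1L)
  w <- truth$surv_age_width / truth$delta
  A <- length(truth$ages)
  if (A %% w != 0)
    stop_("surv_age_width (%g) must tile the %d fine age groups",
          truth$surv_age_width, A)
  grp <- rep(seq_len(A %/% w), each = w)
  Yg <- rowsum(diagnoses$cases, grp)           # groups x periods
  starts <- truth$ages[seq(1, A, by = w)]
  mids <- starts + (truth$surv_age_width - 1) / 2
  periods <- diagnoses$periods
  p_end <- max(periods)

  set.seed(seed)
  out <- vector("list", nrow(Yg) * ncol(Yg))
  k <- 0L
  for (gi in seq_len(nrow(Yg))) for (pj in seq_along(periods)) {
    N <- Yg[gi, pj]
    if (N == 0) next
    FF <- round((p_end - periods[pj]) / truth$delta)   # observable follow-up
    h <- truth_hazard(truth, mids[gi], periods[pj], 0:FF)
    cnt <- drop(stats::rmultinom(1, N, death_time_probs(h)))
    nz <- which(cnt > 0)
    k <- k + 1L
    out[[k]] <- data.frame(
      age_group_start = starts[gi],
      age_group_width = truth$surv_age_width,
      diag_year = periods[pj],
      exit_time = ifelse(nz <= FF + 1L, nz - 1L, FF),
      died = as.integer(nz <= FF + 1L),
      weight = cnt[nz])
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Microsimulated prevalence (individual-level oracle)
#'
#' Simulates individuals through the Lexis plane — Poisson diagnoses on an
#' extended period axis starting `t_max` periods before the study window,
#' multinomial death times from the truth hazard at each individual's own
#' age and period of diagnosis — and counts, per observed cell, the people
#' diagnosed within the last `t_max + 1` periods still alive at period end.
#' This is a direct head count with no use of the convolution formula, so it
#' serves as an independent oracle for [prevalence_rates()].
#'
#' @param truth a [truth_spec()].
#' @param t_max survivorship window (default `truth$t_max`).
#' @param seed integer seed.
#' @return list with `xi` (ages x periods matrix of simulated prevalence
#'   rates over the truth grid), `counts` (survivor counts), and `offsets`.
#' @export
microsim_prevalence <- function(truth, t_max = truth$t_max, seed = 1) {
  stopifnot(inherits(truth, "truth_spec"))
  check_number(t_max, "t_max", min = 0, integer = TRUE)
  d <- truth$delta
  periods_ext <- seq(truth$periods[1] - t_max * d, max(truth$periods), by = d)
  A <- length(truth$ages); Pe <- length(periods_ext)
  P <- length(truth$periods)
  O_ext <- offset_matrix(truth, periods_ext)
  lr <- matrix(truth_log_rate(truth, rep(truth$ages, Pe),
                              rep(periods_ext, each = A)), A, Pe)
  set.seed(seed)
  Y <- matrix(stats::rpois(A * Pe, O_ext * exp(lr)), A, Pe)

  Scount <- matrix(0, A, Pe)
  for (ai in seq_len(A)) for (pj in seq_len(Pe)) {
    N <- Y[ai, pj]
    if (N == 0) next
    h <- truth_hazard(truth, truth$ages[ai], periods_ext[pj], 0:t_max)
    cnt <- drop(stats::rmultinom(1, N, death_time_probs(h)))
    dead_by <- cumsum(cnt[seq_len(t_max + 1L)])
    imax <- min(t_max, A - ai, Pe - pj)
    for (i in 0:imax) {
      alive <- N - dead_by[i + 1L]
      Scount[ai + i, pj + i] <- Scount[ai + i, pj + i] + alive
    }
  }
  obs <- (Pe - P + 1L):Pe
  O_obs <- offset_matrix(truth)
  xi <- Scount[, obs, drop = FALSE] / O_obs
  dimnames(xi) <- list(age = truth$ages, period = truth$periods)
  list(xi = xi, counts = Scount[, obs, drop = FALSE], offsets = O_obs)
}
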