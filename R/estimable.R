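# Estimable functions of the APC fit and linear-operator summaries.

# Linear functionals of the coefficient vector ---------------------------------
#
# Every estimable quantity used downstream (age curves, rate-ratio curves,
# fitted log rates, third-variable curvature factors) is a linear functional
# L'beta of the fitted coefficients, so log-scale variances follow from
# L %*% param_cov %*% t(L).  These builders return one row per evaluation
# point.

# log LongAge(a | c0): mu + (aL+pL)(a - abar) + age_dev_a  +  drift*(c0-cbar)
# + cohort_dev_c0 (the c0 anchor absorbed so that CRR(c0|c0) = 1).
L_long_age <- function(fit, a_idx, c0_idx) {
  n <- length(fit$coefficients)
  L <- matrix(0, length(a_idx), n)
  L[, fit$index$mu] <- 1
  L[, fit$index$atrend] <- fit$lexis$ages[a_idx] - fit$centers["age"]
  L[, fit$index$drift] <- fit$lexis$cohorts[c0_idx] - fit$centers["cohort"]
  L[, fit$index$age] <- fit$basis$age[a_idx, , drop = FALSE]
  L[, fit$index$cohort] <- matrix(fit$basis$cohort[c0_idx, ],
                                  length(a_idx), ncol(fit$basis$cohort),
                                  byrow = TRUE)
  L
}

# log CrossAge(a | p0): mu + (aL-gL)(a - abar) + age_dev_a + drift*(p0-pbar)
# + period_dev_p0, using (aL-gL) = long_age_trend - net_drift.
L_cross_age <- function(fit, a_idx, p0_idx) {
  n <- length(fit$coefficients)
  L <- matrix(0, length(a_idx), n)
  da <- fit$lexis$ages[a_idx] - fit$centers["age"]
  L[, fit$index$mu] <- 1
  L[, fit$index$atrend] <- da
  L[, fit$index$drift] <- fit$lexis$periods[p0_idx] - fit$centers["period"] - da
  L[, fit$index$age] <- fit$basis$age[a_idx, , drop = FALSE]
  L[, fit$index$period] <- matrix(fit$basis$period[p0_idx, ],
                                  length(a_idx), ncol(fit$basis$period),
                                  byrow = TRUE)
  L
}

# log CRR(c | c0): drift*(c - c0) + cohort_dev_c - cohort_dev_c0
L_crr <- function(fit, c_idx, c0_idx) {
  n <- length(fit$coefficients)
  L <- matrix(0, length(c_idx), n)
  L[, fit$index$drift] <- fit$lexis$cohorts[c_idx] - fit$lexis$cohorts[c0_idx]
  L[, fit$index$cohort] <-
    fit$basis$cohort[c_idx, , drop = FALSE] -
    matrix(fit$basis$cohort[c0_idx, ], length(c_idx),
           ncol(fit$basis$cohort), byrow = TRUE)
  L
}

# log PRR(p | p0): drift*(p - p0) + period_dev_p - period_dev_p0
L_prr <- function(fit, p_idx, p0_idx) {
  n <- length(fit$coefficients)
  L <- matrix(0, length(p_idx), n)
  L[, fit$index$drift] <- fit$lexis$periods[p_idx] - fit$lexis$periods[p0_idx]
  L[, fit$index$period] <-
    fit$basis$period[p_idx, , drop = FALSE] -
    matrix(fit$basis$period[p0_idx, ], length(p_idx),
           ncol(fit$basis$period), byrow = TRUE)
  L
}

# Unanchored log rate-ratio functionals, used only for joinpoint weights:
# variance of drift*(c - cbar) + cohort_dev_c, positive for all cohorts.
L_crr_unanchored <- function(fit, c_idx) {
  n <- length(fit$coefficients)
  L <- matrix(0, length(c_idx), n)
  L[, fit$index$drift] <- fit$lexis$cohorts[c_idx] - fit$centers["cohort"]
  L[, fit$index$cohort] <- fit$basis$cohort[c_idx, , drop = FALSE]
  L
}

L_prr_unanchored <- function(fit, p_idx) {
  n <- length(fit$coefficients)
  L <- matrix(0, length(p_idx), n)
  L[, fit$index$drift] <- fit$lexis$periods[p_idx] - fit$centers["period"]
  L[, fit$index$period] <- fit$basis$period[p_idx, , drop = FALSE]
  L
}

lfun_var <- function(L, Sigma) rowSums((L %*% Sigma) * L)

# theta extractors as linear functionals: theta_x = q2' B %*% beta_x
theta_functional <- function(fit, which = c("period", "cohort")) {
  which <- match.arg(which)
  n <- length(fit$coefficients)
  v <- numeric(n)
  if (which == "period")
    v[fit$index$period] <- drop(crossprod(fit$basis$q2_period$values,
                                          fit$basis$period))
  else
    v[fit$index$cohort] <- drop(crossprod(fit$basis$q2_cohort$values,
                                          fit$basis$cohort))
  v
}

# Default references: cohort nearest the cohort center with maximal support,
# period nearest the period center.
default_references <- function(fit) {
  A <- length(fit$lexis$ages); P <- length(fit$lexis$periods)
  support <- vapply(seq_along(fit$lexis$cohorts), function(ci)
    sum(fit$cell_cohort == ci), integer(1))
  full <- which(support == max(support))
  c0_idx <- full[which.min(abs(fit$lexis$cohorts[full] - fit$centers["cohort"]))]
  p0_idx <- which.min(abs(fit$lexis$periods - fit$centers["period"]))
  list(c0_idx = c0_idx, p0_idx = p0_idx)
}

#' Estimable functions of an APC fit
#'
#' Computes the four estimable-function curves of the fitted APC model: the
#' longitudinal age curve `LongAge(a | c0)` (fitted rates over age following
#' the reference cohort `c0`), the cross-sectional age curve
#' `CrossAge(a | p0)` (over age within the reference period `p0`), and the
#' cohort and period rate-ratio curves `CRR(c | c0)` and `PRR(p | p0)`,
#' normalized so that `CRR(c0 | c0) = PRR(p0 | p0) = 1` exactly.  Pointwise
#' log-scale variances come from the delta method on the parameter
#' covariance.
#'
#' @param fit an [fit_apc()] object.
#' @param c0 reference cohort label; default: the cohort with full support
#'   nearest the cohort center.
#' @param p0 reference period label; default: the period nearest the period
#'   center.
#' @return object of class `apc_efs`: data frames `long_age`, `cross_age`,
#'   `crr`, `prr` (each with the index, `estimate`, `log_var`), references
#'   `c0`, `p0`, and joinpoint weighting variances for the rate-ratio curves.
#' @export
estimable_functions <- function(fit, c0 = NULL, p0 = NULL) {
  stopifnot(inherits(fit, "apc_fit"))
  refs <- default_references(fit)
  cohorts <- fit$lexis$cohorts; periods <- fit$lexis$periods
  if (is.null(c0)) c0_idx <- refs$c0_idx
  else {
    c0_idx <- match(c0, cohorts)
    if (is.na(c0_idx))
      stop_("c0 = %s is not a represented cohort; valid labels: %s",
            format(c0), fmt_vec(cohorts))
  }
  if (is.null(p0)) p0_idx <- refs$p0_idx
  else {
    p0_idx <- match(p0, periods)
    if (is.na(p0_idx))
      stop_("p0 = %s is not an observed period; valid labels: %s",
            format(p0), fmt_vec(periods))
  }
  S <- fit$param_cov
  beta <- fit$coefficients
  a_idx <- seq_along(fit$lexis$ages)
  c_idx <- seq_along(cohorts)
  p_idx <- seq_along(periods)

  mk <- function(L, labels, col) {
    est <- exp(drop(L %*% beta))
    df <- data.frame(labels, estimate = est, log_var = lfun_var(L, S))
    names(df)[1] <- col
    df
  }
  long_age <- mk(L_long_age(fit, a_idx, c0_idx), fit$lexis$ages, "age")
  cross_age <- mk(L_cross_age(fit, a_idx, p0_idx), fit$lexis$ages, "age")
  crr <- mk(L_crr(fit, c_idx, c0_idx), cohorts, "cohort")
  prr <- mk(L_prr(fit, p_idx, p0_idx), periods, "period")
  crr$w_var <- lfun_var(L_crr_unanchored(fit, c_idx), S)
  prr$w_var <- lfun_var(L_prr_unanchored(fit, p_idx), S)

  structure(list(long_age = long_age, cross_age = cross_age,
                 crr = crr, prr = prr,
                 c0 = cohorts[c0_idx], p0 = periods[p0_idx],
                 c0_idx = c0_idx, p0_idx = p0_idx),
            class = "apc_efs")
}

#' @export
print.apc_efs <- function(x, ...) {
  cat(sprintf("APC estimable functions (reference cohort %g, period %g)\n",
              x$c0, x$p0))
  cat(sprintf("  LongAge spans %.3g-%.3g; CrossAge %.3g-%.3g\n",
              min(x$long_age$estimate), max(x$long_age$estimate),
              min(x$cross_age$estimate), max(x$cross_age$estimate)))
  cat(sprintf("  CRR spans %.3f-%.3f over %d cohorts; PRR %.3f-%.3f over %d periods\n",
              min(x$crr$estimate), max(x$crr$estimate), nrow(x$crr),
              min(x$prr$estimate), max(x$prr$estimate), nrow(x$prr)))
  invisible(x)
}

#' Fitted log rates assembled from either decomposition
#'
#' Assembles the fitted log-rate surface from the age-cohort decomposition
#' (`LongAge x CRR x` period-curvature factor) or the age-period
#' decomposition (`CrossAge x PRR x` cohort-curvature factor).  The two
#' assemblies are algebraically identical; comparing them is a useful
#' internal-consistency check.
#'
#' @param fit an [fit_apc()] object.
#' @param form `"age_cohort"` or `"age_period"`.
#' @param cov if `TRUE`, also return the full delta-method covariance of the
#'   cell log rates (an `AP x AP` matrix; can be large).
#' @return list with `log_rates` (ages x periods matrix) and, if requested,
#'   `cov` (covariance of `as.vector(log_rates)`).
#' @export
fitted_log_rates <- function(fit, form = c("age_cohort", "age_period"),
                             cov = FALSE) {
  stopifnot(inherits(fit, "apc_fit"))
  form <- match.arg(form)
  refs <- default_references(fit)
  A <- length(fit$lexis$ages); P <- length(fit$lexis$periods)
  beta <- fit$coefficients
  ai <- fit$cell_age; pi <- fit$cell_period; ci <- fit$cell_cohort

  if (form == "age_cohort") {
    la <- drop(L_long_age(fit, seq_len(A), refs$c0_idx) %*% beta)
    rr <- drop(L_crr(fit, seq_along(fit$lexis$cohorts), refs$c0_idx) %*% beta)
    third <- fit$period_dev
    lr <- la[ai] + rr[ci] + third[pi]
  } else {
    ca <- drop(L_cross_age(fit, seq_len(A), refs$p0_idx) %*% beta)
    rr <- drop(L_prr(fit, seq_len(P), refs$p0_idx) %*% beta)
    third <- fit$cohort_dev
    lr <- ca[ai] + rr[pi] + third[ci]
  }
  out <- list(log_rates = matrix(lr, A, P, dimnames = dimnames(fit$lexis$cases)))
  if (cov)
    out$cov <- fit$design %*% fit$param_cov %*% t(fit$design)
  out
}

#' Aggregate rates over age groups with a linear operator
#'
#' Summarizes an age-by-period rate matrix into grouped series using
#' offset-weighted means within each age group, propagating the covariance of
#' the member cells through the weight vector (`w' Sigma w` per period).
#'
#' @param rates ages x periods matrix of rates.
#' @param cov covariance of `as.vector(rates)` (AP x AP), or a matrix of
#'   per-cell variances of the same shape as `rates` (treated as diagonal),
#'   or `NULL` (variances reported as `NA`).
#' @param groups named list of age-index vectors (indices into the rows of
#'   `rates`); groups must be non-empty and within range.
#' @param offsets person-years matrix of the same shape, used as weights.
#' @return data frame with columns `group`, `period` (column index or label),
#'   `rate`, `var`.
#' @export
aggregate_rates <- function(rates, cov = NULL, groups, offsets) {
  rates <- as.matrix(rates); offsets <- as.matrix(offsets)
  stopifnot(identical(dim(rates), dim(offsets)))
  A <- nrow(rates); P <- ncol(rates)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  diag_cov <- !is.null(cov) && identical(dim(cov), dim(rates))
  out <- list()
  for (g in names(groups)) {
    rows <- groups[[g]]
    if (length(rows) == 0L) stop_("group '%s' is empty", g)
    if (any(rows < 1 | rows > A)) stop_("group '%s' has out-of-range ages", g)
    rate <- numeric(P); v <- rep(NA_real_, P)
    for (j in seq_len(P)) {
      w <- offsets[rows, j] / sum(offsets[rows, j])
      rate[j] <- sum(w * rates[rows, j])
      if (diag_cov) {
        v[j] <- sum(w^2 * cov[rows, j])
      } else if (!is.null(cov)) {
        cells <- rows + (j - 1L) * A
        v[j] <- drop(t(w) %*% cov[cells, cells, drop = FALSE] %*% w)
      }
    }
    out[[g]] <- data.frame(group = g,
                           period = colnames(rates) %||% seq_len(P),
                           rate = rate, var = v)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
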