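# Forward and backward incidence-rate projection from an APC fit.
#
# Under the age-cohort (AC) form a projected cell is
#   LongAge(a | c0) x CRR-term(c) x period-curvature factor,
# where the CRR term is the fitted cohort rate ratio for partially observed
# cohorts and a joinpoint extrapolation of log CRR for unobserved cohorts.
# The age-period (AP) form uses CrossAge(a | p0) x extrapolated PRR x
# cohort-curvature factor, with partially observed cohorts keeping their
# fitted deviations.  The third-variable curvature factor is anchored at 1 at
# the last observed period/cohort and continues the orthogonal quadratic
# theta * q2 by its boundary slope ("linear"), by the full quadratic
# ("quadratic"), or not at all ("none"; "horizontal" freezes the anchored
# factor at its boundary value 1 and therefore coincides with "none").
# Back-casting mirrors every rule toward earlier periods using the first
# joinpoint segment and the curvature slope at the first period/cohort.

third_options <- c("none", "linear", "horizontal", "quadratic")

# Curvature-factor coefficient multiplying the theta functional.
third_coeff <- function(third, q2, x, anchor) {
  switch(third,
         none = 0,
         horizontal = 0,
         linear = q2$deriv(anchor) * (x - anchor),
         quadratic = q2$eval(x) - q2$eval(anchor))
}

# Joinpoint fit to a log rate-ratio curve with inverse-variance weights.
fit_rr_trend <- function(index, estimate, w_var, max_knots, min_seg) {
  w <- 1 / pmax(w_var, max(w_var) * 1e-8, 1e-12)
  fit_piecewise_linear(index, log(estimate), w,
                       max_knots = max_knots, min_seg = min_seg)
}

#' Project incidence rates forward and backward in time
#'
#' Extends the fitted APC rate surface over `h_fwd` future and `h_back` past
#' periods under one of the two decomposition forms, with a configurable
#' treatment of the third variable's quadratic curvature.  Over observed
#' periods the projection reproduces the fitted rates exactly.  Log-scale
#' variances combine the APC delta-method variance with the joinpoint
#' extrapolation variance, treating the two stages as independent.
#'
#' @param fit an [fit_apc()] object.
#' @param efs optional [estimable_functions()] result (computed with default
#'   references when omitted).
#' @param h_fwd,h_back number of projected periods forward / backward.
#' @param form `"AC"` (age-cohort, default) or `"AP"` (age-period).
#' @param third third-variable curvature treatment: `"none"` (default),
#'   `"linear"`, `"horizontal"` (equals `"none"` under the boundary-anchored
#'   factor), or `"quadratic"`.
#' @param rr_extrap `"linear"` (default) joinpoint continuation of the
#'   rate-ratio trend, or `"horizontal"` (flattened tails).
#' @param crr_trend,prr_trend optional [fit_piecewise_linear()] objects for
#'   the log CRR / log PRR curves, e.g. tail-modified by [scale_slope()] for
#'   counterfactuals; fitted internally with inverse-variance weights when
#'   omitted.
#' @param max_knots,min_seg joinpoint search configuration for internally
#'   fitted rate-ratio trends.
#' @return object of class `rate_forecast`: `rates` and `log_var` matrices on
#'   the extended age x period grid, a `mask` matrix with per-cell provenance
#'   (`observed-fitted`, `forecast-partial-cohort`,
#'   `forecast-extrapolated-cohort`, `forecast-period`, `back-cast`), axis
#'   metadata, and a `provenance` list recording the options and trends used.
#' @seealso [enumerate_model_set()], [average_models()], [prevalence_rates()]
#' @export
forecast_incidence <- function(fit, efs = NULL, h_fwd = 10, h_back = 0,
                               form = c("AC", "AP"),
                               third = third_options,
                               rr_extrap = c("linear", "horizontal"),
                               crr_trend = NULL, prr_trend = NULL,
                               max_knots = 3, min_seg = 3) {
  stopifnot(inherits(fit, "apc_fit"))
  form <- match.arg(form)
  third <- match.arg(third)
  rr_extrap <- match.arg(rr_extrap)
  check_number(h_fwd, "h_fwd", min = 0, integer = TRUE)
  check_number(h_back, "h_back", min = 0, integer = TRUE)
  efs <- efs %||% estimable_functions(fit)

  lx <- fit$lexis
  ages <- lx$ages; periods <- lx$periods; cohorts <- lx$cohorts
  A <- length(ages); P <- length(periods); d <- lx$delta
  p1 <- periods[1]; pP <- periods[P]
  c_min <- cohorts[1]; c_max <- cohorts[length(cohorts)]
  periods_ext <- seq(p1 - h_back * d, pP + h_fwd * d, by = d)
  Pe <- length(periods_ext)
  npar <- length(fit$coefficients)
  beta <- fit$coefficients
  Sig <- fit$param_cov

  if (form == "AC") {
    trend <- crr_trend %||% fit_rr_trend(cohorts, efs$crr$estimate,
                                         efs$crr$w_var, max_knots, min_seg)
  } else {
    trend <- prr_trend %||% fit_rr_trend(periods, efs$prr$estimate,
                                         efs$prr$w_var, max_knots, min_seg)
  }
  if (rr_extrap == "horizontal") trend <- flatten_tail(trend, side = "both")

  q2p <- fit$basis$q2_period; q2c <- fit$basis$q2_cohort
  v_theta_p <- theta_functional(fit, "period")
  v_theta_c <- theta_functional(fit, "cohort")

  Lmat <- matrix(0, A * Pe, npar)
  ptr <- length(trend$coef)
  Jmat <- matrix(0, A * Pe, ptr)     # functional rows on the joinpoint coefs
  mask <- matrix("", A, Pe)

  c0i <- efs$c0_idx; p0i <- efs$p0_idx
  base_long <- L_long_age(fit, seq_len(A), c0i)     # A x npar
  base_cross <- L_cross_age(fit, seq_len(A), p0i)

  for (j in seq_len(Pe)) {
    p <- periods_ext[j]
    rows <- (j - 1L) * A + seq_len(A)
    observed <- p >= p1 - 1e-9 & p <= pP + 1e-9
    if (observed) {
      pj <- which.min(abs(periods - p))
      cells <- (pj - 1L) * A + seq_len(A)
      Lmat[rows, ] <- fit$design[cells, , drop = FALSE]
      mask[, j] <- "observed-fitted"
      next
    }
    backward <- p < p1
    cc <- p - ages                                   # cohort labels this column
    on_grid <- cc >= c_min - 1e-9 & cc <= c_max + 1e-9

    if (form == "AC") {
      L <- base_long
      ci <- round((cc - c_min) / d) + 1L
      # observed cohorts: fitted CRR relative to c0
      if (any(on_grid))
        L[on_grid, ] <- L[on_grid, ] +
          L_crr(fit, ci[on_grid], c0i)
      # unobserved cohorts: joinpoint-extrapolated log CRR
      if (any(!on_grid))
        Jmat[rows[!on_grid], ] <- trend_functional(trend, cc[!on_grid])
      anchor <- if (backward) p1 else pP
      tc <- third_coeff(third, q2p, p, anchor)
      if (tc != 0) L <- L + tc * rep(1, A) %o% v_theta_p
      Lmat[rows, ] <- L
      mask[, j] <- if (backward) "back-cast"
        else ifelse(on_grid, "forecast-partial-cohort",
                    "forecast-extrapolated-cohort")
    } else {
      L <- base_cross
      Jmat[rows, ] <- rep(1, A) %o% drop(trend_functional(trend, p))
      ci <- round((cc - c_min) / d) + 1L
      if (any(on_grid))                              # fitted cohort deviations
        L[on_grid, fit$index$cohort] <- L[on_grid, fit$index$cohort] +
          fit$basis$cohort[ci[on_grid], , drop = FALSE]
      if (any(!on_grid)) {
        anchor <- if (backward) c_min else c_max
        tcs <- vapply(cc[!on_grid], function(cx)
          third_coeff(third, q2c, cx, anchor), numeric(1))
        L[!on_grid, ] <- L[!on_grid, ] + tcs %o% v_theta_c
      }
      Lmat[rows, ] <- L
      mask[, j] <- if (backward) "back-cast" else "forecast-period"
    }
  }

  jp_val <- drop(Jmat %*% trend$coef)
  jp_var <- lfun_var(Jmat, trend$coef_cov)
  log_rates <- matrix(drop(Lmat %*% beta) + jp_val, A, Pe)
  log_var <- matrix(lfun_var(Lmat, Sig) + jp_var, A, Pe)
  dimnames(log_rates) <- dimnames(log_var) <- dimnames(mask) <-
    list(age = ages, period = periods_ext)

  structure(list(rates = exp(log_rates), log_rates = log_rates,
                 log_var = log_var, mask = mask,
                 ages = ages, periods = periods_ext, delta = d,
                 observed_periods = periods,
                 lfun = list(L = Lmat, J = Jmat, param_cov = Sig,
                             trend_cov = trend$coef_cov),
                 provenance = list(form = form, third = third,
                                   rr_extrap = rr_extrap,
                                   c0 = efs$c0, p0 = efs$p0,
                                   trend_knots = trend$interior,
                                   tail_scale = trend$tail_scale),
                 trend = trend),
            class = "rate_forecast")
}

#' @export
print.rate_forecast <- function(x, ...) {
  tab <- table(factor(x$mask))
  cat(sprintf("Incidence rate forecast (%s form, third-variable '%s', RR extrapolation '%s')\n",
              x$provenance$form, x$provenance$third, x$provenance$rr_extrap))
  cat(sprintf("  grid: %d ages x %d periods (%g-%g)\n", length(x$ages),
              length(x$periods), min(x$periods), max(x$periods)))
  cat("  cell provenance:", paste(sprintf("%s=%d", names(tab), tab),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate the taxonomy of incidence forecasting models
#'
#' `which = "four_basic"` returns the four basic models: the two
#' decomposition forms crossed with including or omitting the linear
#' third-variable curvature trend.  `which = "twelve_full"` returns the
#' twelve distinct models formed by crossing form, rate-ratio extrapolation
#' (`linear` vs `horizontal`) and third-variable treatment (`quadratic`,
#' `linear`, `none`); because the curvature factor is anchored at 1 at the
#' boundary, a horizontal deviation extension coincides with `none`, which is
#' what reduces the 16 nominal combinations to 12 distinct models.  Each
#' forecast's provenance carries a `group` label recording whether trends are
#' extrapolated for both period and cohort, for only one, or for neither.
#'
#' @param fit an [fit_apc()] object.
#' @param efs optional [estimable_functions()].
#' @param h_fwd,h_back forecast horizons (periods).
#' @param which `"four_basic"` or `"twelve_full"`.
#' @param ... further arguments passed to [forecast_incidence()].
#' @return named list of `rate_forecast` objects.
#' @export
enumerate_model_set <- function(fit, efs = NULL, h_fwd = 10, h_back = 0,
                                which = c("four_basic", "twelve_full"), ...) {
  which <- match.arg(which)
  efs <- efs %||% estimable_functions(fit)
  specs <- if (which == "four_basic") {
    expand.grid(form = c("AC", "AP"), third = c("linear", "none"),
                rr_extrap = "linear", stringsAsFactors = FALSE)
  } else {
    expand.grid(form = c("AC", "AP"), rr_extrap = c("linear", "horizontal"),
                third = c("quadratic", "linear", "none"),
                stringsAsFactors = FALSE)
  }
  out <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    fc <- forecast_incidence(fit, efs, h_fwd = h_fwd, h_back = h_back,
                             form = s$form, third = s$third,
                             rr_extrap = s$rr_extrap, ...)
    rr_trended <- s$rr_extrap == "linear"
    dev_trended <- s$third != "none"
    cohort_trended <- if (s$form == "AC") rr_trended else dev_trended
    period_trended <- if (s$form == "AC") dev_trended else rr_trended
    fc$provenance$group <-
      if (cohort_trended && period_trended) "both"
      else if (period_trended) "period-only"
      else if (cohort_trended) "cohort-only"
      else "neither"
    fc$provenance$tag <- sprintf("%s_rr-%s_dev-%s", s$form, s$rr_extrap, s$third)
    out[[i]] <- fc
  }
  names(out) <- vapply(out, function(f) f$provenance$tag, character(1))
  out
}

#' Average a set of rate forecasts
#'
#' Combines forecasts cell-wise by the arithmetic mean of the rates.
#' Uncertainty is summarized either as the mean of the member variances
#' (`ci_mode = "mean_var"`) or as the union span of the member 95%
#' confidence intervals (`ci_mode = "span"`).
#'
#' @param forecasts list of `rate_forecast` objects on identical grids with
#'   identical masks.
#' @param ci_mode `"mean_var"` (default) or `"span"`.
#' @param level confidence level for the span mode (default 0.95).
#' @return a `rate_forecast` with averaged rates; in span mode the result
#'   additionally carries `ci_lower` / `ci_upper` matrices.
#' @export
average_models <- function(forecasts, ci_mode = c("mean_var", "span"),
                           level = 0.95) {
  ci_mode <- match.arg(ci_mode)
  stopifnot(length(forecasts) >= 1L)
  f1 <- forecasts[[1]]
  # Provenance masks may legitimately differ between the AC and AP forms in
  # the forecast region; require agreement on the coarse partition only.
  coarse <- function(m) ifelse(startsWith(m, "forecast"), "forecast", m)
  for (f in forecasts[-1]) {
    if (!isTRUE(all.equal(f$ages, f1$ages)) ||
        !isTRUE(all.equal(f$periods, f1$periods)))
      stop_("forecasts are on different grids and cannot be averaged")
    if (!identical(coarse(f$mask), coarse(f1$mask)))
      stop_("forecasts have different observed/back-cast/forecast partitions")
  }
  k <- length(forecasts)
  rates <- Reduce(`+`, lapply(forecasts, `[[`, "rates")) / k
  log_var <- Reduce(`+`, lapply(forecasts, `[[`, "log_var")) / k
  out <- f1
  out$rates <- rates
  out$log_rates <- log(rates)
  out$log_var <- log_var
  out$mask <- matrix(coarse(f1$mask), nrow(f1$mask), ncol(f1$mask),
                     dimnames = dimnames(f1$mask))
  out$provenance <- list(form = "average", third = "average",
                         rr_extrap = "average", ci_mode = ci_mode,
                         members = lapply(forecasts, function(f)
                           f$provenance$tag %||%
                             paste(f$provenance$form, f$provenance$third,
                                   sep = "_")))
  if (ci_mode == "span") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    lowers <- lapply(forecasts, function(f)
      exp(f$log_rates - z * sqrt(f$log_var)))
    uppers <- lapply(forecasts, function(f)
      exp(f$log_rates + z * sqrt(f$log_var)))
    out$ci_lower <- Reduce(pmin, lowers)
    out$ci_upper <- Reduce(pmax, uppers)
  }
  out
}

#' Export a rate forecast as long-format CSV
#'
#' Columns `age`, `period`, `rate`, `log_var`, `mask`, `form`, `third`.
#'
#' @param fc a `rate_forecast`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_forecast <- function(fc, path) {
  stopifnot(inherits(fc, "rate_forecast"))
  g <- expand.grid(age = fc$ages, period = fc$periods)
  g$rate <- as.vector(fc$rates)
  g$log_var <- as.vector(fc$log_var)
  g$mask <- as.vector(fc$mask)
  g$form <- fc$provenance$form
  g$third <- fc$provenance$third
  utils::write.csv(g, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
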