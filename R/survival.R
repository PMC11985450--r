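# Additive discrete-time log-hazard model in time since diagnosis, age at
# diagnosis, and period of diagnosis:
#   ln(E[D_{a,p,t}] / M_{a,p,t}) = nu + f_T(t) + f_A(a) + f_P(p),
# fitted as a Poisson GLM for deaths with offset log M (the standard
# discrete-hazard approximation for small per-period hazards).  Each
# component is a piecewise-linear spline with joinpoint-selected knots or an
# anchored B-spline; components are zero at their axis minimum so the
# intercept is the log hazard at the grid origin.  The period component (and
# the others) extrapolates linearly in both directions on the linear
# predictor scale, which is what lets survival trends be projected into past
# and future diagnosis years.

# -- hazard components --------------------------------------------------------

new_hazard_component <- function(type, coef, coef_cov, x_range,
                                 interior = numeric(0), knots = NULL,
                                 ord = NULL) {
  structure(list(type = type, coef = coef, coef_cov = coef_cov,
                 x_range = x_range, interior = interior, knots = knots,
                 ord = ord, tail_scale = c(lower = 1, upper = 1)),
            class = "hazard_component")
}

# Rows mapping component coefficients to component values at x (component is
# 0 at the axis minimum; linear continuation scaled by tail_scale outside).
component_functional <- function(comp, x) {
  lo <- comp$x_range[1]; hi <- comp$x_range[2]
  if (comp$type == "pwl") {
    kn <- c(lo, comp$interior)
    p <- length(kn)
    L <- matrix(0, length(x), p)
    for (i in seq_along(x)) {
      xi <- x[i]
      if (xi >= lo && xi <= hi) L[i, ] <- pmax(xi - kn, 0)
      else if (xi > hi)
        L[i, ] <- pmax(hi - kn, 0) + comp$tail_scale["upper"] * (xi - hi)
      else
        L[i, 1] <- comp$tail_scale["lower"] * (xi - lo)
    }
    L
  } else {
    bmin <- drop(splines::splineDesign(comp$knots, lo, ord = comp$ord))
    anch <- function(xx)
      splines::splineDesign(comp$knots, xx, ord = comp$ord) -
        rep(1, length(xx)) %o% bmin
    L <- matrix(0, length(x), length(bmin))
    inside <- x >= lo & x <= hi
    if (any(inside)) L[inside, ] <- anch(x[inside])
    if (any(x > hi)) {
      d_hi <- drop(splines::splineDesign(comp$knots, hi, ord = comp$ord,
                                         derivs = 1L))
      b_hi <- drop(anch(hi))
      L[x > hi, ] <- rep(1, sum(x > hi)) %o% b_hi +
        comp$tail_scale["upper"] * (x[x > hi] - hi) %o% d_hi
    }
    if (any(x < lo)) {
      d_lo <- drop(splines::splineDesign(comp$knots, lo, ord = comp$ord,
                                         derivs = 1L))
      L[x < lo, ] <- comp$tail_scale["lower"] * (x[x < lo] - lo) %o% d_lo
    }
    L[, -1, drop = FALSE]   # drop redundant first column (anchored basis)
  }
}

component_value <- function(comp, x) {
  if (!length(comp$coef)) return(numeric(length(x)))
  drop(component_functional(comp, x) %*% comp$coef)
}

#' @rdname flatten_tail
#' @export
scale_slope.hazard_component <- function(fit, factor,
                                         side = c("upper", "lower", "both"),
                                         ...) {
  side <- match.arg(side)
  sides <- if (side == "both") c("lower", "upper") else side
  fit$tail_scale[sides] <- fit$tail_scale[sides] * factor
  fit
}

#' @rdname flatten_tail
#' @param component for `hazard_fit` objects: which component's tail to
#'   modify, `"period"`, `"age"` or `"time"`.
#' @export
scale_slope.hazard_fit <- function(fit, factor, component = "period",
                                   side = c("upper", "lower", "both"), ...) {
  slot <- switch(match.arg(component, c("period", "age", "time")),
                 period = "p_component", age = "a_component",
                 time = "t_component")
  fit[[slot]] <- scale_slope(fit[[slot]], factor, side = match.arg(side))
  fit
}

# -- fitting ------------------------------------------------------------------

# Exhaustive BIC search for interior knots of one pwl component, others held
# fixed.  Returns the chosen interior knot values.
select_component_knots <- function(build_design, y, offs, values, max_knots,
                                   min_seg) {
  cand_all <- values[-c(1, length(values))]
  if (max_knots == 0 || length(cand_all) == 0) return(numeric(0))
  idx_all <- seq_along(cand_all)
  best <- numeric(0); best_bic <- Inf
  n <- length(y)
  for (k in 0:max_knots) {
    sets <- if (k == 0) list(integer(0))
      else Filter(function(s) k == 1 || all(diff(s) >= min_seg),
                  utils::combn(idx_all, k, simplify = FALSE))
    if (!length(sets)) next
    for (s in sets) {
      X <- build_design(cand_all[s])
      f <- glm_poisson_fit(X, y, offset = offs)
      bic <- f$deviance + (ncol(X) + k) * log(n)
      if (bic < best_bic - 1e-9) { best_bic <- bic; best <- cand_all[s] }
    }
  }
  best
}

#' Fit the additive discrete-time log-hazard survival model
#'
#' @param surv a [tabulate_survivorship()] result (or [read_survivorship()]).
#'   Age groups are entered at their midpoints,
#'   `start + (width - 1) / 2` years; cells with zero at-risk count are
#'   dropped.
#' @param method `"joinpoint"` (piecewise-linear components with
#'   BIC-selected knots, default) or `"bspline"` (anchored B-spline
#'   components with fixed knots at quantiles).
#' @param knot_config list of options: `max_knots` (named vector for
#'   `t`/`a`/`p`, default `c(t = 2, a = 1, p = 1)`), `min_seg` (minimum
#'   distinct axis values between knots, default 2), `df` (B-spline free
#'   parameters per component, default 4, bounded by the number of distinct
#'   axis values), `knots` (optional named list of fixed interior knots,
#'   bypassing selection).
#' @return object of class `hazard_fit`: intercept `nu0` (log hazard at the
#'   grid origin), components `t_component`, `a_component`, `p_component`,
#'   joint coefficient covariance `coef_cov`, dispersion-free Poisson GLM
#'   diagnostics, and `age_eval_points` (the midpoints used).
#' @seealso [hazard_at()], [survival_curve()], [prevalence_rates()]
#' @export
fit_hazard <- function(surv, method = c("joinpoint", "bspline"),
                       knot_config = list()) {
  stopifnot(inherits(surv, "survarray"))
  method <- match.arg(method)
  mk <- knot_config$max_knots %||% c(t = 2, a = 1, p = 1)
  min_seg <- knot_config$min_seg %||% 2
  df_cfg <- knot_config$df %||% 4
  if (length(df_cfg) == 1) df_cfg <- c(t = df_cfg, a = df_cfg, p = df_cfg)

  mid <- surv$age_starts + (surv$age_width - 1) / 2
  g <- expand.grid(ai = seq_along(surv$age_starts),
                   pj = seq_along(surv$periods),
                   tk = seq_len(surv$t_max + 1L))
  M <- as.vector(surv$at_risk); D <- as.vector(surv$deaths)
  keep <- M > 0
  g <- g[keep, , drop = FALSE]; M <- M[keep]; D <- D[keep]
  tv <- (g$tk - 1L)
  av <- mid[g$ai]
  pv <- surv$periods[g$pj]

  axes <- list(t = sort(unique(tv)), a = sort(unique(av)),
               p = sort(unique(pv)))
  for (nm in names(axes))
    if (length(axes[[nm]]) < 2L)
      stop_("axis '%s' has a single level; the %s component is not identifiable",
            nm, switch(nm, t = "time-since-diagnosis", a = "age", p = "period"))

  bspline_meta <- function(axis_vals, df) {
    df <- max(2, min(df, length(axis_vals)))
    ord <- min(4L, df)
    n_int <- df - ord
    lo <- min(axis_vals); hi <- max(axis_vals)
    intq <- if (n_int > 0)
      stats::quantile(axis_vals, seq_len(n_int) / (n_int + 1), names = FALSE)
      else numeric(0)
    list(knots = c(rep(lo, ord), intq, rep(hi, ord)), ord = ord)
  }
  mk_comp_basis <- function(x, axis_vals, interior, meta, type) {
    lo <- min(axis_vals)
    if (type == "pwl") {
      pwl_basis(x, c(lo, interior))
    } else {
      B <- splines::splineDesign(meta$knots, x, ord = meta$ord)
      Bmin <- drop(splines::splineDesign(meta$knots, lo, ord = meta$ord))
      (B - rep(1, length(x)) %o% Bmin)[, -1, drop = FALSE]
    }
  }

  interior <- list(t = numeric(0), a = numeric(0), p = numeric(0))
  spline_meta <- list()
  if (method == "joinpoint") {
    fixed <- knot_config$knots
    vars <- list(t = tv, a = av, p = pv)
    for (nm in c("t", "a", "p")) {
      if (!is.null(fixed[[nm]])) { interior[[nm]] <- fixed[[nm]]; next }
      build <- function(int_nm) {
        ib <- interior; ib[[nm]] <- int_nm
        cbind(1,
              mk_comp_basis(tv, axes$t, ib$t, NULL, "pwl"),
              mk_comp_basis(av, axes$a, ib$a, NULL, "pwl"),
              mk_comp_basis(pv, axes$p, ib$p, NULL, "pwl"))
      }
      interior[[nm]] <- select_component_knots(build, D, log(M), axes[[nm]],
                                               mk[[nm]], min_seg)
    }
    Bt <- mk_comp_basis(tv, axes$t, interior$t, NULL, "pwl")
    Ba <- mk_comp_basis(av, axes$a, interior$a, NULL, "pwl")
    Bp <- mk_comp_basis(pv, axes$p, interior$p, NULL, "pwl")
  } else {
    spline_meta <- list(t = bspline_meta(axes$t, df_cfg[["t"]]),
                        a = bspline_meta(axes$a, df_cfg[["a"]]),
                        p = bspline_meta(axes$p, df_cfg[["p"]]))
    Bt <- mk_comp_basis(tv, axes$t, NULL, spline_meta$t, "bspline")
    Ba <- mk_comp_basis(av, axes$a, NULL, spline_meta$a, "bspline")
    Bp <- mk_comp_basis(pv, axes$p, NULL, spline_meta$p, "bspline")
  }

  X <- cbind(1, Bt, Ba, Bp)
  fit <- glm_poisson_fit(X, D, offset = log(M))
  if (!fit$converged) stop_("hazard GLM did not converge")
  beta <- fit$coefficients
  W <- fit$weights
  cov <- chol2inv(chol(crossprod(X * sqrt(W))))

  ix <- list(nu = 1L,
             t = 1L + seq_len(ncol(Bt)),
             a = 1L + ncol(Bt) + seq_len(ncol(Ba)),
             p = 1L + ncol(Bt) + ncol(Ba) + seq_len(ncol(Bp)))

  mk_component <- function(nm, B) {
    rng <- range(axes[[nm]])
    if (method == "joinpoint")
      new_hazard_component("pwl", unname(beta[ix[[nm]]]),
                           cov[ix[[nm]], ix[[nm]], drop = FALSE], rng,
                           interior = interior[[nm]])
    else
      new_hazard_component("bspline", unname(beta[ix[[nm]]]),
                           cov[ix[[nm]], ix[[nm]], drop = FALSE], rng,
                           knots = spline_meta[[nm]]$knots,
                           ord = spline_meta[[nm]]$ord)
  }

  structure(list(nu0 = unname(beta[1]),
                 t_component = mk_component("t", Bt),
                 a_component = mk_component("a", Ba),
                 p_component = mk_component("p", Bp),
                 method = method, coef = beta, coef_cov = cov, index = ix,
                 deviance = fit$deviance,
                 df_resid = length(D) - ncol(X),
                 age_eval_points = mid, t_max = surv$t_max,
                 axes = axes, delta = surv$delta),
            class = "hazard_fit")
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat(sprintf("Discrete-time hazard model (%s components)\n", x$method))
  cat(sprintf("  log hazard at origin (t=%g, a=%g, p=%g): %.4f  [h = %.4f]\n",
              x$axes$t[1], x$axes$a[1], x$axes$p[1], x$nu0, exp(x$nu0)))
  if (x$method == "joinpoint") {
    for (nm in c("t", "a", "p")) {
      comp <- x[[paste0(substr(nm, 1, 1), "_component")]]
      cat(sprintf("  %s component: %d knot(s)%s\n",
                  switch(nm, t = "time", a = "age", p = "period"),
                  length(comp$interior),
                  if (length(comp$interior))
                    sprintf(" at %s", fmt_vec(comp$interior)) else ""))
    }
  }
  cat(sprintf("  deviance %.1f on %d df\n", x$deviance, x$df_resid))
  invisible(x)
}

#' Terminal (boundary) slope of a hazard component
#'
#' Convenience accessor for the linear-predictor slope used when the
#' component is extrapolated beyond the data range, together with its
#' standard error.
#'
#' @param fit a [fit_hazard()] object.
#' @param component `"period"`, `"age"` or `"time"`.
#' @param side `"upper"` (default) or `"lower"`.
#' @return named vector with `slope` and `se`.
#' @export
hazard_terminal_slope <- function(fit, component = "period",
                                  side = c("upper", "lower")) {
  stopifnot(inherits(fit, "hazard_fit"))
  side <- match.arg(side)
  slot <- switch(match.arg(component, c("period", "age", "time")),
                 period = "p_component", age = "a_component",
                 time = "t_component")
  comp <- fit[[slot]]
  x0 <- if (side == "upper") comp$x_range[2] else comp$x_range[1]
  h <- 1e-3 * max(1, diff(comp$x_range))
  L <- (component_functional(comp, x0 + if (side == "upper") h else -h) -
          component_functional(comp, x0)) / (if (side == "upper") h else -h)
  c(slope = drop(L %*% comp$coef),
    se = sqrt(max(0, drop(L %*% comp$coef_cov %*% t(L)))))
}

#' Evaluate the fitted discrete-time hazard
#'
#' Returns the per-period death probability `h = exp(nu)` at the given age
#' at diagnosis, period of diagnosis, and follow-up time.  Ages and periods
#' may lie outside the fitted grid (linear extrapolation on the
#' linear-predictor scale); `t` must lie within the survivorship window.
#' Hazards are truncated at `1 - 1e-6` so that `1 - h` stays positive.
#'
#' @param fit a [fit_hazard()] object.
#' @param a age at diagnosis (years; vectorized).
#' @param p period of diagnosis (calendar year; vectorized).
#' @param t integer follow-up time in `0..t_max` (vectorized).
#' @return numeric vector of hazards.
#' @export
hazard_at <- function(fit, a, p, t) {
  stopifnot(inherits(fit, "hazard_fit"))
  if (any(t < 0 | t > fit$t_max))
    stop_("t must lie in [0, %d] (the survivorship window)", fit$t_max)
  n <- max(length(a), length(p), length(t))
  a <- rep_len(a, n); p <- rep_len(p, n); t <- rep_len(t, n)
  lp <- fit$nu0 + component_value(fit$t_component, t) +
    component_value(fit$a_component, a) + component_value(fit$p_component, p)
  pmin(exp(lp), 1 - 1e-6)
}

# Uniform hazard accessor shared by survival_curve / prevalence / microsim:
# accepts a hazard_fit, a constant_hazard, or a function(a, p, t).
hazard_eval <- function(h, a, p, t) {
  if (inherits(h, "hazard_fit")) hazard_at(h, a, p, t)
  else if (inherits(h, "const_hazard")) rep_len(h$h, max(length(a), length(p), length(t)))
  else if (is.function(h)) {
    n <- max(length(a), length(p), length(t))
    pmin(rep_len(h(rep_len(a, n), rep_len(p, n), rep_len(t, n)), n), 1 - 1e-6)
  } else stop_("unsupported hazard object of class '%s'", class(h)[1])
}

#' Constant-hazard object
#'
#' A degenerate hazard model with the same per-period death probability
#' everywhere; usable wherever a fitted hazard is accepted
#' ([survival_curve()], [prevalence_rates()]).  `constant_hazard(0)` gives
#' survival identically 1, which is the closed-form check case for the
#' prevalence convolution.
#'
#' @param h death probability per period, in `[0, 1)`.
#' @param t_max nominal survivorship window (default `Inf`).
#' @return object of class `const_hazard`.
#' @export
constant_hazard <- function(h, t_max = Inf) {
  check_number(h, "h", min = 0)
  if (h >= 1) stop_("constant hazard must be < 1")
  structure(list(h = h, t_max = t_max), class = "const_hazard")
}

#' Cumulative survival after diagnosis
#'
#' Probability of surviving through `i` elapsed periods after diagnosis at
#' age `a` in period `p`: the discrete product
#' `S(i) = prod_{j=0..i} (1 - h(a, p, j))`, where `t = 0` is the diagnosis
#' period itself (so people dying in their diagnosis period never enter the
#' prevalent cohort).  `method = "exp"` gives the continuous-time
#' approximation `exp(-sum h)` for sensitivity analysis.
#'
#' @param fit a [fit_hazard()], [constant_hazard()], or `function(a, p, t)`.
#' @param a age at diagnosis (years).
#' @param p period of diagnosis.
#' @param i elapsed periods, `0 <= i <= t_max` (vectorized; returns `S(i)`
#'   for each requested `i`).
#' @param method `"product"` (default) or `"exp"`.
#' @return numeric vector of survival probabilities in `(0, 1]`.
#' @export
survival_curve <- function(fit, a, p, i, method = c("product", "exp")) {
  method <- match.arg(method)
  imax <- max(i)
  if (any(i < 0)) stop_("i must be >= 0")
  if (inherits(fit, "hazard_fit") && imax > fit$t_max)
    stop_("i exceeds the survivorship window t_max = %d", fit$t_max)
  h <- hazard_eval(fit, a, p, 0:imax)
  S <- if (method == "product") cumprod(1 - h) else exp(-cumsum(h))
  S[i + 1L]
}

#' Export fitted hazard component curves
#'
#' @param fit a [fit_hazard()] object.
#' @return data frame with columns `component`, `x`, `estimate`, `se`
#'   (linear-predictor scale, component anchored at 0 at its axis minimum).
#' @export
hazard_component_table <- function(fit) {
  stopifnot(inherits(fit, "hazard_fit"))
  out <- lapply(c(time = "t_component", age = "a_component",
                  period = "p_component"), function(slot) {
    comp <- fit[[slot]]
    x <- switch(slot, t_component = fit$axes$t, a_component = fit$axes$a,
                p_component = fit$axes$p)
    L <- component_functional(comp, x)
    data.frame(x = x, estimate = drop(L %*% comp$coef),
               se = sqrt(pmax(0, lfun_var(L, comp$coef_cov))))
  })
  res <- do.call(rbind, Map(function(nm, df) cbind(component = nm, df),
                            names(out), out))
  rownames(res) <- NULL
  res
}
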