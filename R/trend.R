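# Piecewise-linear (joinpoint-style) and B-spline trend fits with linear
# extrapolation beyond both data ends.  Shared by the incidence rate-ratio
# extrapolations and the survival hazard components.

#' Fit a piecewise-linear (joinpoint-style) trend
#'
#' Weighted least-squares fit of a continuous piecewise-linear function with
#' breakpoints ("joinpoints") placed on observed `x` values.  The number and
#' location of interior knots are chosen by exhaustive grid search, scoring
#' each candidate by BIC on the weighted Gaussian likelihood with two
#' parameters charged per knot (location and slope change).  Ties prefer
#' fewer knots, so an exactly linear signal selects zero knots.  Reported
#' coefficient covariances are conditional on the selected knots (selection
#' uncertainty is not propagated).
#'
#' @param x strictly increasing numeric vector (e.g. periods or cohorts).
#' @param y response values.
#' @param w positive weights (default equal).
#' @param max_knots maximum number of interior knots (default 3).
#' @param min_seg minimum number of observations per segment (default 3).
#' @return object of class `pwl_fit` with elements `knots` (all breakpoints,
#'   first and last equal to the data endpoints), `coef` (intercept at
#'   `min(x)`, first-segment slope, slope increments at interior knots),
#'   `coef_cov`, `criterion` (BIC trace per knot count), `fitted`, and
#'   tail-modification state used by [flatten_tail()] / [scale_slope()].
#' @seealso [extrapolate()], [fit_bspline_trend()]
#' @examples
#' x <- 1:20
#' y <- 0.5 + 0.1 * x + pmax(x - 12, 0) * -0.15
#' f <- fit_piecewise_linear(x, y)
#' f$knots
#' @export
fit_piecewise_linear <- function(x, y, w = NULL, max_knots = 3, min_seg = 3) {
  n <- length(x)
  if (length(y) != n) stop_("x and y lengths differ")
  if (is.unsorted(x, strictly = TRUE)) stop_("x must be strictly increasing")
  w <- w %||% rep(1, n)
  if (any(w <= 0) || length(w) != n) stop_("weights must be positive, length n")
  check_number(max_knots, "max_knots", min = 0, integer = TRUE)
  check_number(min_seg, "min_seg", min = 2, integer = TRUE)
  if (n < 2 && max_knots == 0) stop_("need at least 2 observations")
  # largest k satisfying the segment constraint k * min_seg <= n - min_seg + 1
  kmax_feasible <- max(0, (n - min_seg + 1) %/% min_seg)
  if (max_knots > kmax_feasible)
    stop_("max_knots = %d infeasible: n = %d and min_seg = %d allow at most %d knot(s)",
          max_knots, n, min_seg, kmax_feasible)

  cand <- seq_len(n)
  cand <- cand[cand >= min_seg & cand <= n - min_seg + 1]
  # numerical floor so that exact (noise-free) fits tie across knot counts
  # and the tie-break then prefers fewer knots
  wvar <- sum(w * (y - sum(w * y) / sum(w))^2) / sum(w)
  floor_s2 <- 1e-12 * max(wvar, mean(y^2)) + 1e-300

  fit_one <- function(kidx) {
    X <- cbind(1, pwl_basis(x, c(x[1], x[kidx])))
    f <- stats::lm.wfit(X, y, w)
    rss <- sum(w * f$residuals^2)
    list(coef = f$coefficients, rss = rss, X = X)
  }
  knot_sets <- function(k) {
    if (k == 0) return(list(integer(0)))
    sets <- utils::combn(cand, k, simplify = FALSE)
    Filter(function(s) k == 1 || all(diff(s) >= min_seg), sets)
  }

  best <- NULL; best_bic <- Inf; trace <- data.frame()
  for (k in 0:max_knots) {
    sets <- knot_sets(k)
    if (!length(sets)) next
    k_best <- NULL; k_rss <- Inf
    for (s in sets) {
      f <- fit_one(s)
      if (f$rss < k_rss) { k_rss <- f$rss; k_best <- c(f, list(kidx = s)) }
    }
    s2 <- max(k_rss / n, floor_s2)
    bic <- n * log(s2) + (2 + 2 * k) * log(n)
    trace <- rbind(trace, data.frame(knots = k, rss = k_rss, bic = bic))
    if (bic < best_bic - 1e-9) { best_bic <- bic; best <- c(k_best, list(k = k)) }
  }

  kidx <- best$kidx
  X <- best$X
  npar <- ncol(X)
  df_resid <- n - npar
  s2 <- if (df_resid > 0) max(best$rss / df_resid, 0) else 0
  XtWX <- crossprod(X * sqrt(w))
  coef_cov <- s2 * chol2inv(chol(XtWX))

  structure(list(knots = c(x[1], x[kidx], x[n]),
                 interior = x[kidx],
                 coef = unname(best$coef),
                 coef_cov = coef_cov,
                 criterion = trace,
                 x_range = range(x), x = x, y = y, w = w,
                 fitted = drop(X %*% best$coef),
                 tail_scale = c(lower = 1, upper = 1)),
            class = "pwl_fit")
}

#' @export
print.pwl_fit <- function(x, ...) {
  k <- length(x$interior)
  slopes <- cumsum(x$coef[-1])
  cat(sprintf("Piecewise-linear fit: %d interior knot(s)%s\n", k,
              if (k) sprintf(" at %s", fmt_vec(x$interior)) else ""))
  cat(sprintf("  segment slopes: %s\n", fmt_vec(slopes)))
  if (any(x$tail_scale != 1))
    cat(sprintf("  tail modifications: lower x%g, upper x%g\n",
                x$tail_scale["lower"], x$tail_scale["upper"]))
  invisible(x)
}

# Row functionals mapping coefficients to values at x_new, with linear
# continuation (scaled by tail_scale) beyond both data ends.
pwl_functional <- function(fit, x_new) {
  kn <- c(fit$x_range[1], fit$interior)
  p <- length(kn) + 1L
  lo <- fit$x_range[1]; hi <- fit$x_range[2]
  L <- matrix(0, length(x_new), p)
  for (i in seq_along(x_new)) {
    xi <- x_new[i]
    if (xi >= lo && xi <= hi) {
      L[i, ] <- c(1, pmax(xi - kn, 0))
    } else if (xi > hi) {
      base <- c(1, pmax(hi - kn, 0))
      slope <- c(0, rep(1, p - 1L))            # terminal slope = sum of increments
      L[i, ] <- base + fit$tail_scale["upper"] * (xi - hi) * slope
    } else {
      base <- c(1, rep(0, p - 1L))
      slope <- c(0, 1, rep(0, p - 2L))          # first-segment slope
      L[i, ] <- base + fit$tail_scale["lower"] * (xi - lo) * slope
    }
  }
  L
}

#' Fit a B-spline trend with linear tail extrapolation
#'
#' Weighted least-squares fit on a B-spline basis with fixed interior knots
#' at weighted quantiles of `x`.  Outside the data range the fitted curve is
#' continued exactly linearly using the boundary derivative, so the fit can
#' be extrapolated in both directions like the piecewise-linear fit.
#'
#' @param x strictly increasing numeric vector.
#' @param y response values.
#' @param w positive weights (default equal).
#' @param df total number of free parameters (>= 2).  `df = 2` is a straight
#'   line, `df = 4` a single cubic; larger `df` adds interior knots at
#'   quantiles.  `df` may not exceed the number of observations.
#' @return object of class `bspline_trend`.
#' @seealso [extrapolate()], [fit_piecewise_linear()]
#' @export
fit_bspline_trend <- function(x, y, w = NULL, df = 4) {
  n <- length(x)
  if (length(y) != n) stop_("x and y lengths differ")
  if (is.unsorted(x, strictly = TRUE)) stop_("x must be strictly increasing")
  w <- w %||% rep(1, n)
  check_number(df, "df", min = 2, integer = TRUE)
  if (df > n) stop_("df = %d exceeds the number of observations (%d)", df, n)
  ord <- min(4L, df)
  n_int <- df - ord
  interior <- if (n_int > 0)
    weighted_quantile(x, w, seq_len(n_int) / (n_int + 1)) else numeric(0)
  knots <- c(rep(x[1], ord), interior, rep(x[n], ord))
  X <- splines::splineDesign(knots, x, ord = ord)
  f <- stats::lm.wfit(X, y, w)
  if (anyNA(f$coefficients))
    stop_("degenerate B-spline basis (df = %d, n = %d): coincident knots?", df, n)
  rss <- sum(w * f$residuals^2)
  df_resid <- n - df
  s2 <- if (df_resid > 0) rss / df_resid else 0
  coef_cov <- s2 * chol2inv(chol(crossprod(X * sqrt(w))))
  structure(list(knots = knots, ord = ord, interior = interior, df = df,
                 coef = unname(f$coefficients), coef_cov = coef_cov,
                 x_range = range(x), x = x, y = y, w = w,
                 fitted = drop(X %*% f$coefficients),
                 tail_scale = c(lower = 1, upper = 1)),
            class = "bspline_trend")
}

#' @export
print.bspline_trend <- function(x, ...) {
  cat(sprintf("B-spline trend: order %d, df %d, %d interior knot(s)%s\n",
              x$ord, x$df, length(x$interior),
              if (length(x$interior)) sprintf(" at %s", fmt_vec(x$interior)) else ""))
  if (any(x$tail_scale != 1))
    cat(sprintf("  tail modifications: lower x%g, upper x%g\n",
                x$tail_scale["lower"], x$tail_scale["upper"]))
  invisible(x)
}

bspline_functional <- function(fit, x_new) {
  lo <- fit$x_range[1]; hi <- fit$x_range[2]
  L <- matrix(0, length(x_new), length(fit$coef))
  inside <- x_new >= lo & x_new <= hi
  if (any(inside))
    L[inside, ] <- splines::splineDesign(fit$knots, x_new[inside], ord = fit$ord)
  d_lo <- splines::splineDesign(fit$knots, lo, ord = fit$ord, derivs = 1L)
  d_hi <- splines::splineDesign(fit$knots, hi, ord = fit$ord, derivs = 1L)
  b_lo <- splines::splineDesign(fit$knots, lo, ord = fit$ord)
  b_hi <- splines::splineDesign(fit$knots, hi, ord = fit$ord)
  up <- x_new > hi
  if (any(up))
    L[up, ] <- rep(1, sum(up)) %o% drop(b_hi) +
      fit$tail_scale["upper"] * (x_new[up] - hi) %o% drop(d_hi)
  dn <- x_new < lo
  if (any(dn))
    L[dn, ] <- rep(1, sum(dn)) %o% drop(b_lo) +
      fit$tail_scale["lower"] * (x_new[dn] - lo) %o% drop(d_lo)
  L
}

trend_functional <- function(fit, x_new) {
  if (inherits(fit, "pwl_fit")) pwl_functional(fit, x_new)
  else if (inherits(fit, "bspline_trend")) bspline_functional(fit, x_new)
  else stop_("not a trend fit object")
}

#' Evaluate or extrapolate a trend fit
#'
#' Inside the data range this returns the fitted curve; beyond either end it
#' continues linearly, using the terminal-segment slope (forward) or the
#' first-segment slope (backward), each possibly modified by
#' [flatten_tail()] or [scale_slope()].  Pointwise variances come from the
#' delta method on the coefficient covariance and are conditional on the
#' selected knots.
#'
#' @param fit a [fit_piecewise_linear()] or [fit_bspline_trend()] object.
#' @param x_new numeric evaluation points.
#' @return data frame with columns `x`, `fit`, `var`.
#' @export
extrapolate <- function(fit, x_new) {
  L <- trend_functional(fit, x_new)
  data.frame(x = x_new,
             fit = drop(L %*% fit$coef),
             var = lfun_var(L, fit$coef_cov))
}

#' @export
predict.pwl_fit <- function(object, newdata = NULL, ...) {
  x_new <- newdata %||% object$x
  extrapolate(object, x_new)$fit
}

#' @export
predict.bspline_trend <- function(object, newdata = NULL, ...) {
  x_new <- newdata %||% object$x
  extrapolate(object, x_new)$fit
}

#' Counterfactual tail modifications of a trend fit
#'
#' `flatten_tail()` replaces the extrapolation slope beyond the chosen data
#' end with zero (a horizontal continuation of the boundary value);
#' `scale_slope()` multiplies it by `factor` (0.5x / 1.5x scenario analyses;
#' `factor = 0` is equivalent to flattening, `factor = 1` leaves the fit
#' unchanged).  Fitted values inside the data range are never affected.
#'
#' @param fit a trend fit ([fit_piecewise_linear()] / [fit_bspline_trend()])
#'   or a [fit_hazard()] object (then `component` selects which hazard
#'   component's tail to modify).
#' @param side `"upper"` (forward extrapolation, default), `"lower"`
#'   (back-casting) or `"both"`.
#' @param ... passed to methods.
#' @return a modified copy of `fit`.
#' @export
flatten_tail <- function(fit, ...) UseMethod("flatten_tail")

#' @rdname flatten_tail
#' @export
flatten_tail.default <- function(fit, side = c("upper", "lower", "both"), ...) {
  scale_slope(fit, 0, side = match.arg(side), ...)
}

#' @rdname flatten_tail
#' @param factor multiplier applied to the extrapolation slope.
#' @export
scale_slope <- function(fit, factor, ...) UseMethod("scale_slope")

#' @rdname flatten_tail
#' @export
scale_slope.default <- function(fit, factor, side = c("upper", "lower", "both"),
                                ...) {
  side <- match.arg(side)
  if (!inherits(fit, c("pwl_fit", "bspline_trend")))
    stop_("no scale_slope method for class '%s'", class(fit)[1])
  check_number(factor, "factor")
  sides <- if (side == "both") c("lower", "upper") else side
  fit$tail_scale[sides] <- fit$tail_scale[sides] * factor
  fit
}
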