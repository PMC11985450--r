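# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
check_number <- function(x, name, min = -Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_("'%s' must be a single finite number", name)
  if (x < min) stop_("'%s' must be >= %s", name, format(min))
  if (integer && x != round(x)) stop_("'%s' must be an integer", name)
  invisible(x)
}

# Equally spaced, strictly increasing axis; returns the common step.
axis_step <- function(v, name) {
  if (length(v) < 2L) return(NA_real_)
  d <- diff(v)
  if (any(d <= 0)) stop_("%s axis must be strictly increasing", name)
  if (max(d) - min(d) > 1e-8 * max(abs(v), 1))
    stop_("%s axis is not equally spaced (steps range %g to %g)",
          name, min(d), max(d))
  mean(d)
}

# Weighted quantiles of x (type-7-like interpolation on the weighted CDF).
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

fmt_vec <- function(v, digits = 4) paste(format(v, digits = digits), collapse = ", ")

# Poisson IRLS that tolerates non-integer responses (expected-count
# fixtures); only the spurious non-integer warning is muffled.
glm_poisson_fit <- function(X, y, offset) {
  withCallingHandlers(
    stats::glm.fit(X, y, family = stats::poisson(), offset = offset,
                   intercept = FALSE),
    warning = function(w) {
      if (grepl("non-integer", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}
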