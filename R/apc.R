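#' Fit the age-period-cohort incidence model
#'
#' Fits the log-linear APC rate model through its estimable parametrization:
#' a grand mean, the longitudinal age trend `(alphaL + piL)`, the net drift
#' `(piL + gammaL)`, and complete age/period/cohort deviations constrained to
#' be orthogonal to the constant and linear functions of their own index.
#' Only estimable quantities are ever reported; no arbitrary split of the
#' non-identifiable linear trends is made.  Each complete deviation vector is
#' further partitioned into an orthogonal-quadratic component (`theta * q2`)
#' and higher-order residual deviations.
#'
#' The default engine is a Poisson GLM with log link and offset `log(O)`
#' (iteratively reweighted least squares).  The `wls` engine regresses
#' observed log rates on the same design with weights `Y`; zero-count cells
#' get `0.5` added for the log transform only and are flagged in the result.
#' Under `family = "quasipoisson"` a dispersion factor (Pearson chi-square
#' over residual df, floored at 1) scales the parameter covariance.
#'
#' @param lexis a [lexis_diagram()]; requires at least 3 age groups and 3
#'   periods so the quadratics are estimable.
#' @param family `"poisson"` (default) or `"quasipoisson"`.
#' @param engine `"irls"` (Poisson regression, default) or `"wls"`
#'   (weighted least squares on log rates).
#' @return An object of class `apc_fit`.  Key elements: `mu`,
#'   `long_age_trend`, `net_drift`, `cross_age_trend`, complete deviations
#'   `age_dev`/`period_dev`/`cohort_dev`, quadratic coefficients
#'   `theta_age`/`theta_period`/`theta_cohort` with residual deviations
#'   `resid_age_dev`/`resid_period_dev`/`resid_cohort_dev`, `param_cov`,
#'   `dispersion`, `centers`, goodness-of-fit statistics, and internal basis
#'   objects used by downstream functions.
#' @references The estimable-function formulation of APC analysis
#'   (net drift, longitudinal/cross-sectional age curves, cohort and period
#'   rate-ratio curves) is standard in cancer-surveillance APC tools.
#' @seealso [estimable_functions()], [fitted_log_rates()],
#'   [forecast_incidence()]
#' @export
fit_apc <- function(lexis, family = c("poisson", "quasipoisson"),
                    engine = c("irls", "wls")) {
  stopifnot(inherits(lexis, "lexis"))
  family <- match.arg(family)
  engine <- match.arg(engine)
  A <- length(lexis$ages); P <- length(lexis$periods)
  if (A < 3L || P < 3L)
    stop_("need at least 3 age groups and 3 periods (got %d x %d)", A, P)

  ages <- lexis$ages; periods <- lexis$periods; cohorts <- lexis$cohorts
  abar <- mean(ages); pbar <- mean(periods); cbar <- mean(cohorts)

  Ba <- ortho_dev_basis(ages)
  Bp <- ortho_dev_basis(periods)
  Bc <- ortho_dev_basis(cohorts)

  ai <- rep(seq_len(A), times = P)
  pi <- rep(seq_len(P), each = A)
  ci <- pi - ai + A                     # cohort index into 1..(A+P-1)

  X <- cbind(1, ages[ai] - abar, cohorts[ci] - cbar,
             Ba[ai, , drop = FALSE], Bp[pi, , drop = FALSE],
             Bc[ci, , drop = FALSE])
  npar <- ncol(X)
  idx <- list(mu = 1L, atrend = 2L, drift = 3L,
              age = 3L + seq_len(A - 2L),
              period = 3L + (A - 2L) + seq_len(P - 2L),
              cohort = 3L + (A - 2L) + (P - 2L) + seq_len(A + P - 3L))
  colnames(X) <- c("mu", "age_trend", "net_drift",
                   paste0("age_dev", seq_len(A - 2L)),
                   paste0("period_dev", seq_len(P - 2L)),
                   paste0("cohort_dev", seq_len(A + P - 3L)))

  y <- as.vector(lexis$cases)
  o <- as.vector(lexis$offsets)
  zero_cells <- sum(y == 0)

  if (engine == "irls") {
    fit <- glm_poisson_fit(X, y, offset = log(o))
    if (!fit$converged)
      stop_("Poisson IRLS did not converge in %d iterations (deviance %g)",
            fit$iter, fit$deviance)
    beta <- fit$coefficients
    W <- fit$weights                     # IRLS working weights = fitted means
    mu_hat <- fit$fitted.values
    pearson <- sum((y - mu_hat)^2 / mu_hat)
    deviance <- fit$deviance
  } else {
    ylog <- log((y + 0.5 * (y == 0)) / o)
    W <- y                               # delta-method weights
    keep <- W > 0
    if (!any(keep)) stop_("wls engine needs at least one non-zero cell")
    b <- stats::lm.wfit(X[keep, , drop = FALSE], ylog[keep], W[keep])
    beta <- b$coefficients
    if (anyNA(beta)) stop_("wls design is rank-deficient")
    mu_hat <- o * exp(drop(X %*% beta))
    pearson <- sum((y - mu_hat)^2 / mu_hat)
    deviance <- 2 * sum(ifelse(y > 0, y * log(y / mu_hat), 0) - (y - mu_hat))
  }
  df_resid <- length(y) - npar
  dispersion <- if (family == "quasipoisson") max(1, pearson / df_resid) else 1

  XtWX <- crossprod(X * sqrt(W))
  param_cov <- dispersion * chol2inv(chol(XtWX))
  dimnames(param_cov) <- list(colnames(X), colnames(X))

  age_dev <- drop(Ba %*% beta[idx$age])
  period_dev <- drop(Bp %*% beta[idx$period])
  cohort_dev <- drop(Bc %*% beta[idx$cohort])

  qa <- ortho_quad(ages); qp <- ortho_quad(periods); qc <- ortho_quad(cohorts)
  pa <- partition_deviations(age_dev, index = ages)
  pp <- partition_deviations(period_dev, index = periods)
  pc <- partition_deviations(cohort_dev, index = cohorts)

  structure(list(
    mu = unname(beta[1]),
    long_age_trend = unname(beta[2]),
    net_drift = unname(beta[3]),
    cross_age_trend = unname(beta[2] - beta[3]),
    age_dev = age_dev, period_dev = period_dev, cohort_dev = cohort_dev,
    theta_age = pa$theta, theta_period = pp$theta, theta_cohort = pc$theta,
    resid_age_dev = pa$resid, resid_period_dev = pp$resid,
    resid_cohort_dev = pc$resid,
    coefficients = beta, param_cov = param_cov, dispersion = dispersion,
    centers = c(age = abar, period = pbar, cohort = cbar),
    gof = c(deviance = deviance, pearson = pearson, df = df_resid),
    family = family, engine = engine, zero_cells = zero_cells,
    basis = list(age = Ba, period = Bp, cohort = Bc,
                 q2_age = qa, q2_period = qp, q2_cohort = qc),
    index = idx, design = X, cell_age = ai, cell_period = pi, cell_cohort = ci,
    fitted_counts = mu_hat,
    lexis = lexis), class = "apc_fit")
}

#' Split a deviation vector into quadratic and higher-order parts
#'
#' Projects a complete deviation vector (orthogonal to the constant and
#' linear functions of its index) onto the orthogonal unit-norm quadratic
#' `q2` of the index grid, returning the curvature coefficient `theta` and
#' the residual higher-order deviations.  By construction
#' `dev = theta * q2 + resid` with `resid` orthogonal to constant, linear and
#' quadratic.  `theta` is basis-dependent; the package always uses the
#' unit-Euclidean-norm `q2`, so `theta * q2` is the invariant quantity.
#'
#' @param dev numeric deviation vector (length >= 3).
#' @param index grid labels the deviations are indexed by (defaults to
#'   `seq_along(dev)`); must be equally spaced.
#' @param weights optional inner-product weights (default unweighted).
#' @return list with `theta` (scalar), `resid` (vector), and `q2`
#'   (the [ortho_quad()] values used).
#' @export
partition_deviations <- function(dev, index = seq_along(dev), weights = NULL) {
  if (length(dev) < 3L) stop_("deviation vector must have length >= 3")
  if (length(index) != length(dev)) stop_("index and dev lengths differ")
  if (is.null(weights)) {
    q2 <- ortho_quad(index)$values
  } else {
    # weighted Gram-Schmidt of index^2 against {1, index}
    w <- weights / sum(weights)
    x <- index; y <- index^2
    y <- y - sum(w * y)
    x1 <- x - sum(w * x)
    y <- y - sum(w * y * x1) / sum(w * x1^2) * x1
    q2 <- y / sqrt(sum(w * y^2))
    theta <- sum(w * dev * q2)
    return(list(theta = theta, resid = dev - theta * q2, q2 = q2))
  }
  theta <- sum(dev * q2)
  list(theta = theta, resid = dev - theta * q2, q2 = q2)
}

#' @export
coef.apc_fit <- function(object, ...) object$coefficients

#' @export
vcov.apc_fit <- function(object, ...) object$param_cov

#' @export
fitted.apc_fit <- function(object, type = c("rate", "count", "log_rate"), ...) {
  type <- match.arg(type)
  A <- length(object$lexis$ages); P <- length(object$lexis$periods)
  cnt <- matrix(object$fitted_counts, A, P,
                dimnames = dimnames(object$lexis$cases))
  switch(type,
         count = cnt,
         rate = cnt / object$lexis$offsets,
         log_rate = log(cnt / object$lexis$offsets))
}

#' @export
print.apc_fit <- function(x, ...) {
  cat("Age-period-cohort incidence model (estimable parametrization)\n")
  cat(sprintf("  engine %s, family %s; %d x %d Lexis grid\n", x$engine,
              x$family, length(x$lexis$ages), length(x$lexis$periods)))
  se <- sqrt(diag(x$param_cov)[2:3])
  cat(sprintf("  grand mean (log rate)      %8.4f\n", x$mu))
  cat(sprintf("  longitudinal age trend/yr  %8.4f (se %.4f)\n",
              x$long_age_trend, se[1]))
  cat(sprintf("  net drift/yr               %8.4f (se %.4f)\n",
              x$net_drift, se[2]))
  cat(sprintf("  dispersion %.3f; deviance %.1f on %d df\n",
              x$dispersion, x$gof["deviance"], x$gof["df"]))
  invisible(x)
}

#' @export
summary.apc_fit <- function(object, ...) {
  se <- sqrt(diag(object$param_cov))
  ans <- list(fit = object,
              trends = data.frame(
                parameter = c("grand_mean", "long_age_trend", "net_drift",
                              "cross_age_trend"),
                estimate = c(object$mu, object$long_age_trend,
                             object$net_drift, object$cross_age_trend),
                se = c(se[1], se[2], se[3],
                       sqrt(se[2]^2 + se[3]^2 -
                            2 * object$param_cov[2, 3]))),
              theta = c(age = object$theta_age, period = object$theta_period,
                        cohort = object$theta_cohort),
              gof = object$gof, dispersion = object$dispersion)
  class(ans) <- "summary.apc_fit"
  ans
}

#' @export
print.summary.apc_fit <- function(x, ...) {
  print(x$fit)
  cat("\nEstimable trend parameters (per year of index):\n")
  print(x$trends, row.names = FALSE, digits = 4)
  cat("\nQuadratic curvature coefficients theta (unit-norm q2 basis):\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' Machine-readable parameter table of an APC fit
#'
#' @param fit an [fit_apc()] result.
#' @return data frame with columns `parameter`, `estimate`, `se`.
#' @export
apc_parameter_table <- function(fit) {
  stopifnot(inherits(fit, "apc_fit"))
  data.frame(parameter = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = sqrt(diag(fit$param_cov)))
}
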