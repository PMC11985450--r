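# Prevalence as the convolution of lagged incidence with modeled survival:
#   xi(a, p) = sum_{i=0}^{T} lambda(a - i, p - i) * S(a - i, p - i, i),
# where S is the cumulative survival of the cohort diagnosed at age a-i in
# period p-i through i elapsed periods.  Each elapsed period ages a cohort by
# exactly one age bin, which is why age and period bin widths must match.
# Early calendar periods need incidence from before the data window ("burn
# in"); back-cast incidence supplies those terms, and a completeness mask
# records cells where terms were truncated instead.

# Survival array S[a_idx, p_idx, i+1] for diagnosis cells on the extended
# grid, i = 0..t_max, under any hazard object accepted by hazard_eval().
survival_array <- function(surv, ages, periods, t_max, method = "product") {
  A <- length(ages); P <- length(periods)
  H <- array(0, dim = c(A, P, t_max + 1L))
  grid_a <- rep(ages, times = P)
  grid_p <- rep(periods, each = A)
  for (i in 0:t_max)
    H[, , i + 1L] <- matrix(hazard_eval(surv, grid_a, grid_p, i), A, P)
  if (t_max == 0)
    return(if (method == "product") 1 - H else exp(-H))
  S <- if (method == "product") aperm(apply(1 - H, c(1, 2), cumprod), c(2, 3, 1))
       else aperm(apply(H, c(1, 2), function(h) exp(-cumsum(h))), c(2, 3, 1))
  S
}

# Core convolution given an incidence matrix on the extended grid and a
# precomputed survival array; returns the prevalence matrix over all columns.
convolve_prevalence <- function(lambda, S, t_max) {
  A <- nrow(lambda); P <- ncol(lambda)
  xi <- matrix(0, A, P)
  for (i in 0:t_max) {
    src_a <- seq_len(A - i); src_p <- seq_len(P - i)
    dst_a <- src_a + i; dst_p <- src_p + i
    xi[dst_a, dst_p] <- xi[dst_a, dst_p] +
      lambda[src_a, src_p, drop = FALSE] * S[src_a, src_p, i + 1L]
  }
  xi
}

#' Prevalence rates by incidence-survival convolution
#'
#' Computes expected prevalence rates `xi(a, p)` — cancer survivors per
#' person-year, counting people diagnosed within the last `t_max + 1`
#' periods and alive at period end — by convolving the (back-cast +
#' observed + forecast) incidence rates with the modeled survival of each
#' diagnosis cohort.  Terms whose diagnosis age falls below the youngest
#' modeled age contribute zero (such cohorts were not eligible for counted
#' diagnosis); terms whose diagnosis period precedes the extended grid are
#' unavailable and mark the cell incomplete (`complete_mask = FALSE`).
#'
#' @param inc a [forecast_incidence()] result (its back-cast horizon should
#'   be at least `t_max` for fully complete early-period estimates), or any
#'   object with `rates`, `ages`, `periods`, `delta`.
#' @param surv a [fit_hazard()] result, a [constant_hazard()], or a
#'   `function(a, p, t)` returning per-period hazards.
#' @param t_max survivorship window `T` (periods); must not exceed the
#'   fitted window of `surv`.
#' @param survival_method `"product"` (default) or `"exp"`, as in
#'   [survival_curve()].
#' @return object of class `prevalence_est`: `xi` (ages x periods matrix of
#'   prevalence rates over the full incidence grid), `complete_mask`,
#'   `t_max`, axis metadata and provenance.  Bootstrap variances are added
#'   by [bootstrap_covariance()].
#' @export
prevalence_rates <- function(inc, surv, t_max,
                             survival_method = c("product", "exp")) {
  survival_method <- match.arg(survival_method)
  check_number(t_max, "t_max", min = 0, integer = TRUE)
  if (inherits(surv, "hazard_fit") && t_max > surv$t_max)
    stop_("t_max = %d exceeds the fitted survivorship window (%d)",
          t_max, surv$t_max)
  if (inherits(surv, "hazard_fit") &&
      abs(surv$delta - inc$delta) > 1e-8)
    stop_("incidence grid delta (%g) and survival grid delta (%g) differ",
          inc$delta, surv$delta)
  lambda <- inc$rates
  ages <- inc$ages; periods <- inc$periods
  A <- length(ages); P <- length(periods)

  S <- survival_array(surv, ages, periods, t_max, survival_method)
  xi <- convolve_prevalence(lambda, S, t_max)

  # A cell is incomplete iff a needed term has an on-grid age but its
  # diagnosis period precedes the grid: columns j <= t_max lack term i >= j
  # whenever the age a - i is still on the grid (row index > i).
  # Cell (r, j) needs term i iff age row r - i >= 1; the term is off-grid in
  # period iff i >= j.  Hence incomplete iff j <= t_max and r >= j + 1.
  complete <- matrix(TRUE, A, P)
  for (j in seq_len(min(t_max, P)))
    if (j + 1L <= A) complete[(j + 1L):A, j] <- FALSE
  dimnames(xi) <- dimnames(complete) <- list(age = ages, period = periods)

  structure(list(xi = xi, complete_mask = complete, t_max = t_max,
                 ages = ages, periods = periods, delta = inc$delta,
                 cell_var = NULL, full_cov = NULL,
                 provenance = list(incidence = inc$provenance %||% "matrix",
                                   survival = class(surv)[1],
                                   survival_method = survival_method)),
            class = "prevalence_est")
}

#' @export
print.prevalence_est <- function(x, ...) {
  cat(sprintf("Prevalence estimate: %d ages x %d periods, window T = %d\n",
              length(x$ages), length(x$periods), x$t_max))
  cat(sprintf("  complete cells: %d / %d%s\n", sum(x$complete_mask),
              length(x$complete_mask),
              if (!is.null(x$cell_var)) "; bootstrap variances attached" else ""))
  cat(sprintf("  xi range %.3g to %.3g\n", min(x$xi), max(x$xi)))
  invisible(x)
}

#' First-order (delta-method) variance components of prevalence rates
#'
#' Approximate per-cell variances of the convolution estimate, split into an
#' incidence part (log-rate variances of the forecast propagated through the
#' convolution, terms treated as independent) and a survival part (exact
#' first-order propagation of the hazard-model coefficient covariance within
#' each cell, with incidence and survival treated as independent stages).
#' Useful for diagnostics and for calibrated comparisons against simulated
#' truth; the package's primary uncertainty tool for prevalence remains the
#' parametric bootstrap.
#'
#' @param inc a [forecast_incidence()] result (needs `log_var`).
#' @param surv a [fit_hazard()] object.
#' @param t_max survivorship window.
#' @return list with matrices `inc_var`, `surv_var`, `total` (ages x
#'   periods, aligned with `inc`).
#' @export
prevalence_delta_var <- function(inc, surv, t_max) {
  stopifnot(inherits(surv, "hazard_fit"))
  check_number(t_max, "t_max", min = 0, integer = TRUE)
  ages <- inc$ages; periods <- inc$periods
  A <- length(ages); P <- length(periods)
  lam <- inc$rates; lv <- inc$log_var
  S <- survival_array(surv, ages, periods, t_max)
  npar <- length(surv$coef)
  ix <- surv$index
  La <- component_functional(surv$a_component, ages)
  Lp <- component_functional(surv$p_component, periods)
  Lt <- component_functional(surv$t_component, 0:t_max)

  use_lfun <- !is.null(inc$lfun)
  inc_var <- matrix(0, A, P)
  if (use_lfun) {
    WL <- matrix(0, A * P, ncol(inc$lfun$L))   # accumulated APC functional
    WJ <- matrix(0, A * P, ncol(inc$lfun$J))   # accumulated joinpoint functional
  }
  Gacc <- array(0, c(A, P, npar))       # gradient of xi wrt hazard coefs
  cumg <- array(0, c(A, P, npar))       # grad of -log S(i) per source cell
  for (i in 0:t_max) {
    h_i <- matrix(hazard_eval(surv, rep(ages, P), rep(periods, each = A), i),
                  A, P)
    r <- h_i / (1 - h_i)
    cumg[, , ix$nu] <- cumg[, , ix$nu] + r
    for (k in seq_along(ix$t))
      cumg[, , ix$t[k]] <- cumg[, , ix$t[k]] + r * Lt[i + 1L, k]
    for (k in seq_along(ix$a))
      cumg[, , ix$a[k]] <- cumg[, , ix$a[k]] + r * La[, k]
    for (k in seq_along(ix$p))
      cumg[, , ix$p[k]] <- cumg[, , ix$p[k]] + r * rep(Lp[, k], each = A)
    src_a <- seq_len(A - i); src_p <- seq_len(P - i)
    dst_a <- src_a + i; dst_p <- src_p + i
    contrib <- lam[src_a, src_p, drop = FALSE] * S[src_a, src_p, i + 1L]
    if (use_lfun) {
      src_cells <- as.vector(outer(src_a, (src_p - 1L) * A, `+`))
      dst_cells <- as.vector(outer(dst_a, (dst_p - 1L) * A, `+`))
      WL[dst_cells, ] <- WL[dst_cells, ] +
        as.vector(contrib) * inc$lfun$L[src_cells, , drop = FALSE]
      WJ[dst_cells, ] <- WJ[dst_cells, ] +
        as.vector(contrib) * inc$lfun$J[src_cells, , drop = FALSE]
    } else {
      inc_var[dst_a, dst_p] <- inc_var[dst_a, dst_p] +
        contrib^2 * lv[src_a, src_p, drop = FALSE]
    }
    for (k in seq_len(npar))
      Gacc[dst_a, dst_p, k] <- Gacc[dst_a, dst_p, k] -
        contrib * cumg[src_a, src_p, k]
  }
  if (use_lfun)
    inc_var <- matrix(rowSums((WL %*% inc$lfun$param_cov) * WL) +
                        rowSums((WJ %*% inc$lfun$trend_cov) * WJ), A, P)
  G <- matrix(Gacc, A * P, npar)
  surv_var <- matrix(rowSums((G %*% surv$coef_cov) * G), A, P)
  dimnames(inc_var) <- dimnames(surv_var) <- list(age = ages, period = periods)
  list(inc_var = inc_var, surv_var = surv_var, total = inc_var + surv_var)
}

#' Parametric-bootstrap covariance of prevalence rates
#'
#' Propagates incidence sampling uncertainty into the prevalence estimates:
#' each replicate samples case counts `Y* ~ Poisson(lambda * O)` cell-wise
#' on the extended grid, forms replicate rates `lambda* = Y* / O`, re-runs
#' the convolution against the fixed survival model, and the covariance is
#' the sample covariance of the flattened replicate prevalence matrices.
#' The survival fit is held fixed throughout, exactly as in the procedure
#' this implements; survival-parameter uncertainty is not included.
#'
#' @param lambda_hat ages x periods matrix of incidence rates on the
#'   extended grid (e.g. `forecast$rates`).
#' @param offsets strictly positive person-years matrix of the same shape.
#' @param surv hazard model (as in [prevalence_rates()]).
#' @param t_max survivorship window.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed; same seed gives bit-identical results.
#' @param ages,periods axis labels (taken from `lambda_hat` dimnames or a
#'   `rate_forecast` when omitted).
#' @param full_cov keep the AP x AP covariance matrix (default TRUE).
#' @param survival_method `"product"` or `"exp"`.
#' @return list with `cell_var` (ages x periods matrix of bootstrap
#'   variances) and, if requested, `cov` (AP x AP covariance of
#'   `as.vector(xi)`), plus `B` and `seed`.
#' @export
bootstrap_covariance <- function(lambda_hat, offsets, surv, t_max, B = 2000,
                                 seed = 1, ages = NULL, periods = NULL,
                                 full_cov = TRUE,
                                 survival_method = c("product", "exp")) {
  survival_method <- match.arg(survival_method)
  if (inherits(lambda_hat, "rate_forecast")) {
    ages <- ages %||% lambda_hat$ages
    periods <- periods %||% lambda_hat$periods
    lambda_hat <- lambda_hat$rates
  }
  lambda_hat <- as.matrix(lambda_hat); offsets <- as.matrix(offsets)
  stopifnot(identical(dim(lambda_hat), dim(offsets)))
  if (any(offsets <= 0)) stop_("offsets must be strictly positive")
  mu <- lambda_hat * offsets
  if (any(!is.finite(mu)) || any(mu < 0))
    stop_("lambda * O must be finite and non-negative")
  check_number(B, "B", min = 2, integer = TRUE)
  A <- nrow(lambda_hat); P <- ncol(lambda_hat)
  ages <- ages %||% as.numeric(rownames(lambda_hat) %||% seq_len(A))
  periods <- periods %||% as.numeric(colnames(lambda_hat) %||% seq_len(P))

  S <- survival_array(surv, ages, periods, t_max, survival_method)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))

  reps <- matrix(0, A * P, B)
  for (b in seq_len(B)) {
    lam_b <- matrix(stats::rpois(A * P, mu), A, P) / offsets
    reps[, b] <- as.vector(convolve_prevalence(lam_b, S, t_max))
  }
  m <- rowMeans(reps)
  centered <- reps - m
  cell_var <- matrix(rowSums(centered^2) / (B - 1), A, P,
                     dimnames = list(age = ages, period = periods))
  out <- list(cell_var = cell_var, B = B, seed = seed)
  if (full_cov) out$cov <- tcrossprod(centered) / (B - 1)
  out
}
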