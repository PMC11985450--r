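#' Convert rates into population case counts
#'
#' Multiplies estimated or forecast rates by population person-years to give
#' expected annual incident case counts (burden) or the number of people
#' living with a diagnosis within the last `T` years (survivorship).
#' Population projections enter as constants: count variances are
#' `pop^2 * var(rate)` cell-wise, and group totals propagate either
#' independently-summed cell variances or, when a full rate covariance is
#' supplied, the exact `w' Sigma w` with `w` the population weights.
#'
#' @param rates ages x periods matrix of rates (or a `rate_forecast` /
#'   `prevalence_est`, from which rates, variances and the grid are taken).
#' @param var per-cell rate variances (matrix like `rates`), or `NULL`.
#' @param pop a [population_table()] (may extend beyond the rate grid; the
#'   overlap is used) or a matrix aligned with `rates`.
#' @param groups optional named list of age-index vectors; per-period group
#'   totals and their variances are then reported as well.
#' @param full_cov optional AP x AP covariance of `as.vector(rates)` used
#'   for group-total variances.
#' @return object of class `count_forecast`: `counts` and `var` matrices,
#'   and (when `groups` given) a data frame `group_totals` with columns
#'   `group`, `period`, `count`, `var`.
#' @export
apply_population <- function(rates, var = NULL, pop, groups = NULL,
                             full_cov = NULL) {
  if (inherits(rates, "rate_forecast")) {
    fc <- rates
    rates <- fc$rates
    if (is.null(var)) var <- fc$rates^2 * fc$log_var  # delta method from log scale
    ages <- fc$ages; periods <- fc$periods
  } else if (inherits(rates, "prevalence_est")) {
    pe <- rates
    rates <- pe$xi
    if (is.null(var)) var <- pe$cell_var
    ages <- pe$ages; periods <- pe$periods
  } else {
    rates <- as.matrix(rates)
    ages <- as.numeric(rownames(rates) %||% seq_len(nrow(rates)))
    periods <- as.numeric(colnames(rates) %||% seq_len(ncol(rates)))
  }
  if (inherits(pop, "population_table")) {
    ai <- match(ages, pop$ages); pj <- match(periods, pop$periods)
    if (anyNA(ai) || anyNA(pj))
      stop_("population grid does not cover the rate grid (ages %s, periods %s)",
            fmt_vec(range(ages)), fmt_vec(range(periods)))
    popm <- pop$counts[ai, pj, drop = FALSE]
  } else {
    popm <- as.matrix(pop)
    if (!identical(dim(popm), dim(rates)))
      stop_("population matrix (%dx%d) does not match the rate grid (%dx%d)",
            nrow(popm), ncol(popm), nrow(rates), ncol(rates))
  }
  counts <- rates * popm
  cvar <- if (!is.null(var)) as.matrix(var) * popm^2 else NULL
  dimnames(counts) <- list(age = ages, period = periods)
  if (!is.null(cvar)) dimnames(cvar) <- dimnames(counts)

  group_totals <- NULL
  if (!is.null(groups)) {
    if (is.null(names(groups)))
      names(groups) <- paste0("group", seq_along(groups))
    A <- nrow(counts); P <- ncol(counts)
    rowsets <- lapply(groups, function(g) {
      if (length(g) == 0L) stop_("empty age group")
      if (any(g < 1 | g > A)) stop_("age group indices out of range")
      g
    })
    res <- list()
    for (g in names(rowsets)) {
      rows <- rowsets[[g]]
      tot <- colSums(counts[rows, , drop = FALSE])
      v <- rep(NA_real_, P)
      for (j in seq_len(P)) {
        w <- popm[rows, j]
        if (!is.null(full_cov)) {
          cells <- rows + (j - 1L) * A
          v[j] <- drop(t(w) %*% full_cov[cells, cells, drop = FALSE] %*% w)
        } else if (!is.null(var)) {
          v[j] <- sum(w^2 * as.matrix(var)[rows, j])
        }
      }
      res[[g]] <- data.frame(group = g, period = periods, count = tot, var = v)
    }
    group_totals <- do.call(rbind, res)
    rownames(group_totals) <- NULL
  }
  structure(list(counts = counts, var = cvar, group_totals = group_totals),
            class = "count_forecast")
}

#' @export
print.count_forecast <- function(x, ...) {
  cat(sprintf("Count forecast: %d ages x %d periods; total %s expected cases\n",
              nrow(x$counts), ncol(x$counts),
              format(round(sum(x$counts)), big.mark = ",")))
  if (!is.null(x$group_totals))
    cat(sprintf("  %d group series attached\n",
                length(unique(x$group_totals$group))))
  invisible(x)
}
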