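#' Lexis diagram of case counts and person-years
#'
#' Bundles an age-by-period matrix of case counts `Y` with the matching
#' person-years offsets `O` on a common grid.  Rows are age groups labelled by
#' the lower bound of each bin, columns are calendar periods labelled by the
#' period start; bins are half-open `[start, start + delta)` and the bin width
#' `delta` must be shared by the two axes so that birth cohorts run along the
#' diagonals, indexed by `c = p - a`.
#'
#' @param cases non-negative integer matrix of case counts (ages x periods).
#' @param offsets strictly positive matrix of person-years, same shape.
#' @param age_start lower bound of the first age bin, in years.
#' @param period_start first calendar period (bin start).
#' @param delta common bin width in years (default 1).
#' @return An object of class `lexis` with elements `cases`, `offsets`,
#'   `ages`, `periods`, `cohorts` (the `A + P - 1` diagonal labels), and
#'   `delta`.
#' @seealso [read_rate_matrix()] to build one from CSV files, [fit_apc()].
#' @examples
#' lx <- lexis_diagram(matrix(5, 4, 6), matrix(1e5, 4, 6),
#'                     age_start = 40, period_start = 2000)
#' lx
#' @export
lexis_diagram <- function(cases, offsets, age_start, period_start, delta = 1) {
  cases <- as.matrix(cases); offsets <- as.matrix(offsets)
  if (!identical(dim(cases), dim(offsets)))
    stop_("cases (%dx%d) and offsets (%dx%d) must have identical shape",
          nrow(cases), ncol(cases), nrow(offsets), ncol(offsets))
  if (any(!is.finite(cases)) || any(cases < 0))
    stop_("case counts must be finite and non-negative")
  if (any(!is.finite(offsets)) || any(offsets <= 0))
    stop_("offsets (person-years) must be finite and strictly positive")
  check_number(delta, "delta", min = .Machine$double.eps)
  A <- nrow(cases); P <- ncol(cases)
  ages <- age_start + delta * (seq_len(A) - 1L)
  periods <- period_start + delta * (seq_len(P) - 1L)
  cohorts <- seq(periods[1] - ages[A], periods[P] - ages[1], by = delta)
  dimnames(cases) <- dimnames(offsets) <- list(age = ages, period = periods)
  structure(list(cases = cases, offsets = offsets, ages = ages,
                 periods = periods, cohorts = cohorts, delta = delta),
            class = "lexis")
}

#' @export
print.lexis <- function(x, ...) {
  cat(sprintf("Lexis diagram: %d age groups x %d periods (delta = %g)\n",
              length(x$ages), length(x$periods), x$delta))
  cat(sprintf("  ages    %g-%g, periods %g-%g, %d birth cohorts (%g-%g)\n",
              min(x$ages), max(x$ages) + x$delta,
              min(x$periods), max(x$periods) + x$delta,
              length(x$cohorts), min(x$cohorts), max(x$cohorts)))
  cat(sprintf("  %s cases over %s person-years (crude rate %.3g)\n",
              format(sum(x$cases), big.mark = ","),
              format(sum(x$offsets), big.mark = ","),
              sum(x$cases) / sum(x$offsets)))
  invisible(x)
}

#' Observed rates of a Lexis diagram
#'
#' @param lexis a [lexis_diagram()].
#' @return matrix of observed rates `Y / O`.
#' @export
observed_rates <- function(lexis) {
  stopifnot(inherits(lexis, "lexis"))
  lexis$cases / lexis$offsets
}

#' Read an age-by-period rate-matrix CSV
#'
#' The expected layout is the one used throughout the package: first column
#' `age` holding age-group start values, remaining column headers holding
#' period start values, numeric body.  Both axes must be strictly increasing
#' and equally spaced with a common bin width.
#'
#' @param path CSV file path.
#' @param kind one of `"cases"`, `"offsets"`, `"population"`; recorded on the
#'   result and used for validation (`offsets`/`population` must be strictly
#'   positive, `cases` non-negative).
#' @return A `rate_matrix`: list with `values` (ages x periods matrix),
#'   `ages`, `periods`, `delta`, `kind`.
#' @seealso [write_rate_matrix()]
#' @export
read_rate_matrix <- function(path, kind = c("cases", "offsets", "population")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L || tolower(names(df)[1]) != "age")
    stop_("expected first column 'age' followed by period columns in %s", path)
  ages <- as.numeric(df[[1]])
  periods <- suppressWarnings(as.numeric(names(df)[-1]))
  if (any(is.na(periods)))
    stop_("period column headers must be numeric in %s", path)
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rate_matrix(values, ages, periods, kind)
}

# Constructor shared by the reader and the synthetic module.
rate_matrix <- function(values, ages, periods, kind) {
  da <- axis_step(ages, "age")
  dp <- axis_step(periods, "period")
  delta <- if (is.na(da)) dp else if (is.na(dp)) da else da
  if (!is.na(da) && !is.na(dp) && abs(da - dp) > 1e-8)
    stop_("age bin width (%g) and period bin width (%g) must be equal", da, dp)
  if (any(!is.finite(values))) stop_("matrix body must be numeric and finite")
  if (any(values < 0)) stop_("negative entries are not allowed")
  if (kind %in% c("offsets", "population") && any(values <= 0))
    stop_("%s must be strictly positive", kind)
  dimnames(values) <- list(age = ages, period = periods)
  structure(list(values = values, ages = ages, periods = periods,
                 delta = delta, kind = kind),
            class = "rate_matrix")
}

#' Write an age-by-period matrix CSV
#'
#' Inverse of [read_rate_matrix()]: writes the `age` column followed by one
#' column per period.
#'
#' @param x a `rate_matrix`, a `lexis` component, or a plain matrix (then
#'   `ages` and `periods` must be supplied).
#' @param path output CSV path.
#' @param ages,periods axis labels when `x` is a bare matrix.
#' @return `path`, invisibly.
#' @export
write_rate_matrix <- function(x, path, ages = NULL, periods = NULL) {
  if (inherits(x, "rate_matrix")) {
    values <- x$values; ages <- x$ages; periods <- x$periods
  } else {
    values <- as.matrix(x)
    if (is.null(ages) || is.null(periods))
      stop_("ages and periods are required when writing a bare matrix")
  }
  df <- data.frame(age = ages, values, check.names = FALSE)
  names(df) <- c("age", periods)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Population table aligned to a rate grid
#'
#' Wraps population person-year estimates/projections on an age-by-period
#' grid; the grid may extend beyond the observed periods (e.g. census
#' projections) so that forecast rates can be converted to counts.
#'
#' @param counts strictly positive matrix (ages x periods).
#' @param age_start,period_start,delta grid metadata as in [lexis_diagram()].
#' @return object of class `population_table`.
#' @seealso [apply_population()]
#' @export
population_table <- function(counts, age_start, period_start, delta = 1) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts <= 0))
    stop_("population counts must be finite and strictly positive")
  ages <- age_start + delta * (seq_len(nrow(counts)) - 1L)
  periods <- period_start + delta * (seq_len(ncol(counts)) - 1L)
  dimnames(counts) <- list(age = ages, period = periods)
  structure(list(counts = counts, ages = ages, periods = periods, delta = delta),
            class = "population_table")
}

# Convert a rate_matrix of kind "population" to a population_table.
as_population_table <- function(x) {
  if (inherits(x, "population_table")) return(x)
  stopifnot(inherits(x, "rate_matrix"))
  population_table(x$values, x$ages[1], x$periods[1], x$delta)
}

#' Assemble a Lexis diagram from two CSV files
#'
#' @param cases_path,offsets_path paths to the case-count and person-years
#'   CSVs in the [read_rate_matrix()] layout.
#' @return a [lexis_diagram()].
#' @export
read_lexis <- function(cases_path, offsets_path) {
  y <- read_rate_matrix(cases_path, "cases")
  o <- read_rate_matrix(offsets_path, "offsets")
  if (!isTRUE(all.equal(y$ages, o$ages)) ||
      !isTRUE(all.equal(y$periods, o$periods)))
    stop_("cases and offsets files are on different grids")
  lexis_diagram(y$values, o$values, y$ages[1], y$periods[1], y$delta)
}
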