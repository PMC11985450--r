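#' Tabulate a case listing into survivorship arrays
#'
#' Converts an individual-level (or weighted pre-aggregated) case listing of
#' survival after diagnosis into the two three-dimensional arrays used by the
#' discrete-time hazard model: `M[a, p, t]`, the number of persons diagnosed
#' in age group `a` and period `p` still at risk `t` periods after diagnosis,
#' and `D[a, p, t]`, the number of those dying (all causes) at follow-up time
#' `t`.  Time `t = 0` means death in the same period as diagnosis.  Follow-up
#' is truncated at `t_max`: records exiting later are carried in `M` up to
#' `t_max` and treated as censored there.
#'
#' @param records data frame with columns `age_group_start`,
#'   `age_group_width`, `diag_year`, `exit_time` (integer periods from
#'   diagnosis to death/censoring), `died` (0/1 all-cause death indicator) and
#'   optionally `weight` (positive multiplicity, default 1).
#' @param age_starts equally spaced lower bounds of the survival age groups.
#' @param periods equally spaced diagnosis periods covered by the tabulation.
#' @param t_max maximum follow-up time `T` (periods).
#' @param outside how to treat records outside the stated grid: `"error"`
#'   (default) or `"skip"` (drop with a message).
#' @return object of class `survarray`: list with 3-d arrays `at_risk` and
#'   `deaths` (dims age x period x time, time `0..t_max`), plus axis metadata
#'   `age_starts`, `age_width`, `periods`, `delta`, `t_max`.
#' @examples
#' rec <- data.frame(age_group_start = 50, age_group_width = 5,
#'                   diag_year = 2000, exit_time = 2, died = 1)
#' sv <- tabulate_survivorship(rec, age_starts = 50, periods = 2000:2002,
#'                             t_max = 5)
#' sv$at_risk[1, 1, ]  # at risk through t = 2
#' @export
tabulate_survivorship <- function(records, age_starts, periods, t_max,
                                  outside = c("error", "skip")) {
  outside <- match.arg(outside)
  check_number(t_max, "t_max", min = 0, integer = TRUE)
  need <- c("age_group_start", "age_group_width", "diag_year", "exit_time", "died")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop_("records is missing columns: %s", paste(miss, collapse = ", "))
  w <- records$weight %||% rep(1, nrow(records))
  if (any(w <= 0)) stop_("weights must be positive")
  if (any(records$exit_time < 0)) stop_("exit_time must be >= 0")
  if (!all(records$died %in% c(0, 1))) stop_("died must be 0 or 1")

  age_width <- axis_step(age_starts, "survival age")
  if (is.na(age_width)) age_width <- unique(records$age_group_width)[1]
  delta <- axis_step(periods, "survival period")
  if (is.na(delta)) delta <- 1
  wdth <- unique(records$age_group_width)
  if (length(wdth) > 1L) stop_("records mix several age_group_width values")
  if (length(age_starts) > 1L && abs(wdth - age_width) > 1e-8)
    stop_("age_group_width (%g) does not match the age_starts spacing (%g)",
          wdth, age_width)

  ai <- match(records$age_group_start, age_starts)
  pi <- match(records$diag_year, periods)
  bad <- is.na(ai) | is.na(pi)
  if (any(bad)) {
    if (outside == "error")
      stop_("%d record(s) fall outside the tabulation grid (first: age %g, year %g)",
            sum(bad), records$age_group_start[which(bad)[1]],
            records$diag_year[which(bad)[1]])
    message(sprintf("tabulate_survivorship: skipping %d record(s) outside the grid",
                    sum(bad)))
    records <- records[!bad, , drop = FALSE]
    ai <- ai[!bad]; pi <- pi[!bad]; w <- w[!bad]
  }

  A <- length(age_starts); P <- length(periods); TT <- t_max + 1L
  M <- array(0, dim = c(A, P, TT),
             dimnames = list(age = age_starts, period = periods, t = 0:t_max))
  D <- array(0, dim = dim(M), dimnames = dimnames(M))

  exit <- pmin(records$exit_time, t_max)
  died <- ifelse(records$exit_time > t_max, 0, records$died)  # censored at t_max
  for (r in seq_along(ai)) {
    tt <- 0:exit[r] + 1L
    M[ai[r], pi[r], tt] <- M[ai[r], pi[r], tt] + w[r]
    if (died[r] == 1)
      D[ai[r], pi[r], exit[r] + 1L] <- D[ai[r], pi[r], exit[r] + 1L] + w[r]
  }
  structure(list(at_risk = M, deaths = D, age_starts = age_starts,
                 age_width = age_width, periods = periods, delta = delta,
                 t_max = t_max),
            class = "survarray")
}

#' @export
print.survarray <- function(x, ...) {
  cat(sprintf("Survivorship arrays: %d age groups (width %g) x %d periods x t = 0..%d\n",
              length(x$age_starts), x$age_width, length(x$periods), x$t_max))
  cat(sprintf("  diagnosed: %s  deaths within window: %s\n",
              format(sum(x$at_risk[, , 1]), big.mark = ","),
              format(sum(x$deaths), big.mark = ",")))
  invisible(x)
}

#' Write / read survivorship arrays as long-format CSV
#'
#' Columns `age`, `period`, `t`, `at_risk`, `deaths`; one row per cell.
#'
#' @param surv a `survarray`.
#' @param path CSV path.
#' @return `path` (write) or a `survarray` (read).
#' @export
write_survivorship <- function(surv, path) {
  stopifnot(inherits(surv, "survarray"))
  g <- expand.grid(age = surv$age_starts, period = surv$periods, t = 0:surv$t_max)
  g$at_risk <- as.vector(surv$at_risk)
  g$deaths <- as.vector(surv$deaths)
  utils::write.csv(g, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survivorship
#' @param age_width width of the survival age groups (read only).
#' @export
read_survivorship <- function(path, age_width = NULL) {
  df <- utils::read.csv(path)
  need <- c("age", "period", "t", "at_risk", "deaths")
  if (!all(need %in% names(df)))
    stop_("expected columns %s in %s", paste(need, collapse = ", "), path)
  ages <- sort(unique(df$age)); periods <- sort(unique(df$period))
  tmax <- max(df$t)
  M <- array(0, dim = c(length(ages), length(periods), tmax + 1L),
             dimnames = list(age = ages, period = periods, t = 0:tmax))
  D <- array(0, dim = dim(M), dimnames = dimnames(M))
  idx <- cbind(match(df$age, ages), match(df$period, periods), df$t + 1L)
  M[idx] <- df$at_risk
  D[idx] <- df$deaths
  aw <- age_width %||% axis_step(ages, "survival age")
  if (is.na(aw)) aw <- 1
  dl <- axis_step(periods, "survival period"); if (is.na(dl)) dl <- 1
  structure(list(at_risk = M, deaths = D, age_starts = ages, age_width = aw,
                 periods = periods, delta = dl, t_max = tmax),
            class = "survarray")
}
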