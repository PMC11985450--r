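# Reproducible end-to-end runs from a single configuration, wiring the
# modules together: simulate -> fit-incidence -> forecast-incidence ->
# fit-survival -> prevalence -> counts.  A thin command-line wrapper over
# apc_run() ships in inst/cli/apcprev.R.

default_run_config <- function() {
  list(
    seed = 1,
    out_dir = "apcprev-run",
    inputs = list(cases = NULL, offsets = NULL, survivorship = NULL,
                  population = NULL),
    model = list(family = "poisson", engine = "irls"),
    forecast = list(form = "AC", third = "none", rr_extrap = "linear",
                    h_fwd = 10, h_back = 10, max_knots = 3, min_seg = 3,
                    ci_mode = "mean_var", scale_factor = 1),
    survival = list(method = "joinpoint", t_max = 10),
    bootstrap = list(B = 0),
    synthetic = list()
  )
}

#' Read, merge and validate a run configuration
#'
#' Configurations are YAML files whose keys mirror [default_run_config()]
#' (any subset; unknown keys are rejected so typos fail loudly).  Values
#' given in `overrides` win over the file, which wins over the defaults.
#'
#' @param path YAML file path, or `NULL` for defaults only.
#' @param overrides named list of overrides (e.g. from command-line flags).
#' @return validated configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  merge_into <- function(base, new, where) {
    for (nm in names(new)) {
      if (!nm %in% names(base))
        stop_("unknown config key '%s%s'", where, nm)
      if (is.list(base[[nm]]) && length(base[[nm]]) == 0)
        base[[nm]] <- as.list(new[[nm]])      # free-form section (synthetic)
      else if (is.list(base[[nm]]))
        base[[nm]] <- merge_into(base[[nm]], as.list(new[[nm]]),
                                 paste0(where, nm, "."))
      else base[[nm]] <- new[[nm]]
    }
    base
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop_("config file not found: %s", path)
    cfg <- merge_into(cfg, yaml::read_yaml(path), "")
  }
  if (length(overrides)) cfg <- merge_into(cfg, overrides, "")
  cfg
}

#' Run a pipeline command
#'
#' Executes one of the pipeline stages against a configuration, writing
#' tabular outputs, a run log and a machine-readable manifest (the fully
#' merged configuration plus package version and seed) into
#' `config$out_dir`, so any output directory is sufficient to re-execute
#' the run.
#'
#' Commands: `"simulate"` (write synthetic inputs from the `synthetic`
#' config), `"fit-incidence"`, `"forecast-incidence"`, `"fit-survival"`,
#' `"prevalence"`, `"counts"`, or `"all"` (the full chain; with no declared
#' inputs it runs on freshly simulated data).
#'
#' @param command one of the commands above.
#' @param config a configuration list from [read_run_config()], or a YAML
#'   path.
#' @return named list of the objects produced (invisibly for `"all"`).
#' @export
apc_run <- function(command = c("all", "simulate", "fit-incidence",
                                "forecast-incidence", "fit-survival",
                                "prevalence", "counts"),
                    config = read_run_config()) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat(sprintf("apcprev %s | command %s | seed %d | %s\n",
              as.character(utils::packageVersion("apcprev")), command,
              config$seed, format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file = log_path)
  jsonlite::write_json(c(list(package = "apcprev",
                              version = as.character(utils::packageVersion("apcprev")),
                              command = command), config),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)

  truth <- do.call(truth_spec, config$synthetic)
  out <- list()

  get_lexis <- function() {
    if (!is.null(config$inputs$cases))
      read_lexis(config$inputs$cases, config$inputs$offsets)
    else generate_lexis(truth, seed = config$seed)
  }
  get_surv <- function() {
    if (!is.null(config$inputs$survivorship))
      read_survivorship(config$inputs$survivorship)
    else {
      rec <- generate_case_listing(truth, seed = config$seed + 1L)
      w <- truth$surv_age_width / truth$delta
      tabulate_survivorship(rec,
                            age_starts = truth$ages[seq(1, length(truth$ages), by = w)],
                            periods = truth$periods,
                            t_max = config$survival$t_max)
    }
  }

  if (command %in% c("simulate", "all") && is.null(config$inputs$cases)) {
    lx <- generate_lexis(truth, seed = config$seed)
    write_rate_matrix(lx$cases, file.path(config$out_dir, "cases.csv"),
                      lx$ages, lx$periods)
    write_rate_matrix(lx$offsets, file.path(config$out_dir, "offsets.csv"),
                      lx$ages, lx$periods)
    logf("simulate: wrote %d x %d Lexis diagram (%d cases)",
         nrow(lx$cases), ncol(lx$cases), sum(lx$cases))
    out$lexis <- lx
    if (command == "simulate") return(out)
  }

  lx <- out$lexis %||% get_lexis()
  fit <- fit_apc(lx, family = config$model$family, engine = config$model$engine)
  utils::write.csv(apc_parameter_table(fit),
                   file.path(config$out_dir, "apc_parameters.csv"),
                   row.names = FALSE)
  logf("fit-incidence: net drift %.5f (se %.5f), dispersion %.3f",
       fit$net_drift, sqrt(fit$param_cov[3, 3]), fit$dispersion)
  out$fit <- fit
  if (command == "fit-incidence") return(out)

  if (command %in% c("forecast-incidence", "prevalence", "counts", "all")) {
    fc <- forecast_incidence(fit,
                             h_fwd = config$forecast$h_fwd,
                             h_back = config$forecast$h_back,
                             form = config$forecast$form,
                             third = config$forecast$third,
                             rr_extrap = config$forecast$rr_extrap,
                             max_knots = config$forecast$max_knots,
                             min_seg = config$forecast$min_seg)
    if (config$forecast$scale_factor != 1) {
      tr <- scale_slope(fc$trend, config$forecast$scale_factor, side = "both")
      fc <- forecast_incidence(fit,
                               h_fwd = config$forecast$h_fwd,
                               h_back = config$forecast$h_back,
                               form = config$forecast$form,
                               third = config$forecast$third,
                               crr_trend = if (config$forecast$form == "AC") tr,
                               prr_trend = if (config$forecast$form == "AP") tr)
    }
    write_forecast(fc, file.path(config$out_dir, "incidence_forecast.csv"))
    logf("forecast-incidence: %s form, knots at [%s], mask: %s",
         fc$provenance$form, fmt_vec(fc$provenance$trend_knots),
         paste(sprintf("%s=%d", names(table(fc$mask)), table(fc$mask)),
               collapse = " "))
    out$forecast <- fc
    if (command == "forecast-incidence") return(out)
  }

  if (command %in% c("fit-survival", "prevalence", "counts", "all")) {
    sv <- get_surv()
    hz <- fit_hazard(sv, method = config$survival$method)
    utils::write.csv(hazard_component_table(hz),
                     file.path(config$out_dir, "hazard_components.csv"),
                     row.names = FALSE)
    logf("fit-survival: nu0 %.4f, period slope %+.5f",
         hz$nu0, hazard_terminal_slope(hz, "period")["slope"])
    out$hazard <- hz
    if (command == "fit-survival") return(out)
  }

  if (command %in% c("prevalence", "counts", "all")) {
    prev <- prevalence_rates(out$forecast, out$hazard,
                             t_max = config$survival$t_max)
    if (config$bootstrap$B >= 2) {
      Oe <- offset_matrix(truth, out$forecast$periods)
      bs <- bootstrap_covariance(out$forecast, Oe, out$hazard,
                                 t_max = config$survival$t_max,
                                 B = config$bootstrap$B,
                                 seed = config$seed + 2L, full_cov = FALSE)
      prev$cell_var <- bs$cell_var
    }
    g <- expand.grid(age = prev$ages, period = prev$periods)
    g$xi <- as.vector(prev$xi)
    g$var <- if (!is.null(prev$cell_var)) as.vector(prev$cell_var) else NA
    g$complete <- as.vector(prev$complete_mask)
    utils::write.csv(g, file.path(config$out_dir, "prevalence.csv"),
                     row.names = FALSE)
    logf("prevalence: %d complete cells, xi range %.3g-%.3g",
         sum(prev$complete_mask), min(prev$xi), max(prev$xi))
    out$prevalence <- prev
    if (command == "prevalence") return(out)
  }

  if (command %in% c("counts", "all")) {
    pop <- if (!is.null(config$inputs$population))
      as_population_table(read_rate_matrix(config$inputs$population, "population"))
    else population_table(offset_matrix(truth), truth$ages[1],
                          truth$periods[1], truth$delta)
    pj <- intersect(out$prevalence$periods, pop$periods)
    keep <- match(pj, out$prevalence$periods)
    cnt <- apply_population(out$prevalence$xi[, keep, drop = FALSE],
                            var = out$prevalence$cell_var[, keep],
                            pop = pop$counts[, match(pj, pop$periods), drop = FALSE])
    utils::write.csv(data.frame(expand.grid(age = out$prevalence$ages, period = pj),
                                count = as.vector(cnt$counts)),
                     file.path(config$out_dir, "survivorship_counts.csv"),
                     row.names = FALSE)
    logf("counts: total survivorship %0.f in final period",
         sum(cnt$counts[, ncol(cnt$counts)]))
    out$counts <- cnt
  }
  invisible(out)
}
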