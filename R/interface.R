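# Configuration handling and the reproducible simulate / generate / fit
# pipeline.  A run is described by one YAML file; every output file embeds
# the config MD5 for provenance.

#' Read and validate a run configuration
#'
#' The YAML config describes a scenario either by `fixture` (a
#' [builtin_fixtures()] name) or by explicit `params`, `optics` and
#' `schedule` blocks, plus optional `sample_days`, `noise` and `fit`
#' blocks.  Units follow the reporting conventions: vessel radius in cm
#' (`optics$radius_cm`), nitrate in mg/L, light in umol m^-2 s^-1 -- the
#' field names carry the units so cm/m and mg/g mix-ups fail loudly.
#'
#' @param path Path to a YAML file.
#' @return A validated config object of class `moss_config` with resolved
#'   `params`, `optics`, `schedule` and the raw blocks; the file's MD5 is
#'   attached as attribute `md5`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  cfg <- validate_config(raw)
  attr(cfg, "md5") <- unname(tools::md5sum(path))
  cfg
}

#' @rdname read_run_config
#' @param config A raw config list (as parsed from YAML).
#' @export
validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a mapping", call. = FALSE)
  fixture <- NULL
  if (!is.null(config$fixture)) {
    fx <- builtin_fixtures()
    if (!config$fixture %in% names(fx)) {
      stop(sprintf("config field 'fixture': unknown fixture '%s' (known: %s)",
                   config$fixture, paste(names(fx), collapse = ", ")),
           call. = FALSE)
    }
    fixture <- fx[[config$fixture]]
    params <- fixture$params
    optics <- fixture$optics
    schedule <- fixture$schedule
    sample_days <- config$sample_days %||% fixture$sampling_times
    observed <- fixture$observed
  } else {
    params <- .config_params(config$params)
    optics <- .config_optics(config$optics)
    schedule <- .config_schedule(config$schedule)
    sample_days <- config$sample_days %||% seq(0, schedule$t_end)
    observed <- config$observed %||% .OBS_VARIABLES
  }
  noise <- NULL
  if (!is.null(config$noise)) {
    nb <- config$noise
    if (is.null(nb$seed)) {
      stop("config field 'noise$seed' is required for stochastic generation",
           call. = FALSE)
    }
    cv <- nb$cv %||% 0.05
    if (is.list(cv)) cv <- unlist(cv)
    noise <- noise_model(cv = cv, replicates = nb$replicates %||% 2L,
                         seed = nb$seed)
  }
  fit <- NULL
  if (!is.null(config$fit)) {
    fb <- config$fit
    for (f in c("free", "bounds", "seed")) {
      if (is.null(fb[[f]])) {
        stop(sprintf("config field 'fit$%s' is required", f), call. = FALSE)
      }
    }
    fb$free <- unlist(fb$free)
    fb$bounds <- lapply(fb$bounds, unlist)
    miss <- setdiff(fb$free, names(fb$bounds))
    if (length(miss)) {
      stop("config field 'fit$bounds' lacks entries for: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    fb$scaling <- fb$scaling %||% "max"
    fb$settings <- fb$settings %||% list()
    fit <- fb
  }
  structure(
    list(name = config$name %||% (config$fixture %||% "run"),
         fixture = config$fixture, params = params, optics = optics,
         schedule = schedule, sample_days = sort(unique(unlist(sample_days))),
         observed = observed, noise = noise, fit = fit),
    class = "moss_config"
  )
}

.config_params <- function(block) {
  if (is.null(block)) {
    stop("config field 'params' is missing (and no 'fixture' given)",
         call. = FALSE)
  }
  for (f in c("r_X_max", "k_N", "k_I", "y_X_N")) {
    if (is.null(block[[f]])) {
      stop(sprintf("config field 'params$%s' is missing", f), call. = FALSE)
    }
  }
  as_kinetic_params(block)
}

.config_optics <- function(block) {
  if (is.null(block)) {
    stop("config field 'optics' is missing", call. = FALSE)
  }
  for (f in c("sigma_X", "radius_cm")) {
    if (is.null(block[[f]])) {
      stop(sprintf("config field 'optics$%s' is missing", f), call. = FALSE)
    }
  }
  il <- block$incident_light %||% 350
  if (is.list(il)) il <- do.call(rbind, lapply(il, as.data.frame))
  optical_geometry(sigma_X = block$sigma_X, radius_cm = block$radius_cm,
                   incident_light = il)
}

.config_schedule <- function(block) {
  if (is.null(block)) stop("config field 'schedule' is missing", call. = FALSE)
  for (f in c("mode", "t_end", "initial")) {
    if (is.null(block[[f]])) {
      stop(sprintf("config field 'schedule$%s' is missing", f), call. = FALSE)
    }
  }
  ini <- block$initial
  for (f in c("c_X", "c_N")) {
    if (is.null(ini[[f]])) {
      stop(sprintf("config field 'schedule$initial$%s' is missing", f),
           call. = FALSE)
    }
  }
  ev <- block$exchange_events
  if (!is.null(ev)) ev <- do.call(rbind, lapply(ev, as.data.frame))
  operation_schedule(
    mode = block$mode, t_end = block$t_end,
    initial = reactor_state(ini$c_X, ini$c_N, ini$c_P %||% 0, ini$V %||% 5),
    feed = block$feed, dilution = block$dilution, exchange_events = ev)
}

.config_md5 <- function(config) {
  md5 <- attr(config, "md5")
  if (!is.null(md5)) return(md5)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config)[c("name", "fixture")], tmp)
  unname(tools::md5sum(tmp))
}

.as_config <- function(config) {
  if (inherits(config, "moss_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    return(read_run_config(config))
  }
  validate_config(config)
}

#' Run a simulation from a config
#'
#' Writes `<name>_trajectory.csv` (with the config MD5 in the header) and a
#' plain-text run log recording parameters, schedule, tolerances and the
#' package version.
#'
#' @param config A config path, raw list, or `moss_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `moss_trajectory` and the file paths.
#' @export
run_simulate <- function(config, out_dir = ".") {
  cfg <- .as_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  md5 <- .config_md5(cfg)
  traj <- simulate_reactor(cfg$params, cfg$optics, cfg$schedule)
  csv <- file.path(out_dir, paste0(cfg$name, "_trajectory.csv"))
  export_trajectory(traj, csv, comments = c(
    sprintf("config_md5: %s", md5),
    sprintf("mode: %s", cfg$schedule$mode)))
  log <- file.path(out_dir, paste0(cfg$name, "_simulate.log"))
  writeLines(c(
    sprintf("mossreactor %s", as.character(utils::packageVersion("mossreactor"))),
    sprintf("config_md5: %s", md5),
    sprintf("mode: %s, t_end: %g d", cfg$schedule$mode, cfg$schedule$t_end),
    sprintf("params: %s", paste(sprintf("%s=%g", names(unclass(cfg$params)),
                                        unlist(cfg$params)), collapse = ", ")),
    sprintf("optics: sigma_X=%g m^2/g, r_R=%g m", cfg$optics$sigma_X,
            cfg$optics$r_R),
    "integrator: ode45, rtol 1e-8, atol 1e-10"), log)
  invisible(list(trajectory = traj, files = c(trajectory = csv, log = log)))
}

#' Generate synthetic observations from a config
#'
#' @inheritParams run_simulate
#' @param seed Optional override of `noise$seed`.
#' @return Invisibly, a list with the `moss_dataset` and the file path.
#' @export
run_generate <- function(config, out_dir = ".", seed = NULL) {
  cfg <- .as_config(config)
  if (is.null(cfg$noise)) {
    stop("config field 'noise' is required for generation", call. = FALSE)
  }
  if (!is.null(seed)) cfg$noise$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  md5 <- .config_md5(cfg)
  fixture <- scenario_fixture(cfg$name, cfg$params, cfg$optics, cfg$schedule,
                              cfg$sample_days, cfg$observed)
  ds <- generate_observations(fixture, cfg$noise)
  csv <- file.path(out_dir, paste0(cfg$name, "_observations.csv"))
  write_observations(ds, csv, comments = c(
    sprintf("config_md5: %s", md5),
    sprintf("seed: %d", cfg$noise$seed),
    sprintf("cv: %s", paste(sprintf("%s=%g", names(cfg$noise$cv),
                                    cfg$noise$cv), collapse = ", "))))
  invisible(list(dataset = ds, files = c(observations = csv)))
}

#' Fit kinetic parameters from a config
#'
#' Reads the observation CSV named in `fit$data` (defaults to the dataset
#' the config would generate), runs [fit_kinetics()] and writes a JSON
#' report (estimates, bounds, seed, objective, per-variable R^2) plus a
#' model-vs-data table for plotting.
#'
#' @inheritParams run_generate
#' @return Invisibly, a list with the `moss_fit` and the file paths.
#' @export
run_fit <- function(config, out_dir = ".", seed = NULL) {
  cfg <- .as_config(config)
  if (is.null(cfg$fit)) {
    stop("config field 'fit' is required", call. = FALSE)
  }
  if (!is.null(seed)) cfg$fit$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  md5 <- .config_md5(cfg)
  if (!is.null(cfg$fit$data)) {
    obs <- read_observations(cfg$fit$data)
    ds <- observed_dataset(obs, cfg$schedule, name = cfg$name)
  } else {
    if (is.null(cfg$noise)) {
      stop("config field 'fit$data' (or a 'noise' block to generate from) ",
           "is required", call. = FALSE)
    }
    fixture <- scenario_fixture(cfg$name, cfg$params, cfg$optics,
                                cfg$schedule, cfg$sample_days, cfg$observed)
    ds <- generate_observations(fixture, cfg$noise)
  }
  fit <- fit_kinetics(ds, free = cfg$fit$free, bounds = cfg$fit$bounds,
                      base_params = cfg$params, optics = cfg$optics,
                      seed = cfg$fit$seed, settings = cfg$fit$settings,
                      scaling = cfg$fit$scaling)
  json <- file.path(out_dir, paste0(cfg$name, "_fit.json"))
  report <- list(
    config_md5 = md5,
    dataset = cfg$name,
    seed = fit$seed,
    objective = fit$objective,
    scaling = fit$scaling,
    estimates = as.list(fit$estimates),
    fixed = stats::setNames(
      lapply(setdiff(names(unclass(fit$params)), fit$free),
             function(n) fit$params[[n]]),
      setdiff(names(unclass(fit$params)), fit$free)),
    bounds = fit$bounds,
    r_squared = as.list(fit$r_squared),
    population_size = fit$population_size,
    generations = fit$generations,
    converged = fit$converged
  )
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  # model-vs-data table
  times <- sort(unique(ds$data$time_d))
  traj <- simulate_reactor(fit$params, fit$optics, ds$schedule,
                           output_times = times)
  tab <- ds$data
  tab$model <- mapply(function(t, v) {
    traj[[.TRAJ_COLUMN[v]]][match(t, traj$time_d)]
  }, tab$time_d, tab$variable)
  csv <- file.path(out_dir, paste0(cfg$name, "_fitted_vs_observed.csv"))
  write_observations(tab, csv, comments = sprintf("config_md5: %s", md5))
  invisible(list(fit = fit, files = c(report = json, table = csv)))
}

#' Default recovery bounds around a parameter set
#'
#' One decade either side of the reference value for each free parameter
#' (the recovery-test protocol); a zero reference gets `c(0, small)`.
#'
#' @param params A [kinetic_params()] object (reference values).
#' @param free Parameter names.
#' @param optics Optional [optical_geometry()] for `sigma_X` bounds.
#' @param factor Bound half-width factor (default 10).
#' @return Named list of `c(lower, upper)`.
#' @export
recovery_bounds <- function(params, free, optics = NULL, factor = 10) {
  params <- as_kinetic_params(params)
  out <- lapply(free, function(nm) {
    v <- if (nm == "sigma_X") {
      if (is.null(optics)) stop("optics needed for sigma_X bounds",
                                call. = FALSE)
      optics$sigma_X
    } else params[[nm]]
    if (v == 0) c(0, 1) else c(v / factor, v * factor)
  })
  stats::setNames(out, free)
}
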