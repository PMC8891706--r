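# Generation of observation datasets with the measurement structure of the
# bioreactor study: roughly daily sampling, two replicate measurements per
# point, multiplicative noise, nitrate depletion near the end of a batch run.

#' Measurement noise model
#'
#' Independent multiplicative Gaussian noise per replicate:
#' `value * (1 + CV * z)` with `z ~ N(0,1)`, truncated at zero.
#'
#' @param cv Coefficient of variation, either a single value for all
#'   variables or a named vector over `biomass`, `nitrate`, `product`.
#'   Default 0.05 (5%).
#' @param replicates Replicate measurements per time point (default 2,
#'   mirroring duplicate determinations).
#' @param seed Integer seed.
#' @return An object of class `moss_noise`.
#' @export
noise_model <- function(cv = 0.05, replicates = 2L, seed = 1L) {
  if (length(cv) == 1L && is.null(names(cv))) {
    cv <- c(biomass = cv, nitrate = cv, product = cv)
  }
  miss <- setdiff(.OBS_VARIABLES, names(cv))
  if (length(miss)) cv[miss] <- 0.05
  cv <- cv[.OBS_VARIABLES]
  if (any(cv < 0)) stop("CV must be >= 0", call. = FALSE)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  structure(list(cv = cv, replicates = replicates, seed = as.integer(seed)),
            class = "moss_noise")
}

#' Scenario fixture
#'
#' A named, fully specified simulation scenario: kinetic parameters, optics,
#' operating schedule, sampling times and the set of observed variables.
#'
#' @param name Fixture name.
#' @param params A [kinetic_params()] object.
#' @param optics A [optical_geometry()] object.
#' @param schedule A [operation_schedule()].
#' @param sampling_times Observation times (d).
#' @param observed Variables measured in the scenario.
#' @return An object of class `moss_fixture`.
#' @export
scenario_fixture <- function(name, params, optics, schedule, sampling_times,
                             observed = c("biomass", "nitrate", "product")) {
  stopifnot(is.character(name), inherits(schedule, "moss_schedule"))
  observed <- match.arg(observed, .OBS_VARIABLES, several.ok = TRUE)
  sampling_times <- sort(unique(sampling_times))
  if (any(sampling_times < 0) || any(sampling_times > schedule$t_end)) {
    stop("sampling_times must lie within [0, t_end]", call. = FALSE)
  }
  structure(
    list(name = name, params = as_kinetic_params(params), optics = optics,
         schedule = schedule, sampling_times = sampling_times,
         observed = observed),
    class = "moss_fixture"
  )
}

#' @export
print.moss_fixture <- function(x, ...) {
  cat(sprintf("<moss_fixture> '%s' (%s, %d sampling times, observes %s)\n",
              x$name, x$schedule$mode, length(x$sampling_times),
              paste(x$observed, collapse = "/")))
  invisible(x)
}

#' Built-in scenario fixtures
#'
#' Scenarios mirroring the published bioreactor runs of the MFHR1-producing
#' Physcomitrella line B and its parental line: kinetic parameters are the
#' fitted batch/semi-continuous sets, schedules follow the reported
#' protocols (5 L batch; daily exchange of 2 L from day 6 at D = 0.4 d^-1
#' for 11 d, or 1 L from day 7 at D = 0.2 d^-1 for 10 d; fed-batch from 4 L
#' with 0.2 L/d of 5x medium at 2500 mg NO3-/L from day 7).  The parental
#' line carries no product gene, so its product terms are zero and only
#' biomass and nitrate are observed.  Initial state for every scenario:
#' 0.1 g DW/L biomass, 500 mg/L nitrate, no product.
#'
#' @return Named list of [scenario_fixture()] objects: `parental-batch`,
#'   `lineB-batch`, `lineB-semicontinuous-D0.4`, `lineB-semicontinuous-D0.2`,
#'   `lineB-fedbatch`.
#' @examples
#' builtin_fixtures()[["lineB-batch"]]$params$r_X_max  # 0.699 d^-1
#' @export
builtin_fixtures <- function() {
  init5 <- reactor_state(c_X = 0.1, c_N = 500, c_P = 0, V = 5)
  init4 <- reactor_state(c_X = 0.1, c_N = 500, c_P = 0, V = 4)
  parental <- kinetic_params(r_X_max = 0.699, k_N = 3.58, k_I = 15.01,
                             y_X_N = 9.615, r_p_max = 0, k_p = 0, k_pd = 0)
  lineB_batch <- kinetic_params(r_X_max = 0.699, k_N = 4.41, k_I = 15.29,
                                y_X_N = 7.042, r_p_max = 0.327, k_p = 1.010,
                                k_pd = 0.0801)
  lineB_semi <- kinetic_params(r_X_max = 0.647, k_N = 3.91, k_I = 16.86,
                               y_X_N = 5.050, r_p_max = 0.236, k_p = 1.545,
                               k_pd = 0.0801)
  opt_parental <- optical_geometry(sigma_X = 0.021, radius_cm = 8.75,
                                   incident_light = 350)
  opt_batch <- optical_geometry(sigma_X = 0.049, radius_cm = 8.75,
                                incident_light = 350)
  opt_semi <- optical_geometry(sigma_X = 0.044, radius_cm = 8.75,
                               incident_light = 350)
  fx <- list(
    scenario_fixture(
      "parental-batch", parental, opt_parental,
      operation_schedule("batch", t_end = 8, initial = init5),
      sampling_times = 0:8, observed = c("biomass", "nitrate")),
    scenario_fixture(
      "lineB-batch", lineB_batch, opt_batch,
      operation_schedule("batch", t_end = 8, initial = init5),
      sampling_times = 0:8),
    scenario_fixture(
      "lineB-semicontinuous-D0.4", lineB_semi, opt_semi,
      operation_schedule("semi_continuous_rate", t_end = 11, initial = init5,
                         dilution = list(start_day = 6, rate = 0.4,
                                         c_N_f = 500)),
      sampling_times = 0:11),
    scenario_fixture(
      "lineB-semicontinuous-D0.2", lineB_semi, opt_semi,
      operation_schedule("semi_continuous_rate", t_end = 10, initial = init5,
                         dilution = list(start_day = 7, rate = 0.2,
                                         c_N_f = 500)),
      sampling_times = 0:10),
    scenario_fixture(
      "lineB-fedbatch", lineB_batch, opt_batch,
      operation_schedule("fed_batch", t_end = 12, initial = init4,
                         feed = list(start_day = 7, rate = 0.2,
                                     c_N_f = 2500)),
      sampling_times = 0:12)
  )
  stats::setNames(fx, vapply(fx, `[[`, character(1), "name"))
}

#' Generate a noisy observation dataset from a fixture
#'
#' Simulates the fixture, samples the trajectory at the fixture's sampling
#' times and applies the replicate noise model.  Seeded and reproducible;
#' the session RNG state is restored on exit.
#'
#' @param fixture A [scenario_fixture()].
#' @param noise A [noise_model()].
#' @return A `moss_dataset`; the generating truth is attached as attributes
#'   `truth_params` and `truth_optics`.
#' @examples
#' ds <- generate_observations(builtin_fixtures()[["lineB-batch"]],
#'                             noise_model(cv = 0.05, replicates = 2, seed = 7))
#' head(ds$data)
#' @export
generate_observations <- function(fixture, noise = noise_model()) {
  stopifnot(inherits(fixture, "moss_fixture"), inherits(noise, "moss_noise"))
  traj <- simulate_reactor(fixture$params, fixture$optics, fixture$schedule,
                           output_times = fixture$sampling_times)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(noise$seed)
  rows <- list()
  for (v in fixture$observed) {
    true_vals <- traj[[.TRAJ_COLUMN[v]]]
    for (r in seq_len(noise$replicates)) {
      z <- stats::rnorm(length(true_vals))
      vals <- pmax(true_vals * (1 + noise$cv[[v]] * z), 0)
      rows[[paste(v, r)]] <- data.frame(
        time_d = traj$time_d, variable = v, value = vals, replicate_id = r,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$time_d, match(df$variable, .OBS_VARIABLES),
                 df$replicate_id), ]
  rownames(df) <- NULL
  ds <- observed_dataset(df, fixture$schedule, name = fixture$name)
  attr(ds, "truth_params") <- fixture$params
  attr(ds, "truth_optics") <- fixture$optics
  ds
}
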