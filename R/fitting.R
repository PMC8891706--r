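# Global least-squares estimation of the kinetic parameters from observed
# trajectories, and goodness of fit.

.OBS_VARIABLES <- c("biomass", "nitrate", "product")
.TRAJ_COLUMN <- c(biomass = "biomass_gDW_per_L",
                  nitrate = "nitrate_mg_per_L",
                  product = "product_mg_per_L")

#' Observed bioreactor dataset
#'
#' Couples long-format measurements to the operating schedule under which
#' they were taken.
#'
#' @param data Data frame with columns `time_d`, `variable` (one of
#'   `"biomass"`, `"nitrate"`, `"product"`), `value`, and optionally
#'   `replicate_id` and `sd`.
#' @param schedule The [operation_schedule()] of the run.
#' @param name Label used in reports.
#' @return An object of class `moss_dataset` with the measurement table,
#'   the schedule and the mask of observed variables.
#' @export
observed_dataset <- function(data, schedule, name = "dataset") {
  stopifnot(is.data.frame(data))
  need <- c("time_d", "variable", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("observation data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0L) stop("observation data is empty", call. = FALSE)
  bad <- setdiff(unique(data$variable), .OBS_VARIABLES)
  if (length(bad)) {
    stop(sprintf("unknown variable(s) %s; admissible names: %s",
                 paste(sQuote(bad), collapse = ", "),
                 paste(.OBS_VARIABLES, collapse = ", ")), call. = FALSE)
  }
  if (!inherits(schedule, "moss_schedule")) {
    stop("schedule must be an operation_schedule()", call. = FALSE)
  }
  if (any(data$time_d < 0) || any(data$time_d > schedule$t_end)) {
    stop("observation times must lie within [0, t_end]", call. = FALSE)
  }
  if (is.null(data$replicate_id)) data$replicate_id <- 1L
  structure(
    list(data = data, schedule = schedule, name = name,
         observed = intersect(.OBS_VARIABLES, unique(data$variable))),
    class = "moss_dataset"
  )
}

#' @export
print.moss_dataset <- function(x, ...) {
  cat(sprintf("<moss_dataset> '%s': %d observations of {%s} over %d times (%s run)\n",
              x$name, nrow(x$data), paste(x$observed, collapse = ", "),
              length(unique(x$data$time_d)), x$schedule$mode))
  invisible(x)
}

#' Write / read long-format observation CSV
#'
#' Columns `time_d`, `variable`, `value`, `replicate_id` (and `sd` when
#' present); `#`-prefixed comment lines carry provenance.
#'
#' @param dataset A `moss_dataset` (or plain data frame in the same layout).
#' @param path File path.
#' @param comments Extra provenance lines.
#' @return `path` invisibly (write); a data frame (read).
#' @export
write_observations <- function(dataset, path, comments = character()) {
  df <- if (inherits(dataset, "moss_dataset")) dataset$data else dataset
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# mossreactor observations",
               paste0("# ", comments)[seq_along(comments)]), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE,
                     col.names = TRUE, qmethod = "double")
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$variable), .OBS_VARIABLES)
  if (length(bad)) {
    stop(sprintf("unknown variable(s) %s in %s; admissible names: %s",
                 paste(sQuote(bad), collapse = ", "), path,
                 paste(.OBS_VARIABLES, collapse = ", ")), call. = FALSE)
  }
  df
}

# Lean simulator used inside the optimizer loop: the attenuation cache, the
# segment plan and the output-time layout are precomputed once per fit; per
# candidate only the light-response curve and the ODE solve are redone.
.make_fast_simulator <- function(schedule, optics, times, c_max,
                                 rtol = 1e-8, atol = 1e-10) {
  segs <- .segment_plan(optics, schedule)
  cache <- build_attenuation_cache(optics$r_R)
  c_grid <- seq(0, c_max, length.out = .PHI_GRID_N)
  I0_levels <- unique(segs$I0)
  mode_code <- switch(schedule$mode,
                      batch = 0, semi_continuous_events = 0,
                      fed_batch = 1, semi_continuous_rate = 2)
  ev <- if (schedule$mode == "semi_continuous_events") {
    schedule$exchange_events
  } else NULL
  times <- sort(unique(times))
  y0 <- with(schedule$initial, c(c_X = c_X, c_N = c_N, c_P = c_P, V = V,
                                 H_X = 0, H_P = 0))

  function(params, sigma_X = optics$sigma_X) {
    phi_by_I0 <- lapply(I0_levels, function(I0) {
      phi_grid_from_cache(cache, sigma_X, params$k_I, I0, c_grid)
    })
    names(phi_by_I0) <- as.character(I0_levels)
    y <- y0
    out <- matrix(NA_real_, nrow = length(times), ncol = 6,
                  dimnames = list(NULL, names(y0)))
    if (any(times == 0)) out[times == 0, ] <- y
    for (i in seq_len(nrow(segs))) {
      t0 <- segs$t0[i]; t1 <- segs$t1[i]
      df <- .schedule_DF(schedule, t0, y[["V"]])
      outs <- times[times > t0 & times <= t1]
      tt <- sort(unique(c(t0, outs, t1)))
      p <- .pack_parms(params, mode_code, df$D, df$F, df$c_N_f,
                       phi_by_I0[[as.character(segs$I0[i])]], c_max)
      sol <- tryCatch(
        deSolve::ode(y = y, times = tt, func = "mossreactor_derivs",
                     parms = p, dllname = "mossreactor",
                     initfunc = "mossreactor_init", method = "ode45",
                     rtol = rtol, atol = atol, maxsteps = 100000),
        warning = function(w) NULL, error = function(e) NULL)
      if (is.null(sol) || attr(sol, "istate")[1] < 0 || anyNA(sol[, -1])) {
        return(NULL)
      }
      thr <- -1e-6 * pmax(1, apply(abs(sol[, -1, drop = FALSE]), 2, max))
      if (any(sweep(sol[, -1, drop = FALSE], 2, thr, `<`))) return(NULL)
      sol[, -1][sol[, -1] < 0] <- 0
      if (length(outs)) {
        out[match(outs, times), ] <- sol[match(outs, sol[, "time"]), -1]
      }
      y <- sol[nrow(sol), -1]
      y[y < 0] <- 0
      if (!is.null(ev) && any(abs(ev$day - t1) < 1e-12)) {
        e <- ev[abs(ev$day - t1) < 1e-12, ][1, ]
        hx <- e$fraction * y[["V"]] * y[["c_X"]]
        hp <- e$fraction * y[["V"]] * y[["c_P"]]
        y[["c_X"]] <- y[["c_X"]] * (1 - e$fraction)
        y[["c_P"]] <- y[["c_P"]] * (1 - e$fraction)
        y[["c_N"]] <- y[["c_N"]] * (1 - e$fraction) +
          e$c_N_fresh * e$fraction
        y[["H_X"]] <- y[["H_X"]] + hx
        y[["H_P"]] <- y[["H_P"]] + hp
      }
    }
    out <- cbind(time = times, out)
    out
  }
}

# Residual layout for one dataset: observation rows mapped onto the rows of
# the simulated state matrix, with per-variable scales.
.residual_plan <- function(dataset, scaling) {
  df <- dataset$data
  times <- sort(unique(df$time_d))
  scale <- vapply(.OBS_VARIABLES, function(v) {
    vals <- df$value[df$variable == v]
    if (!length(vals)) return(1)
    s <- max(abs(vals))
    if (scaling == "none" || s == 0) 1 else s
  }, numeric(1))
  state_col <- c(biomass = "c_X", nitrate = "c_N", product = "c_P")
  list(times = times,
       row = match(df$time_d, times),
       state = state_col[df$variable],
       var = df$variable,
       value = df$value,
       scale = scale[df$variable])
}

#' Least-squares objective for a parameter candidate
#'
#' Simulates every dataset's schedule, reads the model at the observation
#' times (dense solver output), and returns the pooled sum of squared
#' residuals.  By default each residual is divided by the maximum absolute
#' observed value of its dataset-variable before squaring, so biomass (g/L),
#' nitrate (hundreds of mg/L) and product (tenths of mg/L) contribute on a
#' common scale; `scaling = "none"` gives the raw unweighted sum of squares.
#' An integrator failure at a candidate yields a large finite penalty rather
#' than an error.
#'
#' @param candidate Named numeric vector of parameter values to evaluate
#'   (any subset of the kinetic parameters plus `sigma_X`); the remaining
#'   parameters are taken from `base_params` / `optics`.
#' @param datasets A `moss_dataset` or list of them (joint fit).
#' @param base_params A [kinetic_params()] object with the fixed values.
#' @param optics A [optical_geometry()] object.
#' @param scaling `"max"` (default) or `"none"`.
#' @return Scalar objective value (>= 0).
#' @export
fit_objective <- function(candidate, datasets, base_params, optics,
                          scaling = c("max", "none")) {
  scaling <- match.arg(scaling)
  datasets <- .as_dataset_list(datasets)
  ctx <- .fit_context(datasets, base_params, optics, scaling)
  ctx$objective(candidate)
}

.as_dataset_list <- function(datasets) {
  if (inherits(datasets, "moss_dataset")) datasets <- list(datasets)
  if (!length(datasets) || !all(vapply(datasets, inherits, TRUE, "moss_dataset"))) {
    stop("datasets must be one or more moss_dataset objects", call. = FALSE)
  }
  datasets
}

# Shared machinery between fit_objective() and fit_kinetics(): fast
# simulators and residual plans per dataset, plus the closure evaluating a
# named candidate.
.fit_context <- function(datasets, base_params, optics, scaling,
                         y_upper = NULL) {
  base_params <- as_kinetic_params(base_params)
  y_hi <- max(base_params$y_X_N, y_upper %||% 0)
  plans <- lapply(datasets, .residual_plan, scaling = scaling)
  sims <- lapply(seq_along(datasets), function(i) {
    sch <- datasets[[i]]$schedule
    pmax_ <- base_params
    pmax_$y_X_N <- y_hi
    .make_fast_simulator(sch, optics, plans[[i]]$times,
                         c_max = .phi_c_max(pmax_, sch))
  })
  objective <- function(candidate) {
    p <- base_params
    sigma_X <- optics$sigma_X
    if (length(candidate)) {
      nm <- names(candidate)
      if (is.null(nm) || any(nm == "")) {
        stop("candidate must be a named vector", call. = FALSE)
      }
      for (j in seq_along(candidate)) {
        if (nm[j] == "sigma_X") sigma_X <- candidate[[j]]
        else if (nm[j] %in% names(p)) p[[nm[j]]] <- candidate[[j]]
        else stop("unknown parameter: ", nm[j], call. = FALSE)
      }
    }
    if (any(unlist(p) < 0) || sigma_X < 0) return(1e10)
    total <- 0
    for (i in seq_along(datasets)) {
      sim <- sims[[i]](p, sigma_X)
      if (is.null(sim)) return(1e10)
      plan <- plans[[i]]
      model <- sim[cbind(plan$row, match(plan$state, colnames(sim)))]
      total <- total + sum(((plan$value - model) / plan$scale)^2)
    }
    total
  }
  list(objective = objective, sims = sims, plans = plans,
       base_params = base_params)
}

#' Per-variable coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` per observed variable, computed on replicate
#' means against the model trajectory.  A variable whose replicate means
#' have zero variance is reported as `NA` (undefined), not 1.
#'
#' @param trajectory A `moss_trajectory` containing the observation times.
#' @param dataset A `moss_dataset`.
#' @return Named numeric vector over the observed variables.
#' @export
r_squared <- function(trajectory, dataset) {
  df <- dataset$data
  out <- vapply(dataset$observed, function(v) {
    sub <- df[df$variable == v, ]
    means <- tapply(sub$value, sub$time_d, mean)
    tt <- as.numeric(names(means))
    if (length(means) < 2L) return(NA_real_)
    idx <- vapply(tt, function(t) {
      j <- which(abs(trajectory$time_d - t) < 1e-8)
      if (!length(j)) NA_integer_ else j[1]
    }, integer(1))
    if (anyNA(idx)) {
      stop("trajectory does not contain all observation times", call. = FALSE)
    }
    yhat <- trajectory[[.TRAJ_COLUMN[v]]][idx]
    ss_tot <- sum((means - mean(means))^2)
    if (ss_tot == 0) return(NA_real_)
    1 - sum((means - yhat)^2) / ss_tot
  }, numeric(1))
  names(out) <- dataset$observed
  out
}

#' Fit kinetic parameters by differential evolution
#'
#' Bounded global least squares: [de_optimize()] minimizes [fit_objective()]
#' over the free parameters, followed (by default) by a local gradient-free
#' Nelder-Mead polish.  With the default protocol the optical parameters
#' (`sigma_X`, `k_I`) are held fixed, which avoids the confounding between
#' absorption and light affinity when light never limits strongly.
#'
#' @param datasets A `moss_dataset` or list of them (shared parameters).
#' @param free Character vector of parameter names to estimate (kinetic
#'   parameter names and/or `"sigma_X"`).
#' @param bounds Named list mapping each free parameter to `c(lower, upper)`.
#' @param base_params A [kinetic_params()] holding the fixed values (and
#'   starting scale for the free ones).
#' @param optics A [optical_geometry()] object.
#' @param seed Integer seed (mandatory; the fit is bit-reproducible).
#' @param settings Optional list overriding optimizer settings: `popsize`
#'   (members per dimension, default 15), `max_generations` (500), `tol`
#'   (1e-8), `stall_generations` (80), `mutation` (c(0.5, 1)), `crossover`
#'   (0.7), `polish` (TRUE).
#' @param scaling Residual scaling, `"max"` (default) or `"none"`.
#' @return An object of class `moss_fit`: estimated [kinetic_params()],
#'   free/fixed split, objective value, per-variable R^2 (per dataset),
#'   optimizer diagnostics, bounds and seed.
#' @export
fit_kinetics <- function(datasets, free, bounds, base_params, optics, seed,
                         settings = list(), scaling = c("max", "none")) {
  scaling <- match.arg(scaling)
  datasets <- .as_dataset_list(datasets)
  if (!length(free)) stop("no free parameters", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  miss <- setdiff(free, names(bounds))
  if (length(miss)) {
    stop("missing bounds for: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  lower <- vapply(free, function(n) bounds[[n]][1], numeric(1))
  upper <- vapply(free, function(n) bounds[[n]][2], numeric(1))
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower > upper)) {
    stop("bounds must be finite with lower <= upper", call. = FALSE)
  }
  s <- utils::modifyList(
    list(popsize = 15L, max_generations = 500L, tol = 1e-8,
         stall_generations = 80L, mutation = c(0.5, 1), crossover = 0.7,
         polish = TRUE),
    settings)

  ctx <- .fit_context(datasets, base_params, optics, scaling,
                      y_upper = if ("y_X_N" %in% free) upper[["y_X_N"]])
  fn <- function(x) ctx$objective(stats::setNames(x, free))

  de <- de_optimize(fn, lower, upper, seed = seed, popsize = s$popsize,
                    max_generations = s$max_generations, tol = s$tol,
                    stall_generations = s$stall_generations,
                    mutation = s$mutation, crossover = s$crossover)
  best <- de$par; best_val <- de$value
  if (isTRUE(s$polish) && any(upper > lower)) {
    pol <- .polish_nm(fn, best, lower, upper)
    if (pol$value <= best_val) {
      best <- pol$par; best_val <- pol$value
    }
  }
  names(best) <- free

  est_params <- ctx$base_params
  est_optics <- optics
  for (nm in free) {
    if (nm == "sigma_X") est_optics$sigma_X <- best[[nm]]
    else est_params[[nm]] <- best[[nm]]
  }

  r2 <- lapply(datasets, function(ds) {
    traj <- simulate_reactor(est_params, est_optics, ds$schedule,
                             output_times = sort(unique(ds$data$time_d)))
    r_squared(traj, ds)
  })
  names(r2) <- vapply(datasets, `[[`, character(1), "name")
  if (length(r2) == 1L) r2 <- r2[[1]]

  structure(
    list(params = est_params, optics = est_optics,
         estimates = best, free = free,
         fixed = setdiff(c(names(ctx$base_params), "sigma_X"), free),
         objective = best_val, r_squared = r2,
         seed = as.integer(seed),
         population_size = max(s$popsize * length(free), 20L),
         generations = de$generations, n_eval = de$n_eval,
         converged = de$converged, message = de$message,
         bounds = bounds[free], settings = s, scaling = scaling,
         datasets = vapply(datasets, `[[`, character(1), "name")),
    class = "moss_fit"
  )
}

#' @export
print.moss_fit <- function(x, ...) {
  cat("<moss_fit>\n")
  cat(sprintf("  datasets: %s\n", paste(x$datasets, collapse = ", ")))
  cat(sprintf("  objective: %.6g  (%s after %d generations, %d evaluations)\n",
              x$objective, x$message, x$generations, x$n_eval))
  cat("  estimates:\n")
  for (nm in x$free) {
    cat(sprintf("    %-8s = %.4g   (bounds %.4g .. %.4g)\n", nm,
                x$estimates[[nm]], x$bounds[[nm]][1], x$bounds[[nm]][2]))
  }
  r2 <- x$r_squared
  if (is.list(r2)) {
    for (nm in names(r2)) {
      cat(sprintf("  R^2 [%s]: %s\n", nm,
                  paste(sprintf("%s = %.3f", names(r2[[nm]]), r2[[nm]]),
                        collapse = ", ")))
    }
  } else {
    cat(sprintf("  R^2: %s\n",
                paste(sprintf("%s = %.3f", names(r2), r2), collapse = ", ")))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
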