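# Differential evolution (best/1/bin with dithered mutation), the global
# optimizer behind the least-squares fit.  Self-contained so the whole
# estimation pipeline is reproducible from a single integer seed.

#' Differential evolution global minimizer
#'
#' Minimizes `fn` over a box.  Strategy best/1/bin: each trial vector is the
#' current best member plus a dithered difference of two random members,
#' binomially crossed with the target (at least one coordinate always taken
#' from the mutant).  Out-of-bounds coordinates are resampled uniformly
#' between the violated bound and the best member.  Termination: population
#' collapse (standard deviation of the population objectives below
#' `tol * |mean|`), stagnation (no relative improvement of the best
#' objective larger than `tol` over `stall_generations` consecutive
#' generations), or `max_generations`.
#'
#' @param fn Objective, called with a numeric vector.
#' @param lower,upper Bound vectors (finite, `lower <= upper`).
#' @param seed Integer seed; the RNG state of the session is restored on
#'   exit.
#' @param popsize Members per free dimension (population size is
#'   `popsize * length(lower)`, at least 20).
#' @param max_generations Generation cap.
#' @param tol Relative convergence tolerance.
#' @param stall_generations Stagnation window.
#' @param mutation Dither range for the differential weight.
#' @param crossover Crossover probability CR.
#' @return List with `par`, `value`, `generations`, `n_eval`, `converged`
#'   (TRUE unless the generation cap was hit while still improving) and
#'   `message`.
#' @export
de_optimize <- function(fn, lower, upper, seed,
                        popsize = 15L, max_generations = 500L,
                        tol = 1e-8, stall_generations = 80L,
                        mutation = c(0.5, 1), crossover = 0.7) {
  d <- length(lower)
  stopifnot(length(upper) == d, d >= 1L,
            all(is.finite(lower)), all(is.finite(upper)),
            all(lower <= upper))
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  np <- max(as.integer(popsize) * d, 20L)
  span <- upper - lower
  pop <- matrix(runif(np * d), nrow = np) * rep(span, each = np) +
    rep(lower, each = np)
  energy <- apply(pop, 1L, fn)
  n_eval <- np
  best_i <- which.min(energy)
  best <- pop[best_i, ]
  best_e <- energy[best_i]

  stall <- 0L
  gen <- 0L
  msg <- "max_generations reached"
  converged <- FALSE
  while (gen < max_generations) {
    gen <- gen + 1L
    improved <- FALSE
    for (i in seq_len(np)) {
      idx <- sample.int(np, 3L)
      idx <- idx[idx != i][1:2]
      Fw <- runif(1L, mutation[1], mutation[2])
      mutant <- best + Fw * (pop[idx[1], ] - pop[idx[2], ])
      cross <- runif(d) < crossover
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      low_bad <- trial < lower
      high_bad <- trial > upper
      if (any(low_bad)) {
        trial[low_bad] <- lower[low_bad] +
          runif(sum(low_bad)) * (best[low_bad] - lower[low_bad])
      }
      if (any(high_bad)) {
        trial[high_bad] <- upper[high_bad] -
          runif(sum(high_bad)) * (upper[high_bad] - best[high_bad])
      }
      e <- fn(trial)
      n_eval <- n_eval + 1L
      if (e <= energy[i]) {
        pop[i, ] <- trial
        energy[i] <- e
        if (e < best_e) {
          if (best_e - e > tol * (abs(best_e) + tol)) improved <- TRUE
          best_e <- e
          best <- trial
        }
      }
    }
    stall <- if (improved) 0L else stall + 1L
    if (stats::sd(energy) <= tol * abs(mean(energy))) {
      msg <- "population converged"
      converged <- TRUE
      break
    }
    if (stall >= stall_generations) {
      msg <- sprintf("stagnated for %d generations", stall_generations)
      converged <- TRUE
      break
    }
  }
  list(par = best, value = best_e, generations = gen, n_eval = n_eval,
       converged = converged, message = msg)
}

# Bounded Nelder-Mead polish: coordinates are clamped to the box and a
# quadratic penalty discourages excursions, so the refined point stays
# admissible.
.polish_nm <- function(fn, par, lower, upper, maxit = 300L) {
  if (length(par) == 1L) {
    res <- stats::optim(par, fn, method = "Brent", lower = lower,
                        upper = upper, control = list(maxit = maxit))
    return(list(par = res$par, value = res$value))
  }
  pen_fn <- function(x) {
    xc <- pmin(pmax(x, lower), upper)
    excess <- sum(((x - xc) / (upper - lower + 1e-12))^2)
    fn(xc) * (1 + excess) + excess
  }
  res <- stats::optim(par, pen_fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-12))
  par2 <- pmin(pmax(res$par, lower), upper)
  list(par = par2, value = fn(par2))
}
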