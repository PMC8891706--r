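# Specific rate laws: Monod nitrate uptake, nitrate- and light-limited growth
# combined by the minimum (threshold) law, and product formation/degradation.

#' Kinetic parameter set
#'
#' The rate-law constants of the unstructured model.  The maximum specific
#' nitrate uptake rate is not an independent parameter: it is derived as
#' `r_N_max = r_X_max / y_X_N` so that growth on nitrate reproduces
#' `r_X_max * c_N / (c_N + k_N)`.
#'
#' @param r_X_max Maximum specific growth rate (d^-1).
#' @param k_N Nitrate half-saturation constant for growth (mg NO3-/L).
#' @param k_I Light half-saturation constant (umol m^-2 s^-1).
#' @param y_X_N Biomass yield on nitrate (g DW biomass per g nitrate).
#' @param r_p_max Maximum specific product formation rate (mg product per
#'   g DW per d).  Zero for lines that carry no product gene.
#' @param k_p Nitrate half-saturation constant for product synthesis (mg/L).
#' @param k_pd Specific product degradation constant (L per g DW per d).
#'
#' @return An object of class `moss_params` (named list, all fields numeric
#'   scalars).
#' @examples
#' kinetic_params(r_X_max = 0.699, k_N = 4.41, k_I = 15.29, y_X_N = 7.042,
#'                r_p_max = 0.327, k_p = 1.010, k_pd = 0.0801)
#' @export
kinetic_params <- function(r_X_max, k_N, k_I, y_X_N,
                           r_p_max = 0, k_p = 0, k_pd = 0) {
  p <- list(r_X_max = r_X_max, k_N = k_N, k_I = k_I, y_X_N = y_X_N,
            r_p_max = r_p_max, k_p = k_p, k_pd = k_pd)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("parameter '%s' must be a finite numeric scalar", nm),
           call. = FALSE)
    }
    if (v < 0) stop(sprintf("parameter '%s' must be >= 0", nm), call. = FALSE)
  }
  if (p$y_X_N <= 0) stop("y_X_N must be > 0", call. = FALSE)
  structure(p, class = "moss_params")
}

#' @export
print.moss_params <- function(x, ...) {
  cat("<moss_params>\n")
  cat(sprintf("  r_X_max: %g d^-1       k_N: %g mg/L    k_I: %g umol/(m^2 s)\n",
              x$r_X_max, x$k_N, x$k_I))
  cat(sprintf("  y_X_N:   %g g/g     r_p_max: %g mg/(g d)\n",
              x$y_X_N, x$r_p_max))
  cat(sprintf("  k_p:     %g mg/L      k_pd: %g L/(g d)\n", x$k_p, x$k_pd))
  invisible(x)
}

# Coerce a named list/vector to moss_params, filling product terms with 0.
as_kinetic_params <- function(x) {
  if (inherits(x, "moss_params")) return(x)
  x <- as.list(x)
  need <- c("r_X_max", "k_N", "k_I", "y_X_N")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("missing kinetic parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  kinetic_params(
    r_X_max = x$r_X_max, k_N = x$k_N, k_I = x$k_I, y_X_N = x$y_X_N,
    r_p_max = if (is.null(x$r_p_max)) 0 else x$r_p_max,
    k_p = if (is.null(x$k_p)) 0 else x$k_p,
    k_pd = if (is.null(x$k_pd)) 0 else x$k_pd
  )
}

#' Specific nitrate uptake rate
#'
#' Monod uptake `r_N = r_N_max * c_N / (c_N + k_N)` with
#' `r_N_max = r_X_max / y_X_N` (g nitrate per g DW per d).
#'
#' @param c_N Nitrate concentration (mg/L); may be a vector.
#' @param params A [kinetic_params()] object.
#' @return Uptake rate(s) in g nitrate per g DW per d.
#' @export
nitrate_uptake_rate <- function(c_N, params) {
  params <- as_kinetic_params(params)
  if (any(!is.finite(c_N)) || any(c_N < 0)) {
    stop("c_N must be finite and >= 0", call. = FALSE)
  }
  r_N_max <- params$r_X_max / params$y_X_N
  ifelse(c_N + params$k_N > 0, r_N_max * c_N / (c_N + params$k_N), 0)
}

#' Product formation and degradation rates
#'
#' Formation is Monod in nitrate, `r_p = r_p_max * c_N / (c_N + k_p)`;
#' degradation is first order in product, `r_p_d = k_pd * c_P`.  Both are
#' specific rates (per g DW biomass).
#'
#' @param c_N Nitrate concentration (mg/L).
#' @param c_P Intracellular product concentration (mg/L).
#' @param params A [kinetic_params()] object.
#' @return List with `r_p` and `r_p_d`, both in mg product per g DW per d.
#' @export
protein_rates <- function(c_N, c_P, params) {
  params <- as_kinetic_params(params)
  if (!is.finite(c_N) || c_N < 0) stop("c_N must be >= 0", call. = FALSE)
  if (!is.finite(c_P) || c_P < 0) stop("c_P must be >= 0", call. = FALSE)
  r_p <- if (c_N + params$k_p > 0) {
    params$r_p_max * c_N / (c_N + params$k_p)
  } else 0
  list(r_p = r_p, r_p_d = params$k_pd * c_P)
}

#' Effective specific rates under nitrate/light co-limitation
#'
#' Evaluates both limitation branches -- growth on nitrate
#' (`y_X_N * r_N(c_N)`) and the volume-averaged light-limited rate -- and
#' takes their minimum (threshold model).  When light limits, nitrate uptake
#' is slaved to growth through the yield (`r_N = r_X / y_X_N`); when nitrate
#' limits, the same identity holds by construction of the Monod branch, so
#' the yield coupling `r_X = y_X_N * r_N` is universal.
#'
#' @param c_N Nitrate (mg/L).
#' @param c_X Biomass (g DW/L).
#' @param c_P Product (mg/L).
#' @param params A [kinetic_params()] object.
#' @param optics A [optical_geometry()] object.
#' @param time Time in days (for the light schedule).
#' @return A list of class `moss_rates`: `r_X` (d^-1), `r_N`
#'   (g nitrate/g DW/d), `r_p`, `r_p_d` (mg/g DW/d) and `limiting_regime`
#'   (`"nitrate"` or `"light"`).  Ties are labelled `"nitrate"`.
#' @examples
#' p <- kinetic_params(0.699, 4.41, 15.29, 7.042, 0.327, 1.010, 0.0801)
#' opt <- optical_geometry(0.049, 8.75, 350)
#' effective_rates(c_N = 441, c_X = 0, c_P = 0, p, opt)
#' @export
effective_rates <- function(c_N, c_X, c_P, params, optics, time = 0) {
  params <- as_kinetic_params(params)
  if (!is.finite(c_X) || c_X < 0) stop("c_X must be >= 0", call. = FALSE)
  r_X_N <- params$y_X_N * nitrate_uptake_rate(c_N, params)
  r_X_I <- light_limited_growth_rate(c_X, optics, params$r_X_max,
                                     params$k_I, time)
  if (r_X_N <= r_X_I) {
    r_X <- r_X_N
    regime <- "nitrate"
  } else {
    r_X <- r_X_I
    regime <- "light"
  }
  pr <- protein_rates(c_N, c_P, params)
  structure(
    list(r_X = r_X, r_N = r_X / params$y_X_N,
         r_p = pr$r_p, r_p_d = pr$r_p_d, limiting_regime = regime),
    class = "moss_rates"
  )
}

#' Product content per gram fresh weight
#'
#' Converts an intracellular product concentration and a dry-weight biomass
#' density into specific productivity per gram fresh weight.  No default
#' FW:DW ratio is shipped -- it is culture-dependent and must be supplied
#' from own measurements.
#'
#' @param c_P Product concentration (mg/L).
#' @param c_X Biomass density (g DW/L).
#' @param fw_dw_ratio Fresh weight per dry weight (g FW / g DW).
#' @return Specific productivity in mg product per g FW (x1000 for ug/g).
#' @export
fw_specific_productivity <- function(c_P, c_X, fw_dw_ratio) {
  if (missing(fw_dw_ratio)) {
    stop("fw_dw_ratio must be supplied; no default is shipped", call. = FALSE)
  }
  stopifnot(fw_dw_ratio > 0, all(c_X > 0), all(c_P >= 0))
  c_P / (c_X * fw_dw_ratio)
}

#' Doubling time of exponential growth
#'
#' @param r Specific growth rate (d^-1).
#' @return `ln(2) / r` in days.
#' @examples
#' doubling_time(0.699)  # about one day
#' @export
doubling_time <- function(r) {
  stopifnot(is.numeric(r), all(r > 0))
  log(2) / r
}
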