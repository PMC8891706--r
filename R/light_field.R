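# Beer-Lambert light field in a side-illuminated cylindrical vessel.
#
# The vessel is treated as an infinite cylinder whose wall is homogeneously
# illuminated, so the cross-section carries all the geometry.  A point at
# distance `a` from the axis receives light from every direction theta in
# [0, pi] (symmetry halves the circle); each ray is attenuated exponentially
# along its chord from the wall to the point.

# Quadrature sizes: 64 trapezoid panels over theta, 32 Gauss-Legendre nodes
# over the radius (with the cylindrical weight a).  Both integrands are smooth.
.N_THETA_PANELS <- 64L
.N_RADIAL <- 32L

.theta_nodes <- function() seq(0, pi, length.out = .N_THETA_PANELS + 1L)

.theta_weights <- function() {
  n <- .N_THETA_PANELS + 1L
  h <- pi / .N_THETA_PANELS
  w <- rep(h, n)
  w[c(1L, n)] <- h / 2
  w
}

.radial_nodes <- function(r_R) {
  gl <- pracma::gaussLegendre(.N_RADIAL, 0, r_R)
  list(a = gl$x, w = gl$w)
}

#' Optical geometry of the photobioreactor
#'
#' Bundles the quantities that determine the internal light field: the cell
#' absorption cross-section, the vessel radius, and the incident-light
#' schedule at the wall.
#'
#' @param sigma_X Cell absorption cross-section in m^2 per g dry weight
#'   (DW).  Fitted values for Physcomitrella protonema lie around
#'   0.02--0.05 m^2/g.
#' @param radius_cm Cylinder radius in cm (as customarily reported for
#'   bench-scale vessels); converted to metres internally.
#' @param incident_light Either a single photon flux density I0 in
#'   umol m^-2 s^-1 (constant illumination), or a data frame with columns
#'   `from_day` and `I0` describing a piecewise-constant schedule; the first
#'   interval must start at day 0.
#'
#' @return An object of class `moss_optics` with fields `sigma_X` (m^2/g),
#'   `r_R` (m) and `light` (step schedule).
#' @examples
#' opt <- optical_geometry(sigma_X = 0.049, radius_cm = 8.75, incident_light = 350)
#' light_at(opt, 3)
#' @export
optical_geometry <- function(sigma_X, radius_cm, incident_light = 350) {
  stopifnot(is.numeric(sigma_X), length(sigma_X) == 1L, is.finite(sigma_X))
  if (sigma_X < 0) stop("sigma_X must be >= 0", call. = FALSE)
  stopifnot(is.numeric(radius_cm), length(radius_cm) == 1L)
  if (!is.finite(radius_cm) || radius_cm <= 0) {
    stop("radius_cm must be > 0", call. = FALSE)
  }
  light <- as_light_schedule(incident_light)
  structure(
    list(sigma_X = sigma_X, r_R = radius_cm / 100, light = light),
    class = "moss_optics"
  )
}

#' @export
print.moss_optics <- function(x, ...) {
  cat("<moss_optics>\n")
  cat(sprintf("  sigma_X: %g m^2/g DW\n", x$sigma_X))
  cat(sprintf("  r_R:     %g m (%g cm)\n", x$r_R, x$r_R * 100))
  cat("  incident light (umol m^-2 s^-1):\n")
  for (i in seq_len(nrow(x$light))) {
    cat(sprintf("    from day %g: %g\n", x$light$from_day[i], x$light$I0[i]))
  }
  invisible(x)
}

as_light_schedule <- function(incident_light) {
  if (is.numeric(incident_light) && length(incident_light) == 1L) {
    incident_light <- data.frame(from_day = 0, I0 = incident_light)
  }
  if (!is.data.frame(incident_light) ||
      !all(c("from_day", "I0") %in% names(incident_light))) {
    stop("incident_light must be a single value or a data frame with ",
         "columns 'from_day' and 'I0'", call. = FALSE)
  }
  sch <- incident_light[order(incident_light$from_day), c("from_day", "I0")]
  if (nrow(sch) < 1L || sch$from_day[1] != 0) {
    stop("incident_light schedule must start at day 0", call. = FALSE)
  }
  if (anyDuplicated(sch$from_day)) {
    stop("incident_light schedule has overlapping intervals", call. = FALSE)
  }
  if (any(sch$I0 < 0) || any(!is.finite(sch$I0))) {
    stop("I0 must be finite and >= 0 on every interval", call. = FALSE)
  }
  rownames(sch) <- NULL
  sch
}

#' Incident light at a given time
#'
#' @param optics A [optical_geometry()] object.
#' @param time Time in days.
#' @return Photon flux density I0 (umol m^-2 s^-1) at the vessel wall.
#' @export
light_at <- function(optics, time) {
  sch <- optics$light
  idx <- findInterval(time, sch$from_day)
  idx[idx < 1L] <- 1L
  sch$I0[idx]
}

#' Chord length of a light ray inside the vessel cross-section
#'
#' Distance travelled from the vessel wall to an interior point by a straight
#' ray arriving at angle `theta` (measured in the cross-sectional plane; the
#' geometry is symmetric over \[0, pi\]).  Closed form:
#' `p = -a cos(theta) + sqrt(r_R^2 - a^2 sin^2(theta))`.
#'
#' @param radial_position Distance `a` of the point from the cylinder axis (m),
#'   in \[0, r_R\].
#' @param angle Arrival angle theta in radians, in \[0, pi\].  May be a vector.
#' @param r_R Cylinder radius (m).
#' @return Path length(s) in metres, in \[0, 2 r_R\].
#' @examples
#' chord_path_length(0, 1.2, 0.0875)        # every ray travels one radius
#' chord_path_length(0.0875, pi, 0.0875)    # full diameter from the far wall
#' @export
chord_path_length <- function(radial_position, angle, r_R) {
  stopifnot(is.numeric(radial_position), is.numeric(angle), is.numeric(r_R))
  if (r_R <= 0) stop("r_R must be > 0", call. = FALSE)
  if (any(radial_position < 0) || any(radial_position > r_R)) {
    stop("radial_position must lie in [0, r_R]", call. = FALSE)
  }
  if (any(angle < 0) || any(angle > pi)) {
    stop("angle must lie in [0, pi]", call. = FALSE)
  }
  a <- radial_position
  -a * cos(angle) + sqrt(pmax(r_R^2 - (a * sin(angle))^2, 0))
}

#' Angle-averaged light intensity at a point in the vessel
#'
#' Mean Beer-Lambert-attenuated intensity over all arrival directions,
#' `(1/pi) * integral_0^pi I0 exp(-sigma_X c_X p(a, theta)) dtheta`,
#' evaluated by trapezoid quadrature.  The attenuation exponent uses the
#' biomass concentration converted from g/L to g/m^3 (factor 1000) so that
#' sigma_X (m^2/g) times concentration (g/m^3) times path (m) is
#' dimensionless.
#'
#' @param radial_position Distance from the axis (m); may be a vector.
#' @param c_X Biomass concentration (g DW/L).
#' @param optics A [optical_geometry()] object.
#' @param time Time in days (selects the incident light from the schedule).
#' @return Mean intensity (umol m^-2 s^-1), in (0, I0].
#' @examples
#' opt <- optical_geometry(0.049, 8.75, 350)
#' local_mean_intensity(0, c_X = 2, opt)     # centre of the vessel
#' local_mean_intensity(0.0875, c_X = 2, opt) # at the wall
#' @export
local_mean_intensity <- function(radial_position, c_X, optics, time = 0) {
  stopifnot(is.numeric(c_X), length(c_X) == 1L)
  if (!is.finite(c_X) || c_X < 0) stop("c_X must be >= 0", call. = FALSE)
  I0 <- light_at(optics, time)
  th <- .theta_nodes()
  wt <- .theta_weights() / pi
  s <- optics$sigma_X * c_X * 1000   # 1/m
  vapply(radial_position, function(a) {
    p <- chord_path_length(a, th, optics$r_R)
    I0 * sum(wt * exp(-s * p))
  }, numeric(1))
}

#' Volume-averaged light-limited specific growth rate
#'
#' Monod kinetics in light evaluated at the local mean intensity and averaged
#' over the vessel cross-section with the cylindrical volume element:
#' `rbar = (2/r_R^2) * integral_0^r_R r_X_max * I(a)/(I(a)+k_I) * a da`,
#' by Gauss-Legendre quadrature over the radius.
#'
#' @param c_X Biomass concentration (g DW/L).
#' @param optics A [optical_geometry()] object.
#' @param r_X_max Maximum specific growth rate (d^-1).
#' @param k_I Light half-saturation constant (umol m^-2 s^-1).
#' @param time Time in days.
#' @return Specific growth rate (d^-1), in \[0, r_X_max\]; strictly decreasing
#'   in `c_X` when `sigma_X > 0`.
#' @examples
#' opt <- optical_geometry(0.049, 8.75, 350)
#' light_limited_growth_rate(0, opt, r_X_max = 0.699, k_I = 15.29)
#' light_limited_growth_rate(3, opt, r_X_max = 0.699, k_I = 15.29)
#' @export
light_limited_growth_rate <- function(c_X, optics, r_X_max, k_I, time = 0) {
  stopifnot(r_X_max >= 0, k_I >= 0)
  if (!is.finite(c_X) || c_X < 0) stop("c_X must be >= 0", call. = FALSE)
  r_X_max * light_monod_factor(c_X, optics, k_I, time)
}

# Dimensionless volume-averaged Monod-in-light factor in (0, 1].
light_monod_factor <- function(c_X, optics, k_I, time = 0) {
  rad <- .radial_nodes(optics$r_R)
  Ibar <- local_mean_intensity(rad$a, c_X, optics, time)
  f <- if (k_I == 0) rep(1, length(Ibar)) else Ibar / (Ibar + k_I)
  (2 / optics$r_R^2) * sum(rad$w * rad$a * f)
}

# Attenuation cache for the reactor module: E[j, m] is the angle-averaged
# Beer-Lambert factor at radial node a_j for optical density s_m = sigma_X *
# 1000 * c_X (1/m).  Depends only on r_R, so one cache serves any kinetic or
# optical candidate during fitting.  s nodes are square-root-spaced (dense
# near zero where curvature is largest); evaluation interpolates linearly.
build_attenuation_cache <- function(r_R, s_max = 2500, n_s = 2400L) {
  rad <- .radial_nodes(r_R)
  th <- .theta_nodes()
  wt <- .theta_weights() / pi
  s_nodes <- s_max * seq(0, 1, length.out = n_s)^2
  P <- outer(rad$a, th, function(a, th) chord_path_length(a, th, r_R))
  E <- matrix(0, nrow = .N_RADIAL, ncol = n_s)
  for (m in seq_len(n_s)) {
    E[, m] <- exp(-s_nodes[m] * P) %*% wt
  }
  list(r_R = r_R, a = rad$a, w = rad$w, s_nodes = s_nodes, E = E,
       s_max = s_max)
}

# Volume-averaged Monod-in-light factor phi(c_X) tabulated on a uniform
# biomass grid, from the attenuation cache.  Returned as a vector ready for
# linear interpolation (used by the compiled ODE right-hand side).
phi_grid_from_cache <- function(cache, sigma_X, k_I, I0, c_grid) {
  s <- pmin(sigma_X * 1000 * c_grid, cache$s_max)
  idx <- findInterval(s, cache$s_nodes, rightmost.closed = TRUE)
  idx[idx >= length(cache$s_nodes)] <- length(cache$s_nodes) - 1L
  s0 <- cache$s_nodes[idx]
  s1 <- cache$s_nodes[idx + 1L]
  frac <- ifelse(s1 > s0, (s - s0) / (s1 - s0), 0)
  # interpolate each radial row at every grid point
  Elo <- cache$E[, idx, drop = FALSE]
  Ehi <- cache$E[, idx + 1L, drop = FALSE]
  Eint <- Elo + sweep(Ehi - Elo, 2L, frac, `*`)
  Ibar <- I0 * Eint
  f <- if (k_I == 0) (Ibar >= 0) + 0 else Ibar / (Ibar + k_I)
  as.numeric((2 / cache$r_R^2) * crossprod(cache$w * cache$a, f))
}
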