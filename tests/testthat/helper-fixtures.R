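# Shared objects for the test suite; everything is built in code.

lineB_params <- function() {
  kinetic_params(r_X_max = 0.699, k_N = 4.41, k_I = 15.29, y_X_N = 7.042,
                 r_p_max = 0.327, k_p = 1.010, k_pd = 0.0801)
}

lineB_optics <- function() {
  optical_geometry(sigma_X = 0.049, radius_cm = 8.75, incident_light = 350)
}

batch_schedule <- function(t_end = 8, c_N0 = 500) {
  operation_schedule("batch", t_end = t_end,
                     initial = reactor_state(c_X = 0.1, c_N = c_N0,
                                             c_P = 0, V = 5))
}

# Independent geometric oracle: march along the ray direction from the
# interior point and find where it crosses the circle, by root bracketing.
ray_chord_oracle <- function(a, theta, r_R) {
  f <- function(s) sqrt((a + s * cos(theta))^2 + (s * sin(theta))^2) - r_R
  stats::uniroot(f, c(0, 2 * r_R + 1e-12), tol = 1e-14)$root
}

# Stratified Monte-Carlo oracle for the angle-averaged intensity: one
# jittered ray per stratum of [0, pi].
mc_mean_intensity <- function(a, c_X, optics, n_rays = 1e6, time = 0) {
  I0 <- light_at(optics, time)
  u <- stats::runif(n_rays)
  theta <- (seq_len(n_rays) - u) / n_rays * pi
  p <- chord_path_length(a, theta, optics$r_R)
  mean(I0 * exp(-optics$sigma_X * c_X * 1000 * p))
}
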