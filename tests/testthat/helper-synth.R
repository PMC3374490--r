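# Shared fixtures: all synthetic, built in code.

default_geom <- function() shell_geometry()

default_poly_stretch <- function(scale_eq = 1.015, scale_pol = 1.012) {
  stretch_polynomial_from_affine(default_geom(), scale_eq, scale_pol)
}

# Noiseless (or noisy) synthetic eye with the default geometry/field.
quick_eye <- function(pressures = c(7, 30), n_points = 40, noise_sd = 0,
                      seed = 1L, stretch = default_poly_stretch(),
                      geom = default_geom(), eye_id = "eye1") {
  simulate_inflation(geom, stretch, pressures, n_points,
                     noise_model(noise_sd, seed), eye_id = eye_id)
}

# Region-labeled reference meridian of a synthetic eye.
ref_meridian <- function(eye) {
  pts <- trace_points_at(eye$traces, eye$pressures[1L])
  m <- parameterize_meridian(fit_ellipse(pts), pts,
                             eye_id = eye$eye_id, pressure = eye$pressures[1L])
  assign_regions(m)
}

# Points on a rotated/translated ellipse arc (exact, no noise).
ellipse_arc_points <- function(a = 2, b = 1.5, tilt = 0, center = c(0, 0),
                               nu = seq(0.2, 2.6, length.out = 40)) {
  q <- rbind(a * cos(nu), b * sin(nu))
  R <- matrix(c(cos(tilt), sin(tilt), -sin(tilt), cos(tilt)), 2L)
  sweep(t(R %*% q), 2L, center, `+`)
}

# Random physically valid quartic stretch field (deterministic in seed);
# retries with derived seeds until simulate_inflation accepts it.
random_poly_stretch <- function(geom, seed) {
  for (k in 0:19) {
    st <- with_seed(seed * 100L + k, {
      base <- stretch_polynomial_from_affine(
        geom, stats::runif(1, 1.006, 1.03), stats::runif(1, 1.005, 1.025))
      amp <- 0.1 * max(abs(base$c1))
      base$c1 <- base$c1 + stats::rnorm(5, sd = amp * c(1, 0.5, 0.2, 0.1, 0.05))
      base$c2 <- base$c2 + stats::rnorm(5, sd = amp * c(1, 0.5, 0.2, 0.1, 0.05))
      base
    })
    ok <- tryCatch({
      validate_stretch_physical(geom, st, c(7, 30), 7)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(st)
  }
  stop("could not draw a physical random stretch field")
}
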