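# Forward simulation of an inflation test with closed-form ground truth.

# Cumulative reference arc length s(t) from the first sampled angle, by fine
# trapezoidal quadrature of |X'(t)| (smooth integrand; 8001 nodes keep the
# error well below 1e-7 mm on mm-sized eyes).
ref_arclength_grid <- function(geom, t_min, t_max, n = 8001L) {
  tg <- seq(t_min, t_max, length.out = n)
  sp <- row_norm(ref_d1(geom, tg))
  h <- diff(tg)
  sg <- c(0, cumsum(h * (sp[-n] + sp[-1L]) / 2))
  list(t = tg, s = sg)
}

# Truth state at angles t for one pressure: strains, curvature radii and
# stress resultants of the prescribed map.
truth_state <- function(geom, stretch, t, p, p0) {
  w <- pressure_weight(stretch, p, p0)
  st <- deformed_state(geom, stretch, t, w)
  X1 <- geom$a * sin(t)
  lam_phi <- row_norm(st$d1) / row_norm(ref_d1(geom, t))
  lam_theta <- st$x[, 1L] / X1
  rad <- curve_radii(st$x, st$d1, st$d2)
  res <- resultants_from_radii(p, rad$r_transverse, rad$r_meridional)
  data.frame(
    t = t,
    x1_mm = st$x[, 1L], x2_mm = st$x[, 2L],
    lambda_phi = lam_phi, lambda_theta = lam_theta,
    E_phi = (lam_phi^2 - 1) / 2, E_theta = (lam_theta^2 - 1) / 2,
    r_meridional_mm = rad$r_meridional, r_transverse_mm = rad$r_transverse,
    n_phi = res$n_phi, n_theta = res$n_theta)
}

# Reject stretch fields that compress anywhere at any simulated pressure.
validate_stretch_physical <- function(geom, stretch, pressures, p0) {
  tg <- seq(geom$onh_gap_angle, pi - geom$fixture_gap_angle, length.out = 401L)
  for (p in pressures) {
    w <- pressure_weight(stretch, p, p0)
    st <- deformed_state(geom, stretch, tg, w)
    lam_phi <- row_norm(st$d1) / row_norm(ref_d1(geom, tg))
    lam_theta <- st$x[, 1L] / (geom$a * sin(tg))
    if (any(lam_phi < 1 - 1e-9) || any(lam_theta < 1 - 1e-9))
      stop(sprintf(
        "stretch field is unphysical (stretch < 1) at p = %g mmHg", p),
        call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate an inflation test on an ellipsoidal shell
#'
#' Generates noisy edge traces for one synthetic eye at a series of pressure
#' steps, together with the exact strains, curvature radii and membrane stress
#' resultants of the prescribed deformation map. The first pressure is the
#' reference pressure `P0` (deformation zero there); truth strains are
#' `E = (lambda^2 - 1) / 2` per principal direction and truth resultants come
#' from shell-of-revolution equilibrium applied to the exact deformed
#' curvatures.
#'
#' @param geometry A [shell_geometry()].
#' @param stretch A stretch field from [stretch_affine()],
#'   [stretch_polynomial()] or [stretch_polynomial_from_affine()].
#' @param pressures Ascending pressures in mmHg; the first entry is the
#'   reference pressure.
#' @param n_points Number of tracked edge points (>= 10; default 40).
#' @param noise A [noise_model()]; `noise_model(0)` gives exact traces.
#' @param eye_id Identifier used in the output tables.
#' @return An object of class `synthetic_eye` with elements `traces` (long
#'   data frame: `eye_id`, `pressure_mmHg`, `point_index`, `x_mm`, `y_mm`) and
#'   `truth` (per pressure and point: noiseless coordinates, stretches,
#'   strains, curvature radii and resultants), plus the generating objects.
#' @examples
#' eye <- simulate_inflation(shell_geometry(1.7, 1.7), stretch_affine(1.05, 1.05),
#'                           pressures = c(7, 30), noise = noise_model(0))
#' subset(eye$truth, pressure_mmHg == 30)$E_phi[1]  # (1.05^2 - 1) / 2
#' @export
simulate_inflation <- function(geometry, stretch, pressures,
                               n_points = 40L, noise = noise_model(),
                               eye_id = "eye1") {
  stopifnot(inherits(geometry, "shell_geometry"),
            inherits(stretch, "stretch_field"),
            inherits(noise, "noise_model"))
  pressures <- as.numeric(pressures)
  if (length(pressures) < 1L || any(diff(pressures) <= 0))
    stop("pressures must be strictly ascending, first = reference pressure",
         call. = FALSE)
  if (n_points < 10L) stop("n_points must be >= 10", call. = FALSE)
  p0 <- pressures[1L]
  validate_stretch_physical(geometry, stretch, pressures, p0)

  t0 <- geometry$onh_gap_angle
  t1 <- pi - geometry$fixture_gap_angle
  t <- seq(t0, t1, length.out = n_points)
  sg <- ref_arclength_grid(geometry, t0, t1)
  s_pts <- stats::approx(sg$t, sg$s, xout = t)$y

  truth <- do.call(rbind, lapply(pressures, function(p) {
    ts <- truth_state(geometry, stretch, t, p, p0)
    cbind(data.frame(eye_id = eye_id, pressure_mmHg = p,
                     point_index = seq_len(n_points), s_mm = s_pts), ts)
  }))

  sd_mm <- um_to_mm(noise$position_sd_um)
  noise_mat <- if (sd_mm > 0) {
    with_seed(noise$seed,
              matrix(stats::rnorm(2L * n_points * length(pressures), sd = sd_mm),
                     ncol = 2L))
  } else matrix(0, nrow = n_points * length(pressures), ncol = 2L)

  traces <- data.frame(
    eye_id = eye_id,
    pressure_mmHg = rep(pressures, each = n_points),
    point_index = rep(seq_len(n_points), times = length(pressures)),
    x_mm = truth$x1_mm + noise_mat[, 1L],
    y_mm = truth$x2_mm + noise_mat[, 2L])

  structure(
    list(eye_id = eye_id, traces = traces, truth = truth,
         geometry = geometry, stretch = stretch, noise = noise,
         pressures = pressures, n_points = n_points,
         arc_grid = sg),
    class = "synthetic_eye")
}

#' @export
print.synthetic_eye <- function(x, ...) {
  cat(sprintf(
    "Synthetic eye '%s': %d points, pressures %s mmHg, noise sd %.2f um\n",
    x$eye_id, x$n_points, paste(x$pressures, collapse = ", "),
    x$noise$position_sd_um))
  invisible(x)
}

#' Ground truth of a synthetic eye at arbitrary arc-length locations
#'
#' Evaluates the exact strains and stress resultants of the prescribed
#' deformation map at reference arc-length locations `s` (measured from the
#' first tracked point, on the ONH side), for comparison with pipeline
#' estimates at the same locations.
#'
#' @param eye A `synthetic_eye` from [simulate_inflation()].
#' @param pressure One of the simulated pressures (mmHg).
#' @param s Arc-length locations in mm within the sampled meridian.
#' @return Data frame with `s_mm`, `E_phi`, `E_theta`, `n_phi`, `n_theta`,
#'   curvature radii and stretches.
#' @export
truth_at <- function(eye, pressure, s) {
  stopifnot(inherits(eye, "synthetic_eye"))
  if (!any(abs(eye$pressures - pressure) < 1e-9))
    stop("pressure was not simulated", call. = FALSE)
  sg <- eye$arc_grid
  if (any(s < -1e-9) || any(s > max(sg$s) + 1e-9))
    stop("arc-length location outside the sampled meridian", call. = FALSE)
  t <- stats::approx(sg$s, sg$t, xout = s)$y
  ts <- truth_state(eye$geometry, eye$stretch, t, pressure, eye$pressures[1L])
  cbind(data.frame(s_mm = s), ts)
}

#' Simulate a cohort of inflation-tested eyes
#'
#' Repeats [simulate_inflation()] for `n_eyes` eyes, drawing a per-eye
#' log-normal multiplier on the deformation amplitude to emulate biological
#' between-eye variability, with all randomness derived from one seed.
#'
#' @inheritParams simulate_inflation
#' @param n_eyes Number of eyes.
#' @param scatter_sd Standard deviation of the log amplitude multiplier
#'   (default 0.15; 0 gives identical eyes up to measurement noise).
#' @param seed Integer seed governing both the per-eye multipliers and the
#'   per-eye measurement noise.
#' @param eye_prefix Prefix for eye identifiers.
#' @param amplitude_scale Common multiplier on the deformation amplitude
#'   applied to every eye (e.g. 0.7 reduces the response by 30%).
#' @return List with `eyes` (list of `synthetic_eye`) and `traces` (combined
#'   long data frame).
#' @export
simulate_inflation_cohort <- function(n_eyes, geometry, stretch, pressures,
                                      n_points = 40L, position_sd_um = 0.46,
                                      scatter_sd = 0.15, seed = 1L,
                                      eye_prefix = "eye",
                                      amplitude_scale = 1) {
  stopifnot(n_eyes >= 1L)
  mult <- with_seed(seed, exp(stats::rnorm(n_eyes, sd = scatter_sd)))
  mult <- mult * amplitude_scale
  eyes <- vector("list", n_eyes)
  for (i in seq_len(n_eyes)) {
    st_i <- scale_stretch(stretch, mult[i])
    eyes[[i]] <- simulate_inflation(
      geometry, st_i, pressures, n_points,
      noise = noise_model(position_sd_um, seed = seed + 1000L + i),
      eye_id = sprintf("%s%02d", eye_prefix, i))
  }
  list(eyes = eyes,
       traces = do.call(rbind, lapply(eyes, `[[`, "traces")))
}

# Scale the deformation amplitude (lambda - 1, or the displacement
# polynomial) by a positive factor.
scale_stretch <- function(stretch, factor) {
  if (stretch$mode == "affine") {
    stretch$scale_eq <- 1 + (stretch$scale_eq - 1) * factor
    stretch$scale_pol <- 1 + (stretch$scale_pol - 1) * factor
  } else {
    stretch$c1 <- stretch$c1 * factor
    stretch$c2 <- stretch$c2 * factor
  }
  stretch
}

#' Write a synthetic dataset to disk
#'
#' Writes the edge traces and truth tables as CSV and a JSON manifest holding
#' the geometry, stretch-field, noise and seed metadata.
#'
#' @param eye A `synthetic_eye` (or list of them).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_inflation_dataset <- function(eye, dir) {
  eyes <- if (inherits(eye, "synthetic_eye")) list(eye) else eye
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traces <- do.call(rbind, lapply(eyes, `[[`, "traces"))
  truth <- do.call(rbind, lapply(eyes, `[[`, "truth"))
  p_traces <- file.path(dir, "edge_traces.csv")
  p_truth <- file.path(dir, "truth.csv")
  p_manifest <- file.path(dir, "manifest.json")
  utils::write.csv(traces, p_traces, row.names = FALSE)
  utils::write.csv(truth, p_truth, row.names = FALSE)
  manifest <- lapply(eyes, function(e) list(
    eye_id = e$eye_id,
    geometry = unclass(e$geometry),
    stretch = unclass(e$stretch),
    noise = unclass(e$noise),
    pressures = e$pressures, n_points = e$n_points))
  jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(traces = p_traces, truth = p_truth, manifest = p_manifest))
}
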