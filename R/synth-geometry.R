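# Synthetic shell geometry, prescribed deformation fields, and noise model.
#
# The generator treats the posterior sclera as a revolved ellipsoid whose
# meridian is sampled along one side of the silhouette, from the optic nerve
# head (ONH) gap to the fixture gap.  The camera frame is (e1, e2) with e2 the
# axis of revolution; the meridian point at polar angle t (measured from the
# posterior pole, where the ONH sits) is
#   X(t) = (a sin t, -b cos t),   t in [onh_gap, pi - fixture_gap],
# with a the equatorial and b the polar semi-axis.

#' Axisymmetric shell geometry for the synthetic sclera
#'
#' Describes the reference (unloaded-at-`P0`) scleral shape as an ellipsoid of
#' revolution. The meridian edge trace excludes an arc around the optic nerve
#' head and another at the holder, mirroring what the camera can see in an
#' inflation test.
#'
#' Defaults correspond to a mouse eye: equatorial semi-axis 1.7 mm (half of a
#' ~3.4 mm nasal-temporal width) and polar semi-axis 1.9 mm.
#'
#' @param semi_axis_equatorial Equatorial semi-axis in mm (> 0).
#' @param semi_axis_polar Polar semi-axis (along the axis of revolution), mm.
#' @param onh_gap_angle Meridian arc excluded around the ONH, radians (>= 0).
#' @param fixture_gap_angle Arc excluded at the holder, radians (>= 0).
#' @return An object of class `shell_geometry`.
#' @examples
#' shell_geometry()                      # default mouse eye
#' shell_geometry(1.7, 1.7)              # sphere
#' @export
shell_geometry <- function(semi_axis_equatorial = 1.7, semi_axis_polar = 1.9,
                           onh_gap_angle = 0.35, fixture_gap_angle = 0.35) {
  stopifnot_scalar(semi_axis_equatorial, "semi_axis_equatorial", positive = TRUE)
  stopifnot_scalar(semi_axis_polar, "semi_axis_polar", positive = TRUE)
  stopifnot_scalar(onh_gap_angle, "onh_gap_angle")
  stopifnot_scalar(fixture_gap_angle, "fixture_gap_angle")
  if (onh_gap_angle < 0 || fixture_gap_angle < 0)
    stop("gap angles must be >= 0", call. = FALSE)
  if (onh_gap_angle + fixture_gap_angle >= pi)
    stop("gap angles must sum to less than pi", call. = FALSE)
  structure(
    list(a = semi_axis_equatorial, b = semi_axis_polar,
         onh_gap_angle = onh_gap_angle, fixture_gap_angle = fixture_gap_angle),
    class = "shell_geometry")
}

#' @export
print.shell_geometry <- function(x, ...) {
  cat(sprintf(
    "Shell geometry: equatorial %.3f mm, polar %.3f mm, gaps %.2f / %.2f rad\n",
    x$a, x$b, x$onh_gap_angle, x$fixture_gap_angle))
  invisible(x)
}

# Reference meridian and derivatives w.r.t. t; each returns an n x 2 matrix.
ref_point <- function(geom, t) cbind(geom$a * sin(t), -geom$b * cos(t))
ref_d1    <- function(geom, t) cbind(geom$a * cos(t),  geom$b * sin(t))
ref_d2    <- function(geom, t) cbind(-geom$a * sin(t), geom$b * cos(t))

#' Prescribed deformation fields for the inflation simulator
#'
#' The simulator drives the shell with a prescribed kinematic map rather than
#' a constitutive solve: ground truth only requires a known deformation. Two
#' field families are provided.
#'
#' `stretch_affine()` scales the two semi-axes independently, so every
#' deformed configuration is again an exact ellipsoid. The circumferential
#' stretch is spatially uniform and all curvatures are closed-form; this mode
#' is the reference for stress-resultant ground truth.
#'
#' `stretch_polynomial()` adds a displacement field whose Cartesian components
#' are 4th-order polynomials in the meridian angle t. Because the analysis
#' itself fits 4th-order displacement polynomials, ground truth generated this
#' way lies inside the method's function space and strain/resultant recovery
#' can be checked to numerical precision. Pointwise meridional and
#' circumferential stretches are derived from the map and validated to be
#' >= 1 (unphysical fields are rejected by [simulate_inflation()]).
#'
#' `stretch_polynomial_from_affine()` projects the displacement of an affine
#' scaling onto the quartic space, giving a realistic smooth field in
#' polynomial form.
#'
#' For both families the pressure dependence is
#' `w(p) = ((p - P0) / (anchor_pressure - P0))^pressure_exponent`, zero at the
#' reference pressure and 1 at `anchor_pressure`; an exponent < 1 makes the
#' strain-pressure curve concave (stiffening with pressure).
#'
#' @param scale_equatorial,scale_polar Semi-axis scale factors at the anchor
#'   pressure (>= 1).
#' @param coeffs_e1,coeffs_e2 Length-5 polynomial coefficients (mm, increasing
#'   powers of the meridian angle t) of the displacement components at the
#'   anchor pressure.
#' @param pressure_exponent Dimensionless exponent of the pressure response
#'   (> 0; default 0.5).
#' @param anchor_pressure Pressure (mmHg) at which the field reaches its full
#'   amplitude (default 30).
#' @return An object of class `stretch_field`.
#' @examples
#' stretch_affine(1.015, 1.012)
#' @export
stretch_affine <- function(scale_equatorial = 1.015, scale_polar = 1.012,
                           pressure_exponent = 0.5, anchor_pressure = 30) {
  stopifnot_scalar(scale_equatorial, "scale_equatorial", positive = TRUE)
  stopifnot_scalar(scale_polar, "scale_polar", positive = TRUE)
  stopifnot_scalar(pressure_exponent, "pressure_exponent", positive = TRUE)
  if (scale_equatorial < 1 || scale_polar < 1)
    stop("affine scale factors below 1 are unphysical for inflation", call. = FALSE)
  structure(
    list(mode = "affine", scale_eq = scale_equatorial, scale_pol = scale_polar,
         exponent = pressure_exponent, anchor = anchor_pressure),
    class = "stretch_field")
}

#' @rdname stretch_affine
#' @export
stretch_polynomial <- function(coeffs_e1, coeffs_e2,
                               pressure_exponent = 0.5, anchor_pressure = 30) {
  if (length(coeffs_e1) != 5L || length(coeffs_e2) != 5L)
    stop("displacement polynomials must have exactly 5 coefficients (order 4)",
         call. = FALSE)
  stopifnot_scalar(pressure_exponent, "pressure_exponent", positive = TRUE)
  structure(
    list(mode = "polynomial", c1 = as.numeric(coeffs_e1),
         c2 = as.numeric(coeffs_e2),
         exponent = pressure_exponent, anchor = anchor_pressure),
    class = "stretch_field")
}

#' @rdname stretch_affine
#' @param geometry A [shell_geometry()] the projected field refers to.
#' @export
stretch_polynomial_from_affine <- function(geometry,
                                           scale_equatorial = 1.015,
                                           scale_polar = 1.012,
                                           pressure_exponent = 0.5,
                                           anchor_pressure = 30) {
  stopifnot(inherits(geometry, "shell_geometry"))
  t <- seq(geometry$onh_gap_angle, pi - geometry$fixture_gap_angle,
           length.out = 201L)
  u1 <- (scale_equatorial - 1) * geometry$a * sin(t)
  u2 <- -(scale_polar - 1) * geometry$b * cos(t)
  V <- outer(t, 0:4, `^`)
  c1 <- qr.solve(V, u1)
  c2 <- qr.solve(V, u2)
  stretch_polynomial(c1, c2, pressure_exponent, anchor_pressure)
}

#' @export
print.stretch_field <- function(x, ...) {
  if (x$mode == "affine") {
    cat(sprintf(
      "Affine stretch field: equatorial x%.4f, polar x%.4f at %g mmHg (exponent %.2f)\n",
      x$scale_eq, x$scale_pol, x$anchor, x$exponent))
  } else {
    cat(sprintf(
      "Quartic displacement field (anchor %g mmHg, exponent %.2f)\n",
      x$anchor, x$exponent))
  }
  invisible(x)
}

# Pressure weight w(p) in [0, 1]; zero at and below the reference pressure.
pressure_weight <- function(stretch, p, p0) {
  anchor <- stretch$anchor
  if (anchor <= p0) stop("anchor pressure must exceed the reference pressure",
                         call. = FALSE)
  w <- pmax(0, (p - p0) / (anchor - p0))^stretch$exponent
  w
}

# Deformed meridian and t-derivatives under a stretch field at weight w.
# Returns list(x, d1, d2) of n x 2 matrices.
deformed_state <- function(geom, stretch, t, w) {
  if (stretch$mode == "affine") {
    sa <- 1 + (stretch$scale_eq - 1) * w
    sp <- 1 + (stretch$scale_pol - 1) * w
    list(x  = cbind(sa * geom$a * sin(t), -sp * geom$b * cos(t)),
         d1 = cbind(sa * geom$a * cos(t),  sp * geom$b * sin(t)),
         d2 = cbind(-sa * geom$a * sin(t), sp * geom$b * cos(t)))
  } else {
    u  <- cbind(polyval(stretch$c1, t), polyval(stretch$c2, t))
    d1c1 <- polyder(stretch$c1); d1c2 <- polyder(stretch$c2)
    up <- cbind(polyval(d1c1, t), polyval(d1c2, t))
    upp <- cbind(polyval(polyder(d1c1), t), polyval(polyder(d1c2), t))
    list(x  = ref_point(geom, t) + w * u,
         d1 = ref_d1(geom, t) + w * up,
         d2 = ref_d2(geom, t) + w * upp)
  }
}

#' Measurement noise model for tracked edge points
#'
#' Gaussian position noise applied independently to each coordinate of every
#' tracked point. The default standard deviation, 0.46 um, is the displacement
#' error budget of the tracking chain: 0.36 um pixel-distance calibration
#' uncertainty plus 0.10 um inherent correlation error (see [error_budget()]).
#'
#' @param position_sd_um Per-coordinate standard deviation in micrometers
#'   (>= 0).
#' @param seed Integer seed for the noise draws.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(position_sd_um = 0.46, seed = 1L) {
  stopifnot_scalar(position_sd_um, "position_sd_um")
  if (position_sd_um < 0) stop("position_sd_um must be >= 0", call. = FALSE)
  structure(list(position_sd_um = position_sd_um, seed = as.integer(seed)),
            class = "noise_model")
}
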