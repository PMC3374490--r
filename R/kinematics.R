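# Displacement fields and Green-Lagrange strains.
#
# The displacement of each tracked point, u = x - X, is least-squares fitted
# component-wise to a 4th-order polynomial in the parametric angle of the
# fitted reference ellipse. Strains are evaluated from analytic derivatives
# of the fitted polynomials, chained through the angle-to-arc-length map of
# the ellipse, rather than by point-wise numerical differentiation (which
# would amplify the tracking noise).

#' Fit a fourth-order displacement polynomial
#'
#' Computes per-point displacements `u = x - X` between a deformed trace and
#' the reference trace (matched point correspondence), and fits each Cartesian
#' component to a 4th-order polynomial in the reference ellipse angle.
#'
#' @param meridian Reference [parameterize_meridian()] result.
#' @param deformed_points n x 2 deformed coordinates (mm), same tracked points
#'   in the same order as the reference.
#' @param pressure Pressure (mmHg) of the deformed trace, carried through.
#' @return An object of class `displacement_fit`: 5 x 2 coefficient matrix in
#'   the normalized angle, the normalization, and `fit_rms` (mm, pooled over
#'   both components).
#' @export
fit_displacement <- function(meridian, deformed_points, pressure = NA_real_) {
  stopifnot(inherits(meridian, "meridian_param"))
  xd <- as.matrix(deformed_points)
  if (nrow(xd) != nrow(meridian$points))
    stop("mismatched point counts between reference and deformed trace",
         call. = FALSE)
  if (nrow(xd) < 6L)
    stop("need at least 6 matched points for a quartic fit", call. = FALSE)
  u <- xd - meridian$points
  nu <- meridian$nu
  mid <- (max(nu) + min(nu)) / 2
  half <- (max(nu) - min(nu)) / 2
  if (half <= 0) stop("degenerate angular extent", call. = FALSE)
  z <- (nu - mid) / half
  V <- outer(z, 0:4, `^`)
  fit <- stats::lm.fit(V, u)
  coeffs <- unname(fit$coefficients)
  resid <- fit$residuals
  structure(
    list(coeffs = coeffs, nu_mid = mid, nu_half = half,
         fit_rms = sqrt(mean(resid^2)), pressure = pressure,
         n_points = nrow(xd)),
    class = "displacement_fit")
}

#' @export
print.displacement_fit <- function(x, ...) {
  cat(sprintf(
    "Displacement fit at %g mmHg: quartic in ellipse angle, rms %.3g um (n = %d)\n",
    x$pressure, mm_to_um(x$fit_rms), x$n_points))
  invisible(x)
}

# Fitted displacement and its d/dnu at angles nu; n x 2 matrices.
displacement_at <- function(dfit, nu) {
  z <- (nu - dfit$nu_mid) / dfit$nu_half
  cbind(polyval(dfit$coeffs[, 1L], z), polyval(dfit$coeffs[, 2L], z))
}
displacement_d1 <- function(dfit, nu) {
  z <- (nu - dfit$nu_mid) / dfit$nu_half
  cbind(polyval(polyder(dfit$coeffs[, 1L]), z),
        polyval(polyder(dfit$coeffs[, 2L]), z)) / dfit$nu_half
}
displacement_d2 <- function(dfit, nu) {
  z <- (nu - dfit$nu_mid) / dfit$nu_half
  cbind(polyval(polyder(polyder(dfit$coeffs[, 1L])), z),
        polyval(polyder(polyder(dfit$coeffs[, 2L])), z)) / dfit$nu_half^2
}

#' Meridional Green-Lagrange strain
#'
#' Evaluates `E_phi = dX/ds . du/ds + 1/2 du/ds . du/ds` at reference
#' arc-length locations, using analytic derivatives of the fitted ellipse and
#' displacement polynomial. With s the reference arc length, `|dX/ds| = 1`
#' and this equals the full form `(|dx/ds|^2 - 1) / 2`.
#'
#' @param meridian Reference [parameterize_meridian()] result.
#' @param dfit A [fit_displacement()] result.
#' @param s Arc-length locations (mm) within the fitted arc; extrapolation is
#'   refused.
#' @return Numeric vector of meridional strains.
#' @export
meridional_strain <- function(meridian, dfit, s) {
  stopifnot(inherits(meridian, "meridian_param"),
            inherits(dfit, "displacement_fit"))
  nu <- nu_of_s(meridian, s)
  f <- meridian$fit
  Xp <- ellipse_d1_at(f$semi_major, f$semi_minor, f$tilt, nu)
  up <- displacement_d1(dfit, nu)
  (rowSums(Xp * up) + 0.5 * rowSums(up^2)) / rowSums(Xp^2)
}

#' Circumferential Green-Lagrange strain
#'
#' `E_theta = ((d / D)^2 - 1) / 2` from the ratio of deformed to reference
#' cross-section diameter, under the axisymmetry assumption.
#'
#' @param D Reference diameters (mm, > 0).
#' @param d Deformed diameters (mm, > 0).
#' @return Numeric vector of circumferential strains.
#' @examples
#' circumferential_strain(2, 2.2)  # 0.105
#' @export
circumferential_strain <- function(D, d) {
  if (any(D <= 0) || any(d <= 0))
    stop("diameters must be > 0", call. = FALSE)
  ((d / D)^2 - 1) / 2
}

#' Deformed cross-section diameter at arc-length locations
#'
#' Twice the perpendicular distance of the analytically displaced point
#' (fitted ellipse point plus fitted displacement) from the axis of
#' revolution.
#'
#' @inheritParams meridional_strain
#' @return Numeric vector of deformed diameters (mm).
#' @export
deformed_diameter <- function(meridian, dfit, s) {
  nu <- nu_of_s(meridian, s)
  f <- meridian$fit
  X <- ellipse_point_at(f$center, f$semi_major, f$semi_minor, f$tilt, nu)
  x <- X + displacement_at(dfit, nu)
  2 * axis_distance(x, meridian$axis)
}

#' Reference cross-section diameter at arc-length locations
#'
#' @inheritParams meridional_strain
#' @return Numeric vector of reference diameters (mm).
#' @export
reference_diameter <- function(meridian, s) {
  nu <- nu_of_s(meridian, s)
  f <- meridian$fit
  X <- ellipse_point_at(f$center, f$semi_major, f$semi_minor, f$tilt, nu)
  2 * axis_distance(X, meridian$axis)
}
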