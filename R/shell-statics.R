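# Curvature radii of the deformed meridian and membrane stress resultants
# from thin-shell equilibrium.
#
# For a thin shell of revolution under internal pressure p, axial equilibrium
# and normal equilibrium give
#   n_phi   = p * r_t / 2
#   n_theta = p * r_t * (2 * r_m - r_t) / (2 * r_m)
# where r_m is the radius of curvature of the deformed meridian and r_t the
# transverse radius (distance from the surface point to the axis of
# revolution along the outward normal). Both reduce to Laplace's p*r/2 on a
# sphere; in the cylinder limit (r_m -> Inf) n_theta -> p*R and
# n_phi -> p*R/2. The normal-equilibrium identity n_phi/r_m + n_theta/r_t = p
# holds exactly and is used as an independent check in the tests.

# Curvature radii of a planar meridian curve given its point and first two
# parameter derivatives (n x 2 matrices), relative to an axis of revolution
# (default: the vertical axis through x1 = 0, the generator's frame).
curve_radii <- function(x, d1, d2, axis = list(point = c(0, 0), dir = c(0, 1))) {
  cross <- d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L]
  sp <- row_norm(d1)
  if (any(abs(cross) < 1e-12 * sp^3))
    stop("degenerate (non-convex or flat) meridian curvature", call. = FALSE)
  r_m <- sp^3 / abs(cross)
  dir <- axis$dir / sqrt(sum(axis$dir^2))
  w <- sweep(x, 2L, axis$point)
  along <- as.vector(w %*% dir)
  perp <- w - outer(along, dir)
  rho <- sqrt(rowSums(perp^2))
  e_rho <- perp / pmax(rho, 1e-300)
  tau <- d1 / sp
  nrm <- cbind(tau[, 2L], -tau[, 1L])
  cosang <- abs(rowSums(nrm * e_rho))
  # at a pole (on the axis) both principal radii coincide with the meridian
  # radius for a smooth shell of revolution
  pole <- rho < 1e-9 * pmax(r_m, 1)
  if (any(!pole & cosang < 1e-9))
    stop("surface normal parallel to the axis; transverse radius undefined",
         call. = FALSE)
  r_t <- rho / pmax(cosang, 1e-300)
  r_t[pole] <- r_m[pole]
  list(r_meridional = r_m, r_transverse = r_t)
}

# Eq.-4 resultants from radii in mm and pressure in mmHg; output N/m.
resultants_from_radii <- function(p_mmHg, r_transverse_mm, r_meridional_mm) {
  p <- mmHg_to_Pa(p_mmHg)
  rt <- r_transverse_mm / 1000
  rm <- r_meridional_mm / 1000
  list(n_phi = p * rt / 2,
       n_theta = p * rt * (1 - rt / (2 * rm)))
}

#' Curvature radii of a fitted ellipse
#'
#' Closed-form meridional radius of curvature and transverse radius (distance
#' to the axis of revolution along the outward normal) of an ellipse at
#' parametric angles `nu`.
#'
#' @param fit An [ellipse_fit()].
#' @param nu Parametric angles (radians from the major axis).
#' @param axis Axis of revolution as `list(point =, dir =)`; defaults to the
#'   ellipse principal axis most aligned with the camera vertical.
#' @return Data frame with `nu`, `r_meridional` and `r_transverse` (mm).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 33)[-33]
#' f <- fit_ellipse(cbind(2 * cos(th), 1.5 * sin(th)))
#' ellipse_curvatures(f, pi / 2)$r_meridional  # b^2 / a at the co-vertex
#' @export
ellipse_curvatures <- function(fit, nu, axis = NULL) {
  stopifnot(inherits(fit, "ellipse_fit"))
  ax <- axis %||% default_axis(fit)
  x <- ellipse_point_at(fit$center, fit$semi_major, fit$semi_minor, fit$tilt, nu)
  d1 <- ellipse_d1_at(fit$semi_major, fit$semi_minor, fit$tilt, nu)
  d2 <- ellipse_d2_at(fit$semi_major, fit$semi_minor, fit$tilt, nu)
  rad <- curve_radii(x, d1, d2, ax)
  data.frame(nu = nu, r_meridional = rad$r_meridional,
             r_transverse = rad$r_transverse)
}

#' Curvature radii of the deformed meridian
#'
#' Evaluates the deformed meridian analytically as the fitted reference
#' ellipse plus the fitted displacement polynomial, and returns its
#' meridional radius of curvature and transverse radius at reference
#' arc-length locations.
#'
#' @param meridian Reference [parameterize_meridian()] result.
#' @param dfit A [fit_displacement()] result for the pressure step.
#' @param s Arc-length locations (mm) within the fitted arc.
#' @return Data frame with `s_mm`, `r_meridional` and `r_transverse` (mm).
#' @export
deformed_curvatures <- function(meridian, dfit, s) {
  stopifnot(inherits(meridian, "meridian_param"),
            inherits(dfit, "displacement_fit"))
  nu <- nu_of_s(meridian, s)
  f <- meridian$fit
  x <- ellipse_point_at(f$center, f$semi_major, f$semi_minor, f$tilt, nu) +
    displacement_at(dfit, nu)
  d1 <- ellipse_d1_at(f$semi_major, f$semi_minor, f$tilt, nu) +
    displacement_d1(dfit, nu)
  d2 <- ellipse_d2_at(f$semi_major, f$semi_minor, f$tilt, nu) +
    displacement_d2(dfit, nu)
  rad <- curve_radii(x, d1, d2, meridian$axis)
  data.frame(s_mm = s, r_meridional = rad$r_meridional,
             r_transverse = rad$r_transverse)
}

#' Membrane stress resultants of a thin shell of revolution
#'
#' Computes the meridional and circumferential stress resultants from the
#' deformed curvature radii and the internal pressure:
#' `n_phi = p r_t / 2`, `n_theta = p r_t (2 r_m - r_t) / (2 r_m)`.
#' Pressure is converted at 1 mmHg = 133.322 Pa; radii are in mm and the
#' resultants in N/m.
#'
#' @param p Internal pressure in mmHg (> 0).
#' @param curvatures Data frame with columns `r_meridional` and
#'   `r_transverse` in mm (from [deformed_curvatures()] or
#'   [ellipse_curvatures()]); `r_meridional = Inf` gives the cylinder limit.
#' @return The input data frame with `pressure_mmHg`, `n_phi` and `n_theta`
#'   (N/m) appended.
#' @examples
#' stress_resultants(15, data.frame(r_meridional = 1.7, r_transverse = 1.7))
#' @export
stress_resultants <- function(p, curvatures) {
  stopifnot_scalar(p, "p", positive = TRUE)
  rm_ <- curvatures$r_meridional
  rt_ <- curvatures$r_transverse
  if (is.null(rm_) || is.null(rt_))
    stop("curvatures must have r_meridional and r_transverse columns",
         call. = FALSE)
  if (any(rm_ <= 0) || any(rt_ <= 0))
    stop("curvature radii must be > 0 for a convex inflated shell",
         call. = FALSE)
  res <- resultants_from_radii(p, rt_, rm_)
  out <- curvatures
  out$pressure_mmHg <- p
  out$n_phi <- res$n_phi
  out$n_theta <- res$n_theta
  out
}

#' Mechanical anisotropy ratios
#'
#' Ratios `E_theta / E_phi` and `n_theta / n_phi` describing the directional
#' inequality of strain and membrane force. Ratios whose denominator is
#' smaller in magnitude than `epsilon` are returned as `NA` (undefined, not
#' an error).
#'
#' @param E_phi,E_theta Strain components.
#' @param n_phi,n_theta Stress resultants (N/m).
#' @param epsilon Strain denominator threshold (default 1e-4); the resultant
#'   denominator uses `epsilon` in N/m as well.
#' @return Data frame with `strain_ratio` and `resultant_ratio`.
#' @export
anisotropy_ratios <- function(E_phi, E_theta, n_phi, n_theta, epsilon = 1e-4) {
  strain_ratio <- ifelse(abs(E_phi) < epsilon, NA_real_, E_theta / E_phi)
  resultant_ratio <- ifelse(abs(n_phi) < epsilon, NA_real_, n_theta / n_phi)
  data.frame(strain_ratio = strain_ratio, resultant_ratio = resultant_ratio)
}
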