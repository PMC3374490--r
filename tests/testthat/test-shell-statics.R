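# Curvature radii and membrane equilibrium.

test_that("sphere identity: both radii equal R and resultants equal p*r/2", {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  f <- fit_ellipse(cbind(1.7 * cos(th), 1.7 * sin(th)))
  nu <- seq(0.3, 2.8, length.out = 15)
  curv <- ellipse_curvatures(f, nu)
  expect_equal(curv$r_meridional, rep(1.7, 15), tolerance = 1e-10)
  expect_equal(curv$r_transverse, rep(1.7, 15), tolerance = 1e-10)
  sr <- stress_resultants(15, curv)
  laplace <- 15 * 133.322 * 0.0017 / 2
  expect_equal(sr$n_phi, rep(laplace, 15), tolerance = 1e-10)
  expect_equal(sr$n_theta, rep(laplace, 15), tolerance = 1e-10)
})

test_that("ellipse curvature matches the conic closed forms at the vertices", {
  pts <- ellipse_arc_points(2, 1.5, nu = seq(-0.5, 2.9, length.out = 60))
  f <- fit_ellipse(pts)
  curv <- ellipse_curvatures(f, c(0, pi / 2))
  expect_equal(curv$r_meridional[1], 1.5^2 / 2, tolerance = 1e-8)  # B^2/A
  expect_equal(curv$r_meridional[2], 2^2 / 1.5, tolerance = 1e-8)  # A^2/B
})

test_that("cylinder limit: n_theta = pR and n_phi = pR/2", {
  sr <- stress_resultants(15, data.frame(r_meridional = Inf, r_transverse = 1.7))
  pR <- 15 * 133.322 * 0.0017
  expect_equal(sr$n_theta, pR, tolerance = 1e-12)
  expect_equal(sr$n_phi, pR / 2, tolerance = 1e-12)
})

test_that("curvature operator agrees with a finite-difference oracle", {
  pts <- ellipse_arc_points(1.9, 1.6, tilt = 0.2, center = c(0.1, -0.3),
                            nu = seq(0.1, 2.9, length.out = 60))
  f <- fit_ellipse(pts)
  nu <- seq(0.5, 2.5, length.out = 11)
  curv <- ellipse_curvatures(f, nu)
  h <- 1e-3
  for (i in seq_along(nu)) {
    # 5-point central differences of the parametric curve
    st <- vapply(c(-2, -1, 0, 1, 2), function(k)
      ellipse_points(f, nu[i] + k * h), numeric(2))
    d1 <- (st[, 1] - 8 * st[, 2] + 8 * st[, 4] - st[, 5]) / (12 * h)
    d2 <- (-st[, 1] + 16 * st[, 2] - 30 * st[, 3] + 16 * st[, 4] - st[, 5]) /
      (12 * h^2)
    kappa <- abs(d1[1] * d2[2] - d1[2] * d2[1]) / sum(d1^2)^1.5
    expect_equal(curv$r_meridional[i], 1 / kappa, tolerance = 1e-6)
  }
})

test_that("pipeline resultants equal the simulator ground truth", {
  geom <- default_geom()
  st <- random_poly_stretch(geom, seed = 23L)
  eye <- simulate_inflation(geom, st, c(7, 15, 30), n_points = 40,
                            noise = noise_model(0))
  an <- analyze_eye(eye$traces, pressure_schedule(7, c(15, 30)))
  s <- an$samples
  tv <- do.call(rbind, lapply(unique(s$pressure_mmHg), function(p)
    truth_at(eye, p, s$s_mm[s$pressure_mmHg == p])))
  expect_lt(max(abs(s$n_phi / tv$n_phi - 1)), 1e-8)
  expect_lt(max(abs(s$n_theta / tv$n_theta - 1)), 1e-8)
})

test_that("membrane equilibrium n_phi/r_m + n_theta/r_t = p holds with independently computed curvature radii", {
  # the principal curvature radii are recomputed here by 5-point finite
  # differences of the dense noiseless deformed curve, so the equilibrium
  # residual genuinely cross-checks the resultants rather than restating the
  # formula that produced them
  geom <- default_geom()
  for (seed in c(3L, 9L)) {
    st <- random_poly_stretch(geom, seed)
    dense <- simulate_inflation(geom, st, c(7, 30), n_points = 4001,
                                noise = noise_model(0))
    def <- dense$truth[dense$truth$pressure_mmHg == 30, ]
    i <- seq(201L, 3801L, by = 200L)
    x <- cbind(def$x1_mm, def$x2_mm)
    fd <- function(w) {  # 5-point first/second derivative in index units
      list(d1 = (x[i - 2L, w] - 8 * x[i - 1L, w] + 8 * x[i + 1L, w] -
                   x[i + 2L, w]) / 12,
           d2 = (-x[i - 2L, w] + 16 * x[i - 1L, w] - 30 * x[i, w] +
                   16 * x[i + 1L, w] - x[i + 2L, w]) / 12)
    }
    f1 <- fd(1L); f2 <- fd(2L)
    sp2 <- f1$d1^2 + f2$d1^2
    kappa <- abs(f1$d1 * f2$d2 - f2$d1 * f1$d2) / sp2^1.5
    r_m_fd <- 1 / kappa
    r_t_fd <- def$x1_mm[i] * sqrt(sp2) / abs(f2$d1)
    p_Pa <- 30 * 133.322
    resid <- def$n_phi[i] / (r_m_fd / 1000) +
      def$n_theta[i] / (r_t_fd / 1000) - p_Pa
    expect_lt(max(abs(resid)), 1e-6 * p_Pa)
  }
})

test_that("resultants scale linearly in pressure at fixed geometry", {
  curv <- data.frame(r_meridional = 2.1, r_transverse = 1.8)
  expect_equal(stress_resultants(20, curv)$n_phi,
               2 * stress_resultants(10, curv)$n_phi, tolerance = 1e-12)
  expect_equal(stress_resultants(20, curv)$n_theta,
               2 * stress_resultants(10, curv)$n_theta, tolerance = 1e-12)
})

test_that("anisotropy ratios follow the definitions and encode undefined values", {
  r <- anisotropy_ratios(0.01, 0.02, 1, 1.5)
  expect_equal(r$strain_ratio, 2)
  expect_equal(r$resultant_ratio, 1.5)
  expect_true(is.na(anisotropy_ratios(1e-5, 0.02, 1, 1)$strain_ratio))
  # isotropic sphere: both ratios 1
  sphere <- shell_geometry(1.7, 1.7)
  eye <- simulate_inflation(sphere, stretch_affine(1.03, 1.03), c(7, 30),
                            noise = noise_model(0))
  tr <- eye$truth[eye$truth$pressure_mmHg == 30, ]
  ri <- anisotropy_ratios(tr$E_phi, tr$E_theta, tr$n_phi, tr$n_theta)
  expect_equal(ri$strain_ratio, rep(1, nrow(tr)), tolerance = 1e-9)
  expect_equal(ri$resultant_ratio, rep(1, nrow(tr)), tolerance = 1e-9)
  # circumferentially dominant stretch: strain ratio > 1 everywhere analyzed
  aniso <- stretch_polynomial_from_affine(default_geom(), 1.02, 1.008)
  eye2 <- simulate_inflation(default_geom(), aniso, c(7, 30),
                             noise = noise_model(0))
  an <- analyze_eye(eye2$traces, pressure_schedule(7, 30))
  ra <- anisotropy_ratios(an$samples$E_phi, an$samples$E_theta,
                          an$samples$n_phi, an$samples$n_theta)
  expect_true(all(ra$strain_ratio > 1))
})

test_that("invalid curvature inputs are refused", {
  expect_error(stress_resultants(15, data.frame(r_meridional = -1,
                                                r_transverse = 1.7)), "> 0")
  expect_error(stress_resultants(-5, data.frame(r_meridional = 1,
                                                r_transverse = 1)), "> 0")
})
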