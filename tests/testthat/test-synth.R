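# Synthetic-data generator: closed-form ground truth, physical validation,
# reproducibility, and the cohort-level simulators.

test_that("uniform spherical stretch yields the closed-form strain everywhere", {
  sphere <- shell_geometry(1.7, 1.7)
  eye <- simulate_inflation(sphere, stretch_affine(1.05, 1.05, anchor_pressure = 30),
                            c(7, 30), noise = noise_model(0))
  tr <- eye$truth[eye$truth$pressure_mmHg == 30, ]
  expect_equal(tr$E_phi, rep((1.05^2 - 1) / 2, nrow(tr)), tolerance = 1e-12)
  expect_equal(tr$E_theta, rep((1.05^2 - 1) / 2, nrow(tr)), tolerance = 1e-12)
  # spherical symmetry: equal resultants at every point and pressure
  expect_equal(eye$truth$n_phi, eye$truth$n_theta, tolerance = 1e-10)
})

test_that("reference-pressure-only simulation is the identity", {
  eye <- quick_eye(pressures = 7, noise_sd = 0)
  expect_equal(eye$traces$x_mm, eye$truth$x1_mm, tolerance = 1e-15)
  expect_equal(eye$traces$y_mm, eye$truth$x2_mm, tolerance = 1e-15)
  expect_true(all(eye$truth$E_phi == 0))
  expect_true(all(eye$truth$E_theta == 0))
})

test_that("undeformed sphere at 15 mmHg carries the Laplace resultant", {
  sphere <- shell_geometry(1.7, 1.7)
  eye <- simulate_inflation(sphere, stretch_affine(1, 1, anchor_pressure = 30),
                            pressures = 15, noise = noise_model(0))
  n_expected <- 15 * 133.322 * 0.0017 / 2
  expect_equal(eye$truth$n_phi, rep(n_expected, nrow(eye$truth)),
               tolerance = 1e-10)
  expect_equal(eye$truth$n_phi[1], 1.7, tolerance = 1e-3)
})

test_that("truth strains agree with finite differences of the noiseless traces", {
  geom <- default_geom()
  st <- random_poly_stretch(geom, seed = 42L)
  eye <- simulate_inflation(geom, st, c(7, 30), n_points = 2001,
                            noise = noise_model(0))
  ref <- eye$truth[eye$truth$pressure_mmHg == 7, ]
  def <- eye$truth[eye$truth$pressure_mmHg == 30, ]
  # meridional: segment length ratio at midpoints
  dX <- sqrt(diff(ref$x1_mm)^2 + diff(ref$x2_mm)^2)
  dx <- sqrt(diff(def$x1_mm)^2 + diff(def$x2_mm)^2)
  E_phi_fd <- ((dx / dX)^2 - 1) / 2
  s_mid <- (ref$s_mm[-1] + ref$s_mm[-nrow(ref)]) / 2
  tv <- truth_at(eye, 30, s_mid)
  expect_lt(max(abs(E_phi_fd - tv$E_phi)), 1e-6)
  # circumferential: diameter ratio at the sample points
  E_theta_fd <- ((def$x1_mm / ref$x1_mm)^2 - 1) / 2
  expect_lt(max(abs(E_theta_fd - def$E_theta)), 1e-12)
})

test_that("seeded simulations are reproducible and seeds matter", {
  e1 <- quick_eye(noise_sd = 0.46, seed = 5L)
  e2 <- quick_eye(noise_sd = 0.46, seed = 5L)
  e3 <- quick_eye(noise_sd = 0.46, seed = 6L)
  expect_identical(e1$traces, e2$traces)
  expect_false(isTRUE(all.equal(e1$traces$x_mm, e3$traces$x_mm)))
})

test_that("unphysical inputs are rejected", {
  expect_error(simulate_inflation(default_geom(), default_poly_stretch(),
                                  c(7, 30, 20)), "ascending")
  expect_error(simulate_inflation(default_geom(), default_poly_stretch(),
                                  c(7, 30), n_points = 5), ">= 10")
  shrink <- stretch_polynomial(c(-0.05, 0, 0, 0, 0), rep(0, 5))
  expect_error(simulate_inflation(default_geom(), shrink, c(7, 30)),
               "unphysical")
  expect_error(stretch_affine(0.9, 1), "unphysical")
  expect_error(noise_model(-1), ">= 0")
  expect_error(shell_geometry(onh_gap_angle = 2, fixture_gap_angle = 2),
               "sum")
})

test_that("IOP pair simulator matches its cumulative-exposure truth", {
  # zero elevation, zero noise: treated equals fellow
  pair <- simulate_iop_series(elevation_profile = function(d) rep(0, length(d)),
                              noise_sd = 0)
  expect_equal(pair$treated$iop, pair$fellow$iop)
  # constant +5 over 42 days: rectangle of 210 mmHg-days
  pair <- simulate_iop_series(elevation_profile = function(d) rep(5, length(d)),
                              measurement_days = seq(0, 42, 7), noise_sd = 0)
  expect_equal(positive_integral_iop(pair$treated, pair$fellow), 210)
  # noisy decaying elevation: implementation mean over seeds matches an
  # independent fine-grid positive-part integration of the same series to
  # within 2 SE (the positive-part metric is upward-biased relative to the
  # noiseless trapezoid wherever noise straddles zero, so the oracle is the
  # Monte-Carlo expectation, not the noiseless 210)
  days <- seq(0, 42, 7)
  fine_pi <- function(ser_t, ser_f) {
    g <- seq(0, 42, by = 0.004)
    dt <- stats::approx(ser_t$days, ser_t$iop, g)$y
    df <- stats::approx(ser_f$days, ser_f$iop, g)$y
    sum(pmax((dt - df)[-1] + (dt - df)[-length(g)], 0) / 2 * diff(g))
  }
  prof <- function(d) pmax(10 * (1 - d / 42), 0)
  vals <- t(vapply(1:500, function(i) {
    p <- simulate_iop_series(elevation_profile = prof, measurement_days = days,
                             noise_sd = 2, seed = i)
    c(impl = positive_integral_iop(p$treated, p$fellow),
      oracle = fine_pi(p$treated, p$fellow))
  }, numeric(2)))
  se <- stats::sd(vals[, "impl"]) / sqrt(nrow(vals))
  expect_lt(abs(mean(vals[, "impl"]) - mean(vals[, "oracle"])), 2 * se)
  expect_error(simulate_iop_series(noise_sd = -1), ">= 0")
  expect_error(simulate_iop_series(measurement_days = c(0, 50)), "42")
})

test_that("axon cohort simulator feeds an unbiased estimator", {
  # deterministic fields reproduce the reference nerve exactly
  det <- simulate_axon_cohort(46905, 0.0889, 0.0016, 5, loss_fraction = 0,
                              dispersion = 0)
  expect_equal(estimate_axon_count(det), 46905)
  half <- simulate_axon_cohort(46905, 0.0889, 0.0016, 5, loss_fraction = 0.5,
                               dispersion = 0)
  expect_lt(abs(estimate_axon_count(half) - 46905 * 0.5), 0.6)
  # Poisson fields: estimator bias below 1% of truth over 1000 replicates
  est <- vapply(1:1000, function(i)
    estimate_axon_count(simulate_axon_cohort(46905, 0.0889, dispersion = 1,
                                             seed = i)), numeric(1))
  expect_lt(abs(mean(est) - 46905) / 46905, 0.01)
  expect_error(simulate_axon_cohort(46905, 0.0889, loss_fraction = 1),
               "loss_fraction")
  expect_error(simulate_axon_cohort(46905, 0.001, 0.0016, 5), "exceed")
})

test_that("morphometry simulator reproduces its cell means", {
  cells <- morphometry_reference()
  exact <- simulate_morphometry(transform(cells, length_sd = 0, width_nt_sd = 0,
                                          width_si_sd = 0), seed = 1)
  agg <- stats::aggregate(axial_length_mm ~ strain + age_months + treatment,
                          exact, mean)
  merged <- merge(agg, cells)
  expect_equal(merged$axial_length_mm, merged$length_mm, tolerance = 1e-12)
  # noisy cohort: percent difference estimate within 2 SE of the noiseless value
  sim <- simulate_morphometry(seed = 7)
  m <- function(strain, trt) mean(
    sim$axial_length_mm[sim$strain == strain & sim$treatment == trt &
                          sim$age_months == 4])
  est <- percent_dimension_change(m("Aca23", "glaucoma"), m("Aca23", "control"))
  truth <- percent_dimension_change(4.15, 3.81)
  se_pct <- 100 / 3.81 * sqrt(0.26^2 / 37 + (4.15 / 3.81)^2 * 0.10^2 / 37)
  expect_lt(abs(est - truth), 2 * se_pct)
  # dispersion sanity: single cell, n = 1000, sd 0.1 recovered within 10%
  one <- data.frame(strain = "S", age_months = 4, treatment = "control",
                    n = 1000L, length_mm = 3.5, length_sd = 0.1,
                    width_nt_mm = 3.4, width_nt_sd = 0.1)
  sim1 <- simulate_morphometry(one, seed = 11)
  expect_lt(abs(stats::sd(sim1$axial_length_mm) - 0.1) / 0.1, 0.1)
  expect_error(simulate_morphometry(one, n_per_cell = 1), ">= 2")
})
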