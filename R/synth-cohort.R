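# Cohort-level synthetic data: IOP time series, axon-count samples, and
# ocular morphometry.

#' Default treated-eye IOP elevation profile
#'
#' Exponentially decaying elevation of the injected eye over the 6-week
#' observation window, `peak * exp(-day / tau)` mmHg. With the defaults the
#' cumulative exposure (time integral over 42 days) is about 105 mmHg-days,
#' of the same order as reported cumulative exposures in chronic bead-model
#' glaucoma (means near 90-110 mmHg-days).
#'
#' @param peak Elevation at day 0 (mmHg).
#' @param tau Decay constant in days.
#' @return A function of day returning the elevation in mmHg.
#' @export
default_elevation_profile <- function(peak = 9, tau = 12) {
  force(peak); force(tau)
  function(day) peak * exp(-day / tau)
}

#' IOP series container
#'
#' @param eye_id Identifier.
#' @param arm `"treated"` or `"fellow"`.
#' @param days Measurement days, ascending, >= 0.
#' @param iop IOP values in mmHg (> 0).
#' @return An object of class `iop_series`.
#' @export
iop_series <- function(eye_id, arm = c("treated", "fellow"), days, iop) {
  arm <- match.arg(arm)
  days <- as.numeric(days); iop <- as.numeric(iop)
  if (length(days) != length(iop)) stop("days and iop lengths differ", call. = FALSE)
  if (length(days) < 2L || any(diff(days) <= 0) || any(days < 0))
    stop("days must be ascending and >= 0", call. = FALSE)
  if (any(iop <= 0)) stop("iop must be > 0", call. = FALSE)
  structure(list(eye_id = eye_id, arm = arm, days = days, iop = iop),
            class = "iop_series")
}

#' Simulate a treated/fellow IOP series pair
#'
#' The fellow eye follows the baseline plus measurement noise; the treated eye
#' additionally carries the elevation profile. Measurements follow the chronic
#' bead-model schedule (default: days 0, 3, 7 and then weekly to 42).
#'
#' @param baseline_mean Baseline IOP in mmHg.
#' @param elevation_profile Function of day giving the treated-eye elevation
#'   in mmHg (default [default_elevation_profile()]), or a numeric vector
#'   indexed by day 0..42.
#' @param measurement_days Days of measurement within 0..42, ascending.
#' @param noise_sd Tonometry noise standard deviation in mmHg (>= 0).
#' @param seed Integer seed.
#' @param eye_id Identifier prefix.
#' @return List with elements `treated` and `fellow`, both [iop_series()].
#' @export
simulate_iop_series <- function(baseline_mean = 12.5,
                                elevation_profile = default_elevation_profile(),
                                measurement_days = c(0, 3, 7, 14, 21, 28, 35, 42),
                                noise_sd = 1.5, seed = 1L, eye_id = "animal1") {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  days <- as.numeric(measurement_days)
  if (any(days < 0) || any(days > 42) || any(diff(days) <= 0))
    stop("measurement days must be ascending within [0, 42]", call. = FALSE)
  elev <- if (is.function(elevation_profile)) elevation_profile(days)
          else as.numeric(elevation_profile)[days + 1L]
  if (any(!is.finite(elev))) stop("elevation profile undefined at some days",
                                  call. = FALSE)
  n <- length(days)
  noise <- if (noise_sd > 0)
    with_seed(seed, matrix(stats::rnorm(2L * n, sd = noise_sd), ncol = 2L))
  else matrix(0, n, 2L)
  treated <- pmax(baseline_mean + elev + noise[, 1L], 1)
  fellow <- pmax(baseline_mean + noise[, 2L], 1)
  list(treated = iop_series(paste0(eye_id, "_T"), "treated", days, treated),
       fellow = iop_series(paste0(eye_id, "_F"), "fellow", days, fellow))
}

#' Simulate sampled axon-density measurements for one optic nerve
#'
#' Emulates the sampling estimator used for optic-nerve axon counts: a handful
#' of small fields (classically five 40x40 um images, about 9% of the nerve
#' cross-section) are counted and the mean density times the nerve area
#' estimates the axon number.
#'
#' `dispersion` controls the per-field count noise: 0 gives deterministic
#' (expected) counts, 1 gives Poisson counts, and values > 1 give
#' negative-binomial counts with variance `dispersion * mean`.
#'
#' @param true_count True axon number of the nerve before loss.
#' @param nerve_area Nerve cross-section area in mm^2.
#' @param field_area Area of one sampled field in mm^2 (default 0.0016, a
#'   40x40 um image).
#' @param n_fields Number of sampled fields (default 5).
#' @param loss_fraction Fraction of axons lost, in [0, 1).
#' @param dispersion Per-field count dispersion (>= 0, see Details).
#' @param seed Integer seed.
#' @param nerve_id Identifier.
#' @return An [axon_sample()] object.
#' @export
simulate_axon_cohort <- function(true_count, nerve_area, field_area = 0.0016,
                                 n_fields = 5L, loss_fraction = 0,
                                 dispersion = 1, seed = 1L,
                                 nerve_id = "nerve1") {
  stopifnot_scalar(true_count, "true_count", positive = TRUE)
  stopifnot_scalar(nerve_area, "nerve_area", positive = TRUE)
  if (n_fields < 1L) stop("n_fields must be >= 1", call. = FALSE)
  if (field_area * n_fields > nerve_area)
    stop("sampled fields exceed the nerve area", call. = FALSE)
  if (loss_fraction < 0 || loss_fraction >= 1)
    stop("loss_fraction must be in [0, 1)", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  mu <- true_count * (1 - loss_fraction) / nerve_area * field_area
  counts <- if (dispersion == 0) {
    rep(mu, n_fields)  # expected counts, kept fractional so the estimator is exact
  } else if (dispersion <= 1) {
    with_seed(seed, stats::rpois(n_fields, mu))
  } else {
    with_seed(seed, stats::rnbinom(n_fields, mu = mu,
                                   size = mu / (dispersion - 1)))
  }
  axon_sample(nerve_id, nerve_area, counts / field_area)
}

#' Reference ocular morphometry table
#'
#' Group means and standard deviations (mm) of axial length and globe widths
#' for the two mouse strains by age and glaucoma treatment, as used for the
#' synthetic morphometry defaults and the percent-change worked examples.
#' Widths are nasal-temporal (NT) and superior-inferior (SI); `NA` marks
#' combinations that were not measured.
#'
#' @return Data frame with columns `strain`, `age_months`, `treatment`, `n`,
#'   `length_mm`, `length_sd`, `width_si_mm`, `width_si_sd`, `width_nt_mm`,
#'   `width_nt_sd`.
#' @export
morphometry_reference <- function() {
  data.frame(
    strain = c("Aca23", "Aca23", "Aca23", "WT", "WT", "WT"),
    age_months = c(4, 4, 17, 4, 4, 17),
    treatment = c("control", "glaucoma", "control",
                  "control", "glaucoma", "control"),
    n = c(37L, 37L, 48L, 127L, 30L, 48L),
    length_mm = c(3.81, 4.15, 4.17, 3.39, 4.01, 3.59),
    length_sd = c(0.10, 0.26, 0.12, 0.14, 0.25, 0.11),
    width_si_mm = c(NA, NA, 3.56, 3.23, NA, 3.49),
    width_si_sd = c(NA, NA, 0.15, 0.12, NA, 0.09),
    width_nt_mm = c(3.51, 3.74, 3.65, 3.27, 3.69, 3.55),
    width_nt_sd = c(0.13, 0.18, 0.14, 0.14, 0.29, 0.08))
}

#' Reference optic-nerve axon counts
#'
#' Group means and standard deviations of estimated axon number after six
#' weeks of experimental glaucoma and in untreated fellow eyes.
#'
#' @return Data frame with columns `strain`, `treatment`, `n`, `mean_axons`,
#'   `sd_axons`.
#' @export
axon_reference <- function() {
  data.frame(
    strain = c("Aca23", "Aca23", "WT", "WT"),
    treatment = c("untreated", "injected", "untreated", "injected"),
    n = c(37L, 37L, 29L, 29L),
    mean_axons = c(46905, 46638, 43628, 37025),
    sd_axons = c(7592, 7987, 11162, 14650))
}

#' Simulate a morphometry cohort
#'
#' Gaussian draws of axial length and widths per (strain, age, treatment)
#' cell. Defaults are the reference cohort of [morphometry_reference()].
#'
#' @param cells Data frame in the layout of [morphometry_reference()].
#' @param n_per_cell Number of eyes per cell; `NULL` (default) uses the `n`
#'   column of `cells`. Must be >= 2.
#' @param seed Integer seed.
#' @return Data frame with one row per eye: `eye_id`, `strain`, `age_months`,
#'   `treatment`, `axial_length_mm`, `width_nt_mm`, `width_si_mm`.
#' @export
simulate_morphometry <- function(cells = morphometry_reference(),
                                 n_per_cell = NULL, seed = 1L) {
  req <- c("strain", "age_months", "treatment", "length_mm", "length_sd",
           "width_nt_mm", "width_nt_sd")
  if (!all(req %in% names(cells)))
    stop("cells must contain columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  mean_cols <- intersect(c("length_mm", "width_nt_mm", "width_si_mm"),
                         names(cells))
  if (any(stats::na.omit(unlist(cells[mean_cols])) <= 0))
    stop("all means must be > 0", call. = FALSE)
  with_seed(seed, {
    out <- lapply(seq_len(nrow(cells)), function(i) {
      row <- cells[i, ]
      n <- if (is.null(n_per_cell)) row$n else n_per_cell
      if (is.null(n) || is.na(n) || n < 2L)
        stop("n_per_cell must be >= 2", call. = FALSE)
      draw <- function(m, s) {
        if (is.na(m)) return(rep(NA_real_, n))
        if (is.na(s) || s == 0) rep(m, n) else stats::rnorm(n, m, s)
      }
      data.frame(
        eye_id = sprintf("%s_%gmo_%s_%03d", row$strain, row$age_months,
                         row$treatment, seq_len(n)),
        strain = row$strain, age_months = row$age_months,
        treatment = row$treatment,
        axial_length_mm = draw(row$length_mm, row$length_sd),
        width_nt_mm = draw(row$width_nt_mm, row$width_nt_sd),
        width_si_mm = draw(row$width_si_mm %||% NA_real_,
                           row$width_si_sd %||% NA_real_))
    })
    do.call(rbind, out)
  })
}
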