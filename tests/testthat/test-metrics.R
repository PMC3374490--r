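# Glaucoma quantification metrics.

test_that("axon-count estimator is density times area, rounded", {
  expect_equal(estimate_axon_count(axon_sample("n", 0.0889,
                                               rep(527615, 5))), 46905)
  expect_equal(estimate_axon_count(axon_sample("n", 0.0889, rep(0, 5))), 0)
  expect_equal(estimate_axon_count(axon_sample("n", 0.1, c(4e5, 6e5))), 50000)
  expect_error(axon_sample("n", 0.1, numeric(0)), "at least one")
  expect_error(axon_sample("n", -1, 100), "> 0")
})

test_that("axon-count estimator is linear in area and density", {
  dens <- c(3e5, 5e5, 7e5)
  base <- estimate_axon_count(axon_sample("n", 0.05, dens))
  expect_equal(estimate_axon_count(axon_sample("n", 0.10, dens)), 2 * base)
  expect_equal(estimate_axon_count(axon_sample("n", 0.05, 3 * dens)), 3 * base)
})

test_that("percent axon loss matches the pooled-reference definition", {
  expect_equal(percent_axon_loss(46638, 46905), 0.57, tolerance = 0.005)
  expect_equal(percent_axon_loss(40000, 40000), 0)
  expect_equal(percent_axon_loss(30000, 40000), 25)
  expect_lt(percent_axon_loss(50000, 40000), 0)  # gain is permitted
  expect_error(percent_axon_loss(1, 0), "> 0")
  # loss of the group mean equals the mean of per-eye losses
  counts <- c(41000, 39000, 45000, 37000)
  expect_equal(percent_axon_loss(mean(counts), 43628),
               mean(percent_axon_loss(counts, 43628)))
})

test_that("positive integral IOP matches closed forms and a fine-grid oracle", {
  days <- seq(0, 42, 7)
  flat <- iop_series("f", "fellow", days, rep(12, length(days)))
  expect_equal(positive_integral_iop(
    iop_series("t", "treated", days, rep(12, length(days))), flat), 0)
  expect_equal(positive_integral_iop(
    iop_series("t", "treated", days, rep(17, length(days))), flat), 210)
  # sign-crossing series against dense numerical integration
  fine_oracle <- function(d_days, d_iop, f_days, f_iop) {
    g <- seq(max(min(d_days), min(f_days)), min(max(d_days), max(f_days)),
             by = 1e-3)
    diff_g <- stats::approx(d_days, d_iop, g)$y - stats::approx(f_days, f_iop, g)$y
    pos <- pmax(diff_g, 0)
    sum((pos[-1] + pos[-length(pos)]) / 2 * diff(g)[1])
  }
  for (i in 1:20) {
    iop_t <- with_seed(i, 12 + stats::rnorm(length(days), sd = 4))
    iop_f <- with_seed(100L + i, 12 + stats::rnorm(length(days), sd = 4))
    iop_t <- pmax(iop_t, 2); iop_f <- pmax(iop_f, 2)
    got <- positive_integral_iop(iop_series("t", "treated", days, iop_t),
                                 iop_series("f", "fellow", days, iop_f))
    expect_gte(got, 0)
    expect_equal(got, fine_oracle(days, iop_t, days, iop_f), tolerance = 1e-6)
  }
  # equals the full trapezoid when the difference never goes negative
  iop_t <- c(20, 18, 16, 15, 14, 13, 12.5)
  got <- positive_integral_iop(iop_series("t", "treated", days, iop_t), flat)
  d <- iop_t - 12
  expect_equal(got, sum(diff(days) * (d[-1] + d[-length(d)]) / 2),
               tolerance = 1e-12)
  # interpolatable overlap on different day grids
  got2 <- positive_integral_iop(
    iop_series("t", "treated", c(0, 21, 42), c(17, 17, 17)),
    iop_series("f", "fellow", days, rep(12, length(days))))
  expect_equal(got2, 210)
  expect_error(positive_integral_iop(
    iop_series("t", "treated", c(0, 10), c(15, 15)),
    iop_series("f", "fellow", c(20, 30), c(12, 12))), "overlap")
})

test_that("percent dimension change reproduces the cohort arithmetic", {
  expect_equal(round_half_away(percent_dimension_change(4.15, 3.81)), 9)
  expect_equal(round_half_away(percent_dimension_change(3.69, 3.27)), 13)
  expect_equal(percent_dimension_change(3.5, 3.5), 0)
  expect_error(percent_dimension_change(1, 0), "> 0")
})

test_that("RGC body summary computes group means and percent decrease", {
  fields <- rbind(
    data.frame(retina_id = paste0("c", 1:2), group = "WT",
               treatment = "control", count = 256),
    data.frame(retina_id = paste0("t", 1:2), group = "WT",
               treatment = "treated", count = 128))
  fields <- fields[rep(seq_len(nrow(fields)), each = 4L), ]  # 4 fields each
  out <- rgc_body_summary(fields)
  expect_equal(out$decrease$percent_decrease, 50)
  fields$count <- 200
  expect_equal(rgc_body_summary(fields)$decrease$percent_decrease, 0)
  expect_error(rgc_body_summary(fields[0, ]), "empty")
})

test_that("a simulated RGC decrease is recovered without bias", {
  recover <- function(seed) {
    counts <- with_seed(seed, {
      ctl <- stats::rnorm(4 * 4, 256, 53)
      trt <- stats::rnorm(4 * 4, 256 * (1 - 0.17), 53)
      c(ctl, trt)
    })
    fields <- data.frame(
      retina_id = rep(sprintf("r%02d", 1:8), each = 4L),
      group = "Aca23",
      treatment = rep(c("control", "treated"), each = 16L),
      count = counts)
    rgc_body_summary(fields)$decrease$percent_decrease
  }
  est <- vapply(1:500, recover, numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 17), 2 * se + 0.5)  # 0.5: ratio-of-means bias margin
})

test_that("error budget is the linear sum of its components", {
  expect_equal(error_budget(c(0.36, 0.10)), 0.46)
  expect_equal(error_budget(0), 0)
  for (i in 1:10) {
    ab <- with_seed(i, stats::runif(2, 0, 2))
    expect_equal(error_budget(ab), sum(ab))
  }
  expect_error(error_budget(c(0.3, -0.1)), ">= 0")
})
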