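# Per-eye orchestration into region-averaged stress-resultant--strain curves,
# QC exclusion, and group aggregation.

#' Pressure schedule of an inflation protocol
#'
#' @param P0 Reference pressure in mmHg; the lowest pressure at which the
#'   sclera is unwrinkled, typically 6-8 mmHg.
#' @param steps Ascending analyzed pressure steps in mmHg, all > `P0` and
#'   <= 30 (default `c(10, 14, 18, 22, 26, 30)`).
#' @return An object of class `pressure_schedule`.
#' @export
pressure_schedule <- function(P0 = 7, steps = c(10, 14, 18, 22, 26, 30)) {
  stopifnot_scalar(P0, "P0", positive = TRUE)
  steps <- as.numeric(steps)
  if (length(steps) < 1L || any(diff(steps) <= 0))
    stop("steps must be strictly ascending", call. = FALSE)
  if (steps[1L] <= P0) stop("steps must exceed the reference pressure P0",
                            call. = FALSE)
  if (max(steps) > 30)
    warning("pressure steps above 30 mmHg exceed the usual protocol")
  structure(list(P0 = P0, steps = steps), class = "pressure_schedule")
}

#' Analysis configuration
#'
#' Tunable parameters of the per-eye analysis. QC thresholds are anchored to
#' the displacement measurement error of the tracking chain (0.46 um): a step
#' whose displacement fit rms exceeds `qc_rms_multiple` times that noise
#' floor is discarded as a poor polynomial fit, and an eye with more than
#' `qc_max_invalid_fraction` of its scheduled steps invalid or missing is
#' excluded.
#'
#' @param boundaries Region band fractions, see [assign_regions()].
#' @param n_r23,n_r4 Evaluation points in R2-3 and R4.
#' @param noise_floor_um Displacement measurement error in um (default 0.46).
#' @param qc_rms_multiple Multiple of the noise floor tolerated in the
#'   displacement fit rms (default 3).
#' @param qc_max_invalid_fraction Fraction of scheduled steps that may be
#'   invalid before the eye is excluded (default 0.5).
#' @param correspondence_limit_mm Largest plausible per-point displacement
#'   magnitude (mm); larger raw displacements indicate broken point
#'   correspondence (default 0.15).
#' @param onh_end Which end of the trace is the ONH end (see
#'   [parameterize_meridian()]).
#' @return A list of class `inflation_config`.
#' @export
inflation_config <- function(boundaries = c(0.2, 0.4, 0.6, 0.8),
                             n_r23 = 8L, n_r4 = 4L,
                             noise_floor_um = 0.46,
                             qc_rms_multiple = 3,
                             qc_max_invalid_fraction = 0.5,
                             correspondence_limit_mm = 0.15,
                             onh_end = "min_angle") {
  structure(list(boundaries = boundaries, n_r23 = n_r23, n_r4 = n_r4,
                 noise_floor_um = noise_floor_um,
                 qc_rms_multiple = qc_rms_multiple,
                 qc_max_invalid_fraction = qc_max_invalid_fraction,
                 correspondence_limit_mm = correspondence_limit_mm,
                 onh_end = onh_end),
            class = "inflation_config")
}

trace_points_at <- function(traces, pressure) {
  sel <- abs(traces$pressure_mmHg - pressure) < 1e-9
  if (!any(sel)) return(NULL)
  tr <- traces[sel, , drop = FALSE]
  tr <- tr[order(tr$point_index), , drop = FALSE]
  as.matrix(tr[, c("x_mm", "y_mm")])
}

#' Analyze one eye's inflation test
#'
#' Runs the full analysis chain for a single eye: ellipse fit and meridian
#' parameterization of the reference trace at `P0`, region assignment,
#' per-step displacement fits, strains, deformed curvatures and stress
#' resultants at the evaluation locations (by default 8 points over R2-3 and
#' 4 over R4), and region averaging into one stress-resultant--strain curve
#' per region. Steps failing QC are flagged with a reason; an eye with too
#' many invalid steps is excluded.
#'
#' @param traces Long data frame of edge points for one eye (columns
#'   `eye_id`, `pressure_mmHg`, `point_index`, `x_mm`, `y_mm`), containing a
#'   reference trace at `schedule$P0`.
#' @param schedule A [pressure_schedule()].
#' @param config An [inflation_config()].
#' @return An object of class `eye_analysis` with elements `curves` (region
#'   means per step), `samples` (point-level strain/resultant table) and `qc`
#'   (status and reasons).
#' @export
analyze_eye <- function(traces, schedule = pressure_schedule(),
                        config = inflation_config()) {
  stopifnot(inherits(schedule, "pressure_schedule"),
            inherits(config, "inflation_config"))
  traces <- as.data.frame(traces)
  eye_id <- as.character(traces$eye_id[1L])
  ref_pts <- trace_points_at(traces, schedule$P0)
  if (is.null(ref_pts))
    stop(sprintf("eye '%s': missing reference trace at P0 = %g mmHg",
                 eye_id, schedule$P0), call. = FALSE)

  qc_reasons <- character(0)
  meridian <- tryCatch({
    fit <- fit_ellipse(ref_pts)
    m <- parameterize_meridian(fit, ref_pts, onh_end = config$onh_end,
                               eye_id = eye_id, pressure = schedule$P0)
    assign_regions(m, config$boundaries)
  }, error = function(e) e)
  if (inherits(meridian, "error")) {
    return(structure(list(
      curves = NULL, samples = NULL,
      qc = list(eye_id = eye_id, status = "excluded",
                reasons = paste("poor reference geometry:",
                                conditionMessage(meridian)),
                steps = NULL)),
      class = "eye_analysis"))
  }

  eval_pts <- evaluation_locations(meridian, config$n_r23, config$n_r4)
  rms_limit <- um_to_mm(config$noise_floor_um) * config$qc_rms_multiple

  samples <- list()
  step_log <- data.frame(pressure_mmHg = schedule$steps, status = "missing",
                         reason = "no trace at step", fit_rms_um = NA_real_)
  for (k in seq_along(schedule$steps)) {
    p <- schedule$steps[k]
    pts <- trace_points_at(traces, p)
    if (is.null(pts)) next
    if (nrow(pts) != nrow(ref_pts)) {
      step_log$status[k] <- "invalid"
      step_log$reason[k] <- "poor correspondence"
      next
    }
    disp_mag <- row_norm(pts - meridian$points)
    if (max(disp_mag) > config$correspondence_limit_mm) {
      step_log$status[k] <- "invalid"
      step_log$reason[k] <- "poor correspondence"
      next
    }
    dfit <- fit_displacement(meridian, pts, pressure = p)
    step_log$fit_rms_um[k] <- mm_to_um(dfit$fit_rms)
    if (dfit$fit_rms > rms_limit) {
      step_log$status[k] <- "invalid"
      step_log$reason[k] <- "poor displacement fit"
      next
    }
    res <- tryCatch({
      E_phi <- meridional_strain(meridian, dfit, eval_pts$s_mm)
      D <- reference_diameter(meridian, eval_pts$s_mm)
      d <- deformed_diameter(meridian, dfit, eval_pts$s_mm)
      E_theta <- circumferential_strain(D, d)
      curv <- deformed_curvatures(meridian, dfit, eval_pts$s_mm)
      sr <- stress_resultants(p, curv)
      data.frame(eye_id = eye_id, pressure_mmHg = p,
                 region = eval_pts$region, s_mm = eval_pts$s_mm,
                 E_phi = E_phi, E_theta = E_theta,
                 n_phi = sr$n_phi, n_theta = sr$n_theta)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      step_log$status[k] <- "invalid"
      step_log$reason[k] <- conditionMessage(res)
      next
    }
    step_log$status[k] <- "analyzed"
    step_log$reason[k] <- ""
    samples[[length(samples) + 1L]] <- res
  }

  n_bad <- sum(step_log$status != "analyzed")
  excluded <- n_bad / length(schedule$steps) > config$qc_max_invalid_fraction
  if (excluded) {
    reasons <- unique(c(
      step_log$reason[step_log$status == "invalid"],
      if (any(step_log$status == "missing")) "incomplete protocol"))
    return(structure(list(
      curves = NULL,
      samples = if (length(samples)) do.call(rbind, samples) else NULL,
      qc = list(eye_id = eye_id, status = "excluded", reasons = reasons,
                steps = step_log)),
      class = "eye_analysis"))
  }

  samples <- do.call(rbind, samples)
  agg <- stats::aggregate(
    samples[, c("E_phi", "E_theta", "n_phi", "n_theta")],
    by = list(eye_id = samples$eye_id, region = samples$region,
              pressure_mmHg = samples$pressure_mmHg),
    FUN = mean)
  agg <- agg[order(agg$region, agg$pressure_mmHg), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(
    curves = agg, samples = samples,
    qc = list(eye_id = eye_id, status = "analyzed",
              reasons = character(0), steps = step_log)),
    class = "eye_analysis")
}

#' @export
print.eye_analysis <- function(x, ...) {
  cat(sprintf("Eye '%s': %s", x$qc$eye_id, x$qc$status))
  if (length(x$qc$reasons)) cat(" (", paste(x$qc$reasons, collapse = "; "), ")",
                                sep = "")
  cat("\n")
  if (!is.null(x$curves))
    cat(sprintf("  %d region-curve records over %d pressure steps\n",
                nrow(x$curves), length(unique(x$curves$pressure_mmHg))))
  invisible(x)
}

#' Aggregate region curves across groups
#'
#' Produces per-group, per-step mean and standard error of the region-mean
#' strains and stress resultants, with pairwise nonparametric comparisons
#' (Wilcoxon rank-sum; Kruskal-Wallis across all groups when more than two),
#' Bonferroni-corrected across pressure steps within each region/measure
#' family.
#'
#' @param curves Region curves, the row-bound `curves` elements of
#'   [analyze_eye()] results.
#' @param groups Group labels: a data frame with columns `eye_id` and
#'   `group`, or a named character vector indexed by eye id.
#' @param alpha Significance level after correction (default 0.05).
#' @return An object of class `group_comparison` with `summary` (group mean
#'   +/- SE per region/step/measure) and `comparisons` (pairwise tests with
#'   raw and Bonferroni-adjusted p values).
#' @export
aggregate_groups <- function(curves, groups, alpha = 0.05) {
  curves <- as.data.frame(curves)
  if (is.data.frame(groups)) {
    glab <- stats::setNames(as.character(groups$group),
                            as.character(groups$eye_id))
  } else glab <- groups
  curves$group <- unname(glab[as.character(curves$eye_id)])
  if (any(is.na(curves$group)))
    stop("every eye needs a group label", call. = FALSE)
  n_per_group <- tapply(curves$eye_id, curves$group,
                        function(e) length(unique(e)))
  if (any(n_per_group < 2L))
    stop("each group needs at least 2 eyes", call. = FALSE)

  measures <- c("E_phi", "E_theta", "n_phi", "n_theta")
  long <- do.call(rbind, lapply(measures, function(m) {
    data.frame(group = curves$group, eye_id = curves$eye_id,
               region = curves$region, pressure_mmHg = curves$pressure_mmHg,
               measure = m, value = curves[[m]])
  }))
  se <- function(v) stats::sd(v) / sqrt(length(v))
  summary <- do.call(rbind, by(long, long[c("group", "region",
                                            "pressure_mmHg", "measure")],
    function(d) data.frame(group = d$group[1L], region = d$region[1L],
                           pressure_mmHg = d$pressure_mmHg[1L],
                           measure = d$measure[1L],
                           mean = mean(d$value), se = se(d$value),
                           n = nrow(d))))
  rownames(summary) <- NULL
  summary <- summary[order(summary$region, summary$measure,
                           summary$pressure_mmHg, summary$group), ]

  grp <- sort(unique(long$group))
  pairs <- utils::combn(grp, 2L, simplify = FALSE)
  steps <- sort(unique(long$pressure_mmHg))
  comparisons <- list()
  for (reg in sort(unique(long$region))) for (m in measures) {
    for (pr in pairs) {
      praw <- vapply(steps, function(p) {
        d <- long[long$region == reg & long$measure == m &
                    long$pressure_mmHg == p & long$group %in% pr, ]
        if (length(unique(d$group)) < 2L) return(NA_real_)
        suppressWarnings(stats::wilcox.test(value ~ group, data = d)$p.value)
      }, numeric(1))
      padj <- pmin(1, praw * length(steps))  # Bonferroni within family
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        region = reg, measure = m, pressure_mmHg = steps,
        group_a = pr[1L], group_b = pr[2L],
        p_raw = praw, p_adj = padj,
        significant = !is.na(padj) & padj < alpha)
    }
  }
  comparisons <- do.call(rbind, comparisons)
  rownames(comparisons) <- NULL

  overall <- NULL
  if (length(grp) > 2L) {
    overall <- do.call(rbind, lapply(sort(unique(long$region)), function(reg) {
      do.call(rbind, lapply(measures, function(m) {
        praw <- vapply(steps, function(p) {
          d <- long[long$region == reg & long$measure == m &
                      long$pressure_mmHg == p, ]
          stats::kruskal.test(value ~ factor(group), data = d)$p.value
        }, numeric(1))
        data.frame(region = reg, measure = m, pressure_mmHg = steps,
                   p_raw = praw, p_adj = pmin(1, praw * length(steps)))
      }))
    }))
  }
  structure(list(summary = summary, comparisons = comparisons,
                 overall = overall, alpha = alpha,
                 n_per_group = n_per_group),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison: %s eyes per group (%s)\n",
              paste(x$n_per_group, collapse = "/"),
              paste(names(x$n_per_group), collapse = ", ")))
  sig <- x$comparisons[x$comparisons$significant, , drop = FALSE]
  if (nrow(sig) == 0L) {
    cat(sprintf("No comparison significant at adjusted alpha = %g\n", x$alpha))
  } else {
    cat(sprintf("%d significant comparisons (adjusted alpha = %g):\n",
                nrow(sig), x$alpha))
    print(sig[, c("region", "measure", "pressure_mmHg", "group_a", "group_b",
                  "p_adj")], row.names = FALSE)
  }
  invisible(x)
}
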