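# Quantification metrics for experimental glaucoma studies.

#' Axon-density sample for one optic nerve
#'
#' @param nerve_id Identifier.
#' @param nerve_area Optic-nerve cross-section area in mm^2 (> 0).
#' @param field_densities Axon densities (axons/mm^2) of the sampled fields,
#'   >= 0, at least one field.
#' @return An object of class `axon_sample`.
#' @export
axon_sample <- function(nerve_id, nerve_area, field_densities) {
  stopifnot_scalar(nerve_area, "nerve_area", positive = TRUE)
  field_densities <- as.numeric(field_densities)
  if (length(field_densities) < 1L)
    stop("need at least one sampled field", call. = FALSE)
  if (any(field_densities < 0))
    stop("field densities must be >= 0", call. = FALSE)
  structure(list(nerve_id = nerve_id, nerve_area = nerve_area,
                 field_densities = field_densities),
            class = "axon_sample")
}

#' Estimate the axon number of an optic nerve from sampled densities
#'
#' The mean axon density over the sampled fields multiplied by the
#' cross-section area of the individual nerve, rounded to the nearest axon.
#'
#' @param sample An [axon_sample()].
#' @return Estimated axon count (integer-valued numeric).
#' @examples
#' estimate_axon_count(axon_sample("n1", 0.1, c(4e5, 6e5)))  # 50000
#' @export
estimate_axon_count <- function(sample) {
  stopifnot(inherits(sample, "axon_sample"))
  round(mean(sample$field_densities) * sample$nerve_area)
}

#' Percent axon loss against a pooled fellow-eye mean
#'
#' `100 * (1 - count / pooled_fellow_mean)`; negative values (apparent gain)
#' are permitted.
#'
#' @param count Estimated axon count of the experimental eye (or a group
#'   mean).
#' @param pooled_fellow_mean Mean axon number of the pooled fellow-eye
#'   nerves (> 0).
#' @return Percent loss.
#' @examples
#' percent_axon_loss(30000, 40000)  # 25
#' @export
percent_axon_loss <- function(count, pooled_fellow_mean) {
  if (any(pooled_fellow_mean <= 0))
    stop("pooled fellow mean must be > 0", call. = FALSE)
  100 * (1 - count / pooled_fellow_mean)
}

#' Positive integral IOP exposure
#'
#' Cumulative pressure exposure of the treated eye above its fellow control:
#' the time integral of `max(IOP_treated - IOP_fellow, 0)` in mmHg-days,
#' computed by the trapezoidal rule on the measurement days with linear
#' interpolation at sign crossings (exact for piecewise-linear series). When
#' the two series were measured on different days, both are linearly
#' interpolated onto the union of days within their overlapping range; no
#' extrapolation is performed.
#'
#' @param treated,fellow [iop_series()] objects.
#' @return Positive integral in mmHg-days (>= 0).
#' @export
positive_integral_iop <- function(treated, fellow) {
  stopifnot(inherits(treated, "iop_series"), inherits(fellow, "iop_series"))
  lo <- max(min(treated$days), min(fellow$days))
  hi <- min(max(treated$days), max(fellow$days))
  if (hi <= lo) stop("IOP series do not overlap in time", call. = FALSE)
  days <- sort(unique(c(treated$days, fellow$days)))
  days <- days[days >= lo & days <= hi]
  dt <- stats::approx(treated$days, treated$iop, xout = days)$y
  df <- stats::approx(fellow$days, fellow$iop, xout = days)$y
  d <- dt - df
  total <- 0
  for (i in seq_len(length(days) - 1L)) {
    h <- days[i + 1L] - days[i]
    d1 <- d[i]; d2 <- d[i + 1L]
    if (d1 >= 0 && d2 >= 0) {
      total <- total + h * (d1 + d2) / 2
    } else if (d1 > 0 && d2 < 0) {
      total <- total + h * d1^2 / (2 * (d1 - d2))
    } else if (d1 < 0 && d2 > 0) {
      total <- total + h * d2^2 / (2 * (d2 - d1))
    }  # both <= 0: contributes nothing
  }
  total
}

#' Percent change between two group mean dimensions
#'
#' `100 * (a - b) / b`, the percent by which group mean `a` exceeds reference
#' group mean `b`.
#'
#' @param group_mean_a Mean dimension of the comparison group (mm).
#' @param group_mean_b Mean dimension of the reference group (mm, > 0).
#' @return Percent change.
#' @examples
#' percent_dimension_change(4.15, 3.81)  # ~8.9: glaucoma vs control length
#' @export
percent_dimension_change <- function(group_mean_a, group_mean_b) {
  if (any(group_mean_b <= 0))
    stop("reference mean must be > 0", call. = FALSE)
  100 * (group_mean_a - group_mean_b) / group_mean_b
}

#' Summarize retinal ganglion cell body counts
#'
#' Per-retina mean marker-positive counts, per-group mean and SD, and the
#' percent decrease of the treated group mean against the control group mean
#' within each strain group.
#'
#' @param fields Data frame with one row per imaged field: columns
#'   `retina_id`, `group` (e.g. strain), `treatment` (`"control"` or
#'   `"treated"`) and `count` (marker-positive cells in the field).
#' @return List with `retinas` (per-retina means), `groups` (mean +/- SD per
#'   group x treatment) and `decrease` (percent decrease per group).
#' @export
rgc_body_summary <- function(fields) {
  req <- c("retina_id", "group", "treatment", "count")
  if (!all(req %in% names(fields)))
    stop("fields must contain columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(fields) == 0L) stop("empty field table", call. = FALSE)
  retinas <- stats::aggregate(count ~ retina_id + group + treatment,
                              data = fields, FUN = mean)
  names(retinas)[names(retinas) == "count"] <- "mean_count"
  groups <- do.call(rbind, by(retinas, retinas[c("group", "treatment")],
    function(d) data.frame(group = d$group[1L], treatment = d$treatment[1L],
                           mean = mean(d$mean_count),
                           sd = stats::sd(d$mean_count), n = nrow(d))))
  rownames(groups) <- NULL
  decrease <- do.call(rbind, lapply(unique(groups$group), function(g) {
    ctl <- groups$mean[groups$group == g & groups$treatment == "control"]
    trt <- groups$mean[groups$group == g & groups$treatment == "treated"]
    if (length(ctl) != 1L || length(trt) != 1L)
      stop(sprintf("group '%s' needs both control and treated retinas", g),
           call. = FALSE)
    data.frame(group = g, percent_decrease = 100 * (1 - trt / ctl))
  }))
  list(retinas = retinas, groups = groups, decrease = decrease)
}

#' Displacement measurement error budget
#'
#' Linear sum of the non-negative error components of the displacement
#' measurement chain. The tracking chain's budget is 0.36 um pixel-distance
#' calibration uncertainty plus 0.10 um inherent correlation error, i.e.
#' 0.46 um.
#'
#' @param components Non-negative error components in um.
#' @return Total error in um.
#' @examples
#' error_budget(c(0.36, 0.10))  # 0.46
#' @export
error_budget <- function(components) {
  components <- as.numeric(components)
  if (any(components < 0))
    stop("error components must be >= 0", call. = FALSE)
  sum(components)
}
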