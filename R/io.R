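# File formats, run configuration, and the end-to-end pipeline entry point.
#
# All tables are CSV; configuration is YAML or an R list; QC reports are
# JSON. Coordinates are mm internally; traces supplied in um (columns x_um,
# y_um) are converted at ingest.

TRACE_KEY_COLS <- c("eye_id", "pressure_mmHg", "point_index")

#' Read edge traces from CSV
#'
#' Reads a long table of tracked edge points with columns `eye_id`,
#' `pressure_mmHg`, `point_index` and either `x_mm`/`y_mm` or `x_um`/`y_um`
#' (converted to mm). Point order within each (eye, pressure) trace is taken
#' from `point_index`.
#'
#' @param path CSV file path.
#' @return Data frame with columns `eye_id`, `pressure_mmHg`, `point_index`,
#'   `x_mm`, `y_mm`, ordered by eye, pressure and point index.
#' @export
read_edge_traces <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_keys <- setdiff(TRACE_KEY_COLS, names(df))
  if (length(missing_keys))
    stop("edge-trace file is missing required column(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  has_mm <- all(c("x_mm", "y_mm") %in% names(df))
  has_um <- all(c("x_um", "y_um") %in% names(df))
  if (has_mm && has_um)
    stop("edge-trace file mixes mm and um coordinate columns", call. = FALSE)
  if (!has_mm && !has_um)
    stop("edge-trace file is missing coordinate columns x_mm/y_mm (or x_um/y_um)",
         call. = FALSE)
  if (has_um) {
    df$x_mm <- um_to_mm(df$x_um); df$y_mm <- um_to_mm(df$y_um)
    df$x_um <- NULL; df$y_um <- NULL
  }
  key <- do.call(paste, c(df[TRACE_KEY_COLS], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (eye_id, pressure_mmHg, point_index) rows", call. = FALSE)
  df <- df[order(df$eye_id, df$pressure_mmHg, df$point_index), , drop = FALSE]
  rownames(df) <- NULL
  df[, c(TRACE_KEY_COLS, "x_mm", "y_mm")]
}

#' Write edge traces to CSV
#'
#' @param traces Data frame in the layout produced by [read_edge_traces()]
#'   or [simulate_inflation()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_edge_traces <- function(traces, path) {
  utils::write.csv(traces[, c(TRACE_KEY_COLS, "x_mm", "y_mm")], path,
                   row.names = FALSE)
  invisible(path)
}

PIPELINE_CONFIG_KEYS <- c("seed", "traces", "groups", "schedule", "analysis",
                          "out_dir", "dataset_id")

#' Pipeline run configuration
#'
#' Bundles everything a deterministic end-to-end run needs. Unknown keys are
#' rejected before execution.
#'
#' @param traces Path to an edge-trace CSV, or a traces data frame.
#' @param out_dir Output directory.
#' @param schedule A [pressure_schedule()] or a list with `P0` and `steps`.
#' @param analysis An [inflation_config()] (or list of overrides for it).
#' @param groups Optional group labels: data frame (`eye_id`, `group`), named
#'   vector, or CSV path with those columns.
#' @param seed Integer seed recorded in the run log (the analysis itself is
#'   deterministic; the seed governs any simulation feeding the run).
#' @param dataset_id Identifier stamped into the provenance columns.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(traces, out_dir, schedule = pressure_schedule(),
                            analysis = inflation_config(), groups = NULL,
                            seed = 1L, dataset_id = NULL) {
  if (is.list(schedule) && !inherits(schedule, "pressure_schedule"))
    schedule <- do.call(pressure_schedule, schedule)
  if (is.list(analysis) && !inherits(analysis, "inflation_config"))
    analysis <- do.call(inflation_config, analysis)
  cfg <- list(seed = as.integer(seed), traces = traces, groups = groups,
              schedule = schedule, analysis = analysis, out_dir = out_dir,
              dataset_id = dataset_id)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected before execution.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), PIPELINE_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

#' Run the full inflation analysis pipeline
#'
#' Reads (or accepts) edge traces, analyzes every eye with [analyze_eye()],
#' optionally aggregates groups, and writes `region_curves.csv`,
#' `samples.csv`, `qc.json`, `group_comparison.csv` (when groups are given)
#' and `run_log.txt` into the output directory. Outputs are deterministic
#' given the configuration: identical runs produce byte-identical files.
#' Every table carries `dataset_id` and `config_hash` provenance columns.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the per-eye analyses, combined curves, QC
#'   reports and (if requested) the group comparison.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  traces <- config$traces
  dataset_id <- config$dataset_id
  if (is.character(traces)) {
    dataset_id <- dataset_id %||% basename(traces)
    traces <- read_edge_traces(traces)
  } else {
    dataset_id <- dataset_id %||% "in-memory"
    traces <- as.data.frame(traces)
  }
  cfg_hash <- rlang::hash(list(config$schedule, config$analysis, config$seed,
                               dataset_id))

  eyes <- split(traces, traces$eye_id)
  analyses <- lapply(eyes, function(tr)
    tryCatch(analyze_eye(tr, config$schedule, config$analysis),
             error = function(e) structure(list(
               curves = NULL, samples = NULL,
               qc = list(eye_id = as.character(tr$eye_id[1L]),
                         status = "excluded",
                         reasons = conditionMessage(e), steps = NULL)),
               class = "eye_analysis")))

  curves <- do.call(rbind, lapply(analyses, `[[`, "curves"))
  samples <- do.call(rbind, lapply(analyses, `[[`, "samples"))
  qc <- lapply(analyses, `[[`, "qc")
  if (is.null(curves))
    stop("all eyes were excluded by QC; nothing to report", call. = FALSE)
  rownames(curves) <- rownames(samples) <- NULL

  comparison <- NULL
  groups <- config$groups
  if (!is.null(groups)) {
    if (is.character(groups) && length(groups) == 1L && file.exists(groups))
      groups <- utils::read.csv(groups, stringsAsFactors = FALSE)
    comparison <- aggregate_groups(curves, groups)
  }

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) {
    df$dataset_id <- dataset_id; df$config_hash <- cfg_hash; df
  }
  utils::write.csv(stamp(curves), file.path(out, "region_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(stamp(samples), file.path(out, "samples.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(dataset_id = dataset_id, config_hash = cfg_hash,
         eyes = lapply(unname(qc), function(q)
           list(eye_id = q$eye_id, status = q$status,
                reasons = as.list(q$reasons)))),
    file.path(out, "qc.json"), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(comparison)) {
    utils::write.csv(stamp(comparison$comparisons),
                     file.path(out, "group_comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(stamp(comparison$summary),
                     file.path(out, "group_summary.csv"),
                     row.names = FALSE)
  }
  excl <- Filter(function(q) q$status == "excluded", qc)
  log_lines <- c(
    sprintf("sclerashell %s", as.character(utils::packageVersion("sclerashell"))),
    sprintf("dataset: %s", dataset_id),
    sprintf("config hash: %s", cfg_hash),
    sprintf("seed: %d", config$seed),
    sprintf("eyes analyzed: %d, excluded: %d",
            length(analyses) - length(excl), length(excl)),
    vapply(excl, function(q) sprintf("excluded %s: %s", q$eye_id,
                                     paste(q$reasons, collapse = "; ")),
           character(1)))
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(list(analyses = analyses, curves = curves, samples = samples,
                 qc = qc, comparison = comparison, config_hash = cfg_hash))
}
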