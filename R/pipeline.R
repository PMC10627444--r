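#' Run the full assessment pipeline
#'
#' End to end: metric computation (skipped when a pre-computed metric table
#' is supplied), decile-rank scoring, management-key assignment with
#' recommendations, and group summaries for every grouping column present.
#' Deterministic given inputs and configuration.  When `out_dir` is given,
#' writes `metrics.csv`, `scores.csv`, `management.csv`, one
#' `summary_<label>.csv` per grouping column plus `summary_all.csv`, and a
#' `manifest.json` with the configuration echo, a config hash, package and R
#' versions, the seed, and per-stage unit counts.
#'
#' @param input a [landscape()], a metric-table data.frame, or the path to a
#'   metric CSV.
#' @param config a [framework_config()].
#' @param out_dir optional output directory.
#' @param recommendations recommendation table for [recommend()].
#' @return list with `metrics`, `scores`, `management`, `summaries`
#'   (named list of data.frames), and `manifest`.
#' @examples
#' ls <- generate_landscape(seed = 1, n_units = 4, grid_shape = c(60, 60))
#' res <- run_pipeline(ls)
#' res$summaries$all[, c("group", "n_units", "mean_total")]
#' @export
run_pipeline <- function(input, config = framework_config(), out_dir = NULL,
                         recommendations = default_recommendations()) {
  if (inherits(input, "landscape")) {
    metrics <- compute_metrics(input, config)
  } else if (is.data.frame(input)) {
    metrics <- input
  } else if (is.character(input) && length(input) == 1) {
    metrics <- read_metric_table(input)
  } else stop("input must be a landscape, a metric data.frame, or a CSV path")

  n_in <- nrow(metrics)
  complete <- stats::complete.cases(metrics[, metric_columns()$all])
  if (sum(complete) < 2) {
    stop("fewer than 2 units with complete metrics; cannot rank a cohort")
  }
  dropped <- metrics$unit_id[!complete]
  if (length(dropped)) {
    message("excluding ", length(dropped),
            " unit(s) with incomplete metrics: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  scores <- score_table(metrics[complete, , drop = FALSE],
                        dirs = config$dirs, thresholds = config$thresholds)

  mgmt <- data.frame(unit_id = scores$unit_id,
                     management_key = scores$management_key,
                     actions = vapply(scores$management_key, function(k) {
                       if (is.na(k)) NA_character_
                       else paste(recommend(k, recommendations), collapse = "; ")
                     }, "", USE.NAMES = FALSE),
                     stringsAsFactors = FALSE)

  group_cols <- setdiff(names(scores),
                        c("unit_id", "management_key",
                          grep("^(metric_|sum_|score_|total_)",
                               names(scores), value = TRUE)))
  summaries <- list(all = group_summary(scores, NULL,
                                        sd_denominator = config$sd_denominator))
  for (gc in group_cols) {
    summaries[[gc]] <- group_summary(scores, gc,
                                     sd_denominator = config$sd_denominator)
  }

  manifest <- list(
    package = "marshres",
    package_version = as.character(utils::packageVersion("marshres")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    n_units_in = n_in,
    n_units_scored = nrow(scores),
    n_units_dropped = length(dropped),
    config = list(buffer_m = config$buffer_m,
                  connectivity = config$connectivity,
                  scenarios_m = config$scenarios_m,
                  connectedness_slr_m = config$connectedness_slr_m,
                  migration_connected = config$migration_connected,
                  thresholds = config$thresholds,
                  sign = as.list(config$dirs$sign),
                  weight = as.list(config$dirs$weight)))
  manifest$config_hash <- config_hash(manifest$config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_csv(metrics, file.path(out_dir, "metrics.csv"))
    write_table_csv(scores, file.path(out_dir, "scores.csv"))
    write_table_csv(mgmt, file.path(out_dir, "management.csv"))
    for (nm in names(summaries)) {
      write_table_csv(summaries[[nm]],
                      file.path(out_dir, paste0("summary_", nm, ".csv")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(metrics = metrics, scores = scores, management = mgmt,
       summaries = summaries, manifest = manifest)
}

# stable hash of the configuration (md5 of its canonical JSON)
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
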