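#' Read a driver table from CSV
#'
#' Expects a header row naming the ten drivers (see [driver_names()]) plus
#' any identifier/response columns; validates presence and finiteness of the
#' driver columns.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_driver_table <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  missing <- setdiff(driver_names(), names(d))
  if (length(missing) > 0) {
    abort(paste0("driver column(s) missing from ", path, ": ",
                 paste(missing, collapse = ", ")))
  }
  X <- as.matrix(d[driver_names()])
  if (anyNA(X) || !all(is.finite(X))) abort("non-finite driver values")
  d
}

#' Write the tables and manifests of a completed analysis
#'
#' Writes the long NEP grid, truth and mask tables, trend labels and shares,
#' stability statistics with the Jenks break values, the driver table,
#' per-stratum influence, and (when present) scenario share tables as CSV;
#' the break values, configuration and model skill go to a JSON manifest for
#' reproducibility.
#'
#' @param analysis A `sink_analysis` from [run_sink_analysis()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_analysis_outputs <- function(analysis, dir) {
  stopifnot(inherits(analysis, "sink_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(analysis$nep, "nep.csv")
  wr(analysis$mask, "overlap_mask.csv")
  wr(analysis$trends, "trend_labels.csv")
  wr(analysis$trend_shares, "trend_shares.csv")
  wr(analysis$stability, "stability.csv")
  wr(analysis$stability_shares, "stability_shares.csv")
  wr(analysis$drivers, "drivers.csv")
  wr(analysis$attribution$influence, "influence.csv")
  wr(analysis$attribution$groups, "influence_groups.csv")
  if (!is.null(analysis$comparison)) wr(analysis$comparison, "scenario_comparison.csv")
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(analysis$truth, truth_path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    grid_shape = analysis$config$grid_shape,
    years = range(analysis$config$years),
    trend_kinds = analysis$config$trend_kinds,
    noise_sd = analysis$config$noise_sd,
    seed = analysis$config$seed,
    jenks_breaks = as.numeric(attr(analysis$stability, "breaks")),
    hyper = unclass(analysis$models$trend$hyper),
    skill = if (nrow(analysis$attribution$skill) > 0) analysis$attribution$skill)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(files, truth_path, manifest_path))
}
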