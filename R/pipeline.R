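#' End-to-end synthetic carbon-sink analysis
#'
#' Runs the whole pipeline on a synthetic world with known ground truth:
#' generate the NEP grid and overlap mask, decompose every pixel with EEMD,
#' classify trends with the surrogate significance gate, compute the
#' detrended-CV stability statistic with five natural-breaks classes,
#' attribute stability to the ten drivers per overlap stratum, train the
#' scenario classifiers, and project the supplied covariate scenarios.
#'
#' @param config A [synthetic_config()].
#' @param mask_proportions Six stratum fractions for the overlap mask.
#' @param stratum_effects Optional per-stratum driver weights (see
#'   [generate_driver_table()]).
#' @param scenarios Named list; each entry is either a driver-delta vector
#'   or a list `list(deltas =, year =)`, projected via
#'   [generate_scenario_drivers()] + [project_scenario()].
#' @param ensemble_size,noise_amplitude EEMD settings for the decomposition.
#' @param n_null Surrogates for the significance test.
#' @param hyper [brt_config()] for attribution and scenario models.
#' @param attribution_cv Run repeated cross-validation in the attribution
#'   step (slower).
#' @param folds,reps Cross-validation layout.
#' @param min_rows Minimum usable rows for a stratum to be attributed.
#' @param signal,driver_noise_sd Driver-table linkage strength.
#' @param seed Master seed for the full run.
#' @return List of class `sink_analysis`: `truth`, `mask`, `decomposed`,
#'   `trends`, `trend_shares`, `stability`, `stability_shares`,
#'   `attribution`, `models`, `projections`, `comparison`.
#' @export
run_sink_analysis <- function(config = synthetic_config(),
                              mask_proportions = c(0.0371, 0.175, 0.30,
                                                   0.34, 0.11, 0.0379),
                              stratum_effects = NULL,
                              scenarios = NULL,
                              ensemble_size = 100L, noise_amplitude = 0.2,
                              n_null = 200L, hyper = brt_config(),
                              attribution_cv = FALSE, folds = 10L,
                              reps = 10L, min_rows = 200L, signal = 1,
                              driver_noise_sd = 1, seed = 1L) {
  seeds <- child_seeds(seed, 6L)
  config$seed <- seeds[1]
  world <- generate_nep_grid(config)
  mask <- generate_overlap_mask(config$grid_shape, mask_proportions,
                                seed = seeds[2])
  decomposed <- decompose_grid(world$nep, ensemble_size = ensemble_size,
                               noise_amplitude = noise_amplitude,
                               seed = seeds[3])
  trends <- classify_trend_grid(decomposed, n_null = n_null, seed = seeds[4],
                                ensemble_size = ensemble_size,
                                noise_amplitude = noise_amplitude)
  trend_shares <- trend_proportions(trends, mask)
  stability <- classify_stability(world$nep, k = 5L, mask = mask)
  drivers <- generate_driver_table(config, stability, mask = mask,
                                   stratum_effects = stratum_effects,
                                   signal = signal,
                                   driver_noise_sd = driver_noise_sd)
  drivers$stable <- stability_binary(
    stability$stability_class[match(drivers$pixel, stability$pixel)])
  attribution <- stratified_attribution(
    dplyr::filter(drivers, !is.na(.data$stable)), "stable",
    hyper = hyper, folds = folds, reps = reps, seed = seeds[5],
    min_rows = min_rows, cv = attribution_cv)
  models <- train_class_models(trends, stability, drivers, hyper = hyper,
                               seed = seeds[6])
  projections <- NULL
  comparison <- NULL
  if (!is.null(scenarios)) {
    projections <- purrr::imap(scenarios, function(entry, nm) {
      deltas <- if (is.list(entry)) entry$deltas else entry
      year <- if (is.list(entry)) entry$year %||% NA else NA
      sc <- generate_scenario_drivers(drivers, deltas, scenario = nm)
      project_scenario(models, sc, mask, scenario_id = nm, target_year = year)
    })
    if (length(projections) >= 2) {
      comparison <- compare_scenarios(unname(projections))
    }
  }
  structure(list(truth = world$truth, nep = world$nep, mask = mask,
                 decomposed = decomposed, trends = trends,
                 trend_shares = trend_shares, stability = stability,
                 stability_shares = stability_proportions(stability, mask),
                 drivers = drivers, attribution = attribution,
                 models = models, projections = projections,
                 comparison = comparison, config = config),
            class = "sink_analysis")
}

#' @export
print.sink_analysis <- function(x, ...) {
  cat("<sink_analysis>", nrow(x$truth), "pixels x",
      length(x$config$years), "years\n")
  cat("trend labels:\n")
  print(table(x$trends$label))
  cat("stability classes:\n")
  print(table(x$stability$stability_class))
  cat("climate/human influence (national):\n")
  g <- dplyr::filter(x$attribution$groups, .data$stratum == "national")
  print(as.data.frame(g), row.names = FALSE)
  invisible(x)
}
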