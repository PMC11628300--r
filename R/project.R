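#' Train scenario classifiers for future trend and stability classes
#'
#' Two binary boosted-tree classifiers on the historical record: a trend
#' model (significant increases and positive reversals are "enhanced" = 1;
#' decreases and negative reversals "degraded" = 0) and a stability model
#' (classes 1-2 "stable" = 1; classes 4-5 "unstable" = 0). Pixels outside
#' these vocabularies (nonsignificant trends, the middle stability class)
#' are excluded from training and fall into "other" at projection time.
#'
#' @param labels Trend labels per pixel (from [classify_trend_grid()]).
#' @param stability Stability classes per pixel (from
#'   [classify_stability()]).
#' @param drivers Driver table with `pixel` and the ten driver columns.
#' @param hyper A [brt_config()].
#' @param seed Integer seed.
#' @param cv Record repeated cross-validation scores (slower).
#' @param folds,reps Cross-validation layout when `cv = TRUE`.
#' @return List of class `sink_models`: `trend` and `stability` fitted
#'   `sink_brt` classifiers with `$skill` attached when `cv = TRUE`.
#' @export
train_class_models <- function(labels, stability, drivers,
                               hyper = brt_config(), seed = NULL,
                               cv = FALSE, folds = 10L, reps = 10L) {
  seeds <- child_seeds(seed %||% 1L, 4L)
  trend_tbl <- labels |>
    dplyr::mutate(enhanced = dplyr::case_when(
      .data$label %in% c("increasing", "positive_reversal") ~ 1L,
      .data$label %in% c("decreasing", "negative_reversal") ~ 0L,
      TRUE ~ NA_integer_)) |>
    dplyr::filter(!is.na(.data$enhanced)) |>
    dplyr::inner_join(
      dplyr::select(drivers, "pixel",
                    dplyr::any_of(c(driver_names(), "stratum"))),
      by = "pixel")
  stab_tbl <- stability |>
    dplyr::mutate(stable = stability_binary(.data$stability_class)) |>
    dplyr::filter(!is.na(.data$stable)) |>
    dplyr::inner_join(
      dplyr::select(drivers, "pixel",
                    dplyr::any_of(c(driver_names(), "stratum"))),
      by = "pixel")
  for (nm in c("enhanced", "stable")) {
    tb <- if (nm == "enhanced") trend_tbl else stab_tbl
    if (length(unique(tb[[nm]])) < 2) {
      abort(paste0("training class missing for the ", nm, " model"))
    }
  }
  trend_fit <- fit_brt(trend_tbl, "enhanced", hyper = hyper, seed = seeds[1])
  stab_fit <- fit_brt(stab_tbl, "stable", hyper = hyper, seed = seeds[2])
  if (cv) {
    trend_fit$skill <- cross_validate(trend_tbl, "enhanced", hyper = hyper,
                                      folds = folds, reps = reps,
                                      seed = seeds[3])
    stab_fit$skill <- cross_validate(stab_tbl, "stable", hyper = hyper,
                                     folds = folds, reps = reps,
                                     seed = seeds[4])
  }
  structure(list(trend = trend_fit, stability = stab_fit),
            class = "sink_models")
}

#' Project trend and stability classes under a covariate scenario
#'
#' Applies the fitted classifiers to scenario driver grids. Pixels with
#' class probability above 1/2 are classed enhanced/stable, below 1/2
#' degraded/unstable, exactly 1/2 "other". Deterministic given the models.
#'
#' @param models A `sink_models` from [train_class_models()].
#' @param scenario Scenario driver table: `pixel`, the ten driver columns
#'   and optionally `scenario`; missing drivers raise an error naming them.
#' @param mask Overlap mask (`pixel`, `stratum`).
#' @param scenario_id,target_year Identifiers carried into the output.
#' @return List of class `sink_projection`: `pixels` (per-pixel classes and
#'   probabilities) and `shares` (per-stratum percentages by class type;
#'   rows sum to 100 within stratum and class type).
#' @export
project_scenario <- function(models, scenario, mask,
                             scenario_id = NULL, target_year = NA) {
  stopifnot(inherits(models, "sink_models"))
  scenario_id <- scenario_id %||%
    (if ("scenario" %in% names(scenario)) scenario$scenario[1] else "scenario")
  p_trend <- predict(models$trend, scenario, type = "response")
  p_stab <- predict(models$stability, scenario, type = "response")
  class_of <- function(p, hi, lo) {
    dplyr::case_when(p > 0.5 ~ hi, p < 0.5 ~ lo, TRUE ~ "other")
  }
  pixels <- tibble::tibble(
    pixel = scenario$pixel,
    scenario = scenario_id, target_year = target_year,
    p_enhanced = p_trend, p_stable = p_stab,
    trend_class = class_of(p_trend, "enhanced", "degraded"),
    stability_class = class_of(p_stab, "stable", "unstable")) |>
    dplyr::inner_join(dplyr::select(mask, "pixel", "stratum"), by = "pixel")
  shares <- dplyr::bind_rows(
    pixels |>
      dplyr::count(.data$stratum, class = .data$trend_class) |>
      dplyr::mutate(type = "trend"),
    pixels |>
      dplyr::count(.data$stratum, class = .data$stability_class) |>
      dplyr::mutate(type = "stability")) |>
    dplyr::group_by(.data$type, .data$stratum) |>
    dplyr::mutate(share = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(scenario = scenario_id, target_year = target_year)
  structure(list(pixels = pixels, shares = shares),
            class = "sink_projection")
}

#' @export
print.sink_projection <- function(x, ...) {
  cat("<sink_projection>", x$pixels$scenario[1], "| year",
      x$pixels$target_year[1], "|", nrow(x$pixels), "pixels\n")
  print(tidyr::pivot_wider(x$shares,
                           id_cols = c("type", "stratum"),
                           names_from = "class", values_from = "share",
                           values_fill = 0))
  invisible(x)
}

#' Compare class shares across projected scenarios
#'
#' Long comparison table of per-stratum class shares for two or more
#' projections on the same grid, with a `difference` column against the
#' first (reference) projection.
#'
#' @param results List of `sink_projection` objects.
#' @return Tibble `scenario`, `target_year`, `type`, `stratum`, `class`,
#'   `share`, `difference` (share minus the reference scenario's share for
#'   the same stratum/type/class).
#' @export
compare_scenarios <- function(results) {
  stopifnot(length(results) >= 2,
            all(vapply(results, inherits, logical(1), "sink_projection")))
  pix_sets <- lapply(results, function(r) sort(unique(r$pixels$pixel)))
  if (!all(vapply(pix_sets, identical, logical(1), pix_sets[[1]]))) {
    abort("grid mismatch: projections cover different pixel sets")
  }
  all_shares <- purrr::map_dfr(results, function(r)
    dplyr::select(r$shares, "scenario", "target_year", "type", "stratum",
                  "class", "share"))
  grid <- dplyr::distinct(all_shares, .data$type, .data$stratum, .data$class)
  full <- all_shares |>
    dplyr::distinct(.data$scenario, .data$target_year) |>
    tidyr::expand_grid(grid) |>
    dplyr::left_join(all_shares,
                     by = c("scenario", "target_year", "type", "stratum",
                            "class")) |>
    dplyr::mutate(share = dplyr::coalesce(.data$share, 0))
  ref <- full |>
    dplyr::filter(.data$scenario == results[[1]]$shares$scenario[1],
                  .data$target_year %in% results[[1]]$shares$target_year[1]) |>
    dplyr::select("type", "stratum", "class", ref_share = "share") |>
    dplyr::distinct(.data$type, .data$stratum, .data$class,
                    .keep_all = TRUE)
  full |>
    dplyr::left_join(ref, by = c("type", "stratum", "class"),
                     relationship = "many-to-one") |>
    dplyr::mutate(difference = .data$share - .data$ref_share) |>
    dplyr::select(-"ref_share")
}
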