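#' Configuration of the synthetic carbon-sink world
#'
#' Defines a gridded annual NEP record with known per-pixel trend shapes,
#' interannual noise, an optional quasi-periodic oscillation, and a known
#' driver-to-stability linkage, so that every downstream stage can be
#' validated against ground truth. The grid is split into as many contiguous
#' column bands as there are `trend_kinds`; every pixel in a band shares
#' that band's trend shape.
#'
#' Defaults emulate the study conditions of a national annual NEP record:
#' 38 years (1982-2019), a mean sink level of 300 gC m-2 yr-1, a secular
#' trend of about 1 gC m-2 yr-1 per year, interannual noise of 8 gC m-2 yr-1
#' (fluctuations of roughly +/- 16), and a mid-record turning point (2000)
#' for reversal pixels.
#'
#' @param grid_shape Integer `(rows, cols)`.
#' @param years Inclusive, consecutive year range (>= 16 years).
#' @param trend_kinds Character vector drawn from `linear_up`, `linear_down`,
#'   `reversal_up`, `reversal_down`, `flat`; one grid band per entry.
#' @param trend_rate Trend magnitude, gC m-2 yr-1 per year.
#' @param turning_point_year Reversal vertex year, strictly inside `years`.
#' @param base_level Mean NEP level, gC m-2 yr-1 (positive: sink pixels).
#' @param noise_sd Interannual Gaussian noise SD, gC m-2 yr-1.
#' @param oscillation `list(amplitude =, period =)` of an added sinusoid.
#' @param driver_effects Named weights (the ten [driver_names()]) linking
#'   drivers to the stability response in [generate_driver_table()].
#' @param reversal_shape `"piecewise"` (two linear segments, exact truth
#'   bookkeeping) or `"quadratic"` (smooth vertex).
#' @param seed Integer master seed; pixels draw from child streams indexed
#'   by pixel counter, so generated values do not depend on pixel order.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(20L, 30L), years = 1982:2019,
                             trend_kinds = c("linear_up", "linear_down",
                                             "reversal_up", "reversal_down",
                                             "flat"),
                             trend_rate = 1, turning_point_year = 2000L,
                             base_level = 300, noise_sd = 8,
                             oscillation = list(amplitude = 0, period = 6),
                             driver_effects = c(TEM = 1, PRE = 0.5, SOIL = 1.5,
                                                VPD = 0.25, RAD = 1, CO2 = 1.5,
                                                N2O = 0.25, LUC = 1, POP = 0.5,
                                                GDP = 0.5),
                             reversal_shape = c("piecewise", "quadratic"),
                             seed = 1L) {
  reversal_shape <- match.arg(reversal_shape)
  kinds <- c("linear_up", "linear_down", "reversal_up", "reversal_down", "flat")
  bad <- setdiff(trend_kinds, kinds)
  if (length(bad) > 0) {
    abort(paste0("invalid trend_kind: ", paste(bad, collapse = ", ")))
  }
  if (length(years) < 16L) abort("years must span at least 16 values")
  if (any(diff(years) != 1L)) abort("years must be consecutive")
  if (turning_point_year <= min(years) || turning_point_year >= max(years)) {
    abort("turning_point_year must lie strictly inside the year range")
  }
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (!setequal(names(driver_effects), driver_names())) {
    abort("driver_effects must name exactly the ten drivers")
  }
  structure(list(grid_shape = as.integer(grid_shape), years = as.integer(years),
                 trend_kinds = trend_kinds, trend_rate = trend_rate,
                 turning_point_year = as.integer(turning_point_year),
                 base_level = base_level, noise_sd = noise_sd,
                 oscillation = oscillation,
                 driver_effects = driver_effects[driver_names()],
                 reversal_shape = reversal_shape, seed = as.integer(seed)),
            class = "synthetic_config")
}

kind_to_label <- function(kind) {
  c(linear_up = "increasing", linear_down = "decreasing",
    reversal_up = "positive_reversal", reversal_down = "negative_reversal",
    flat = "nonsignificant")[kind]
}

# noiseless signal for one pixel
synthetic_signal <- function(config, kind) {
  t <- config$years
  tp <- config$turning_point_year
  r <- config$trend_rate
  base <- config$base_level
  trend <- switch(kind,
    linear_up = base + r * (t - min(t)),
    linear_down = base - r * (t - min(t)),
    reversal_up = if (config$reversal_shape == "piecewise") {
      base + r * abs(t - tp)
    } else {
      base + r * (t - tp)^2 / (max(t) - tp)
    },
    reversal_down = if (config$reversal_shape == "piecewise") {
      base + r * (max(t) - min(t)) / 2 - r * abs(t - tp)
    } else {
      base + r * (max(t) - min(t)) / 2 - r * (t - tp)^2 / (max(t) - tp)
    },
    flat = rep(base, length(t)))
  osc <- config$oscillation$amplitude *
    sin(2 * pi * (t - min(t)) / config$oscillation$period)
  trend + osc
}

#' Generate a synthetic annual NEP grid with known ground truth
#'
#' Every pixel's series is (piecewise-)linear trend + sinusoid + iid
#' Gaussian noise, with the trend shape set by the pixel's grid band. The
#' truth table records the noiseless components: the trend label, the
#' turning-point year for reversal pixels, and the detrended coefficient of
#' variation of the noiseless series.
#'
#' @param config A [synthetic_config()].
#' @return List with `nep` (long tibble `pixel, row, col, year, nep`) and
#'   `truth` (tibble `pixel, row, col, trend_kind, label,
#'   turning_point_year, cv_true, mean_true`).
#' @examples
#' world <- generate_nep_grid(synthetic_config(grid_shape = c(4, 5)))
#' dplyr::count(world$truth, label)
#' @export
generate_nep_grid <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  npix <- nr * nc
  t <- config$years
  grid <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc)) |>
    dplyr::mutate(pixel = dplyr::row_number(), .before = 1)
  band <- ceiling(grid$col / (nc / length(config$trend_kinds)))
  band <- pmin(pmax(band, 1L), length(config$trend_kinds))
  grid$trend_kind <- config$trend_kinds[band]
  seeds <- child_seeds(config$seed, npix)

  signals <- lapply(unique(grid$trend_kind), function(k)
    synthetic_signal(config, k))
  names(signals) <- unique(grid$trend_kind)

  nep <- purrr::map_dfr(seq_len(npix), function(i) {
      px <- grid[i, ]
      sig <- signals[[px$trend_kind]]
      noise <- if (config$noise_sd > 0) {
        with_seed(seeds[px$pixel], rnorm(length(t), 0, config$noise_sd))
      } else {
        numeric(length(t))
      }
      tibble::tibble(pixel = px$pixel, row = px$row, col = px$col,
                     year = t, nep = sig + noise)
  })

  truth <- grid |>
    dplyr::mutate(
      label = unname(kind_to_label(.data$trend_kind)),
      turning_point_year = ifelse(
        .data$trend_kind %in% c("reversal_up", "reversal_down"),
        config$turning_point_year, NA_real_),
      cv_true = purrr::map_dbl(.data$trend_kind, function(k) {
        s <- signals[[k]]
        mu <- mean(s)
        det <- detrend_series(s, t)
        sqrt(mean((det - mu)^2)) / mu
      }),
      mean_true = purrr::map_dbl(.data$trend_kind,
                                 function(k) mean(signals[[k]])))
  list(nep = nep, truth = truth)
}

#' Generate a driver table with a known importance structure
#'
#' Builds the ten driver covariates so that each driver's association with
#' the supplied stability response is proportional to its weight in
#' `effects`: driver j is `w_j * standardized(stability) * signal + noise`.
#' Drivers with zero weight are independent of the response. Per-stratum
#' weight sets (e.g. climate-dominant in high-overlap strata) can be given
#' via `stratum_effects`.
#'
#' @param config A [synthetic_config()] (supplies the default weights and
#'   seed).
#' @param stability Tibble with `pixel` and a response column `cv` (finite).
#' @param mask Optional overlap mask (`pixel`, `stratum`); attaches the
#'   stratum column and enables `stratum_effects`.
#' @param stratum_effects Optional named list `stratum value -> weight
#'   vector` overriding `config$driver_effects` within that stratum.
#' @param signal Association strength (driver signal-to-noise scale).
#' @param driver_noise_sd SD of the independent driver noise.
#' @return Tibble: `pixel`, ten driver columns, `cv` (response) and, with a
#'   mask, `stratum`.
#' @export
generate_driver_table <- function(config, stability, mask = NULL,
                                  stratum_effects = NULL, signal = 1,
                                  driver_noise_sd = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!all(c("pixel", "cv") %in% names(stability))) {
    abort("stability must carry pixel and cv columns")
  }
  if (anyNA(stability$cv) || !all(is.finite(stability$cv))) {
    abort("stability grid must be finite")
  }
  d <- dplyr::arrange(stability, .data$pixel)
  if (!is.null(mask)) {
    assert_grid_compatible(
      dplyr::mutate(d, row = 1L, col = 1L),
      dplyr::mutate(dplyr::distinct(mask, .data$pixel), row = 1L, col = 1L),
      "stability and mask")
    d <- dplyr::inner_join(d, dplyr::select(mask, "pixel", "stratum"),
                           by = "pixel")
  }
  n <- nrow(d)
  s_std <- as.numeric(scale(d$cv))
  if (anyNA(s_std)) s_std <- numeric(n) # constant response degenerate case
  seeds <- child_seeds(config$seed + 1L, n)
  W <- matrix(rep(config$driver_effects, each = n), nrow = n,
              dimnames = list(NULL, driver_names()))
  if (!is.null(stratum_effects)) {
    if (is.null(mask)) abort("stratum_effects requires a mask")
    for (s in names(stratum_effects)) {
      rows <- d$stratum == as.integer(s)
      W[rows, ] <- matrix(rep(stratum_effects[[s]][driver_names()],
                              each = sum(rows)), nrow = sum(rows))
    }
  }
  noise <- t(vapply(seq_len(n), function(i)
    with_seed(seeds[i], rnorm(10, 0, driver_noise_sd)), numeric(10)))
  X <- W * s_std * signal + noise
  colnames(X) <- driver_names()
  dplyr::bind_cols(dplyr::select(d, dplyr::any_of(c("pixel", "stratum"))),
                   tibble::as_tibble(X),
                   tibble::tibble(cv = d$cv))
}

#' Generate an integer project-overlap mask
#'
#' Assigns each pixel an overlap stratum 0-5 so that the empirical stratum
#' fractions match the requested proportions to within one pixel (largest
#' remainder apportionment); stratum placement over the grid is random.
#'
#' @param grid_shape Integer `(rows, cols)`.
#' @param proportions Six non-negative fractions (strata 0-5) summing to 1.
#' @param seed Integer seed for the placement.
#' @return Tibble `pixel`, `row`, `col`, `stratum`.
#' @examples
#' m <- generate_overlap_mask(c(20, 30), rep(1 / 6, 6), seed = 1)
#' table(m$stratum)
#' @export
generate_overlap_mask <- function(grid_shape, proportions, seed = 1L) {
  if (length(proportions) != 6L) abort("six proportions (strata 0-5) required")
  if (any(proportions < 0)) abort("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9) abort("proportions must sum to 1")
  nr <- grid_shape[1]; nc <- grid_shape[2]
  npix <- nr * nc
  counts <- floor(proportions * npix)
  rem <- proportions * npix - counts
  short <- npix - sum(counts)
  if (short > 0) {
    top_up <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[top_up] <- counts[top_up] + 1
  }
  strata <- rep(0:5, times = counts)
  strata <- with_seed(seed, sample(strata))
  tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc)) |>
    dplyr::mutate(pixel = dplyr::row_number(), .before = 1) |>
    dplyr::mutate(stratum = strata)
}

#' Shift driver covariates to emulate a future scenario
#'
#' Adds configurable mean deltas to named driver columns: a minimal stand-in
#' for scenario covariate sets (no climate-model emulation is attempted).
#'
#' @param drivers A driver table (ten driver columns).
#' @param deltas Named numeric vector of mean shifts (subset of drivers).
#' @param scenario Scenario identifier attached as a column.
#' @return The shifted driver table with a `scenario` column.
#' @export
generate_scenario_drivers <- function(drivers, deltas,
                                      scenario = "scenario") {
  bad <- setdiff(names(deltas), driver_names())
  if (length(bad) > 0) {
    abort(paste0("unknown driver(s) in deltas: ", paste(bad, collapse = ", ")))
  }
  out <- drivers
  for (nm in names(deltas)) out[[nm]] <- out[[nm]] + deltas[[nm]]
  dplyr::mutate(out, scenario = scenario)
}
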