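#' Ordinary least-squares linear trend of an annual series
#'
#' @param values Numeric annual values.
#' @param years Numeric years (default a unit index).
#' @return A list with `slope` (units per year) and `intercept`.
#' @examples
#' linear_trend(2 * (1990:2019) + 3, 1990:2019)
#' @export
linear_trend <- function(values, years = seq_along(values)) {
  if (length(values) != length(years)) abort("years and values differ in length")
  if (length(unique(years)) < 2L) abort("degenerate series: years are constant")
  fit <- stats::lm.fit(cbind(1, years), values)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]))
}

# sign changes of the residual first differences, ignoring changes whose
# vertex falls within `guard` years of either end. Zero rates inherit the
# previous sign so plateaus do not spawn spurious reversals.
residual_sign_changes <- function(residual, guard = 3L) {
  rate <- diff(residual)
  tol <- 1e-9 * diff(range(residual))
  rate[abs(rate) <= tol] <- 0
  s <- sign(rate)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  nz <- which(s != 0)
  if (length(nz) == 0) return(list(changes = integer(), first_sign = 0))
  s[s == 0] <- s[nz[1]]
  chg <- which(s[-1] != s[-length(s)]) # vertex between rate chg and chg+1
  n <- length(residual)
  keep <- chg + 1L > guard & chg + 1L <= n - guard
  list(changes = chg[keep], first_sign = s[1], signs = s)
}

#' Monte-Carlo surrogate significance test for an (E)EMD residual trend
#'
#' Tests whether a pixel's residual trend is distinguishable from what
#' (E)EMD extracts from structureless noise. The observed statistic is the
#' total variation of the residual (the sum of absolute year-to-year
#' changes; for a monotone residual this is exactly the absolute net
#' change, and it remains sensitive to reversal shapes whose net change
#' cancels) studentised by the standard deviation of the oscillatory part
#' `values - residual`, making it scale-free. The null distribution comes
#' from decomposing `n_null` surrogates — white noise by default, or
#' phase-randomised copies — with the same settings, and the p-value is the
#' Monte-Carlo rank `(1 + #(null >= observed)) / (n_null + 1)`.
#'
#' Because the statistic is studentised, its null distribution depends only
#' on the series length and decomposition settings, not on the series
#' variance; a precomputed [null_trend_statistics()] sample can therefore be
#' shared across the pixels of a grid.
#'
#' @param values The annual series.
#' @param decomposition Its `imf_decomposition`; computed with [emd()]
#'   defaults when missing.
#' @param n_null Number of surrogate series (>= 100).
#' @param alpha Significance level.
#' @param surrogate `"white"` (iid Gaussian) or `"phase"` (phase
#'   randomisation, preserving the power spectrum).
#' @param seed Seed for surrogate generation.
#' @param null_stats Optional precomputed null statistics from
#'   [null_trend_statistics()] with matching length and settings.
#' @return List: `significant`, `p_value`, `statistic`, `null_quantile`
#'   (the (1-alpha) null quantile).
#' @export
significance_test <- function(values, decomposition = NULL, n_null = 200L,
                              alpha = 0.05, surrogate = c("white", "phase"),
                              seed = NULL, null_stats = NULL) {
  surrogate <- match.arg(surrogate)
  if (is.null(decomposition)) decomposition <- emd(values)
  if (is.null(null_stats)) {
    if (n_null < 100L) abort("n_null must be at least 100")
    null_stats <- null_trend_statistics(
      n_years = length(values), n_null = n_null, surrogate = surrogate,
      seed = seed, template = if (surrogate == "phase") values,
      ensemble_size = decomposition$ensemble_size,
      noise_amplitude = decomposition$noise_amplitude,
      config = decomposition$config)
  }
  obs <- trend_statistic(values, decomposition$residual)
  p <- (1 + sum(null_stats >= obs)) / (length(null_stats) + 1)
  list(significant = p <= alpha, p_value = p, statistic = obs,
       null_quantile = unname(quantile(null_stats, 1 - alpha, names = FALSE)))
}

# residual total variation studentised by the oscillatory-part SD;
# 0/0 -> 0 (no trend), x/0 -> Inf (noiseless trend)
trend_statistic <- function(values, residual) {
  num <- sum(abs(diff(residual)))
  den <- sd(values - residual)
  if (num == 0) return(0)
  if (!is.finite(den) || den == 0) return(Inf)
  num / den
}

#' Null distribution of the studentised residual-trend statistic
#'
#' Decomposes `n_null` surrogate series and returns the studentised residual
#' total variation of each, for use as a shared null in [significance_test()] across
#' all pixels of a grid with the same record length and settings.
#'
#' @param n_years Series length.
#' @param n_null Number of surrogates.
#' @param surrogate `"white"` or `"phase"` (the latter requires `template`).
#' @param template Series whose spectrum phase-randomised surrogates keep.
#' @param seed Seed.
#' @inheritParams eemd
#' @return Numeric vector of `n_null` null statistics.
#' @export
null_trend_statistics <- function(n_years, n_null = 200L,
                                  surrogate = c("white", "phase"),
                                  template = NULL, seed = NULL,
                                  ensemble_size = 1L, noise_amplitude = 0,
                                  config = sift_config()) {
  surrogate <- match.arg(surrogate)
  if (surrogate == "phase" && is.null(template)) {
    abort("phase surrogates need a template series")
  }
  with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      z <- if (surrogate == "white") rnorm(n_years) else
        phase_randomize(template)
      d <- if (ensemble_size > 1L && noise_amplitude > 0) {
        eemd(z, ensemble_size = ensemble_size,
             noise_amplitude = noise_amplitude, config = config)
      } else {
        emd(z, config = config)
      }
      trend_statistic(z, d$residual)
    }, numeric(1))
  })
}

# spectrum-preserving surrogate: random phases with conjugate symmetry
phase_randomize <- function(x) {
  n <- length(x)
  mu <- mean(x)
  f <- fft(x - mu)
  m <- floor((n - 1) / 2)
  ph <- runif(m, 0, 2 * pi)
  phase <- numeric(n)
  phase[2:(m + 1)] <- ph
  phase[n:(n - m + 1)] <- -ph
  fnew <- complex(modulus = Mod(f), argument = phase)
  fnew[1] <- f[1]
  if (n %% 2 == 0) fnew[n / 2 + 1] <- f[n / 2 + 1]
  Re(fft(fnew, inverse = TRUE)) / n + mu
}

#' Classify a pixel's nonlinear trend
#'
#' Labels the (E)EMD residual as `increasing` or `decreasing` (monotone
#' rates), `positive_reversal` (decreasing then increasing) or
#' `negative_reversal` (increasing then decreasing) with the turning-point
#' year, or `nonsignificant` when the surrogate test fails. Sign changes
#' within `guard` years of either end are ignored (end-effect protection),
#' and a reversal is declared only when each of its two monotone segments
#' carries at least `min_segment` of the residual's total variation;
#' otherwise the pixel is treated as monotone in the direction of its net
#' change. Residuals with more than one interior sign change are labelled
#' by the segments around the last admissible turning point and flagged
#' `complex`.
#'
#' @param decomposition An `imf_decomposition` of the pixel series.
#' @param guard Years at each end within which rate sign changes are ignored.
#' @param min_segment Minimum fraction of the residual's total variation
#'   each reversal segment must carry.
#' @param alpha,n_null,surrogate,seed,null_stats Passed to
#'   [significance_test()].
#' @param test Set `FALSE` to skip the significance gate (label by shape).
#' @return One-row tibble: `label`, `turning_point_year`,
#'   `residual_net_change`, `linear_slope`, `p_value`, `significant`,
#'   `complex`.
#' @export
classify_trend <- function(decomposition, guard = 3L, min_segment = 0.2,
                           alpha = 0.05, n_null = 200L, surrogate = "white",
                           seed = NULL, null_stats = NULL, test = TRUE) {
  stopifnot(inherits(decomposition, "imf_decomposition"))
  res <- decomposition$residual
  years <- decomposition$years
  sc <- residual_sign_changes(res, guard = guard)
  lt <- linear_trend(decomposition$values, years)
  net <- res[length(res)] - res[1]

  if (test) {
    st <- significance_test(decomposition$values, decomposition,
                            n_null = n_null, alpha = alpha,
                            surrogate = surrogate, seed = seed,
                            null_stats = null_stats)
  } else {
    st <- list(significant = TRUE, p_value = NA_real_)
  }

  complex_shape <- length(sc$changes) > 1L
  if (complex_shape) {
    warn("residual has multiple interior sign changes; labelling by the final segments")
  }
  tp <- NA_real_
  total_var <- sum(abs(diff(res)))
  if (!st$significant || sc$first_sign == 0) {
    label <- "nonsignificant"
  } else if (length(sc$changes) == 0L) {
    label <- if (net >= 0) "increasing" else "decreasing"
  } else {
    i <- sc$changes[length(sc$changes)]
    seg_before <- res[i + 1L] - res[1]
    seg_after <- res[length(res)] - res[i + 1L]
    if (min(abs(seg_before), abs(seg_after)) < min_segment * total_var) {
      label <- if (net >= 0) "increasing" else "decreasing"
    } else {
      tp <- years[i + 1L]
      label <- if (seg_after > 0) "positive_reversal" else "negative_reversal"
    }
  }
  tibble::tibble(label = label, turning_point_year = tp,
                 residual_net_change = net, linear_slope = lt$slope,
                 p_value = st$p_value, significant = st$significant,
                 complex = complex_shape)
}

#' Classify the trend of every pixel in a decomposed grid
#'
#' Grid version of [classify_trend()] working from the output of
#' [decompose_grid()]. The surrogate null is computed once — the studentised
#' statistic is scale-free, so one null sample serves every pixel with the
#' same record length and decomposition settings — and shared.
#'
#' @param decomposed Tibble from [decompose_grid()] (columns `pixel`, `row`,
#'   `col`, `year`, `nep`, `residual`).
#' @param match_null When `TRUE` the surrogate decomposition matches
#'   `ensemble_size`/`noise_amplitude`; when `FALSE` surrogates use plain
#'   EMD, which is far cheaper and has a nearly identical studentised null.
#' @inheritParams classify_trend
#' @inheritParams eemd
#' @return Tibble, one row per pixel, with the [classify_trend()] columns.
#' @export
classify_trend_grid <- function(decomposed, guard = 3L, min_segment = 0.2,
                                alpha = 0.05, n_null = 200L, seed = NULL,
                                ensemble_size = 100L, noise_amplitude = 0.2,
                                match_null = FALSE,
                                config = sift_config()) {
  stopifnot(all(c("pixel", "row", "col", "year", "nep", "residual")
                %in% names(decomposed)))
  n_years <- dplyr::n_distinct(decomposed$year)
  null_stats <- null_trend_statistics(
    n_years = n_years, n_null = n_null, seed = seed,
    ensemble_size = if (match_null) ensemble_size else 1L,
    noise_amplitude = if (match_null) noise_amplitude else 0,
    config = config)
  out <- decomposed |>
    dplyr::arrange(.data$pixel, .data$year) |>
    dplyr::group_by(.data$pixel, .data$row, .data$col) |>
    dplyr::group_modify(function(d, key) {
      dec <- structure(list(imfs = matrix(numeric(), length(d$nep), 0),
                            residual = d$residual, values = d$nep,
                            years = d$year, ensemble_size = 1L,
                            noise_amplitude = 0, config = config),
                       class = "imf_decomposition")
      suppressWarnings(
        classify_trend(dec, guard = guard, min_segment = min_segment,
                       alpha = alpha, null_stats = null_stats))
    }) |>
    dplyr::ungroup()
  n_complex <- sum(out$complex)
  if (n_complex > 0) {
    warn(paste0(n_complex, " pixel(s) had multiple residual sign changes; ",
                "labelled by their final segments"))
  }
  out
}

#' Trend-label composition per project-overlap stratum
#'
#' Percentage of pixels carrying each trend label within each overlap
#' stratum (number of ecological projects covering the pixel, 0-5). Rows sum
#' to 100; strata with no pixels are absent rather than zero-filled.
#'
#' @param labels Tibble with `pixel`, `row`, `col`, `label`.
#' @param mask Tibble with `pixel`, `row`, `col`, `stratum`.
#' @return Tibble `stratum`, `label`, `n`, `share` (percent).
#' @export
trend_proportions <- function(labels, mask) {
  assert_grid_compatible(labels, mask)
  labels |>
    dplyr::inner_join(dplyr::select(mask, "pixel", "stratum"), by = "pixel") |>
    dplyr::filter(!is.na(.data$label)) |>
    dplyr::count(.data$stratum, .data$label, name = "n") |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(share = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
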