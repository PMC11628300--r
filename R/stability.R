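#' Remove the linear trend from an annual series, preserving its mean
#'
#' Subtracts the fitted OLS line and adds back the series mean:
#' `detrended = values - (a*year + b) + mean(values)`. The result has the
#' same mean as the input and zero OLS slope against year.
#'
#' @inheritParams linear_trend
#' @return Numeric vector of detrended values.
#' @export
detrend_series <- function(values, years = seq_along(values)) {
  lt <- linear_trend(values, years)
  values - (lt$slope * years + lt$intercept) + mean(values)
}

#' Detrended coefficient of variation of a carbon-sink series
#'
#' The stability statistic: population standard deviation (divide-by-N) of
#' the detrended series about its mean, divided by the mean,
#' `cv = sqrt(mean((detrended - mean)^2)) / mean`. Larger values mean a more
#' volatile, less stable sink. Pixels that are not sinks on average
#' (`mean <= 0`, since NEP > 0 defines a sink) are flagged and get `cv = NA`.
#'
#' @inheritParams linear_trend
#' @param detrend `"linear"` removes the OLS line (the default, matching the
#'   defining formula); `"eemd"` removes the EEMD residual trend instead.
#' @param ... For `detrend = "eemd"`, arguments passed to [eemd()].
#' @return One-row tibble: `cv`, `mean`, `sink` (logical, mean > 0).
#' @examples
#' stability_cv(c(rep(8, 19), rep(12, 19)))
#' @export
stability_cv <- function(values, years = seq_along(values),
                         detrend = c("linear", "eemd"), ...) {
  detrend <- match.arg(detrend)
  mu <- mean(values)
  if (mu == 0) {
    return(tibble::tibble(cv = NA_real_, mean = mu, sink = FALSE))
  }
  det <- if (detrend == "linear") {
    detrend_series(values, years)
  } else {
    dec <- eemd(values, years, ...)
    values - dec$residual + mu
  }
  cv <- if (mu > 0) sqrt(mean((det - mu)^2)) / mu else NA_real_
  tibble::tibble(cv = cv, mean = mu, sink = mu > 0)
}

#' Fisher-Jenks natural breaks of a one-dimensional distribution
#'
#' Optimal contiguous partition of the sorted values into `k` classes
#' minimising the total within-class sum of squared deviations from the
#' class means (dynamic programme, exact optimum). Returns the `k - 1`
#' break values: the largest member of each of the first `k - 1` classes.
#' Values equal to a break belong to the lower class.
#'
#' @param values Finite numeric vector with at least `k` distinct values.
#' @param k Number of classes.
#' @return Numeric vector of `k - 1` ascending break values, with the
#'   achieved objective as attribute `"objective"`.
#' @examples
#' jenks_breaks(c(1, 2, 3, 100, 101, 102), k = 2)
#' @export
jenks_breaks <- function(values, k) {
  if (anyNA(values) || !all(is.finite(values))) abort("values must be finite")
  k <- as.integer(k)
  if (length(unique(values)) < k) {
    abort(paste0("need at least ", k, " distinct values for ", k, " classes"))
  }
  s <- sort(values)
  res <- .jenks_cpp(s, k)
  breaks <- s[res$last_index[seq_len(k - 1)] + 1L]
  attr(breaks, "objective") <- res$objective
  breaks
}

#' Assign ordinal classes from break values
#'
#' @param values Numeric vector.
#' @param breaks Ascending break values (class maxima); ties go to the lower
#'   class.
#' @return Integer classes `1..(length(breaks) + 1)`; `NA` values stay `NA`.
#' @export
cut_by_breaks <- function(values, breaks) {
  ifelse(is.na(values), NA_integer_,
         1L + rowSums(outer(values, breaks, FUN = ">")))
}

#' Grid-wide stability statistic and five-level natural-breaks classes
#'
#' Computes the detrended coefficient of variation for every pixel of a
#' long-format NEP grid, derives one set of Fisher-Jenks breaks from the
#' full grid's cv distribution (sink pixels only), and assigns each pixel an
#' ordinal class 1 (stable) .. `k` (unstable). Non-sink pixels (mean NEP
#' <= 0) are excluded from the breaks and carry `NA` classes.
#'
#' @param nep Long tibble `pixel`, `row`, `col`, `year`, `nep`.
#' @param k Number of stability classes.
#' @param mask Optional overlap mask (`pixel`, `stratum`); when given, the
#'   per-stratum class composition is attached as attribute `"shares"`.
#' @inheritParams stability_cv
#' @return Tibble, one row per pixel: `pixel`, `row`, `col`, `cv`, `mean`,
#'   `sink`, `stability_class`, `stability_level`; attributes `"breaks"`
#'   (and `"shares"` when `mask` is given).
#' @export
classify_stability <- function(nep, k = 5L, mask = NULL,
                               detrend = c("linear", "eemd"), ...) {
  detrend <- match.arg(detrend)
  stopifnot(all(c("pixel", "row", "col", "year", "nep") %in% names(nep)))
  cv_tbl <- nep |>
    dplyr::arrange(.data$pixel, .data$year) |>
    dplyr::group_by(.data$pixel, .data$row, .data$col) |>
    dplyr::group_modify(~ stability_cv(.x$nep, .x$year, detrend = detrend, ...)) |>
    dplyr::ungroup()
  breaks <- jenks_breaks(cv_tbl$cv[cv_tbl$sink], k = k)
  lv <- if (k == 5L) stability_levels() else paste0("class_", seq_len(k))
  out <- cv_tbl |>
    dplyr::mutate(stability_class = cut_by_breaks(.data$cv, breaks),
                  stability_level = lv[.data$stability_class])
  attr(out, "breaks") <- breaks
  if (!is.null(mask)) {
    attr(out, "shares") <- stability_proportions(out, mask)
  }
  out
}

#' Stability-class composition per project-overlap stratum
#'
#' @param classes Tibble with `pixel` and `stability_class` (from
#'   [classify_stability()]).
#' @param mask Tibble with `pixel`, `stratum`.
#' @return Tibble `stratum`, `stability_class`, `n`, `share` (percent; rows
#'   sum to 100 within a stratum). Strata with no classified pixels are
#'   absent.
#' @export
stability_proportions <- function(classes, mask) {
  classes |>
    dplyr::inner_join(dplyr::select(mask, "pixel", "stratum"), by = "pixel") |>
    dplyr::filter(!is.na(.data$stability_class)) |>
    dplyr::count(.data$stratum, .data$stability_class, name = "n") |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(share = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
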