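#' Sifting configuration for (ensemble) empirical mode decomposition
#'
#' @param sd_tol Cauchy-type stopping threshold for the sifting loop: sifting
#'   of one intrinsic mode function (IMF) stops once the normalised squared
#'   change `sum(m^2)/sum(h^2)` of the candidate falls below this value.
#' @param max_sifts Maximum sifting iterations per IMF.
#' @param max_imfs Maximum number of IMFs to extract before everything left
#'   is declared residual; `NULL` (default) uses the dyadic limit
#'   `floor(log2(n)) + 1` of the series length.
#' @return A list of class `sift_config`.
#' @export
sift_config <- function(sd_tol = 0.2, max_sifts = 10L, max_imfs = NULL) {
  stopifnot(sd_tol > 0, max_sifts >= 1, is.null(max_imfs) || max_imfs >= 1)
  structure(list(sd_tol = sd_tol, max_sifts = as.integer(max_sifts),
                 max_imfs = if (!is.null(max_imfs)) as.integer(max_imfs)),
            class = "sift_config")
}

imf_cap <- function(config, n) {
  config$max_imfs %||% (floor(log2(n)) + 1L)
}

validate_series <- function(values, years) {
  if (!is.numeric(values) || anyNA(values) || !all(is.finite(values))) {
    abort("series values must be finite and free of missing years")
  }
  if (length(values) < 16L) {
    abort("series too short: at least 16 annual values are required")
  }
  if (!is.null(years)) {
    if (length(years) != length(values)) {
      abort("years and values must have equal length")
    }
    if (any(diff(years) <= 0)) abort("years must be strictly increasing")
  }
  invisible(TRUE)
}

#' Empirical mode decomposition of an annual series
#'
#' Decomposes a series into intrinsic mode functions (IMFs, highest frequency
#' first) and a low-frequency residual by iterative sifting: cubic-spline
#' envelopes through the local extrema (mirror-extended at both ends), with a
#' Cauchy-type stopping rule. Decomposition stops when the remainder has
#' fewer than two interior extrema; that remainder is the residual, used
#' downstream as the nonlinear secular trend. The identity
#' `rowSums(imfs) + residual == values` holds to float precision.
#'
#' @param values Numeric vector of annual values (length >= 16, finite).
#' @param years Optional strictly increasing integer years (same length).
#' @param config A [sift_config()].
#' @return An object of class `imf_decomposition`: list with `imfs` (matrix,
#'   one column per IMF), `residual`, `values`, `years`, `ensemble_size`,
#'   `noise_amplitude`.
#' @seealso [eemd()], [residual_rate()]
#' @examples
#' x <- sin(2 * pi * (1:38) / 6) + 0.5 * (1:38)
#' d <- emd(x)
#' max(abs(rowSums(d$imfs) + d$residual - x))
#' @export
emd <- function(values, years = NULL, config = sift_config()) {
  validate_series(values, years)
  dec <- .emd_cpp(as.numeric(values), imf_cap(config, length(values)),
                  config$sd_tol, config$max_sifts)
  new_imf_decomposition(dec, values, years, ensemble_size = 1L,
                        noise_amplitude = 0, config = config)
}

#' Ensemble empirical mode decomposition (EEMD)
#'
#' Runs [emd()] on `ensemble_size` white-noise-perturbed copies of the series
#' and averages the member IMFs and residuals. The added noise breaks mode
#' mixing; averaging cancels it. With `noise_amplitude = 0` or
#' `ensemble_size = 1` this reduces exactly to [emd()].
#'
#' @inheritParams emd
#' @param ensemble_size Number of ensemble members.
#' @param noise_amplitude White-noise standard deviation as a fraction of the
#'   series standard deviation (conventional value 0.2).
#' @param seed Integer seed controlling the noise draws; `NULL` uses the
#'   current RNG stream.
#' @param paired When `TRUE` and `ensemble_size` is even, members are drawn
#'   as +/- noise pairs so the ensemble-mean input equals the series exactly
#'   and the reconstruction defect vanishes.
#' @return An `imf_decomposition` (see [emd()]).
#' @examples
#' x <- sin(2 * pi * (1:38) / 6) + 0.5 * (1:38) + rnorm(38)
#' d <- eemd(x, ensemble_size = 50, seed = 1)
#' @export
eemd <- function(values, years = NULL, ensemble_size = 100L,
                 noise_amplitude = 0.2, seed = NULL, paired = TRUE,
                 config = sift_config()) {
  validate_series(values, years)
  stopifnot(ensemble_size >= 1, noise_amplitude >= 0)
  noise_sd <- noise_amplitude * sd(values)
  dec <- with_seed(seed, {
    .eemd_cpp(as.numeric(values), as.integer(ensemble_size), noise_sd,
              paired, imf_cap(config, length(values)), config$sd_tol,
              config$max_sifts)
  })
  new_imf_decomposition(dec, values, years,
                        ensemble_size = as.integer(ensemble_size),
                        noise_amplitude = noise_amplitude, config = config)
}

new_imf_decomposition <- function(dec, values, years, ensemble_size,
                                  noise_amplitude, config) {
  structure(list(imfs = dec$imfs, residual = as.numeric(dec$residual),
                 values = as.numeric(values),
                 years = years %||% seq_along(values),
                 ensemble_size = ensemble_size,
                 noise_amplitude = noise_amplitude, config = config),
            class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat("<imf_decomposition> n =", length(x$values),
      "| IMFs:", ncol(x$imfs),
      "| ensemble:", x$ensemble_size,
      "| noise amplitude:", x$noise_amplitude, "\n")
  cat("residual net change:",
      signif(x$residual[length(x$residual)] - x$residual[1], 4), "\n")
  invisible(x)
}

#' Year-to-year rate of change of the residual trend
#'
#' First differences of the (E)EMD residual, in response units per year:
#' the instantaneous rate of the nonlinear trend. Length is one less than
#' the series.
#'
#' @param decomposition An `imf_decomposition` from [emd()] or [eemd()].
#' @return Numeric vector of first differences.
#' @export
residual_rate <- function(decomposition) {
  stopifnot(inherits(decomposition, "imf_decomposition"))
  diff(decomposition$residual)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an IMF decomposition into a long tibble
#'
#' @param x An `imf_decomposition`.
#' @param ... Unused.
#' @return A tibble with columns `year`, `component` (`imf_1`, ...,
#'   `residual`, `input`), `value`.
#' @export
tidy.imf_decomposition <- function(x, ...) {
  k <- ncol(x$imfs)
  comp <- cbind(x$imfs, residual = x$residual, input = x$values)
  colnames(comp) <- c(if (k > 0) paste0("imf_", seq_len(k)), "residual",
                      "input")
  tibble::as_tibble(comp) |>
    dplyr::mutate(year = x$years, .before = 1) |>
    tidyr::pivot_longer(-"year", names_to = "component", values_to = "value")
}

#' Decompose every pixel of an annual NEP grid
#'
#' Applies [eemd()] pixel-by-pixel to a long-format grid and returns the
#' residual trend per pixel-year. Pixels are processed on independent child
#' seed streams, so results do not depend on pixel order.
#'
#' @param nep A long tibble with columns `pixel`, `row`, `col`, `year`,
#'   `nep` and no missing years within a pixel.
#' @inheritParams eemd
#' @return A tibble `pixel, row, col, year, nep, residual` plus a per-pixel
#'   attribute-free summary column `n_imfs`.
#' @export
decompose_grid <- function(nep, ensemble_size = 100L, noise_amplitude = 0.2,
                           seed = NULL, paired = TRUE,
                           config = sift_config()) {
  stopifnot(all(c("pixel", "row", "col", "year", "nep") %in% names(nep)))
  pix <- dplyr::distinct(nep, .data$pixel) |> dplyr::arrange(.data$pixel)
  seeds <- child_seeds(seed %||% 1L, nrow(pix))
  nep |>
    dplyr::arrange(.data$pixel, .data$year) |>
    dplyr::group_by(.data$pixel, .data$row, .data$col) |>
    dplyr::group_modify(function(d, key) {
      i <- match(key$pixel, pix$pixel)
      dec <- eemd(d$nep, d$year, ensemble_size = ensemble_size,
                  noise_amplitude = noise_amplitude, seed = seeds[i],
                  paired = paired, config = config)
      dplyr::mutate(d, residual = dec$residual, n_imfs = ncol(dec$imfs))
    }) |>
    dplyr::ungroup()
}
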