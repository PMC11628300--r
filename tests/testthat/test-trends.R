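test_that("linear_trend is exact on noiseless lines and flags degeneracy", {
  lt <- linear_trend(2 * (1990:2027) + 3, 1990:2027)
  expect_equal(lt$slope, 2)
  expect_equal(lt$intercept, 3)
  expect_equal(linear_trend(rep(7, 20))$slope, 0)
  expect_error(linear_trend(1:5, rep(2000, 5)), "degenerate")
})

test_that("OLS slope is an unbiased estimate of a noisy linear rate", {
  set.seed(61)
  t <- 1:38
  slopes <- vapply(1:1000, function(i) {
    linear_trend(0.9888 * t + rnorm(38, 0, 5), t)$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.9888), 2 * se)
})

test_that("shape classification labels canonical residuals", {
  years <- 1982:2019
  t <- years - 2000
  # centred parabola: decreasing then increasing, vertex at 2000
  par_up <- emd(t^2 + 200, years = years)
  lab <- classify_trend(par_up, test = FALSE)
  expect_equal(lab$label, "positive_reversal")
  expect_equal(lab$turning_point_year, 2000)
  # strictly increasing residual
  inc <- emd(3 * seq_along(years) + 100, years = years)
  expect_equal(classify_trend(inc, test = FALSE)$label, "increasing")
  dec <- emd(-3 * seq_along(years) + 100, years = years)
  expect_equal(classify_trend(dec, test = FALSE)$label, "decreasing")
})

test_that("constant series are nonsignificant with p-value one", {
  st <- significance_test(rep(40, 38), n_null = 100, seed = 1)
  expect_false(st$significant)
  expect_equal(st$p_value, 1)
})

test_that("a strong linear trend is detected with small p-value", {
  set.seed(71)
  t <- 1:38
  x <- t + rnorm(38, 0, sd(t) / 5) # signal-to-noise 5
  st <- significance_test(x, n_null = 400, seed = 2)
  expect_true(st$significant)
  expect_lt(st$p_value, 0.01)
})

test_that("type-I error of the surrogate test is near the nominal level", {
  set.seed(81)
  rej <- vapply(1:100, function(i) {
    significance_test(rnorm(38), n_null = 200, seed = 300 + i)$significant
  }, logical(1))
  # wide sanity band at this replicate count; the calibrated check at the
  # full Monte-Carlo size lives in the acceptance suite
  expect_gt(mean(rej), 0)
  expect_lt(mean(rej), 0.15)
})

test_that("labels are invariant to level shifts and flip with sign", {
  set.seed(91)
  years <- 1982:2019
  x <- 2 * seq_along(years) + rnorm(38, 0, 3) + 100
  d1 <- eemd(x, years = years, ensemble_size = 20, seed = 5)
  d2 <- eemd(x + 500, years = years, ensemble_size = 20, seed = 5)
  l1 <- classify_trend(d1, n_null = 100, seed = 6)
  l2 <- classify_trend(d2, n_null = 100, seed = 6)
  expect_equal(l1$label, l2$label)
  d3 <- eemd(-x, years = years, ensemble_size = 20, seed = 5)
  l3 <- classify_trend(d3, n_null = 100, seed = 6)
  expect_equal(l3$label, "decreasing")
  expect_equal(l1$label, "increasing")
  # sign flip swaps reversal polarity too
  v <- abs(years - 2000) * 2 + 150
  lv <- classify_trend(emd(v, years = years), n_null = 100, seed = 6)
  lneg <- classify_trend(emd(-v + 400, years = years), n_null = 100, seed = 6)
  expect_equal(lv$label, "positive_reversal")
  expect_equal(lneg$label, "negative_reversal")
  expect_equal(lv$turning_point_year, lneg$turning_point_year)
})

test_that("multiple interior sign changes fall back to the final segments", {
  years <- 1982:2019
  t <- seq_along(years)
  # W-like residual: down, up, down, up — complex shape
  w <- 5 * sin(2 * pi * t / 38 * 1.8) + 0.1 * t
  dec <- structure(list(imfs = matrix(numeric(), 38, 0), residual = w,
                        values = w, years = years, ensemble_size = 1L,
                        noise_amplitude = 0, config = sift_config()),
                   class = "imf_decomposition")
  expect_warning(lab <- classify_trend(dec, test = FALSE), "multiple")
  expect_true(lab$complex)
  expect_true(lab$label %in% c("increasing", "decreasing",
                               "positive_reversal", "negative_reversal"))
})

test_that("phase-randomised surrogates preserve the spectrum", {
  set.seed(95)
  x <- as.numeric(arima.sim(list(ar = 0.6), 38))
  s <- sinkstability:::phase_randomize(x)
  expect_equal(mean(s), mean(x), tolerance = 1e-10)
  expect_equal(sort(Mod(fft(s - mean(s)))), sort(Mod(fft(x - mean(x)))),
               tolerance = 1e-8)
  st <- significance_test(x, n_null = 100, surrogate = "phase", seed = 1)
  expect_true(is.finite(st$p_value))
})

test_that("noiseless synthetic grids classify perfectly with exact turning points", {
  cfg <- synthetic_config(grid_shape = c(4, 20), noise_sd = 0)
  world <- generate_nep_grid(cfg)
  dec <- decompose_grid(world$nep, ensemble_size = 1, noise_amplitude = 0)
  labels <- classify_trend_grid(dec, n_null = 200, seed = 5)
  joined <- dplyr::inner_join(labels, world$truth, by = "pixel",
                              suffix = c("", "_true"))
  expect_equal(mean(joined$label == joined$label_true), 1)
  rev <- dplyr::filter(joined, grepl("reversal", label_true))
  expect_true(all(rev$turning_point_year == rev$turning_point_year_true))
})

test_that("trend proportions recover a known composition exactly", {
  labels <- tibble::tibble(pixel = 1:60, row = 1, col = 1:60,
                           label = rep(c("increasing", "decreasing",
                                         "nonsignificant"),
                                       times = c(30, 20, 10)))
  mask <- tibble::tibble(pixel = 1:60, row = 1, col = 1:60,
                         stratum = rep(c(0L, 2L), each = 30))
  # stratum 0: 30 increasing; stratum 2: 20 decreasing + 10 nonsignificant
  tp <- trend_proportions(labels, mask)
  expect_equal(tp$share[tp$stratum == 0 & tp$label == "increasing"], 100)
  expect_equal(tp$share[tp$stratum == 2 & tp$label == "decreasing"], 200 / 3)
  expect_equal(tp$share[tp$stratum == 2 & tp$label == "nonsignificant"],
               100 / 3)
  expect_equal(as.numeric(tapply(tp$share, tp$stratum, sum)), rep(100, 2),
               tolerance = 1e-9)
  # strata 1, 3-5 have no pixels and are absent, not zero
  expect_setequal(unique(tp$stratum), c(0L, 2L))
})
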