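test_that("boosting is deterministic and invariant to row order", {
  d <- random_driver_tbl(400, seed = 301)
  d$resp <- d$TEM - 0.5 * d$GDP + rnorm(400, 0, 0.3)
  hy <- brt_config(n_trees = 150, patience = 0)
  f1 <- fit_brt(d, "resp", hyper = hy, seed = 4)
  f2 <- fit_brt(d, "resp", hyper = hy, seed = 4)
  expect_identical(predict(f1, d[1:30, ]), predict(f2, d[1:30, ]))
  f3 <- fit_brt(d[sample(nrow(d)), ], "resp", hyper = hy, seed = 4)
  expect_identical(predict(f1, d[1:30, ]), predict(f3, d[1:30, ]))
})

test_that("training deviance falls towards zero on a learnable target", {
  d <- random_driver_tbl(500, seed = 311)
  d$resp <- 3 * d$SOIL
  f <- fit_brt(d, "resp", hyper = brt_config(n_trees = 800, patience = 0),
               seed = 1)
  dev <- f$train_deviance
  expect_lt(dev[length(dev)], 0.02 * dev[1])
})

test_that("a depth-one stump finds a step threshold within one grid step", {
  grid_x <- seq(-2, 2, by = 0.1)
  d <- tibble::tibble(TEM = rep(grid_x, each = 6))
  d$resp <- as.numeric(d$TEM > 0.35)
  d[driver_names()[-1]] <- 0
  f <- fit_brt(d, "resp", hyper = brt_config(n_trees = 1, learning_rate = 1,
                                             max_depth = 1, bag_fraction = 1,
                                             min_node = 5, patience = 0),
               seed = 1)
  split <- f$trees[[1]][1, ]
  expect_equal(split[1], 0) # split on TEM (feature index 0)
  expect_lt(abs(split[2] - 0.35), 0.1 + 1e-9)
})

test_that("relative influence recovers a single informative driver", {
  set.seed(321)
  d <- random_driver_tbl(2000, seed = 321)
  d$resp <- 2 * d$RAD + rnorm(2000, 0, 0.4)
  f <- fit_brt(d, "resp", hyper = brt_config(n_trees = 400), seed = 9)
  ri <- relative_influence(f)
  expect_equal(sum(ri$influence), 100, tolerance = 1e-6)
  expect_gt(ri$influence[ri$driver == "RAD"], 80)
  expect_true(all(ri$influence[ri$driver != "RAD"] <= 5))
  expect_equal(unname(ri$group[ri$driver == "RAD"]), "climate")
})

test_that("influence splits between duplicated predictors but their sum is stable", {
  set.seed(331)
  n <- 1500
  d <- random_driver_tbl(n, seed = 331)
  d$resp <- 1.5 * d$TEM + rnorm(n, 0, 0.4)
  hy <- brt_config(n_trees = 300)
  single <- relative_influence(fit_brt(d, "resp", hyper = hy, seed = 2))
  dup <- d
  dup$PRE <- d$TEM # exact duplicate column
  both <- relative_influence(fit_brt(dup, "resp", hyper = hy, seed = 2))
  s1 <- single$influence[single$driver == "TEM"]
  s2 <- sum(both$influence[both$driver %in% c("TEM", "PRE")])
  expect_lt(abs(s1 - s2), 5)
})

test_that("rank AUC matches pROC on random score/label vectors", {
  skip_if_not_installed("pROC")
  set.seed(341)
  for (i in 1:100) {
    s <- rnorm(60)
    l <- rbinom(60, 1, 0.4)
    if (length(unique(l)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc(s, l), ref, tolerance = 1e-12)
  }
  expect_error(auc(rnorm(5), rep(1, 5)), "both classes")
})

test_that("AUC grades reproduce the published bands at their boundaries", {
  expect_equal(auc_grade(c(0.95, 0.9)), c("excellent", "excellent"))
  expect_equal(auc_grade(c(0.89, 0.85, 0.8)), c("good", "good", "good"))
  expect_equal(auc_grade(c(0.79, 0.75, 0.7)),
               c("accurate", "accurate", "accurate"))
  expect_equal(auc_grade(c(0.69, 0.65, 0.6)), c("poor", "poor", "poor"))
  expect_equal(auc_grade(0.5), "fail")
})

test_that("cross-validation scores a separable and a null response sensibly", {
  set.seed(351)
  d <- random_driver_tbl(400, seed = 351)
  d$y <- as.integer(d$VPD > 0)
  hy <- brt_config(n_trees = 200)
  cv <- cross_validate(d, "y", hyper = hy, folds = 5, reps = 2, seed = 3)
  expect_equal(cv$metric, "auc")
  expect_gt(cv$score, 0.98)
  d$z <- rbinom(400, 1, 0.5)
  cvn <- cross_validate(d, "z", hyper = brt_config(n_trees = 100),
                        folds = 5, reps = 2, seed = 4)
  expect_lt(abs(cvn$score - 0.5), 0.12)
})

test_that("binary stability response maps the five classes symmetrically", {
  expect_equal(stability_binary(1:5), c(1L, 1L, NA, 0L, 0L))
})

test_that("stratified attribution reports groups and skips small strata", {
  set.seed(361)
  n <- 900
  d <- random_driver_tbl(n, seed = 361)
  d$stratum <- c(rep(0L, 40), rep(1L, 430), rep(2L, 430))
  d$stable <- as.integer(0.8 * d$SOIL + 0.8 * d$CO2 + rnorm(n, 0, 0.6) > 0)
  expect_warning(
    att <- stratified_attribution(d, "stable",
                                  hyper = brt_config(n_trees = 200),
                                  seed = 5, cv = FALSE),
    "skipped")
  expect_setequal(unique(att$influence$stratum),
                  c("national", "stratum_1", "stratum_2"))
  sums <- att$groups |>
    dplyr::group_by(stratum) |>
    dplyr::summarise(total = sum(influence))
  expect_equal(sums$total, rep(100, 3), tolerance = 1e-6)
  # both strata share one generating process: group sums agree approximately
  g <- tidyr::pivot_wider(att$groups, names_from = group,
                          values_from = influence)
  spread <- diff(range(g$climate[g$stratum != "national"]))
  expect_lt(spread, 25)
})

test_that("stratum-specific truths are recovered in the right order", {
  set.seed(371)
  n <- 1200
  d <- random_driver_tbl(n, seed = 371)
  d$stratum <- rep(c(1L, 5L), each = n / 2)
  clim <- 1.2 * d$TEM + 1.2 * d$SOIL
  hum <- 1.2 * d$CO2 + 1.2 * d$LUC
  sig <- ifelse(d$stratum == 5L, clim, hum)
  d$stable <- as.integer(sig + rnorm(n, 0, 0.5) > 0)
  att <- stratified_attribution(d, "stable",
                                hyper = brt_config(n_trees = 300),
                                seed = 6, cv = FALSE)
  g <- tidyr::pivot_wider(att$groups, names_from = group,
                          values_from = influence)
  expect_gt(g$climate[g$stratum == "stratum_5"],
            g$human[g$stratum == "stratum_5"])
  expect_gt(g$human[g$stratum == "stratum_1"],
            g$climate[g$stratum == "stratum_1"])
})

test_that("fits agree with an established gradient-boosting implementation", {
  skip_if_not_installed("xgboost")
  set.seed(381)
  n <- 1200
  d <- random_driver_tbl(n, seed = 381)
  d$resp <- d$TEM + 0.7 * d$CO2 - 0.5 * d$VPD + rnorm(n, 0, 0.5)
  train <- d[1:900, ]
  test <- d[901:1200, ]
  mine <- fit_brt(train, "resp", hyper = brt_config(n_trees = 600), seed = 2)
  p1 <- predict(mine, test)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(train[driver_names()]),
                                 label = train$resp)
  xg <- xgboost::xgb.train(
    params = list(eta = 0.01, max_depth = 3, subsample = 0.75),
    data = dtrain, nrounds = 600)
  p2 <- predict(xg, as.matrix(test[driver_names()]))
  r2 <- function(p) 1 - sum((test$resp - p)^2) / sum((test$resp - mean(train$resp))^2)
  expect_gt(r2(p1), r2(p2) - 0.1)
  expect_gt(cor(p1, p2), 0.9)
  # and the dominant driver agrees
  imp <- xgboost::xgb.importance(model = xg)
  expect_equal(tidy(mine)$driver[1], imp$Feature[1])
})

test_that("degenerate fits raise informative errors", {
  d <- random_driver_tbl(100, seed = 391)
  d$resp <- rep(1, 100)
  expect_error(fit_brt(d, "resp"), "constant response")
  d$resp <- rnorm(100)
  d$TEM[1] <- NA
  expect_error(fit_brt(d, "resp"), "non-finite")
  expect_error(fit_brt(random_driver_tbl(30, seed = 1) |>
                         dplyr::mutate(resp = rnorm(30)), "resp"),
               "50 rows")
  expect_error(fit_brt(d, "missing_col"), "not in data")
})

test_that("tidy and glance summarise a fit", {
  d <- random_driver_tbl(300, seed = 401)
  d$resp <- d$LUC + rnorm(300, 0, 0.5)
  f <- fit_brt(d, "resp", hyper = brt_config(n_trees = 100), seed = 1)
  td <- tidy(f)
  expect_equal(td$driver[1], "LUC")
  gl <- glance(f)
  expect_equal(gl$loss, "gaussian")
  expect_lte(gl$n_trees, 100)
})
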