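# a small synthetic world in which one climate driver controls both the
# trend and the stability vocabulary through known thresholds
make_projection_world <- function(n = 600, seed = 501) {
  set.seed(seed)
  drivers <- random_driver_tbl(n, seed = seed)
  drivers$pixel <- seq_len(n)
  labels <- tibble::tibble(
    pixel = seq_len(n), row = 1L, col = seq_len(n),
    label = ifelse(drivers$SOIL > 0, "increasing", "decreasing"))
  stability <- tibble::tibble(
    pixel = seq_len(n),
    stability_class = ifelse(drivers$TEM > 0, 1L, 5L))
  mask <- tibble::tibble(pixel = seq_len(n), row = 1L, col = seq_len(n),
                         stratum = rep(0:2, length.out = n))
  list(drivers = drivers, labels = labels, stability = stability,
       mask = mask)
}

test_that("the trend vocabulary maps reversals into enhanced and degraded", {
  w <- make_projection_world(300)
  w$labels$label[1:60] <- rep(c("positive_reversal", "negative_reversal",
                                "nonsignificant"), each = 20)
  models <- train_class_models(w$labels, w$stability, w$drivers,
                               hyper = brt_config(n_trees = 60), seed = 1)
  trained_n <- sum(!w$labels$label %in% "nonsignificant")
  # nonsignificant pixels are excluded from the trend training set
  expect_equal(length(models$trend$train_deviance) > 0, TRUE)
  p <- predict(models$trend, w$drivers[w$labels$label == "positive_reversal", ])
  expect_gt(mean(p), 0.5) # positive reversals were trained as enhanced
  p2 <- predict(models$trend,
                w$drivers[w$labels$label == "negative_reversal", ])
  expect_lt(mean(p2), 0.5)
  expect_equal(trained_n, 280)
})

test_that("threshold-determined labels are learned almost perfectly", {
  w <- make_projection_world(800)
  hold <- sample(800, 200)
  models <- train_class_models(w$labels[-hold, ], w$stability[-hold, ],
                               w$drivers,
                               hyper = brt_config(n_trees = 400), seed = 2)
  p <- predict(models$trend, w$drivers[hold, ])
  acc <- mean((p > 0.5) == (w$labels$label[hold] == "increasing"))
  expect_gte(acc, 0.97)
})

test_that("label-shuffled training yields chance-level held-out accuracy", {
  w <- make_projection_world(700, seed = 511)
  set.seed(512)
  w$labels$label <- sample(w$labels$label)
  hold <- sample(700, 200)
  models <- train_class_models(w$labels[-hold, ], w$stability[-hold, ],
                               w$drivers,
                               hyper = brt_config(n_trees = 150), seed = 3)
  p <- predict(models$trend, w$drivers[hold, ])
  acc <- mean((p > 0.5) == (w$labels$label[hold] == "increasing"))
  maj <- max(mean(w$labels$label[hold] == "increasing"),
             mean(w$labels$label[hold] != "increasing"))
  expect_lt(acc, maj + 0.12)
})

test_that("a missing training class raises an error", {
  w <- make_projection_world(200, seed = 521)
  w$labels$label <- "increasing"
  expect_error(train_class_models(w$labels, w$stability, w$drivers,
                                  hyper = brt_config(n_trees = 30), seed = 1),
               "class missing")
})

test_that("projection is a pure function with shares summing to 100", {
  w <- make_projection_world(500, seed = 531)
  models <- train_class_models(w$labels, w$stability, w$drivers,
                               hyper = brt_config(n_trees = 120), seed = 4)
  pr1 <- project_scenario(models, w$drivers, w$mask, scenario_id = "hist")
  pr2 <- project_scenario(models, w$drivers, w$mask, scenario_id = "hist")
  expect_identical(pr1$pixels$trend_class, pr2$pixels$trend_class)
  sums <- pr1$shares |>
    dplyr::group_by(type, stratum) |>
    dplyr::summarise(s = sum(share), .groups = "drop")
  expect_equal(sums$s, rep(100, nrow(sums)), tolerance = 1e-9)
  # shares invariant to pixel order
  shuffled <- w$drivers[sample(nrow(w$drivers)), ]
  pr3 <- project_scenario(models, shuffled, w$mask, scenario_id = "hist")
  expect_equal(dplyr::arrange(pr1$shares, type, stratum, class),
               dplyr::arrange(pr3$shares, type, stratum, class))
})

test_that("shifting the enhancing driver upward raises the enhanced share", {
  w <- make_projection_world(600, seed = 541)
  models <- train_class_models(w$labels, w$stability, w$drivers,
                               hyper = brt_config(n_trees = 250), seed = 5)
  base <- project_scenario(models, w$drivers, w$mask, scenario_id = "base")
  up <- project_scenario(
    models, generate_scenario_drivers(w$drivers, c(SOIL = 1.5), "up"),
    w$mask)
  share_of <- function(pr) {
    mean(pr$pixels$trend_class == "enhanced") * 100
  }
  expect_gt(share_of(up), share_of(base))
})

test_that("projected shares on an identity scenario match the generative rule", {
  w <- make_projection_world(900, seed = 551)
  models <- train_class_models(w$labels, w$stability, w$drivers,
                               hyper = brt_config(n_trees = 400), seed = 6)
  pr <- project_scenario(models, w$drivers, w$mask, scenario_id = "ident")
  truth_share <- mean(w$labels$label == "increasing") * 100
  got <- mean(pr$pixels$trend_class == "enhanced") * 100
  n <- nrow(w$labels)
  binom_err <- 1.96 * sqrt(0.5 * 0.5 / n) * 100
  expect_lt(abs(got - truth_share), binom_err + 2)
})

test_that("scenario comparison reports exact share differences", {
  w <- make_projection_world(400, seed = 561)
  models <- train_class_models(w$labels, w$stability, w$drivers,
                               hyper = brt_config(n_trees = 150), seed = 7)
  a <- project_scenario(models, w$drivers, w$mask, scenario_id = "a",
                        target_year = 2060)
  b <- project_scenario(
    models, generate_scenario_drivers(w$drivers, c(SOIL = 2), "b"),
    w$mask, target_year = 2060)
  self <- compare_scenarios(list(a, a))
  expect_true(all(self$difference == 0))
  cmp <- compare_scenarios(list(a, b))
  # the difference column equals the hand-computed share difference
  for (i in seq_len(nrow(cmp))) {
    ref <- cmp$share[cmp$scenario == "a" &
                       cmp$type == cmp$type[i] &
                       cmp$stratum == cmp$stratum[i] &
                       cmp$class == cmp$class[i]]
    expect_equal(cmp$difference[i], cmp$share[i] - ref)
  }
  # row count: scenarios x strata x classes present
  expect_equal(nrow(cmp),
               2 * nrow(dplyr::distinct(cmp, type, stratum, class)))
})

test_that("grid mismatches and missing drivers raise errors", {
  w <- make_projection_world(200, seed = 571)
  models <- train_class_models(w$labels, w$stability, w$drivers,
                               hyper = brt_config(n_trees = 40), seed = 8)
  expect_error(predict(models$trend, w$drivers[, -match("TEM", names(w$drivers))]),
               "TEM")
  a <- project_scenario(models, w$drivers, w$mask, scenario_id = "a")
  w2 <- make_projection_world(150, seed = 572)
  models2 <- train_class_models(w2$labels, w2$stability, w2$drivers,
                                hyper = brt_config(n_trees = 40), seed = 9)
  b <- project_scenario(models2, w2$drivers, w2$mask, scenario_id = "b")
  expect_error(compare_scenarios(list(a, b)), "grid mismatch")
})
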