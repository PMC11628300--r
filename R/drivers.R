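#' Hyperparameters for the boosted-regression-tree fit
#'
#' Defaults follow common BRT practice for attribution studies: slow
#' learning (0.01) with many shallow trees, stochastic subsampling of 75% of
#' rows per iteration, and early stopping on out-of-bag deviance.
#'
#' @param n_trees Maximum boosting iterations.
#' @param learning_rate Shrinkage applied to every tree.
#' @param max_depth Tree depth (interaction order).
#' @param bag_fraction Fraction of rows drawn (without replacement) per tree.
#' @param min_node Minimum observations per terminal node.
#' @param patience Early stopping: stop when the out-of-bag deviance has not
#'   improved for this many iterations (0 disables).
#' @return List of class `brt_config`.
#' @export
brt_config <- function(n_trees = 2000L, learning_rate = 0.01, max_depth = 3L,
                       bag_fraction = 0.75, min_node = 10L, patience = 50L) {
  stopifnot(n_trees >= 1, learning_rate > 0, max_depth >= 1,
            bag_fraction > 0, bag_fraction <= 1, min_node >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 bag_fraction = bag_fraction,
                 min_node = as.integer(min_node),
                 patience = as.integer(patience)),
            class = "brt_config")
}

#' Fit stochastic gradient-boosted regression trees
#'
#' Stagewise ensemble of depth-limited regression trees: squared-error loss
#' for continuous responses, Bernoulli deviance (logit link, Newton leaf
#' values) for binary ones. Each iteration fits one tree to the current
#' negative gradient on a random `bag_fraction` subsample; the held-out rows
#' monitor deviance for early stopping. Split gains are accumulated per
#' predictor for Friedman relative-influence accounting.
#'
#' Rows are put into a canonical sort order before fitting, so the fit is a
#' function of the data content, not of row order.
#'
#' @param data Data frame containing the predictors and the response.
#' @param response Name of the response column. A column with exactly two
#'   distinct values (or a factor/logical) selects the Bernoulli loss.
#' @param predictors Predictor column names (default: all ten
#'   [driver_names()] present in `data`).
#' @param hyper A [brt_config()].
#' @param seed Integer seed (subsampling).
#' @return Object of class `sink_brt`: trees, loss, feature names, deviance
#'   traces, per-feature split gain.
#' @seealso [relative_influence()], [cross_validate()], [predict.sink_brt()]
#' @export
fit_brt <- function(data, response, predictors = NULL,
                    hyper = brt_config(), seed = NULL) {
  predictors <- predictors %||% intersect(driver_names(), names(data))
  if (length(predictors) == 0) abort("no predictor columns found")
  if (!response %in% names(data)) abort(paste0("response '", response, "' not in data"))
  if (nrow(data) < 50) abort("at least 50 rows are required to fit the ensemble")
  X <- as.matrix(dplyr::select(data, dplyr::all_of(predictors)))
  if (anyNA(X) || !all(is.finite(X))) abort("non-finite predictor values")
  y <- data[[response]]
  if (is.factor(y) || is.character(y)) y <- as.integer(factor(y)) - 1L
  if (is.logical(y)) y <- as.integer(y)
  y <- as.numeric(y)
  if (anyNA(y)) abort("missing response values")
  uy <- unique(y)
  if (length(uy) < 2) abort("constant response: nothing to fit")
  loss <- if (length(uy) == 2 && all(uy %in% c(0, 1))) "bernoulli" else "gaussian"
  ord <- do.call(order, c(as.data.frame(X), list(y)))
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  fit <- with_seed(seed, {
    .brt_fit_cpp(X, y, loss, hyper$n_trees, hyper$learning_rate,
                 hyper$max_depth, hyper$bag_fraction, hyper$min_node,
                 hyper$patience)
  })
  structure(list(trees = fit$trees, init = fit$init,
                 n_trees = fit$n_trees, loss = loss,
                 features = predictors, response = response,
                 hyper = hyper,
                 feature_gain = setNames(as.numeric(fit$feature_gain),
                                         predictors),
                 train_deviance = fit$train_deviance,
                 oob_deviance = fit$oob_deviance),
            class = "sink_brt")
}

#' @export
print.sink_brt <- function(x, ...) {
  cat("<sink_brt>", x$loss, "loss |", x$n_trees, "trees | depth",
      x$hyper$max_depth, "| lr", x$hyper$learning_rate, "\n")
  ri <- relative_influence(x)
  top <- ri[order(-ri$influence), ][1:min(3, nrow(ri)), ]
  cat("top influences:",
      paste0(top$driver, " ", round(top$influence, 1), "%", collapse = ", "),
      "\n")
  invisible(x)
}

#' Predict from a fitted boosted-tree ensemble
#'
#' @param object A `sink_brt`.
#' @param newdata Data frame containing the training predictors.
#' @param type `"response"` (probability for Bernoulli fits, value for
#'   Gaussian) or `"link"` (raw score).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.sink_brt <- function(object, newdata,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("driver(s) missing from newdata: ",
                 paste(missing, collapse = ", ")))
  }
  X <- as.matrix(dplyr::select(newdata, dplyr::all_of(object$features)))
  f <- .brt_predict_cpp(object$trees, object$init,
                        object$hyper$learning_rate, X)
  if (type == "response" && object$loss == "bernoulli") stats::plogis(f) else f
}

#' Friedman relative influence of each driver
#'
#' For every predictor, the summed squared-error (or deviance) reduction of
#' all splits made on it across the ensemble, normalised to percentages that
#' sum to 100. Climate/human group membership is attached.
#'
#' @param object A fitted `sink_brt`.
#' @return Tibble `driver`, `influence` (percent), `group`.
#' @export
relative_influence <- function(object) {
  stopifnot(inherits(object, "sink_brt"))
  g <- object$feature_gain
  total <- sum(g)
  infl <- if (total > 0) 100 * g / total else rep(0, length(g))
  grp <- driver_groups()[object$features]
  tibble::tibble(driver = object$features, influence = unname(infl),
                 group = unname(ifelse(is.na(grp), "other", grp)))
}

#' Area under the ROC curve (rank / Mann-Whitney form)
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`; ties in scores contribute 1/2.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) abort("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Grade an AUC value
#'
#' Standard grading bands: excellent for AUC >= 0.9, good in (0.8, 0.9),
#' accurate in (0.7, 0.8), poor in (0.6, 0.7). Band boundaries are assigned
#' to the higher band; values below 0.6 are graded `"fail"`.
#'
#' @param x AUC value(s) in `[0, 1]`.
#' @return Character vector of grades.
#' @examples
#' auc_grade(c(0.95, 0.85, 0.75, 0.65, 0.5))
#' @export
auc_grade <- function(x) {
  stopifnot(all(x >= 0 & x <= 1))
  dplyr::case_when(x >= 0.9 ~ "excellent",
                   x >= 0.8 ~ "good",
                   x >= 0.7 ~ "accurate",
                   x >= 0.6 ~ "poor",
                   TRUE ~ "fail")
}

#' Repeated stratified k-fold cross-validation of a BRT fit
#'
#' Splits the rows into `folds` class-stratified folds, fits on the
#' remaining folds and scores the held-out fold; the skill score (AUC for
#' binary responses, R-squared for continuous ones) is averaged over folds,
#' then over `reps` independent repetitions. Should a fold end up with a
#' single class (possible only in tiny strata), the repetition is refolded
#' with a fresh seed and a message is logged.
#'
#' @inheritParams fit_brt
#' @param folds Number of folds.
#' @param reps Number of repetitions averaged.
#' @return List: `score` (mean over reps), `metric` (`"auc"` or `"r2"`),
#'   `grade` (AUC grade, binary only), `per_rep` (numeric vector),
#'   `per_fold` (tibble rep/fold/score).
#' @export
cross_validate <- function(data, response, predictors = NULL,
                           hyper = brt_config(), folds = 10L, reps = 10L,
                           seed = NULL) {
  predictors <- predictors %||% intersect(driver_names(), names(data))
  y <- data[[response]]
  if (is.factor(y) || is.character(y)) y <- as.integer(factor(y)) - 1L
  if (is.logical(y)) y <- as.integer(y)
  binary <- length(unique(y)) == 2 && all(unique(y) %in% c(0, 1))
  n <- nrow(data)
  rep_seeds <- child_seeds(seed %||% 1L, reps * 2L)
  per_fold <- purrr::map_dfr(seq_len(reps), function(r) {
    fold_id <- NULL
    attempt <- 0L
    repeat {
      fold_id <- with_seed(rep_seeds[r] + attempt, {
        if (binary) {
          id <- integer(n)
          for (cl in c(0, 1)) {
            idx <- which(y == cl)
            id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
          }
          id
        } else {
          sample(rep_len(seq_len(folds), n))
        }
      })
      ok <- !binary || all(vapply(seq_len(folds), function(f)
        length(unique(y[fold_id == f])) == 2, logical(1)))
      if (ok || attempt >= 5L) break
      attempt <- attempt + 1L
      message("refolding repetition ", r, ": a fold had a single class")
    }
    purrr::map_dfr(seq_len(folds), function(f) {
      test <- fold_id == f
      fit <- fit_brt(data[!test, , drop = FALSE], response, predictors,
                     hyper = hyper, seed = rep_seeds[reps + r] + f)
      p <- predict(fit, data[test, , drop = FALSE], type = "response")
      score <- if (binary) {
        auc(p, y[test])
      } else {
        1 - sum((y[test] - p)^2) / sum((y[test] - mean(y[!test]))^2)
      }
      tibble::tibble(rep = r, fold = f, score = score)
    })
  })
  per_rep <- per_fold |>
    dplyr::group_by(.data$rep) |>
    dplyr::summarise(score = mean(.data$score)) |>
    dplyr::pull(.data$score)
  score <- mean(per_rep)
  list(score = score, metric = if (binary) "auc" else "r2",
       grade = if (binary) auc_grade(score) else NA_character_,
       per_rep = per_rep, per_fold = per_fold)
}

#' Binary stability response from five ordinal classes
#'
#' Classes 1-2 (stable, relatively stable) map to 1, classes 4-5 to 0, the
#' middle class to `NA` (excluded from attribution).
#'
#' @param stability_class Integer classes 1..5.
#' @return Integer 0/1/NA vector.
#' @export
stability_binary <- function(stability_class) {
  dplyr::case_when(stability_class <= 2L ~ 1L,
                   stability_class >= 4L ~ 0L,
                   TRUE ~ NA_integer_)
}

#' Driver attribution per project-overlap stratum
#'
#' Fits the boosted ensemble within each overlap stratum (and once
#' nationally on all rows), returning per-driver relative influence, the
#' climate/human group sums, and the repeated cross-validation skill.
#' Strata with fewer than `min_rows` usable rows are skipped with a warning.
#'
#' @param data Driver table: ten driver columns, a response column, and a
#'   `stratum` column (overlap count 0-5).
#' @inheritParams cross_validate
#' @param min_rows Minimum rows per analysed stratum.
#' @param cv Set `FALSE` to skip cross-validation scoring.
#' @return List with `influence` (tibble: stratum, driver, influence, group),
#'   `groups` (tibble: stratum, group, influence), `skill` (tibble: stratum,
#'   metric, score, grade), `models` (named list of `sink_brt`).
#' @export
stratified_attribution <- function(data, response, predictors = NULL,
                                   hyper = brt_config(), folds = 10L,
                                   reps = 10L, seed = NULL, min_rows = 200L,
                                   cv = TRUE) {
  stopifnot("stratum" %in% names(data))
  strata <- sort(unique(data$stratum))
  groups_run <- c(list(national = data),
                  setNames(lapply(strata, function(s)
                    data[data$stratum == s, , drop = FALSE]),
                    paste0("stratum_", strata)))
  seeds <- child_seeds(seed %||% 1L, length(groups_run) * 2L)
  out <- purrr::imap(groups_run, function(d, nm) {
    d <- d[!is.na(d[[response]]), , drop = FALSE]
    if (nrow(d) < min_rows && nm != "national") {
      warn(paste0(nm, " skipped: only ", nrow(d), " usable rows (< ",
                  min_rows, ")"))
      return(NULL)
    }
    i <- match(nm, names(groups_run))
    fit <- fit_brt(d, response, predictors, hyper = hyper, seed = seeds[i])
    sk <- if (cv) {
      cross_validate(d, response, predictors, hyper = hyper, folds = folds,
                     reps = reps, seed = seeds[length(groups_run) + i])
    }
    list(name = nm, fit = fit, skill = sk)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  influence <- purrr::map_dfr(out, function(o)
    dplyr::mutate(relative_influence(o$fit), stratum = o$name, .before = 1))
  groups <- influence |>
    dplyr::group_by(.data$stratum, .data$group) |>
    dplyr::summarise(influence = sum(.data$influence), .groups = "drop")
  skill <- purrr::map_dfr(out, function(o) {
    if (is.null(o$skill)) return(tibble::tibble())
    tibble::tibble(stratum = o$name, metric = o$skill$metric,
                   score = o$skill$score, grade = o$skill$grade)
  })
  list(influence = influence, groups = groups, skill = skill,
       models = setNames(purrr::map(out, "fit"), purrr::map_chr(out, "name")))
}

#' @rdname fit_brt
#' @param x A `sink_brt` object.
#' @param ... Unused.
#' @export
tidy.sink_brt <- function(x, ...) {
  relative_influence(x) |> dplyr::arrange(dplyr::desc(.data$influence))
}

#' @rdname fit_brt
#' @export
glance.sink_brt <- function(x, ...) {
  tibble::tibble(loss = x$loss, n_trees = x$n_trees,
                 train_deviance = x$train_deviance[length(x$train_deviance)],
                 oob_deviance = min(x$oob_deviance, na.rm = TRUE),
                 learning_rate = x$hyper$learning_rate,
                 max_depth = x$hyper$max_depth,
                 bag_fraction = x$hyper$bag_fraction)
}
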