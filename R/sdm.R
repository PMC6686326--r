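# Per-species random-forest habitat-suitability model: fitting with the
# standard parameterization (1,001 trees, mtry 8, minimum node size 10),
# per-tree prediction access, the mean-median combination rule, per-cell
# confidence values, and the 30-tree bagging ensemble used by the stability
# metrics.

#' Random-forest configuration
#'
#' Defaults are the published parameterization: 1,001 regression trees,
#' eight candidate predictors per split (`mtry`), and a minimum terminal
#' node size of 10 observations.
#'
#' @param n_trees Number of regression trees (default 1001).
#' @param mtry Predictors sampled at each split (default 8).
#' @param min_node Minimum terminal node size (default 10).
#' @param seed RNG seed for the fit (default 42).
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 1001, mtry = 8, min_node = 10, seed = 42) {
  stopifnot(n_trees >= 1, mtry >= 1, min_node >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 min_node = as.integer(min_node), seed = as.integer(seed)),
            class = "rf_config")
}

training_matrix <- function(training) {
  data <- training$data
  pred_cols <- setdiff(names(data), c("cell_id", "mean_iv", "species"))
  if (!length(pred_cols)) {
    stop("bad-predictor: training data has no predictor columns")
  }
  bad <- pred_cols[!vapply(data[pred_cols], is.numeric, logical(1))]
  if (length(bad)) {
    stop("bad-predictor: non-numeric predictor column(s): ",
         paste(bad, collapse = ", "))
  }
  list(x = data[pred_cols], y = data$mean_iv, pred_cols = pred_cols)
}

#' Fit the species random-forest model
#'
#' Fits `mean_iv ~ predictors` with [randomForest::randomForest] and records
#' the out-of-bag pseudo-R^2 (`1 - MSE_oob / Var(y)`, which may be
#' negative), permutation importance scores (percent increase in MSE) and
#' their deterministic ranks (ties broken by predictor name). Fits are
#' reproducible for a fixed seed.
#'
#' @param training A `training_set` (see [filter_training_cells()]) whose
#'   `data` holds `cell_id`, `mean_iv` and numeric predictor columns.
#' @param config An [rf_config()].
#' @return An object of class `rf_sdm`: list with `forest`, `config`,
#'   `predictors`, `oob_r2`, `importance` (data frame `predictor`, `score`,
#'   `rank`), `training_cells`, `species`.
#' @export
fit_rf <- function(training, config = rf_config()) {
  tm <- training_matrix(training)
  if (config$mtry > length(tm$pred_cols)) {
    stop("bad-predictor-count: mtry (", config$mtry,
         ") exceeds the number of predictors (", length(tm$pred_cols), ")")
  }
  if (nrow(tm$x) < config$min_node) {
    stop("insufficient-training: ", nrow(tm$x), " rows < min_node = ",
         config$min_node)
  }
  set.seed(config$seed)
  forest <- randomForest::randomForest(
    x = tm$x, y = tm$y, ntree = config$n_trees, mtry = config$mtry,
    nodesize = config$min_node, importance = TRUE, keep.forest = TRUE)
  oob_r2 <- 1 - mean((tm$y - forest$predicted)^2) /
    mean((tm$y - mean(tm$y))^2)
  score <- randomForest::importance(forest, type = 1, scale = TRUE)[, 1]
  names(score) <- tm$pred_cols
  rank <- rank_by_score(score)
  structure(list(
    forest = forest, config = config, predictors = tm$pred_cols,
    oob_r2 = oob_r2,
    importance = data.frame(predictor = tm$pred_cols,
                            score = as.numeric(score),
                            rank = as.integer(rank),
                            stringsAsFactors = FALSE),
    training_cells = training$data$cell_id,
    species = training$species %||% NA_character_
  ), class = "rf_sdm")
}

#' Top-ranked predictors of a fitted model
#'
#' @param model An `rf_sdm`.
#' @param k Number of predictors (default 5).
#' @param positive_only Drop predictors with non-positive importance scores
#'   (so a model driven by fewer than `k` variables returns a shorter list).
#' @return Character vector of predictor names in rank order.
#' @export
top_predictors <- function(model, k = 5, positive_only = FALSE) {
  imp <- model$importance[order(model$importance$rank), ]
  if (positive_only) imp <- imp[imp$score > 0, , drop = FALSE]
  utils::head(imp$predictor, k)
}

new_ensemble_prediction <- function(cell_id, values) {
  structure(list(
    cell_id = as.character(cell_id),
    values = values,
    mean = rowMeans(values),
    median = apply(values, 1, stats::median),
    cv = apply(values, 1, cv_value)
  ), class = "ensemble_prediction")
}

#' Construct an ensemble prediction from a raw value matrix
#'
#' Mainly for constructing worked examples: wraps a cells-by-trees matrix of
#' predicted IVs into the same object [predict_ensemble()] returns, with the
#' per-cell mean, median and coefficient of variation (sample SD / mean;
#' `Inf` when the mean is 0 but some value is positive, 0 for an all-zero
#' vector).
#'
#' @param values Numeric matrix, one row per cell, one column per tree.
#' @param cell_id Optional cell ids (default `"cell_1"`, ...).
#' @return An `ensemble_prediction`.
#' @export
ensemble_from_values <- function(values, cell_id = NULL) {
  values <- rbind(values)  # promote a bare vector to a 1-row matrix
  cell_id <- cell_id %||% paste0("cell_", seq_len(nrow(values)))
  stopifnot(length(cell_id) == nrow(values))
  new_ensemble_prediction(cell_id, values)
}

#' Per-tree predictions for a set of cells
#'
#' Predictions are made for every supplied cell, including cells that were
#' excluded from training (too few plots, low forest cover, outliers); the
#' model imputes IV everywhere on the lattice.
#'
#' @param model An `rf_sdm`.
#' @param newdata Data frame with `cell_id` and all predictor columns.
#' @return An `ensemble_prediction`: `cell_id`, `values`
#'   (cells x `n_trees` matrix), `mean`, `median`, `cv`.
#' @export
predict_ensemble <- function(model, newdata) {
  miss <- setdiff(model$predictors, names(newdata))
  if (length(miss)) {
    stop("missing predictor column(s): ", paste(miss, collapse = ", "))
  }
  for (p in model$predictors) {
    bad <- which(is.na(newdata[[p]]))
    if (length(bad)) {
      stop("missing value of predictor '", p, "' for cell '",
           newdata$cell_id[bad[1]], "'")
    }
  }
  pr <- stats::predict(model$forest,
                       newdata = newdata[model$predictors],
                       predict.all = TRUE)
  # tree predictions are means of the non-negative response; clip the
  # occasional -1e-16 of floating-point accumulation
  values <- pmax(unname(pr$individual), 0)
  new_ensemble_prediction(newdata$cell_id, values)
}

#' Mean-median combination of ensemble predictions
#'
#' The default prediction for a cell is the mean of the per-tree predicted
#' IVs. When the ensemble median is 0 and the coefficient of variation of
#' the per-tree values is at least `cv_threshold` (default 2.75), the
#' prediction is replaced by 0: more than half the forest votes absent and
#' the spread of the remaining votes is large relative to the mean, so the
#' non-zero mean is treated as an artifact of outlier trees.
#'
#' @param pred An `ensemble_prediction`.
#' @param cv_threshold CV threshold of the zero rule (default 2.75; `Inf`
#'   reduces the combiner to the plain ensemble mean).
#' @return Data frame `cell_id`, `iv`, `method` (`"mean"` or
#'   `"median_zero"`), `mean`, `median`, `cv`.
#' @export
combine_mean_median <- function(pred, cv_threshold = 2.75) {
  stopifnot(inherits(pred, "ensemble_prediction"), cv_threshold >= 0)
  zero <- pred$median == 0 & pred$cv >= cv_threshold
  data.frame(
    cell_id = pred$cell_id,
    iv = ifelse(zero, 0, pred$mean),
    method = ifelse(zero, "median_zero", "mean"),
    mean = pred$mean,
    median = pred$median,
    cv = pred$cv,
    stringsAsFactors = FALSE
  )
}

#' Per-cell prediction confidence
#'
#' The fraction of per-tree predicted values within one dispersion unit of
#' the ensemble center: within one sample standard deviation of the mean
#' for cells predicted by the mean, or within one (unscaled) median
#' absolute deviation of the median for cells where the mean-median rule
#' fired. Bounds are inclusive, so a degenerate ensemble (SD or MAD of 0)
#' credits the values sitting exactly at the center.
#'
#' @param pred An `ensemble_prediction`.
#' @param method Character vector (recycled) of `"mean"` / `"median_zero"`
#'   per cell, e.g. the `method` column of [combine_mean_median()].
#' @return Numeric vector of confidence fractions in `[0, 1]`.
#' @export
confidence_value <- function(pred, method = "mean") {
  stopifnot(inherits(pred, "ensemble_prediction"),
            all(method %in% c("mean", "median_zero")))
  n <- length(pred$cell_id)
  method <- rep_len(method, n)
  conf <- numeric(n)
  for (i in seq_len(n)) {
    v <- pred$values[i, ]
    if (method[i] == "mean") {
      conf[i] <- mean(abs(v - pred$mean[i]) <= stats::sd(v))
    } else {
      mad_i <- stats::median(abs(v - pred$median[i]))
      conf[i] <- mean(abs(v - pred$median[i]) <= mad_i)
    }
  }
  conf
}

#' Fit, combine and score predictions in one step
#'
#' @inheritParams predict_ensemble
#' @inheritParams combine_mean_median
#' @return The [combine_mean_median()] data frame with a `confidence`
#'   column appended.
#' @export
predict_combined <- function(model, newdata, cv_threshold = 2.75) {
  pred <- predict_ensemble(model, newdata)
  out <- combine_mean_median(pred, cv_threshold)
  out$confidence <- confidence_value(pred, out$method)
  out
}

# Per-predictor deviance (sum-of-squares impurity) decrease of one rpart
# regression tree, attributed to the variable of each primary split; the
# entries sum to the tree's total explained deviance.
tree_deviance_profile <- function(fit, predictors) {
  prof <- stats::setNames(numeric(length(predictors)), predictors)
  fr <- fit$frame
  if (nrow(fr) > 1) {
    nodes <- as.integer(row.names(fr))
    for (i in which(fr$var != "<leaf>")) {
      li <- match(2L * nodes[i], nodes)
      ri <- match(2L * nodes[i] + 1L, nodes)
      prof[[as.character(fr$var[i])]] <-
        prof[[as.character(fr$var[i])]] + fr$dev[i] - fr$dev[li] - fr$dev[ri]
    }
  }
  prof
}

profile_top_k <- function(prof, k = 5) {
  prof <- prof[prof > 0]
  if (!length(prof)) return(character(0))
  utils::head(names(prof)[order(-prof, names(prof))], k)
}

#' Construct a bagging ensemble from deviance profiles
#'
#' Wraps a trees-by-predictors matrix of per-tree deviance-explained
#' profiles into the object [fit_bagging()] returns, deriving each tree's
#' top-five predictor ranking from its profile. Useful for worked examples
#' of the stability metrics.
#'
#' @param profiles Non-negative numeric matrix, one row per tree, with
#'   predictor column names.
#' @return A `bagging_ensemble`.
#' @export
bagging_ensemble <- function(profiles) {
  profiles <- rbind(profiles)
  stopifnot(!is.null(colnames(profiles)), all(profiles >= 0))
  top5 <- lapply(seq_len(nrow(profiles)),
                 function(t) profile_top_k(profiles[t, ], 5))
  structure(list(profiles = profiles, top5 = top5,
                 n_models = nrow(profiles),
                 predictors = colnames(profiles)),
            class = "bagging_ensemble")
}

#' Fit the bagging ensemble of single regression trees
#'
#' Fits `n_models` CART regression trees, each on an independent bootstrap
#' resample of the training rows with all predictors available at every
#' split, and extracts per-tree deviance-explained profiles (impurity
#' decrease attributed to the split variable, summing to the tree's total
#' explained deviance) and top-five predictor rankings. The variation of
#' these profiles across trees measures how consistently the model's
#' leading predictors carry its signal (see [cv_deviance_stability()] and
#' [top5_stability()]).
#'
#' @param training A `training_set`.
#' @param n_models Ensemble size (default 30).
#' @param seed RNG seed.
#' @param min_node Minimum terminal node size (default 10, as in the
#'   forest).
#' @param cp Complexity parameter passed to [rpart::rpart.control()].
#' @return A `bagging_ensemble`: `profiles` (`n_models` x P matrix),
#'   `top5` (list of rankings), `n_models`, `predictors`.
#' @export
fit_bagging <- function(training, n_models = 30, seed = 42, min_node = 10,
                        cp = 0.01) {
  tm <- training_matrix(training)
  if (nrow(tm$x) < min_node) {
    stop("insufficient-training: ", nrow(tm$x), " rows < min_node = ", min_node)
  }
  d <- cbind(mean_iv = tm$y, tm$x)
  set.seed(seed)
  profiles <- matrix(0, n_models, length(tm$pred_cols),
                     dimnames = list(NULL, tm$pred_cols))
  for (t in seq_len(n_models)) {
    idx <- sample.int(nrow(d), replace = TRUE)
    fit <- rpart::rpart(mean_iv ~ ., data = d[idx, , drop = FALSE],
                        method = "anova",
                        control = rpart::rpart.control(minbucket = min_node,
                                                       cp = cp, xval = 0))
    profiles[t, ] <- pmax(tree_deviance_profile(fit, tm$pred_cols), 0)
  }
  bagging_ensemble(profiles)
}
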