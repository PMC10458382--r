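# Hyperparameter tuning of a gradient-boosted tree classifier: the Aquila
# Optimizer searches a seven-dimensional box minimizing 1 - accuracy on an
# inner validation split of the training data.

#' The seven-dimensional XGBoost hyperparameter search space
#'
#' Bounds: learning_rate [1.5e-15, 0.9] (log10 scale), colsample_bytree
#' [0.001, 1], gamma [1e-9, 1] (log10), max_depth [1, 200] (integer),
#' subsample [1, 200] (mapped into the learner's (0, 1] domain at decode
#' time, see \code{\link{decode_position}}), min_child_weight [1, 200]
#' (integer), alpha [1e-6, 1] (log10).
#'
#' @return A \code{\link{search_space}} with named dimensions.
#' @export
hyperparam_space_xgb <- function() {
  search_space(
    lb = c(1.5e-15, 0.001, 1e-9, 1, 1, 1, 1e-6),
    ub = c(0.9, 1.0, 1.0, 200, 200, 200, 1.0),
    integer_mask = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    log_mask = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    names = c("learning_rate", "colsample_bytree", "gamma", "max_depth",
              "subsample", "min_child_weight", "alpha")
  )
}

#' Train/test split specification
#'
#' @param test_fraction fraction of rows held out (default 0.30, a 70:30
#'   split).
#' @param stratified preserve the class ratio in both parts (default TRUE).
#' @param seed RNG seed for the partition.
#' @return A \code{split_spec} object.
#' @export
split_spec <- function(test_fraction = 0.30, stratified = TRUE, seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stopf("`test_fraction` must lie in (0, 1)")
  structure(list(test_fraction = test_fraction, stratified = stratified,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/test split of a feature table
#'
#' @param table a \code{feature_table} (needs both classes present).
#' @param spec a \code{\link{split_spec}}.
#' @return List with \code{train} and \code{test} feature tables (disjoint,
#'   sizes within one row of the exact fractions, reproducible per seed).
#' @export
split_data <- function(table, spec = split_spec()) {
  y <- table$label
  if (length(unique(y)) < 2)
    stopf("cannot split a single-class feature table")
  local_seed(spec$seed, {
    test_idx <- integer(0)
    if (spec$stratified) {
      for (cls in sort(unique(y))) {
        rows <- which(y == cls)
        n_test <- round(length(rows) * spec$test_fraction)
        test_idx <- c(test_idx, sample(rows, n_test))
      }
    } else {
      test_idx <- sample(seq_along(y), round(length(y) * spec$test_fraction))
    }
    test_idx <- sort(test_idx)
    train <- table[-test_idx, , drop = FALSE]
    test <- table[test_idx, , drop = FALSE]
    class(train) <- class(test) <- c("feature_table", "data.frame")
    list(train = train, test = test)
  })
}

#' Classification accuracy
#'
#' Accurately classified samples over total samples.
#'
#' @param predicted,actual equal-length binary label vectors.
#' @return Accuracy in [0, 1].
#' @export
accuracy_score <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stopf("`predicted` (%d) and `actual` (%d) differ in length",
          length(predicted), length(actual))
  if (!length(actual)) stopf("empty label vectors")
  mean(predicted == actual)
}

#' Decode an optimizer position into named hyperparameters
#'
#' Log-scaled dimensions are exponentiated (the optimizer searches them in
#' log10 coordinates), integer dimensions are rounded half-up, and the
#' subsample dimension — whose printed bounds [1, 200] fall outside the
#' learner's valid (0, 1] row-sampling domain — is divided by 200 and
#' clamped to [0.005, 1] unless \code{subsample_as_printed}.
#'
#' @param position numeric vector on the optimizer's search scale.
#' @param space the \code{\link{search_space}} (needs dimension names).
#' @param subsample_as_printed pass the subsample value through unmapped.
#' @return Named list of decoded hyperparameter values.
#' @export
decode_position <- function(position, space, subsample_as_printed = FALSE) {
  lb <- to_search_scale(space$lb, space$log_mask)
  ub <- to_search_scale(space$ub, space$log_mask)
  if (any(position < lb - 1e-9) || any(position > ub + 1e-9))
    stopf("position outside the search box")
  vals <- position
  vals[space$log_mask] <- 10^vals[space$log_mask]
  vals <- ifelse(space$integer_mask, floor(vals + 0.5), vals)
  out <- as.list(vals)
  names(out) <- space$names %||% paste0("dim", seq_along(vals))
  if ("subsample" %in% names(out) && !subsample_as_printed)
    out$subsample <- min(max(out$subsample / 200, 0.005), 1.0)
  out
}

feature_matrix <- function(table) {
  as.matrix(table[, setdiff(colnames(table), "label"), drop = FALSE])
}

fit_xgb <- function(table, params, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(feature_matrix(table),
                                 label = table$label, nthread = 1)
  params <- c(params, list(objective = "binary:logistic", nthread = 1,
                           seed = as.integer(seed)))
  model <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = nrounds, verbose = 0)
  structure(list(kind = "xgb", model = model), class = "seizure_model")
}

#' Positive-class scores of a fitted model
#'
#' @param handle a model handle from \code{\link{fit_final}} or
#'   \code{\link{baseline_fit}}.
#' @param table a \code{feature_table}.
#' @return Numeric scores in [0, 1] (probability of the seizure class).
#' @export
predict_scores <- function(handle, table) {
  if (!inherits(handle, "seizure_model")) stopf("`handle` must be a seizure_model")
  x <- feature_matrix(table)
  switch(handle$kind,
    xgb = predict(handle$model, xgboost::xgb.DMatrix(x, nthread = 1)),
    rpart = predict(handle$model, as.data.frame(x))[, "1"],
    rf = predict(handle$model, as.data.frame(x), type = "prob")[, "1"],
    stopf("unknown model kind %s", handle$kind))
}

#' Predicted labels of a fitted model
#' @inheritParams predict_scores
#' @param threshold score cutoff (default 0.5).
#' @return Integer 0/1 labels.
#' @export
predict_labels <- function(handle, table, threshold = 0.5) {
  as.integer(predict_scores(handle, table) > threshold)
}

#' Tuning objective: one minus inner-validation accuracy
#'
#' Decodes the position, fits the gradient-boosted learner on an inner
#' training part and returns \code{1 - accuracy} on the inner validation
#' part (the outer test set is never touched). A learner failure returns the
#' worst-case objective 1 with a warning so the search continues.
#'
#' @param position optimizer position (search scale).
#' @param train_table training \code{feature_table} (both classes present).
#' @param space the hyperparameter \code{\link{search_space}}.
#' @param inner_split a \code{\link{split_spec}} for the inner validation
#'   split (default 80:20).
#' @param nrounds boosting rounds per evaluation (default 50).
#' @return Objective value in [0, 1].
#' @export
tune_objective <- function(position, train_table, space,
                           inner_split = split_spec(0.2), nrounds = 50) {
  hp <- decode_position(position, space)
  res <- tryCatch({
    parts <- split_data(train_table, inner_split)
    model <- fit_xgb(parts$train, hp, nrounds = nrounds,
                     seed = inner_split$seed)
    1 - accuracy_score(predict_labels(model, parts$test), parts$test$label)
  }, error = function(e) {
    warning(sprintf("learner failed (%s); objective set to worst case 1.0",
                    conditionMessage(e)), call. = FALSE)
    1.0
  })
  res
}

#' Tune XGBoost hyperparameters with the Aquila Optimizer
#'
#' Runs \code{\link{ao_optimize}} over the seven-dimensional space, scoring
#' each candidate by \code{\link{tune_objective}}.
#'
#' @param train_table training \code{feature_table}.
#' @param space hyperparameter \code{\link{search_space}} (default
#'   \code{\link{hyperparam_space_xgb}()}).
#' @param aocfg an \code{\link{ao_config}}; default is a desk-scale budget
#'   (population 20, 30 epochs). Pass \code{ao_config()} for the study-scale
#'   250 x 250 budget.
#' @param inner_split inner validation \code{\link{split_spec}}.
#' @param nrounds boosting rounds per evaluation.
#' @return A \code{tune_report}: list with \code{best_hyperparams},
#'   \code{best_objective}, \code{trace} (non-increasing), \code{aocfg},
#'   \code{inner_split}, \code{evaluations}.
#' @export
tune_xgb <- function(train_table, space = hyperparam_space_xgb(),
                     aocfg = ao_config(pop_size = 20, max_iter = 30),
                     inner_split = split_spec(0.2), nrounds = 50) {
  res <- ao_optimize(function(p)
    tune_objective(p, train_table, space, inner_split, nrounds),
    space, aocfg)
  structure(list(best_hyperparams = decode_position(res$best_position, space),
                 best_objective = res$best_fitness, trace = res$history,
                 aocfg = aocfg, inner_split = inner_split,
                 evaluations = res$evaluations),
            class = "tune_report")
}

#' @export
print.tune_report <- function(x, ...) {
  cat(sprintf("<tune_report> best objective %.4f (accuracy %.4f) after %d evaluations\n",
              x$best_objective, 1 - x$best_objective, x$evaluations))
  invisible(x)
}

#' Fit the final tuned classifier
#'
#' @param train_table training \code{feature_table}.
#' @param hyperparams named list of decoded hyperparameters (from a
#'   \code{tune_report}).
#' @param nrounds boosting rounds (default 50).
#' @param seed RNG seed for the learner.
#' @return A \code{seizure_model} handle.
#' @export
fit_final <- function(train_table, hyperparams, nrounds = 50, seed = 1) {
  fit_xgb(train_table, hyperparams, nrounds = nrounds, seed = seed)
}

#' Fit a baseline tree-ensemble comparator
#'
#' \code{"DT"} is a CART decision tree, \code{"RF"} a random forest,
#' \code{"GBC"} a gradient-boosting configuration (shrinkage 0.1, depth 3,
#' full row/column sampling), and \code{"untuned"} the gradient-boosted
#' learner at its stock defaults.
#'
#' @param train_table training \code{feature_table}.
#' @param kind one of \code{"DT"}, \code{"RF"}, \code{"GBC"},
#'   \code{"untuned"}.
#' @param seed RNG seed.
#' @return A \code{seizure_model} handle.
#' @export
baseline_fit <- function(train_table, kind = c("DT", "RF", "GBC", "untuned"),
                         seed = 1) {
  kind <- match.arg(kind)
  df <- as.data.frame(feature_matrix(train_table))
  df$label <- factor(train_table$label, levels = c(0, 1))
  local_seed(seed, switch(kind,
    DT = structure(list(kind = "rpart",
                        model = rpart::rpart(label ~ ., data = df,
                                             method = "class")),
                   class = "seizure_model"),
    RF = structure(list(kind = "rf",
                        model = randomForest::randomForest(label ~ ., data = df,
                                                           ntree = 100)),
                   class = "seizure_model"),
    GBC = fit_xgb(train_table,
                  list(eta = 0.1, max_depth = 3, subsample = 1,
                       colsample_bytree = 1),
                  nrounds = 100, seed = seed),
    untuned = fit_xgb(train_table, list(), nrounds = 50, seed = seed)))
}
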