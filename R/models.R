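# The two sound classifiers. Impact-versus-noise: gradient-boosted trees
# (learning rate 0.1, 300 trees, depth 3). Rebound-versus-noise: soft-voting
# ensemble of boosted trees (0.05, 500, depth 5), an RBF support vector
# machine (C = 1, gamma = "scale") and a 100-unit ReLU/Adam perceptron.
# Trees consume raw features; the SVM and MLP see z-scored features (scaling
# fitted on training data only).

#' Impact-model hyperparameters
#' @param learning_rate,n_trees,max_depth boosted-tree hyperparameters
#'   (defaults 0.1, 300, 3).
#' @return an `impact_config` list.
#' @export
impact_config <- function(learning_rate = 0.1, n_trees = 300L, max_depth = 3L) {
  stopifnot(learning_rate > 0, n_trees > 0, max_depth > 0)
  structure(list(learning_rate = learning_rate, n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth)), class = "impact_config")
}

#' Rebound-ensemble hyperparameters
#' @param learning_rate,n_trees,max_depth boosted-tree member (defaults
#'   0.05, 500, 5).
#' @param svm_cost RBF SVM cost C (default 1).
#' @param mlp_hidden,mlp_epochs perceptron size and training epochs.
#' @return an `ensemble_config` list.
#' @export
ensemble_config <- function(learning_rate = 0.05, n_trees = 500L,
                            max_depth = 5L, svm_cost = 1,
                            mlp_hidden = 100L, mlp_epochs = 150L) {
  structure(list(learning_rate = learning_rate, n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth), svm_cost = svm_cost,
                 mlp_hidden = as.integer(mlp_hidden),
                 mlp_epochs = as.integer(mlp_epochs)),
            class = "ensemble_config")
}

check_binary_labels <- function(labels, positive) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stopf("training data must contain both classes")
  if (!positive %in% labels)
    stopf("positive class '%s' absent from labels", positive)
  labels
}

fit_xgb <- function(x, y01, learning_rate, n_trees, max_depth, seed) {
  dtrain <- xgboost::xgb.DMatrix(data = x, label = y01)
  params <- list(objective = "binary:logistic", eta = learning_rate,
                 max_depth = max_depth, nthread = 1L, seed = seed)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = n_trees,
                     verbose = 0)
}

#' Train the impact-versus-noise model
#'
#' @param features numeric matrix (samples x features).
#' @param labels vector with classes `"impact"` and `"noise"`.
#' @param config an [impact_config()].
#' @param seed integer seed.
#' @return an object of class `impact_model` with a `predict` method.
#' @export
train_impact_model <- function(features, labels, config = impact_config(),
                               seed = 1L) {
  labels <- check_binary_labels(labels, "impact")
  booster <- fit_xgb(features, as.numeric(labels == "impact"),
                     config$learning_rate, config$n_trees, config$max_depth,
                     seed)
  structure(list(booster = booster, positive = "impact",
                 negative = "noise", config = config,
                 n_features = ncol(features), seed = seed),
            class = "impact_model")
}

#' @export
predict.impact_model <- function(object, newdata,
                                 type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- stats::predict(object$booster, newdata)
  probs <- cbind(noise = 1 - p, impact = p)
  if (type == "prob") return(probs)
  ifelse(probs[, object$positive] > 0.5, object$positive, object$negative)
}

#' @export
print.impact_model <- function(x, ...) {
  cat(sprintf(paste0("<impact_model> boosted trees (lr %.3g, %d trees, ",
                     "depth %d), %d features\n"),
              x$config$learning_rate, x$config$n_trees, x$config$max_depth,
              x$n_features))
  invisible(x)
}

#' Train the rebound-versus-noise soft-voting ensemble
#'
#' Fits the three members and combines them by the arithmetic mean of
#' predicted class probabilities ([soft_vote()]). The SVM gamma follows the
#' "scale" rule 1 / (n_features * Var(X)) computed on the z-scored training
#' matrix.
#'
#' @param features numeric matrix (samples x features).
#' @param labels vector with classes `"rebound"` and `"noise"`.
#' @param config an [ensemble_config()].
#' @param seed integer seed.
#' @return an object of class `rebound_ensemble` with a `predict` method.
#' @export
train_rebound_ensemble <- function(features, labels,
                                   config = ensemble_config(), seed = 1L) {
  labels <- check_binary_labels(labels, "rebound")
  y01 <- as.numeric(labels == "rebound")
  xgb <- fit_xgb(features, y01, config$learning_rate, config$n_trees,
                 config$max_depth, seed)
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(features, 2, center), 2, scale, "/")
  gamma <- 1 / (ncol(xs) * stats::var(as.vector(xs)))
  yfac <- factor(labels, levels = c("noise", "rebound"))
  svm <- with_seed(seed, e1071::svm(
    x = xs, y = yfac, kernel = "radial", cost = config$svm_cost,
    gamma = gamma, probability = TRUE, scale = FALSE))
  mlp <- fit_mlp(xs, y01, hidden = config$mlp_hidden,
                 epochs = config$mlp_epochs, seed = derive_seed(seed, 7L))
  structure(list(xgb = xgb, svm = svm, mlp = mlp, center = center,
                 scale = scale, positive = "rebound", negative = "noise",
                 config = config, n_features = ncol(features), seed = seed),
            class = "rebound_ensemble")
}

#' Soft voting: arithmetic mean of member probability matrices
#'
#' @param prob_list list of matrices with identical dimensions and column
#'   names (one row per sample, one column per class).
#' @return the element-wise mean matrix.
#' @export
soft_vote <- function(prob_list) {
  stopifnot(length(prob_list) >= 1)
  Reduce(`+`, prob_list) / length(prob_list)
}

#' @export
predict.rebound_ensemble <- function(object, newdata,
                                     type = c("prob", "class"), ...) {
  type <- match.arg(type)
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  p_xgb <- stats::predict(object$xgb, newdata)
  sv <- stats::predict(object$svm, xs, probability = TRUE)
  p_svm <- attr(sv, "probabilities")[, object$positive]
  p_mlp <- predict_mlp(object$mlp, xs)
  probs <- soft_vote(list(
    cbind(noise = 1 - p_xgb, rebound = p_xgb),
    cbind(noise = 1 - p_svm, rebound = p_svm),
    cbind(noise = 1 - p_mlp, rebound = p_mlp)))
  if (type == "prob") return(probs)
  # tie at 0.5 resolved toward noise (conservative against false positives)
  ifelse(probs[, object$positive] > 0.5, object$positive, object$negative)
}

#' @export
print.rebound_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<rebound_ensemble> soft voting of boosted trees ",
                     "(lr %.3g, %d trees, depth %d) + RBF SVM (C = %g) + ",
                     "MLP (%d ReLU units), %d features\n"),
              x$config$learning_rate, x$config$n_trees, x$config$max_depth,
              x$config$svm_cost, x$config$mlp_hidden, x$n_features))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Shuffles within each class (seeded) and deals samples round-robin into
#' `k` folds, so fold sizes are exactly equal whenever every class count is
#' divisible by `k` (1400 samples -> 1120 train / 280 test per iteration).
#' Each iteration trains on k-1 folds via `trainer` and scores accuracy on
#' the holdout.
#'
#' @param features numeric matrix.
#' @param labels class labels.
#' @param k number of folds (default 5).
#' @param seed integer seed (fold assignment and trainer seeding).
#' @param trainer function `(features, labels, seed)` returning a model whose
#'   `predict(model, newdata, type = "class")` yields labels.
#' @return a `cv_report`: list with `fold_accuracy`, `median_accuracy`,
#'   `fold_sizes`, `folds` (assignment vector), `k`, `seed`.
#' @export
kfold_cv <- function(features, labels, k = 5L, seed = 1L, trainer) {
  labels <- as.character(labels)
  n <- nrow(features)
  stopifnot(n >= k, length(labels) == n)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  if (any(vapply(split(labels, folds), function(l) length(unique(l)), 0L) < 2))
    stopf("stratification failed: a fold lacks a class (too few samples)")
  acc <- numeric(k)
  for (i in seq_len(k)) {
    tr <- folds != i
    model <- trainer(features[tr, , drop = FALSE], labels[tr],
                     derive_seed(seed, i))
    pred <- predict(model, features[!tr, , drop = FALSE], type = "class")
    acc[i] <- mean(pred == labels[!tr])
  }
  structure(list(fold_accuracy = acc, median_accuracy = stats::median(acc),
                 fold_sizes = as.vector(table(folds)), folds = folds,
                 k = k, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold accuracies: %s (median %.4f)\n", x$k,
              paste(sprintf("%.4f", x$fold_accuracy), collapse = ", "),
              x$median_accuracy))
  invisible(x)
}

#' Exhaustive grid search over hyperparameter configurations
#'
#' Evaluates each configuration by mean k-fold CV accuracy; ties go to the
#' earlier entry in grid order.
#'
#' @param features,labels,k,seed as in [kfold_cv()].
#' @param grid list of configuration objects.
#' @param trainer_for function mapping a configuration to a trainer
#'   `(features, labels, seed) -> model`.
#' @return list with `best_config`, `best_index`, and `table` (one row per
#'   grid entry: mean and median CV accuracy).
#' @export
grid_search <- function(features, labels, grid, k = 5L, seed = 1L,
                        trainer_for) {
  stopifnot(length(grid) >= 1)
  rows <- lapply(seq_along(grid), function(i) {
    rep <- kfold_cv(features, labels, k = k, seed = seed,
                    trainer = trainer_for(grid[[i]]))
    data.frame(config = i, mean_accuracy = mean(rep$fold_accuracy),
               median_accuracy = rep$median_accuracy)
  })
  tab <- do.call(rbind, rows)
  best <- which.max(tab$mean_accuracy)   # first maximum = grid order tie-break
  list(best_config = grid[[best]], best_index = best, table = tab)
}
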