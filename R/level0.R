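#' Level-0 learner specification
#'
#' The four decision-tree ensemble kinds used as base (level-0) models in a
#' blend: two bagging methods (random forest on full-grown trees, extremely
#' randomized trees) and two boosting methods (adaptive boosting, gradient
#' boosting). Each is consumed through one uniform contract so blenders and
#' importance aggregation never see backend-specific details.
#'
#' Recognized hyperparameters (validated against the kind):
#' * all kinds: `n_estimators`;
#' * `bagged_full_trees`: `max_depth` (mapped to a `2^max_depth` leaf cap;
#'   trees are full-grown when `NULL`), `mtry`, `bootstrap`, `nodesize`;
#' * `extremely_randomized_trees`: `max_depth`, `mtry`;
#' * `adaptive_boosting`: `max_depth` (weak-learner depth, default 5),
#'   `learning_rate`;
#' * `gradient_boosting`: `max_depth`, `learning_rate`, `subsample`.
#'
#' @param kind one of `"bagged_full_trees"` (alias `"rf"`),
#'   `"extremely_randomized_trees"` (`"extratrees"`), `"adaptive_boosting"`
#'   (`"adaboost"`), `"gradient_boosting"` (`"gbm"`).
#' @param task `"regression"` or `"classification"`.
#' @param hyperparameters named list overriding the kind's defaults.
#' @param random_state integer seed controlling every stochastic element of
#'   the fit.
#' @return an object of class `level0_spec`.
#' @export
level0_spec <- function(kind, task = c("regression", "classification"),
                        hyperparameters = list(), random_state = 0L) {
  task <- match.arg(task)
  aliases <- c(rf = "bagged_full_trees", extratrees = "extremely_randomized_trees",
               adaboost = "adaptive_boosting", gbm = "gradient_boosting")
  if (kind %in% names(aliases)) kind <- aliases[[kind]]
  kinds <- unname(aliases)
  if (!kind %in% kinds) {
    stop_("unknown learner kind '", kind, "'; expected one of ",
          paste(kinds, collapse = ", "))
  }
  defaults <- switch(kind,
    bagged_full_trees = list(n_estimators = 100L, max_depth = NULL,
                             mtry = NULL, bootstrap = TRUE, nodesize = NULL),
    extremely_randomized_trees = list(n_estimators = 100L, max_depth = NULL,
                                      mtry = NULL),
    adaptive_boosting = list(n_estimators = 50L, max_depth = 5L,
                             learning_rate = 1),
    gradient_boosting = list(n_estimators = 100L, max_depth = 3L,
                             learning_rate = 0.1, subsample = 1)
  )
  bad <- setdiff(names(hyperparameters), names(defaults))
  if (length(bad)) {
    stop_("hyperparameters not valid for '", kind, "': ",
          paste(bad, collapse = ", "))
  }
  hp <- utils::modifyList(defaults, hyperparameters, keep.null = TRUE)
  structure(list(kind = kind, task = task, hyperparameters = hp,
                 random_state = as.integer(random_state)),
            class = "level0_spec")
}

#' @export
print.level0_spec <- function(x, ...) {
  hp <- vapply(x$hyperparameters,
               function(v) if (is.null(v)) "NULL" else format(v), "")
  cat("<level0_spec> ", x$kind, " (", x$task, "), seed ", x$random_state,
      "\n  ", paste(names(hp), hp, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

short_kind <- function(kind) {
  c(bagged_full_trees = "rf", extremely_randomized_trees = "extratrees",
    adaptive_boosting = "adaboost", gradient_boosting = "gbm")[[kind]]
}

#' Fit a level-0 ensemble
#'
#' Trains the specified tree ensemble on a descriptor table and extracts its
#' impurity-based (mean-decrease-in-impurity) feature importance, normalized
#' to sum to 1. The fit is deterministic given the table, the spec and its
#' `random_state`.
#'
#' @param train a [descriptor_table].
#' @param spec a [level0_spec] whose task matches the table.
#' @return an object of class `fitted_level0` with fields `spec`, `learner`
#'   (backend fit), `feature_names`, `task`, `classes`/`positive_label`
#'   (classification) and `importance` (an [importance_profile]).
#' @export
fit_level0 <- function(train, spec) {
  stopifnot(inherits(train, "descriptor_table"), inherits(spec, "level0_spec"))
  if (spec$task != train$task) {
    stop_("spec task '", spec$task, "' does not match table task '",
          train$task, "'")
  }
  X <- train$X
  hp <- spec$hyperparameters
  if (train$task == "classification") {
    lev <- sort(unique(train$y))
    if (length(lev) < 2L) stop_("classification target has a single class")
    classes <- c(setdiff(lev, train$positive_label), train$positive_label)
    yf <- factor(train$y, levels = classes)       # positive class last
    y01 <- as.numeric(train$y == train$positive_label)
  } else {
    classes <- NULL
    yf <- y01 <- NULL
  }
  learner <- switch(spec$kind,
    bagged_full_trees = with_seed(spec$random_state, {
      n <- nrow(X)
      randomForest::randomForest(
        x = X, y = if (train$task == "classification") yf else train$y,
        ntree = hp$n_estimators,
        mtry = hp$mtry %||% if (train$task == "classification")
          max(1, floor(sqrt(ncol(X)))) else max(1, floor(ncol(X) / 3)),
        replace = isTRUE(hp$bootstrap),
        sampsize = if (isTRUE(hp$bootstrap)) n else n,
        maxnodes = if (!is.null(hp$max_depth)) 2L^hp$max_depth,
        nodesize = hp$nodesize %||%
          if (train$task == "classification") 1L else 5L
      )
    }),
    extremely_randomized_trees = ranger::ranger(
      x = as.data.frame(X),
      y = if (train$task == "classification") yf else train$y,
      num.trees = hp$n_estimators,
      mtry = hp$mtry %||% NULL,
      max.depth = hp$max_depth %||% 0L,
      splitrule = "extratrees", num.random.splits = 1L,
      replace = FALSE, sample.fraction = 1,
      importance = "impurity",
      probability = train$task == "classification",
      # ranger reads seed 0 as "seed from the clock"; shift to keep
      # random_state = 0 deterministic like the other kinds
      seed = spec$random_state + 1L, num.threads = 1L
    ),
    adaptive_boosting = ada_fit(
      X, y = if (train$task == "classification") as.character(yf) else train$y,
      task = train$task, n_estimators = hp$n_estimators,
      max_depth = hp$max_depth, learning_rate = hp$learning_rate
    ),
    gradient_boosting = {
      dm <- xgboost::xgb.DMatrix(X,
        label = if (train$task == "classification") y01 else train$y,
        nthread = 1L)
      xgboost::xgb.train(
        params = xgboost::xgb.params(
          max_depth = hp$max_depth, eta = hp$learning_rate,
          subsample = hp$subsample, nthread = 1L, seed = spec$random_state,
          objective = if (train$task == "classification")
            "binary:logistic" else "reg:squarederror"),
        data = dm, nrounds = hp$n_estimators, verbose = 0
      )
    }
  )
  fit <- structure(
    list(spec = spec, learner = learner, feature_names = train$feature_names,
         task = train$task, classes = classes,
         positive_label = train$positive_label, importance = NULL),
    class = "fitted_level0"
  )
  fit$importance <- extract_importance(fit)
  fit
}

# Raw backend importance mapped onto the training feature order, then
# normalized onto the simplex (uniform if the backend reports all zeros).
extract_importance <- function(fit) {
  fn <- fit$feature_names
  raw <- switch(fit$spec$kind,
    bagged_full_trees = {
      im <- randomForest::importance(fit$learner)
      stats::setNames(as.numeric(im[, 1L]), rownames(im))
    },
    extremely_randomized_trees = fit$learner$variable.importance,
    adaptive_boosting = ada_importance(fit$learner),
    gradient_boosting = {
      im <- as.data.frame(xgboost::xgb.importance(model = fit$learner))
      stats::setNames(im$Gain, im$Feature)
    }
  )
  scores <- stats::setNames(rep(0, length(fn)), fn)
  raw <- raw[names(raw) %in% fn]
  scores[names(raw)] <- pmax(as.numeric(raw), 0)
  importance_profile(scores, source = short_kind(fit$spec$kind))
}

#' @export
print.fitted_level0 <- function(x, ...) {
  cat("<fitted_level0> ", x$spec$kind, " (", x$task, "), ",
      length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

# Align newdata columns to the training feature set by name.
align_features <- function(newdata, feature_names) {
  X <- if (inherits(newdata, "descriptor_table")) newdata$X else as.matrix(newdata)
  have <- colnames(X)
  if (is.null(have)) stop_("newdata must have feature names")
  missing <- setdiff(feature_names, have)
  extra <- setdiff(have, feature_names)
  if (length(missing) || length(extra)) {
    stop_("feature mismatch; missing: {",
          paste(missing, collapse = ", "), "}, unexpected: {",
          paste(extra, collapse = ", "), "}")
  }
  X[, feature_names, drop = FALSE]
}

#' Predict from a fitted level-0 ensemble
#'
#' @param object a `fitted_level0`.
#' @param newdata a [descriptor_table] or numeric matrix whose columns match
#'   the training features by name (order-insensitive; any symmetric
#'   difference is an error).
#' @param type `"response"` (continuous value or hard label) or `"prob"`
#'   (positive-class probability, classification only).
#' @param ... unused.
#' @return numeric or character vector of length `nrow(newdata)`.
#' @export
predict.fitted_level0 <- function(object, newdata, type = c("response", "prob"),
                                  ...) {
  type <- match.arg(type)
  if (type == "prob" && object$task != "classification") {
    stop_("type = 'prob' is only available for classification")
  }
  X <- align_features(newdata, object$feature_names)
  if (nrow(X) == 0L) {
    return(if (object$task == "regression" || type == "prob") numeric(0)
           else character(0))
  }
  pos <- object$positive_label
  out <- switch(object$spec$kind,
    bagged_full_trees = {
      if (object$task == "regression") {
        as.numeric(predict(object$learner, X))
      } else {
        pr <- predict(object$learner, X, type = "prob")[, pos]
        if (type == "prob") as.numeric(pr)
        else hard_label(pr, object$classes, pos)
      }
    },
    extremely_randomized_trees = {
      pred <- predict(object$learner, data = as.data.frame(X),
                      num.threads = 1L)$predictions
      if (object$task == "regression") as.numeric(pred)
      else {
        pr <- pred[, pos]
        if (type == "prob") as.numeric(pr)
        else hard_label(pr, object$classes, pos)
      }
    },
    adaptive_boosting = {
      if (object$task == "regression") ada_predict(object$learner, X)
      else {
        pr <- ada_predict(object$learner, X, type = "prob", positive = pos)
        if (type == "prob") pr else hard_label(pr, object$classes, pos)
      }
    },
    gradient_boosting = {
      pr <- predict(object$learner, X)
      if (object$task == "regression") as.numeric(pr)
      else if (type == "prob") as.numeric(pr)
      else hard_label(as.numeric(pr), object$classes, pos)
    }
  )
  unname(out)
}

hard_label <- function(prob_pos, classes, positive) {
  neg <- setdiff(classes, positive)
  ifelse(prob_pos >= 0.5, positive, neg)
}

#' Randomized hyperparameter search with k-fold cross-validation
#'
#' Samples up to `n_iter` candidates from the grid implied by `search_space`
#' and scores each by k-fold cross-validation: mean RMSE for regression
#' (lower is better) or mean accuracy for classification (higher is better;
#' folds are class-stratified). Ties keep the earlier-sampled candidate.
#'
#' @param train a [descriptor_table].
#' @param spec a [level0_spec] providing the kind, task and any fixed
#'   hyperparameters.
#' @param search_space named list: each element a vector (or list, to allow
#'   `NULL`) of candidate values for one hyperparameter.
#' @param n_iter maximum number of candidates to evaluate.
#' @param k number of CV folds (>= 2).
#' @param seed integer seed for candidate sampling and fold assignment.
#' @return the winning [level0_spec]; attribute `cv_results` holds the
#'   per-candidate mean scores.
#' @export
tune_level0 <- function(train, spec, search_space = default_search_space(spec),
                        n_iter = 10L, k = 5L, seed = 0L) {
  if (n_iter <= 0) stop_("n_iter must be positive")
  if (k < 2) stop_("k must be >= 2")
  if (!length(search_space)) stop_("search_space is empty")
  search_space <- lapply(search_space, function(v) if (is.list(v)) v else as.list(v))
  grid <- expand.grid(lapply(search_space, seq_along), KEEP.OUT.ATTRS = FALSE)
  order_idx <- with_seed(seed, sample(nrow(grid), min(n_iter, nrow(grid))))
  n <- n_samples(train)
  folds <- with_seed(seed + 1L, {
    if (train$task == "classification") {
      f <- integer(n)
      for (cl in unique(train$y)) {
        ix <- which(train$y == cl)
        f[ix] <- sample(rep_len(seq_len(k), length(ix)))
      }
      f
    } else {
      sample(rep_len(seq_len(k), n))
    }
  })
  scores <- numeric(length(order_idx))
  labels <- character(length(order_idx))
  for (ci in seq_along(order_idx)) {
    hp <- lapply(seq_along(search_space), function(j) {
      search_space[[j]][[grid[order_idx[ci], j]]]
    })
    names(hp) <- names(search_space)
    labels[ci] <- paste(names(hp), vapply(hp, function(v) {
      if (is.null(v)) "NULL" else format(v)
    }, ""), sep = "=", collapse = ",")
    cand <- level0_spec(spec$kind, spec$task,
                        utils::modifyList(spec$hyperparameters, hp,
                                          keep.null = TRUE),
                        spec$random_state)
    fold_scores <- vapply(seq_len(k), function(fold) {
      tr <- subset_table(train, which(folds != fold))
      te <- subset_table(train, which(folds == fold))
      fit <- fit_level0(tr, cand)
      if (train$task == "regression") {
        rmse(te$y, predict(fit, te))
      } else {
        mean(predict(fit, te) == te$y)
      }
    }, numeric(1))
    scores[ci] <- mean(fold_scores)
  }
  best <- if (train$task == "regression") which.min(scores) else which.max(scores)
  hp <- lapply(seq_along(search_space), function(j) {
    search_space[[j]][[grid[order_idx[best], j]]]
  })
  names(hp) <- names(search_space)
  out <- level0_spec(spec$kind, spec$task,
                     utils::modifyList(spec$hyperparameters, hp,
                                       keep.null = TRUE),
                     spec$random_state)
  attr(out, "cv_results") <- data.frame(candidate = seq_along(scores),
                                        params = labels, score = scores,
                                        stringsAsFactors = FALSE)
  out
}

#' Default randomized-search spaces per learner kind
#'
#' Estimator counts in {50, 100, 200, 500}, depths in {3, 5, 8, unlimited}
#' and, for the boosters, learning rates in {0.01, 0.05, 0.1, 0.2}.
#'
#' @param spec a [level0_spec].
#' @return named list of candidate values, overridable in run configs.
#' @export
default_search_space <- function(spec) {
  sp <- list(n_estimators = list(50L, 100L, 200L, 500L),
             max_depth = list(3L, 5L, 8L, NULL))
  if (spec$kind %in% c("adaptive_boosting", "gradient_boosting")) {
    sp$max_depth <- list(3L, 5L, 8L)
    sp$learning_rate <- list(0.01, 0.05, 0.1, 0.2)
  }
  sp
}
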