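#' Blend configuration
#'
#' Bundles the level-0 specs and combiner settings so a whole blend can be
#' refit under different random states (see [repeated_importance()]).
#'
#' @param specs list of >= 2 [level0_spec]s sharing one task.
#' @param variant `"uniform"`, `"linear"` or `"any"`.
#' @param blend_mode `"holdout"` or `"insample"`.
#' @param holdout_fraction fraction of the training set reserved for the
#'   level-1 fit in holdout mode, in (0, 0.5].
#' @return an object of class `blend_config`.
#' @export
blend_config <- function(specs, variant = c("uniform", "linear", "any"),
                         blend_mode = c("holdout", "insample"),
                         holdout_fraction = 0.2) {
  variant <- match.arg(variant)
  blend_mode <- match.arg(blend_mode)
  if (length(specs) < 2L) stop_("need at least 2 level-0 specs")
  if (!all(vapply(specs, inherits, TRUE, "level0_spec"))) {
    stop_("specs must be level0_spec objects")
  }
  tasks <- unique(vapply(specs, `[[`, "", "task"))
  if (length(tasks) != 1L) stop_("all specs must share one task")
  structure(list(specs = specs, variant = variant, blend_mode = blend_mode,
                 holdout_fraction = holdout_fraction, task = tasks),
            class = "blend_config")
}

#' Default level-0 pool
#'
#' The four-kind pool used throughout: random forest, extremely randomized
#' trees, adaptive boosting and gradient boosting, with each kind's default
#' hyperparameters.
#'
#' @param task `"regression"` or `"classification"`.
#' @param random_state seed applied to every spec.
#' @param n_estimators optional common override of the ensemble size.
#' @return list of four [level0_spec]s.
#' @export
default_level0_specs <- function(task, random_state = 0L, n_estimators = NULL) {
  kinds <- c("bagged_full_trees", "extremely_randomized_trees",
             "adaptive_boosting", "gradient_boosting")
  lapply(kinds, function(k) {
    hp <- if (is.null(n_estimators)) list() else list(n_estimators = n_estimators)
    level0_spec(k, task, hp, random_state)
  })
}

# Level-0 prediction matrix: continuous predictions for regression,
# positive-class probabilities for classification. Columns named m<i>_<kind>.
level0_matrix <- function(models, table) {
  task <- models[[1L]]$task
  Z <- vapply(models, function(m) {
    as.numeric(predict(m, table,
                       type = if (task == "classification") "prob" else "response"))
  }, numeric(n_samples(table)))
  Z <- matrix(Z, nrow = n_samples(table))
  colnames(Z) <- vapply(seq_along(models), function(i) {
    paste0("m", i, "_", short_kind(models[[i]]$spec$kind))
  }, "")
  Z
}

#' Fit a blending ensemble
#'
#' Fits the level-0 models, then combines them with one of three level-1
#' blenders:
#' * `uniform` — no level-1 fit; prediction averaging (regression) or
#'   majority voting (classification) with equal weights `1/n`;
#' * `linear` — multiple linear regression (regression) or logistic
#'   regression (classification) on the level-0 prediction matrix; weights
#'   are the normalized absolute coefficients;
#' * `any` — a small gradient-boosting level-1 model (10 estimators,
#'   learning rate 0.1, depth 8 for regression / 4 for classification);
#'   weights are its impurity importances over the n level-0 inputs.
#'
#' In `holdout` mode (the default) the level-0 models are first fit on the
#' non-holdout part of the training set, the level-1 model is fit on their
#' holdout predictions, and the level-0 models are then refit on all
#' training data — keeping the combiner from rewarding level-0 overfit. In
#' `insample` mode the level-1 model is fit directly on full-training-set
#' predictions.
#'
#' @param train a [descriptor_table].
#' @param specs list of >= 2 [level0_spec]s (paper pool: the four kinds).
#' @param variant,blend_mode,holdout_fraction see [blend_config()].
#' @param seed integer seed for the holdout split and level-1 fit.
#' @param level1_params optional overrides (`n_estimators`, `max_depth`,
#'   `learning_rate`) for the `any` level-1 model.
#' @return an object of class `blender` with fields `variant`, `level0`
#'   (fitted models), `level1`, `weights` (on the simplex), `task`,
#'   `blend_mode`, `holdout_fraction`, `fallback_uniform`.
#' @export
fit_blend <- function(train, specs, variant = c("uniform", "linear", "any"),
                      blend_mode = c("holdout", "insample"),
                      holdout_fraction = 0.2, seed = 0L,
                      level1_params = list()) {
  variant <- match.arg(variant)
  blend_mode <- match.arg(blend_mode)
  cfg <- blend_config(specs, variant, blend_mode, holdout_fraction)
  if (blend_mode == "holdout" &&
      (holdout_fraction <= 0 || holdout_fraction > 0.5)) {
    stop_("holdout_fraction must be in (0, 0.5]")
  }
  task <- cfg$task
  n <- length(specs)
  fallback <- FALSE
  level1 <- NULL
  if (variant == "uniform") {
    level0 <- lapply(specs, function(s) fit_level0(train, s))
    weights <- rep(1 / n, n)
  } else {
    if (blend_mode == "insample") {
      level0 <- lapply(specs, function(s) fit_level0(train, s))
      Z <- level0_matrix(level0, train)
      y1 <- train$y
      pos <- train$positive_label
    } else {
      sp <- split_train_test(train, train_ratio = 1 - holdout_fraction,
                             stratify = if (task == "classification")
                               "by_class" else "none",
                             seed = seed)
      sub_models <- lapply(specs, function(s) fit_level0(sp$train, s))
      Z <- level0_matrix(sub_models, sp$test)
      y1 <- sp$test$y
      pos <- train$positive_label
      level0 <- lapply(specs, function(s) fit_level0(train, s))
    }
    if (all(apply(Z, 2L, stats::var) < 1e-12)) {
      warn_("all level-0 predictions are constant; falling back to uniform")
      fallback <- TRUE
      weights <- rep(1 / n, n)
    } else if (variant == "linear") {
      dfz <- as.data.frame(Z)
      if (task == "regression") {
        dfz$.y <- y1
        level1 <- stats::lm(.y ~ ., data = dfz)
      } else {
        dfz$.y <- as.numeric(y1 == pos)
        level1 <- suppressWarnings(
          stats::glm(.y ~ ., data = dfz, family = stats::binomial()))
      }
      weights <- linear_weights(level1, colnames(Z))
      if (is.null(weights)) {
        warn_("all level-1 coefficients are zero; falling back to uniform weights")
        fallback <- TRUE
        weights <- rep(1 / n, n)
      }
    } else {  # any
      lp <- utils::modifyList(
        list(n_estimators = 10L,
             max_depth = if (task == "regression") 8L else 4L,
             learning_rate = 0.1),
        level1_params)
      dm <- xgboost::xgb.DMatrix(
        Z, label = if (task == "classification") as.numeric(y1 == pos) else y1,
        nthread = 1L)
      level1 <- xgboost::xgb.train(
        params = xgboost::xgb.params(
          max_depth = lp$max_depth, eta = lp$learning_rate, nthread = 1L,
          seed = seed,
          objective = if (task == "classification")
            "binary:logistic" else "reg:squarederror"),
        data = dm, nrounds = lp$n_estimators, verbose = 0)
      imp <- as.data.frame(xgboost::xgb.importance(model = level1))
      w <- stats::setNames(rep(0, n), colnames(Z))
      if (nrow(imp)) w[imp$Feature] <- imp$Gain
      if (sum(w) <= 0) {
        warn_("degenerate level-1 fit (no splits); falling back to uniform weights")
        fallback <- TRUE
        weights <- rep(1 / n, n)
      } else {
        weights <- as.numeric(w / sum(w))
      }
    }
  }
  structure(list(variant = variant, level0 = level0, level1 = level1,
                 weights = weights, task = task, blend_mode = blend_mode,
                 holdout_fraction = holdout_fraction, seed = seed,
                 positive_label = train$positive_label,
                 classes = level0[[1L]]$classes,
                 fallback_uniform = fallback),
            class = "blender")
}

# |coef| / sum|coef| over the n level-0 coefficients, intercept excluded;
# NA coefficients (collinear inputs) count as zero. NULL if all zero.
linear_weights <- function(fit, input_names) {
  cf <- stats::coef(fit)
  cf <- cf[setdiff(names(cf), "(Intercept)")]
  w <- stats::setNames(rep(0, length(input_names)), input_names)
  # lm/glm mangle non-syntactic names; match via make.names
  names(cf) <- input_names[match(names(cf), make.names(input_names))]
  cf[is.na(cf)] <- 0
  w[names(cf)] <- abs(cf)
  if (sum(w) <= 0) return(NULL)
  as.numeric(w / sum(w))
}

#' @export
print.blender <- function(x, ...) {
  cat("<blender> ", x$variant, " (", x$task, ", ", x$blend_mode, "), ",
      length(x$level0), " level-0 models\n  weights: ",
      paste(sprintf("%s=%.3f",
                    vapply(x$level0, function(m) short_kind(m$spec$kind), ""),
                    x$weights), collapse = ", "),
      if (x$fallback_uniform) "  [uniform fallback]", "\n", sep = "")
  invisible(x)
}

#' Extract the blender's weight vector
#'
#' Uniform blends have exact `1/n` weights; linear blends normalize the
#' absolute level-1 coefficients; `any` blends use the level-1 model's
#' impurity importances. Always on the probability simplex.
#'
#' @param blender a fitted `blender`.
#' @return numeric weight vector, named by level-0 model.
#' @export
extract_weights <- function(blender) {
  stopifnot(inherits(blender, "blender"))
  stats::setNames(blender$weights,
                  vapply(seq_along(blender$level0), function(i) {
                    paste0("m", i, "_",
                           short_kind(blender$level0[[i]]$spec$kind))
                  }, ""))
}

#' Predict from a blending ensemble
#'
#' Uniform regression is the arithmetic mean of the level-0 predictions;
#' uniform classification is a majority vote of hard labels with even-vote
#' ties resolved positive when the mean positive-class probability is
#' >= 0.5. Linear and `any` blends apply the level-1 model to the level-0
#' prediction matrix (positive-class probabilities for classification).
#'
#' @param object a fitted `blender`.
#' @param newdata a [descriptor_table] or named numeric matrix.
#' @param type `"response"` or, for classification, `"prob"`.
#' @param ... unused.
#' @return prediction vector.
#' @export
predict.blender <- function(object, newdata, type = c("response", "prob"),
                            ...) {
  type <- match.arg(type)
  task <- object$task
  if (type == "prob" && task != "classification") {
    stop_("type = 'prob' is only available for classification")
  }
  pos <- object$positive_label
  if (task == "regression") {
    Z <- level0_matrix(object$level0, newdata)
    if (object$variant == "uniform" || object$fallback_uniform) {
      return(rowMeans(Z))
    }
    if (object$variant == "linear") {
      return(as.numeric(stats::predict(object$level1,
                                       as.data.frame(Z))))
    }
    return(as.numeric(predict(object$level1, Z)))
  }
  # classification
  Z <- level0_matrix(object$level0, newdata)     # positive-class probs
  if (nrow(Z) == 0L) {
    return(if (type == "prob") numeric(0) else character(0))
  }
  if (object$variant == "uniform" || object$fallback_uniform) {
    votes <- vapply(object$level0, function(m) {
      predict(m, newdata) == pos
    }, logical(n_samples_of(newdata)))
    votes <- matrix(votes, nrow = nrow(Z))
    mean_prob <- rowMeans(Z)
    if (type == "prob") return(mean_prob)
    return(majority_vote(rowSums(votes), ncol(votes), mean_prob,
                         object$classes, pos))
  }
  prob <- if (object$variant == "linear") {
    as.numeric(stats::predict(object$level1, as.data.frame(Z),
                              type = "response"))
  } else {
    as.numeric(predict(object$level1, Z))
  }
  if (type == "prob") prob else hard_label(prob, object$classes, pos)
}

# Simple-voting rule: strict majority wins; an even split falls back to the
# mean positive-class probability (>= 0.5 -> positive).
majority_vote <- function(pos_votes, n_models, mean_prob, classes, positive) {
  is_pos <- ifelse(pos_votes * 2 > n_models, TRUE,
                   ifelse(pos_votes * 2 < n_models, FALSE, mean_prob >= 0.5))
  hard_label(as.numeric(is_pos), classes, positive)
}

n_samples_of <- function(newdata) {
  if (inherits(newdata, "descriptor_table")) n_samples(newdata) else nrow(newdata)
}
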