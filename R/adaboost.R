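# Adaptive boosting over CART weak learners (rpart).
#
# Classification uses the SAMME reweighting scheme (two-class discrete
# AdaBoost); regression uses AdaBoost.R2 with linear loss and a weighted-
# median combination. Sample weights are passed straight to rpart, so a fit
# is deterministic for a given table and depth.

ada_control <- function(max_depth) {
  rpart::rpart.control(maxdepth = max_depth, cp = 0, xval = 0,
                       minsplit = 4, maxcompete = 0, maxsurrogate = 0)
}

ada_fit <- function(X, y, task, n_estimators = 50L, max_depth = 5L,
                    learning_rate = 1) {
  n <- nrow(X)
  df <- as.data.frame(X)
  names(df) <- paste0("V", seq_len(ncol(X)))   # rpart-safe names
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  ctl <- ada_control(max_depth)
  if (task == "classification") {
    yf <- factor(y)
    df$.y <- yf
    for (m in seq_len(n_estimators)) {
      fit <- rpart::rpart(.y ~ ., data = df, weights = w * n, method = "class",
                          control = ctl)
      pred <- predict(fit, df, type = "class")
      miss <- as.numeric(pred != yf)
      err <- sum(w * miss)
      if (err <= 0) {             # perfect weak learner dominates the vote
        trees[[length(trees) + 1L]] <- fit
        alphas <- c(alphas, 10)
        break
      }
      if (err >= 0.5) {           # no better than chance: stop boosting
        if (!length(trees)) { trees[[1L]] <- fit; alphas <- 1e-10 }
        break
      }
      alpha <- learning_rate * log((1 - err) / err)
      trees[[length(trees) + 1L]] <- fit
      alphas <- c(alphas, alpha)
      w <- w * exp(alpha * miss)
      w <- w / sum(w)
    }
    classes <- levels(yf)
  } else {
    df$.y <- y
    for (m in seq_len(n_estimators)) {
      fit <- rpart::rpart(.y ~ ., data = df, weights = w * n, method = "anova",
                          control = ctl)
      pred <- predict(fit, df)
      abs_err <- abs(pred - y)
      emax <- max(abs_err)
      if (emax <= 0) {
        trees[[length(trees) + 1L]] <- fit
        alphas <- c(alphas, 10)
        break
      }
      loss <- abs_err / emax
      ebar <- sum(w * loss)
      if (ebar >= 0.5) {
        if (!length(trees)) { trees[[1L]] <- fit; alphas <- 1e-10 }
        break
      }
      beta <- ebar / (1 - ebar)
      alpha <- learning_rate * log(1 / beta)
      trees[[length(trees) + 1L]] <- fit
      alphas <- c(alphas, alpha)
      w <- w * beta^((1 - loss) * learning_rate)
      w <- w / sum(w)
    }
    classes <- NULL
  }
  list(trees = trees, alphas = alphas, task = task, classes = classes,
       var_names = names(df)[seq_len(ncol(X))], orig_names = colnames(X))
}

weighted_median <- function(values, weights) {
  o <- order(values)
  cw <- cumsum(weights[o]) / sum(weights)
  values[o][which(cw >= 0.5)[1L]]
}

# type = "response" (regression value / hard label) or "prob"
# (positive-vote fraction, classification only; `positive` names the class).
ada_predict <- function(model, X, type = "response", positive = NULL) {
  df <- as.data.frame(X)
  names(df) <- model$var_names
  k <- length(model$trees)
  if (model$task == "regression") {
    P <- vapply(model$trees, function(tr) predict(tr, df), numeric(nrow(df)))
    P <- matrix(P, nrow = nrow(df))
    return(apply(P, 1L, function(row) weighted_median(row, model$alphas)))
  }
  votes <- matrix(0, nrow(df), 1L)
  total <- sum(model$alphas)
  pos_score <- rep(0, nrow(df))
  for (m in seq_len(k)) {
    lab <- as.character(predict(model$trees[[m]], df, type = "class"))
    pos_score <- pos_score + model$alphas[m] * (lab == positive)
  }
  prob <- pos_score / total
  if (type == "prob") return(prob)
  neg <- setdiff(model$classes, positive)
  ifelse(prob >= 0.5, positive, neg)
}

# Impurity importance: per-tree rpart importances (normalized to sum 1)
# combined with the estimator weights, mapped back to the full feature set.
ada_importance <- function(model) {
  p <- length(model$var_names)
  agg <- stats::setNames(rep(0, p), model$var_names)
  total <- sum(model$alphas)
  for (m in seq_along(model$trees)) {
    vi <- model$trees[[m]]$variable.importance
    if (is.null(vi) || !length(vi) || sum(vi) <= 0) next
    vi <- vi / sum(vi)
    agg[names(vi)] <- agg[names(vi)] + model$alphas[m] / total * vi
  }
  stats::setNames(as.numeric(agg), model$orig_names)
}
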