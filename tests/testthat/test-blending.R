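test_that("uniform blending has exact equal weights and no level-1 model", {
  gen <- tiny_regression()
  bl <- fit_blend(gen$table, fast_specs("regression"), variant = "uniform")
  expect_identical(bl$weights, rep(0.25, 4))
  expect_null(bl$level1)
  expect_equal(unname(extract_weights(bl)), rep(0.25, 4))
})

test_that("uniform regression predictions equal the level-0 mean exactly", {
  gen <- tiny_regression()
  sp <- split_train_test(gen$table, 0.75, seed = 1)
  specs <- fast_specs("regression")
  bl <- fit_blend(sp$train, specs, variant = "uniform")
  per_model <- sapply(bl$level0, function(m) predict(m, sp$test))
  expect_equal(predict(bl, sp$test), rowMeans(per_model), tolerance = 1e-15)
})

test_that("majority voting follows the stated tie rules", {
  vote <- qsprblend:::majority_vote
  classes <- c("neg", "pos")
  expect_equal(vote(4, 4, 0.9, classes, "pos"), "pos")   # unanimous
  expect_equal(vote(0, 4, 0.1, classes, "pos"), "neg")
  expect_equal(vote(3, 4, 0.2, classes, "pos"), "pos")   # majority beats prob
  expect_equal(vote(2, 4, 0.6, classes, "pos"), "pos")   # 2-2 tie, prob 0.6
  expect_equal(vote(2, 4, 0.4, classes, "pos"), "neg")   # 2-2 tie, prob 0.4
  expect_equal(vote(2, 4, 0.5, classes, "pos"), "pos")   # boundary -> positive
})

test_that("uniform classification agrees with recomputed votes", {
  gen <- tiny_classification()
  sp <- split_train_test(gen$table, 0.75, seed = 2)
  bl <- fit_blend(sp$train, fast_specs("classification"), variant = "uniform")
  labs <- sapply(bl$level0, function(m) predict(m, sp$test))
  probs <- sapply(bl$level0, function(m) predict(m, sp$test, type = "prob"))
  expected <- qsprblend:::majority_vote(rowSums(labs == "pos"), 4,
                                        rowMeans(probs), c("neg", "pos"),
                                        "pos")
  expect_identical(predict(bl, sp$test), expected)
  expect_equal(predict(bl, sp$test, type = "prob"), rowMeans(probs))
})

test_that("linear-blend weights are normalized absolute coefficients", {
  fake_fit <- list(coefficients = c("(Intercept)" = 3, m1_rf = 1,
                                    m2_extratrees = -2, m3_adaboost = 1))
  w <- qsprblend:::linear_weights(fake_fit,
                                  c("m1_rf", "m2_extratrees", "m3_adaboost"))
  expect_equal(w, c(0.25, 0.50, 0.25))
  # collinearity: NA coefficients count as zero
  fake_na <- list(coefficients = c("(Intercept)" = 1, m1_rf = 2,
                                   m2_extratrees = NA))
  expect_equal(qsprblend:::linear_weights(fake_na, c("m1_rf", "m2_extratrees")),
               c(1, 0))
  all_zero <- list(coefficients = c("(Intercept)" = 1, m1_rf = 0))
  expect_null(qsprblend:::linear_weights(all_zero, "m1_rf"))
})

test_that("duplicated level-0 models collapse onto one linear weight", {
  gen <- tiny_regression()
  spec <- level0_spec("rf", "regression", list(n_estimators = 20L), 5)
  bl <- fit_blend(gen$table, list(spec, spec), variant = "linear",
                  blend_mode = "insample")
  # identical predictions are collinear: all weight lands on the first copy
  expect_equal(bl$weights, c(1, 0))
  expect_simplex(bl$weights)
})

test_that("weight vectors lie on the simplex for every variant and task", {
  for (task in c("regression", "classification")) {
    gen <- if (task == "regression") tiny_regression() else tiny_classification()
    for (v in c("uniform", "linear", "any")) {
      bl <- fit_blend(gen$table, fast_specs(task), variant = v, seed = 4)
      expect_simplex(bl$weights)
    }
  }
})

test_that("blend refits with the same seed give identical weights", {
  gen <- tiny_regression()
  specs <- fast_specs("regression")
  w1 <- fit_blend(gen$table, specs, variant = "any", seed = 11)$weights
  w2 <- fit_blend(gen$table, specs, variant = "any", seed = 11)$weights
  expect_identical(w1, w2)
})

test_that("uniform-blend RMSE never exceeds the worst level-0 RMSE", {
  gen <- tiny_regression(n = 150, p = 6, seed = 3)
  specs <- fast_specs("regression")
  bl <- fit_blend(gen$table, specs, variant = "uniform")
  worst_margin <- -Inf
  for (trial in 1:100) {
    ev <- generate_regression(synthetic_spec(
      n_samples = 40, n_features = 6, n_informative = 3,
      effect_sizes = seq(2, 1, length.out = 3), noise_sd = 0.5,
      seed = 5000 + trial))
    level0_rmse <- vapply(bl$level0, function(m) {
      rmse(ev$table$y, predict(m, ev$table))
    }, numeric(1))
    blend_rmse <- rmse(ev$table$y, predict(bl, ev$table))
    worst_margin <- max(worst_margin, blend_rmse - max(level0_rmse))
  }
  expect_lte(worst_margin, 1e-10)
})

test_that("an insample level-1 of sufficient capacity beats the best level-0 on train", {
  gen <- tiny_regression(n = 100, p = 5, noise_sd = 0.5)
  specs <- fast_specs("regression")
  bl <- fit_blend(gen$table, specs, variant = "any", blend_mode = "insample",
                  level1_params = list(n_estimators = 300L,
                                       learning_rate = 0.3))
  best_level0 <- min(vapply(bl$level0, function(m) {
    rmse(gen$table$y, predict(m, gen$table))
  }, numeric(1)))
  expect_lte(rmse(gen$table$y, predict(bl, gen$table)), best_level0)
})

test_that("holdout and insample modes both produce working blenders", {
  gen <- tiny_classification(n = 140, p = 5)
  specs <- fast_specs("classification")
  for (mode in c("holdout", "insample")) {
    bl <- fit_blend(gen$table, specs, variant = "linear", blend_mode = mode,
                    seed = 6)
    expect_true(all(predict(bl, gen$table) %in% c("pos", "neg")))
    pr <- predict(bl, gen$table, type = "prob")
    expect_true(all(pr >= 0 & pr <= 1))
  }
})

test_that("blend configuration is validated", {
  gen <- tiny_regression()
  specs <- fast_specs("regression")
  expect_error(fit_blend(gen$table, specs[1], variant = "uniform"),
               "at least 2")
  expect_error(fit_blend(gen$table, specs, variant = "any",
                         blend_mode = "holdout", holdout_fraction = 0.9),
               "holdout_fraction")
  mixed <- c(specs[1:2], list(level0_spec("rf", "classification")))
  expect_error(fit_blend(gen$table, mixed, variant = "uniform"),
               "share one task")
})
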