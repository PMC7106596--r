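write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("a minimal well-formed file loads with the right shape", {
  path <- write_fixture_csv(data.frame(id = c("s1", "s2"),
                                       d1 = c(0.1, 0.2), d2 = c(1, 2),
                                       y = c(3.5, 4.5)))
  tab <- read_table(path, target_column = "y", task = "regression")
  expect_s3_class(tab, "descriptor_table")
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(tab$feature_names, c("d1", "d2"))
  expect_equal(tab$y, c(3.5, 4.5))
})

test_that("read/write round trip reproduces X, y and feature names exactly", {
  gen <- tiny_regression(n = 30, p = 5)
  p1 <- tempfile(fileext = ".csv")
  write_table(gen$table, p1)
  back <- read_table(p1, target_column = "target", task = "regression")
  expect_equal(back$X, gen$table$X)
  expect_equal(back$y, gen$table$y)
  expect_equal(back$feature_names, gen$table$feature_names)
  expect_equal(back$sample_ids, gen$table$sample_ids)
})

test_that("loader errors name the offending column or ids", {
  path <- write_fixture_csv(data.frame(id = c("a", "b"), d1 = 1:2, y = 1:2))
  expect_error(read_table(path, target_column = "missing_y",
                          task = "regression"), "missing_y")
  path2 <- write_fixture_csv(data.frame(id = c("a", "b"),
                                        d1 = c("low", "high"), y = 1:2))
  expect_error(read_table(path2, target_column = "y", task = "regression"),
               "'d1'")
  path3 <- write_fixture_csv(data.frame(id = c("a", "a"), d1 = 1:2, y = 1:2))
  expect_error(read_table(path3, target_column = "y", task = "regression"),
               "duplicate")
})

test_that("missing values are rejected by default and droppable by policy", {
  df <- data.frame(id = c("a", "b", "c"), d1 = c(1, NA, 3), y = 1:3)
  path <- write_fixture_csv(df)
  expect_error(read_table(path, target_column = "y", task = "regression"),
               "missing values")
  expect_message(
    tab <- read_table(path, target_column = "y", task = "regression",
                      na_action = "drop_rows"),
    "dropped 1")
  expect_equal(n_samples(tab), 2L)
})

test_that("declared categorical columns are integer-encoded with a code map", {
  df <- data.frame(id = c("a", "b", "c"), d1 = c(1, 2, 3),
                   Solvent = c("water", "ethanol", "water"), y = c(1, 2, 3))
  path <- write_fixture_csv(df)
  tab <- read_table(path, target_column = "y", task = "regression",
                    categorical_columns = "Solvent")
  cm <- attr(tab, "code_maps")$Solvent
  expect_equal(names(cm), c("ethanol", "water"))
  expect_equal(unname(tab$X[, "Solvent"]), unname(cm[df$Solvent]))
})

test_that("classification targets must be binary with a valid positive label", {
  X <- matrix(rnorm(12), 6, dimnames = list(NULL, c("d1", "d2")))
  expect_error(descriptor_table(X, rep("LC", 6), task = "classification"),
               "exactly two")
  tab <- descriptor_table(X, rep(c("LC", "NLC"), 3), task = "classification")
  expect_equal(tab$positive_label, "LC")  # alphabetical default
  expect_error(descriptor_table(X, rep(c("LC", "NLC"), 3),
                                task = "classification",
                                positive_label = "XX"), "positive_label")
})

test_that("splitting reproduces the printed partition sizes", {
  # 3786 rod-like compounds at ratio 3:1 -> 2839 train / 947 test
  big <- descriptor_table(matrix(rnorm(3786 * 2), 3786,
                                 dimnames = list(NULL, c("d1", "d2"))),
                          rnorm(3786))
  sp <- split_train_test(big, train_ratio = 0.75, seed = 0)
  expect_equal(n_samples(sp$train), 2839L)
  expect_equal(n_samples(sp$test), 947L)
  # exact division
  small <- descriptor_table(matrix(rnorm(8), 4,
                                   dimnames = list(NULL, c("d1", "d2"))),
                            rnorm(4))
  sps <- split_train_test(small, 0.75, seed = 1)
  expect_equal(n_samples(sps$train), 3L)
  expect_equal(n_samples(sps$test), 1L)
})

test_that("splits are deterministic, disjoint and exhaustive", {
  gen <- tiny_regression(n = 57, p = 3)
  s1 <- split_train_test(gen$table, 0.7, seed = 9)
  s2 <- split_train_test(gen$table, 0.7, seed = 9)
  expect_identical(s1$assignment, s2$assignment)
  ids <- c(s1$train$sample_ids, s1$test$sample_ids)
  expect_setequal(ids, gen$table$sample_ids)
  expect_length(intersect(s1$train$sample_ids, s1$test$sample_ids), 0)
  s3 <- split_train_test(gen$table, 0.7, seed = 10)
  expect_false(identical(s1$assignment, s3$assignment))
})

test_that("group stratification applies the ratio within each group", {
  X <- matrix(rnorm(40), 20, dimnames = list(NULL, c("d1", "d2")))
  tab <- descriptor_table(X, rnorm(20), group = rep(c("g1", "g2"), each = 10))
  sp <- split_train_test(tab, 0.8, stratify = "by_group", seed = 3)
  for (g in c("g1", "g2")) {
    expect_equal(sum(sp$train$group == g), 8L)
    expect_equal(sum(sp$test$group == g), 2L)
  }
})

test_that("undersized strata go to train with a warning", {
  X <- matrix(rnorm(22), 11, dimnames = list(NULL, c("d1", "d2")))
  tab <- descriptor_table(X, rnorm(11),
                          group = c(rep("big", 10), "lonely"))
  expect_warning(sp <- split_train_test(tab, 0.75, stratify = "by_group",
                                        seed = 1),
                 "lonely")
  expect_true("11" %in% sp$train$sample_ids)  # the lonely sample trains
})

test_that("split manifests round-trip through CSV", {
  gen <- tiny_regression(n = 20, p = 3)
  sp <- split_train_test(gen$table, 0.75, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_split_manifest(sp, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(names(back), c("sample_id", "partition"))
  expect_equal(sum(back$partition == "train"), n_samples(sp$train))
})

test_that("invalid train ratios are rejected", {
  gen <- tiny_regression(n = 10, p = 3)
  expect_error(split_train_test(gen$table, 0), "train_ratio")
  expect_error(split_train_test(gen$table, 1), "train_ratio")
})
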