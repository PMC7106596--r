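# Small, fast fixtures shared across test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

tiny_regression <- function(n = 120, p = 8, seed = 1, noise_sd = 0.5) {
  generate_regression(synthetic_spec(
    n_samples = n, n_features = p, n_informative = min(3L, p),
    effect_sizes = seq(2, 1, length.out = min(3L, p)),
    nonlinearity = "interactions", noise_sd = noise_sd, seed = seed))
}

tiny_classification <- function(n = 160, p = 8, seed = 1) {
  generate_classification(synthetic_spec(
    n_samples = n, n_features = p, n_informative = min(3L, p),
    effect_sizes = seq(2, 1, length.out = min(3L, p)),
    noise_sd = 0.5, positive_fraction = 0.73, seed = seed))
}

# Cheap level-0 pool for structural tests (small ensembles).
fast_specs <- function(task, random_state = 0L) {
  list(
    level0_spec("bagged_full_trees", task, list(n_estimators = 25L), random_state),
    level0_spec("extremely_randomized_trees", task, list(n_estimators = 25L), random_state),
    level0_spec("adaptive_boosting", task, list(n_estimators = 10L), random_state),
    level0_spec("gradient_boosting", task, list(n_estimators = 25L), random_state)
  )
}

all_kinds <- c("bagged_full_trees", "extremely_randomized_trees",
               "adaptive_boosting", "gradient_boosting")

expect_simplex <- function(w, tol = 1e-9) {
  expect_true(all(w >= -tol))
  expect_equal(sum(w), 1, tolerance = tol)
}
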