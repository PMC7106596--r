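#' Synthetic descriptor-table specification
#'
#' Emulates the shape of real QSPR descriptor tables — a wide numeric
#' feature matrix (hundreds of descriptors, a few hundred samples) in which
#' only a small planted subset carries signal — with known ground truth, so
#' the modeling and importance machinery can be benchmarked without any
#' external data. Defaults: 400 samples x 100 descriptors with 5 informative
#' features, effect sizes decreasing from 1.5 to 0.75, a pairwise
#' interaction between the first two informative features, unit additive
#' noise (signal-to-noise comparable to the R^2 ~ 0.9 regime typical of
#' well-behaved QSPR regressions) and, for classification, a 73/27 class
#' imbalance mirroring a 2780/3786 positive prevalence.
#'
#' @param n_samples,n_features table dimensions.
#' @param n_informative number of signal-carrying features (the first
#'   `n_informative` columns).
#' @param effect_sizes coefficients of the informative features; default
#'   `seq(1.5, 0.75, length.out = n_informative)`.
#' @param nonlinearity `"interactions"` (default; adds the product of the
#'   first two informative features, coefficient = mean of their effects) or
#'   `"none"`.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param positive_fraction positive-class prevalence for classification.
#' @param seed integer seed; generation is fully reproducible.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 400L, n_features = 100L,
                           n_informative = 5L, effect_sizes = NULL,
                           nonlinearity = c("interactions", "none"),
                           noise_sd = 1, positive_fraction = 0.73,
                           seed = 0L) {
  nonlinearity <- match.arg(nonlinearity)
  if (n_informative > n_features) stop_("n_informative > n_features")
  if (n_informative < 1) stop_("need at least one informative feature")
  if (noise_sd < 0) stop_("noise_sd must be >= 0")
  if (!(positive_fraction > 0 && positive_fraction < 1)) {
    stop_("positive_fraction must be in (0, 1)")
  }
  effect_sizes <- effect_sizes %||%
    seq(1.5, 0.75, length.out = n_informative)
  if (length(effect_sizes) != n_informative) {
    stop_("effect_sizes must have length n_informative")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_sizes = as.numeric(effect_sizes),
                 nonlinearity = nonlinearity, noise_sd = noise_sd,
                 positive_fraction = positive_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Shared latent-score machinery: standard-normal features, linear signal
# over the planted set, optional interaction, additive noise.
synth_latent <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_samples; p <- spec$n_features
    X <- matrix(stats::rnorm(n * p), n, p)
    colnames(X) <- sprintf("f%03d", seq_len(p))
    idx <- seq_len(spec$n_informative)
    signal <- as.numeric(X[, idx, drop = FALSE] %*% spec$effect_sizes)
    if (spec$nonlinearity == "interactions" && spec$n_informative >= 2L) {
      signal <- signal + mean(spec$effect_sizes[1:2]) * X[, 1L] * X[, 2L]
    }
    noise <- if (spec$noise_sd > 0) stats::rnorm(n, sd = spec$noise_sd) else 0
    list(X = X, score = signal + noise, informative = idx)
  })
}

#' Generate a synthetic regression table
#'
#' `y = sum_j beta_j x_j (+ interaction) + N(0, noise_sd)` with independent
#' standard-normal descriptors.
#'
#' @param spec a [synthetic_spec].
#' @return list with `table` (a [descriptor_table]), `informative` (indices
#'   of the planted features) and `effect_sizes`.
#' @export
generate_regression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lat <- synth_latent(spec)
  list(table = descriptor_table(lat$X, lat$score, task = "regression"),
       informative = lat$informative, effect_sizes = spec$effect_sizes)
}

#' Generate a synthetic classification table
#'
#' The latent score of [generate_regression()] is thresholded at its
#' `1 - positive_fraction` quantile: exactly
#' `round(positive_fraction * n_samples)` samples (the top of the noisy
#' score) are labeled `"pos"`, the rest `"neg"`. Quantile thresholding fixes
#' the class balance exactly, which keeps imbalance-sensitive metric tests
#' deterministic.
#'
#' @param spec a [synthetic_spec].
#' @return list with `table` (classification [descriptor_table], positive
#'   label `"pos"`), `informative` and `effect_sizes`.
#' @export
generate_classification <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lat <- synth_latent(spec)
  n_pos <- round(spec$positive_fraction * spec$n_samples)
  o <- order(lat$score, decreasing = TRUE)
  y <- rep("neg", spec$n_samples)
  y[o[seq_len(n_pos)]] <- "pos"
  list(table = descriptor_table(lat$X, y, task = "classification",
                                positive_label = "pos"),
       informative = lat$informative, effect_sizes = spec$effect_sizes)
}

#' Write a synthetic dataset with its ground-truth sidecar
#'
#' Emits the CSV dialect consumed by [read_table()] plus a JSON sidecar
#' recording the planted informative indices, effect sizes and seed.
#'
#' @param gen result of [generate_regression()] or
#'   [generate_classification()].
#' @param path CSV output path; the sidecar is written to
#'   `paste0(path, ".truth.json")`.
#' @param spec the [synthetic_spec] used (for the sidecar).
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(gen, path, spec) {
  write_table(gen$table, path)
  sidecar <- list(informative = gen$informative,
                  effect_sizes = gen$effect_sizes,
                  feature_names = gen$table$feature_names[gen$informative],
                  seed = spec$seed, nonlinearity = spec$nonlinearity,
                  noise_sd = spec$noise_sd)
  jsonlite::write_json(sidecar, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
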