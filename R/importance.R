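#' Feature-importance profile
#'
#' A named, nonnegative per-feature score vector on the probability simplex
#' (scores sum to 1), with a provenance tag. All importances in the package
#' — per-learner mean-decrease-in-impurity vectors and blended aggregates —
#' are carried in this form, so rankings from different sources are directly
#' comparable.
#'
#' @param scores nonnegative numeric vector, named or paired with
#'   `feature_names`. Renormalized onto the simplex only when the sum drifts
#'   from 1 by more than 1e-9.
#' @param feature_names optional names (defaults to `names(scores)`).
#' @param source provenance tag, e.g. `"rf"` or `"uniform_blend"`.
#' @param n_repeats number of random states averaged into the profile.
#' @return an object of class `importance_profile`.
#' @export
importance_profile <- function(scores, feature_names = names(scores),
                               source = "unknown", n_repeats = 1L) {
  force(feature_names)
  scores <- as.numeric(scores)
  if (is.null(feature_names)) stop_("feature names are required")
  if (length(scores) != length(feature_names)) {
    stop_("scores and feature_names differ in length")
  }
  if (any(scores < 0)) stop_("importance scores must be nonnegative")
  s <- sum(scores)
  if (s <= 0) {
    scores <- rep(1 / length(scores), length(scores))
  } else if (abs(s - 1) > 1e-9) {
    scores <- scores / s
  }
  structure(list(feature_names = as.character(feature_names),
                 scores = stats::setNames(scores, feature_names),
                 source = source, n_repeats = as.integer(n_repeats)),
            class = "importance_profile")
}

#' @export
print.importance_profile <- function(x, ...) {
  cat("<importance_profile> ", length(x$scores), " features, source: ",
      x$source, ", repeats: ", x$n_repeats, "\n", sep = "")
  print(utils::head(rank_features(x, min(5L, length(x$scores))), 5L))
  invisible(x)
}

#' Aggregate importances across level-0 models (FI_blend)
#'
#' The blended importance is the convex combination of the level-0
#' importance vectors under the blender's weight vector:
#' `FI_blend = sum_i w_i * FI_i`. Since each profile sums to 1 and the
#' weights sum to 1, the result is already on the simplex; it is only
#' renormalized when floating-point drift exceeds 1e-9.
#'
#' @param profiles list of [importance_profile]s sharing one feature set
#'   (aligned by name).
#' @param weights nonnegative weights summing to 1, one per profile.
#' @param source provenance tag for the result.
#' @return an [importance_profile].
#' @export
blend_importance <- function(profiles, weights, source = "blend") {
  if (!length(profiles)) stop_("no profiles given")
  if (length(weights) != length(profiles)) {
    stop_("need one weight per profile")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6) {
    stop_("weights must be nonnegative and sum to 1")
  }
  fn <- profiles[[1L]]$feature_names
  acc <- stats::setNames(rep(0, length(fn)), fn)
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    if (!setequal(p$feature_names, fn)) {
      stop_("profile ", i, " has a different feature set")
    }
    acc <- acc + weights[i] * p$scores[fn]
  }
  importance_profile(acc, fn, source = source,
                     n_repeats = max(vapply(profiles, `[[`, 1L, "n_repeats")))
}

#' Blended importance of a fitted blender
#'
#' @param blender a fitted `blender` (see [fit_blend()]).
#' @return the weighted-sum [importance_profile] over its level-0 models.
#' @export
feature_importance <- function(blender) {
  stopifnot(inherits(blender, "blender"))
  blend_importance(lapply(blender$level0, `[[`, "importance"),
                   blender$weights,
                   source = paste0(blender$variant, "_blend"))
}

#' Seed-averaged importance
#'
#' Random state influences impurity importance, so profiles are averaged
#' over repeated fits with different random states (default ten runs, seeds
#' 0-9). Accepts either a [level0_spec] (each repeat refits that learner
#' with `random_state` set to the seed) or a [blend_config] (each repeat
#' refits the whole blend, every level-0 seed and the blend seed set to the
#' repeat seed, and aggregates with [blend_importance()]).
#'
#' @param train a [descriptor_table].
#' @param spec a [level0_spec] or [blend_config].
#' @param seeds nonempty integer vector of random states.
#' @return the elementwise-mean [importance_profile] with `n_repeats` set.
#' @export
repeated_importance <- function(train, spec, seeds = 0:9) {
  if (!length(seeds)) stop_("seeds must be nonempty")
  profiles <- lapply(seeds, function(s) {
    prof <- tryCatch({
      if (inherits(spec, "level0_spec")) {
        sp <- spec
        sp$random_state <- as.integer(s)
        fit_level0(train, sp)$importance
      } else if (inherits(spec, "blend_config")) {
        specs <- lapply(spec$specs, function(x) {
          x$random_state <- as.integer(s)
          x
        })
        bl <- fit_blend(train, specs, variant = spec$variant,
                        blend_mode = spec$blend_mode,
                        holdout_fraction = spec$holdout_fraction,
                        seed = as.integer(s))
        feature_importance(bl)
      } else {
        stop_("spec must be a level0_spec or blend_config")
      }
    }, error = function(e) {
      stop_("importance fit failed for seed ", s, ": ", conditionMessage(e))
    })
    prof
  })
  mean_scores <- Reduce(`+`, lapply(profiles, function(p) {
    p$scores[profiles[[1L]]$feature_names]
  })) / length(profiles)
  importance_profile(mean_scores, profiles[[1L]]$feature_names,
                     source = profiles[[1L]]$source,
                     n_repeats = length(seeds))
}

#' Rank features by importance
#'
#' Descending by score; ties broken by ascending feature name so rankings
#' are deterministic and reproducible.
#'
#' @param profile an [importance_profile].
#' @param top_k number of features to report, `1 <= top_k <= n_features`.
#' @return data frame with columns `rank`, `feature`, `score`, `source`,
#'   `n_repeats`.
#' @export
rank_features <- function(profile, top_k = length(profile$scores)) {
  p <- length(profile$scores)
  if (top_k < 1 || top_k > p) {
    stop_("top_k must be between 1 and ", p)
  }
  o <- order(-profile$scores, profile$feature_names)
  o <- o[seq_len(top_k)]
  data.frame(rank = seq_len(top_k),
             feature = profile$feature_names[o],
             score = as.numeric(profile$scores[o]),
             source = profile$source,
             n_repeats = profile$n_repeats,
             stringsAsFactors = FALSE)
}

#' Export a ranking as TSV
#'
#' @param profile an [importance_profile].
#' @param path output path.
#' @param top_k rows to write.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(profile, path, top_k = min(10L, length(profile$scores))) {
  utils::write.table(rank_features(profile, top_k), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Horizontal bar chart of the top-k features
#'
#' @param profile an [importance_profile].
#' @param top_k bars to draw.
#' @param main plot title.
#' @return the ranking data frame, invisibly.
#' @export
plot_importance <- function(profile, top_k = min(10L, length(profile$scores)),
                            main = paste("Top", top_k, "descriptors -",
                                         profile$source)) {
  rk <- rank_features(profile, top_k)
  graphics::barplot(rev(rk$score), names.arg = rev(rk$feature), horiz = TRUE,
                    las = 1, main = main, xlab = "feature importance")
  invisible(rk)
}
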