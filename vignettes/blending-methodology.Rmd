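---
title: "Blending tree ensembles for interpretable QSPR models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blending tree ensembles for interpretable QSPR models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsprblend)
```

## The problem

Quantitative structure–property relationship (QSPR) models map numeric
molecular descriptors — atom counts, topological indices, quantum-chemical
quantities such as the HOMO–LUMO gap — to a measured property: a
fluorescence emission wavelength (regression) or the presence of
liquid-crystal behaviour (binary classification). Decision-tree ensembles
are the workhorse learners for such tables because they need no feature
scaling, handle thousands of correlated descriptors, and expose an
impurity-based feature importance that chemists can read as a descriptor
ranking.

The difficulty is that different ensemble strategies disagree. Bagging
methods (random forest, extremely randomized trees) and boosting methods
(AdaBoost, gradient boosting) fit the same data comparably well yet
distribute importance over different descriptors, so any single model gives
a one-sided interpretation. `qsprblend` addresses this by *blending*: the
four ensembles become level-0 models, a simple level-1 combiner merges
their predictions, and the per-model importance vectors are merged with the
same weights, giving one consensus ranking.

## The blending model

Let $\hat y^{(1)}, \dots, \hat y^{(n)}$ be the level-0 predictions
($n = 4$ here). Three combiners are provided:

* **uniform** — no meta-learning: the prediction is the arithmetic mean
  (regression) or a simple majority vote of hard labels (classification);
  weights $w_i = 1/n$ exactly.
* **linear** — multiple linear regression, or logistic regression for
  classification, fitted on the level-0 prediction matrix;
  $w_i = |\beta_i| / \sum_j |\beta_j|$ with the intercept excluded.
* **any** — a deliberately small gradient-boosting machine (10 estimators,
  learning rate 0.1, tree depth 8 for regression and 4 for classification)
  fitted on the same matrix; $w_i$ is its impurity importance over the $n$
  inputs. The small capacity matters: the level-1 model should only learn
  how to weigh four already-strong predictors, not re-model the data.

The blended feature importance is the convex combination

$$FI_{\mathrm{blend}} = \sum_{i=1}^{n} w_i \, FI_i,$$

where each $FI_i$ is the level-0 model's mean-decrease-in-impurity vector
normalized to sum to 1. Because the weights and the $FI_i$ each lie on the
probability simplex, so does $FI_{\mathrm{blend}}$ — the package
renormalizes only when floating-point drift exceeds $10^{-9}$.

### Level-1 fitting modes

The classical description of blending feeds the training data through the
level-0 models and trains the combiner on those in-sample predictions.
With heavily overfit level-0 models (full-grown bagged trees reach near-zero
training error) this rewards memorization, so the package defaults to a
*holdout* mode: the level-0 models are first fitted on 80% of the training
set, the combiner is fitted on their predictions for the held-out 20%, and
the level-0 models are then refitted on all training data. `insample` mode
is retained as an option because it reproduces the classical flow and its
near-perfect training fits; which mode produced any particular published
table is generally not knowable, and neither is claimed to replicate such
tables exactly.

Degenerate combiner fits are handled conservatively: if every level-0
prediction is constant, or the linear coefficients are all zero, or the
level-1 GBM makes no splits, the blender warns and falls back to uniform
weights.

### Voting ties

With four voters a 2–2 classification tie is possible. Ties break by the
mean positive-class probability (positive when $\ge 0.5$). This rule is a
package choice — simple voting schemes rarely specify the even-split case —
and it is deterministic, which the test suite requires.

### A note on collinear level-0 models

If two level-0 models produce identical predictions, the linear combiner's
design matrix is singular; the fit drops the duplicated column (its
coefficient is `NA`, treated as weight 0) and the entire weight lands on
the first copy. The combined prediction is then the fitted linear transform
of that model's prediction — not necessarily the model's prediction itself,
since an unconstrained linear blender has an intercept and slope. Only the
uniform combiner guarantees that identical level-0 models reproduce their
common prediction exactly.

## Level-0 learners

The four kinds are consumed behind one contract
(`level0_spec()` / `fit_level0()` / `predict()`), so blenders never see
backend details:

| kind | backend | importance |
|------|---------|------------|
| `bagged_full_trees` | `randomForest` | increase in node purity |
| `extremely_randomized_trees` | `ranger` (`splitrule = "extratrees"`, no bootstrap, full sample) | impurity |
| `adaptive_boosting` | in-package SAMME / AdaBoost.R2 over `rpart` trees | weighted per-tree impurity importances |
| `gradient_boosting` | `xgboost` | gain |

The AdaBoost loop is implemented in the package on top of `rpart` weak
learners: SAMME reweighting for two-class problems and AdaBoost.R2 with
linear loss and a weighted-median combination for regression. Weak-learner
depth defaults to 5; sample weights are passed directly to `rpart`, which
makes an AdaBoost fit fully deterministic. Importance is the
estimator-weight-weighted sum of per-tree normalized impurity importances.

Hyperparameter defaults follow common practice (100 trees for the forests
and GBM, 50 boosting rounds, learning rate 0.1 for GBM); `tune_level0()`
performs the randomized search with five-fold cross-validation — RMSE for
regression, accuracy with class-stratified folds for classification — over
a default grid of estimator counts {50, 100, 200, 500}, depths
{3, 5, 8, unlimited} and learning rates {0.01, 0.05, 0.1, 0.2}. Ties keep
the earlier-sampled candidate so the search is reproducible. One mapping is
approximate: `randomForest` has no depth parameter, so a `max_depth` of $d$
on the bagged-trees kind caps leaves at $2^d$.

Determinism is part of the contract: a fit depends only on the data, the
spec and its `random_state`. (Internally the state passed to `ranger` is
shifted by one because that backend reads seed 0 as "seed from the clock".)

## Evaluation metrics

Regression uses RMSE (target units, e.g. nm) and $R^2 = 1 -
SS_{res}/SS_{tot}$, with $SS_{tot}$ always taken about the mean of the
evaluated set itself — for a test set, the test-set mean, the dominant
convention for predictive $R^2$.

Classification uses the confusion counts $a$ (true positive), $b$ (false
negative), $c$ (false positive), $d$ (true negative):
accuracy $(a+d)/N$, precision $a/(a+c)$, recall $a/(a+b)$,
F1 $= 2a/(2a+b+c)$ and the Matthews correlation coefficient
$(ad - bc)/\sqrt{(a+b)(a+c)(b+d)(c+d)}$, the statistic of choice under the
~73/27 class imbalance typical of liquid-crystal screens. Zero-denominator
precision/recall/F1 are reported as `NA`; a zero MCC denominator yields 0
by the usual convention, flagged in the report. Percentages round half-up
to one decimal (`as_percent()`), matching how such tables are printed,
while internal values keep full precision.

## Data handling

`read_table()` consumes delimited text (header, id column first), rejects
missing values by default (`drop_rows` is available for user data),
integer-encodes declared categorical columns such as solvent species — one
column, one importance score — and validates binary targets.
`split_train_test()` assigns `floor(ratio * n)` samples to training, which
reproduces the 2839/947 partition of a 3786-compound set at ratio 3:1.
Plain random splitting is the default; group- and class-stratified variants
apply the ratio within each stratum and give strata with fewer than two
samples to training with a warning.

## The synthetic benchmark

`generate_regression()` / `generate_classification()` emulate the *shape*
of descriptor tables — wide, numeric, mostly uninformative — with known
ground truth. Features are independent standard normal; the target is a
linear combination of a small planted subset plus, by default, one pairwise
interaction between the two strongest planted features (pure-linear targets
understate the differences between tree ensembles) and Gaussian noise.
Defaults, chosen once as the benchmark conditions:

* 400 samples × 100 descriptors, 5 informative;
* effect sizes decreasing linearly from 1.5 to 0.75, interaction
  coefficient equal to the mean of the two leading effects;
* `noise_sd = 1`, putting the signal-to-noise ratio in the
  $R^2 \approx 0.9$ regime that well-behaved QSPR regressions reach;
* classification prevalence 0.73 (mirroring 2780 positives of 3786),
  imposed by thresholding the latent score at its quantile so the class
  balance is *exact* and imbalance-sensitive metric tests stay
  deterministic.

What the generator does **not** emulate: descriptor correlation structure,
heavy-tailed or discrete descriptor distributions, activity cliffs, and
family structure in chemical datasets. Passing benchmarks on this generator
demonstrates that the machinery is correct — signal recovery, weight
algebra, metric arithmetic — not that any particular chemical dataset will
reach a given accuracy.

Random-state sensitivity of impurity importance is handled by
`repeated_importance()`, which averages profiles over a seed list (default
0–9, i.e. ten repeats; "about ten" conventions differ, and ten matches the
repeat count used in practice). The bundled benchmark scripts average over
three model seeds per generator seed, a problem-size choice that leaves the
recovery result unchanged while keeping 20-generator-seed sweeps fast.

## Numerical and degenerate-input choices

* Importance vectors that come back all-zero (a backend fitted only root
  nodes) become the uniform profile rather than an invalid zero vector.
* Ranking ties break alphabetically by feature name — published rankings
  never show ties, and determinism is required for testing.
* Weighted sums of simplex vectors are renormalized only beyond $10^{-9}$
  drift, so `blend_importance()` is exact in exact arithmetic.
* MCC is computed in double precision from the start; products like
  $720 \times 736 \times 211 \times 227$ overflow 32-bit integers.
* An AdaBoost round whose weighted error reaches 0.5 stops the boosting
  loop (keeping at least one learner); a perfect round dominates the vote.

## Known limitations

* The AdaBoost importance uses `rpart`'s split-improvement accounting,
  which is CART-faithful but not bit-identical to other toolkits'
  mean-decrease-in-impurity.
* Only two-class classification is supported; multiclass metrics and
  ROC/AUC are out of scope.
* Blending here is single-level with a fixed pool of tree ensembles;
  out-of-fold stacked generalization is deliberately not implemented — the
  holdout mode is the leak-resistant middle ground.
* Descriptor computation (Dragon, RDKit, quantum-chemical pipelines) is out
  of scope; the package starts from a numeric descriptor table.

## A worked miniature

```{r example, eval = FALSE}
gen <- generate_regression(synthetic_spec(n_samples = 300, seed = 1))
sp <- split_train_test(gen$table, train_ratio = 0.75, seed = 1)
specs <- default_level0_specs("regression", random_state = 0)
blend <- fit_blend(sp$train, specs, variant = "any", seed = 1)
extract_weights(blend)
evaluate_predictions(sp$test, predict(blend, sp$test))
rank_features(feature_importance(blend), top_k = 10)
```

The weights report how much the non-linear combiner relies on each level-0
model; the ranking is the consensus descriptor ordering with the planted
features at the top.
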