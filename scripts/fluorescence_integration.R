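#!/usr/bin/env Rscript
# Optional integration run on the fluorescence-dye descriptor tables
# (not shipped with the package; supply your own copies). Fits the four
# level-0 ensembles and the three blenders on the training table and
# reports train/test R^2 and RMSE. Values are reported for comparison
# only; nothing is asserted.
#
# Usage:
#   Rscript scripts/fluorescence_integration.R \
#     --train train_descriptors.csv --test test_descriptors.csv \
#     --target lambda_em [--id-column <name>] [--seed 0]
#
# The files are expected in the read_table() dialect: header row, one id
# column, numeric descriptor columns, one target column (emission
# wavelength in nm).

suppressPackageStartupMessages({
  library(optparse)
  library(qsprblend)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--train", type = "character"),
  make_option("--test", type = "character"),
  make_option("--target", type = "character", default = "lambda_em"),
  make_option("--id-column", type = "character", default = NULL,
              dest = "id_column"),
  make_option("--seed", type = "integer", default = 0L)
)))
if (is.null(opts$train) || is.null(opts$test)) {
  stop("--train and --test descriptor files are required", call. = FALSE)
}

train <- read_table(opts$train, target_column = opts$target,
                    task = "regression", id_column = opts$id_column)
test <- read_table(opts$test, target_column = opts$target,
                   task = "regression", id_column = opts$id_column)
message(sprintf("train: %d x %d, test: %d x %d",
                n_samples(train), n_features(train),
                n_samples(test), n_features(test)))

specs <- default_level0_specs("regression", random_state = opts$seed,
                              n_estimators = 500L)
report <- function(name, model) {
  tr <- evaluate_predictions(train, predict(model, train))
  te <- evaluate_predictions(test, predict(model, test))
  cat(sprintf("%-14s train R2 %.3f RMSE %6.2f | test R2 %.3f RMSE %6.2f\n",
              name, tr$r_squared, tr$rmse, te$r_squared, te$rmse))
}
for (s in specs) {
  report(s$kind, fit_level0(train, s))
}
for (v in c("uniform", "linear", "any")) {
  report(paste0(v, "_blend"),
         fit_blend(train, specs, variant = v, seed = opts$seed))
}
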