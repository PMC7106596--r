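#' Descriptor table
#'
#' The central data container: a samples-by-descriptors numeric matrix with a
#' target vector, matching the layout of precomputed molecular-descriptor
#' tables (one row per sample/measurement, one numeric column per descriptor).
#' For classification the target must take exactly two values, one of which is
#' designated the positive class (e.g. "LC" for liquid-crystal behaviour).
#'
#' @param X numeric matrix or data frame, n samples x p descriptors, with
#'   column names. Missing values are rejected.
#' @param y target vector of length n: numeric for regression, two-valued
#'   (factor, character or numeric) for classification.
#' @param task `"regression"` or `"classification"`.
#' @param sample_ids unique sample identifiers; defaults to `1..n` as
#'   character.
#' @param group optional per-sample stratification label (e.g. chromophore
#'   family) of length n.
#' @param positive_label label treated as the positive class. Defaults to the
#'   alphabetically first label for character/factor targets (so "LC" beats
#'   "NLC") and to the larger value for numeric 0/1 targets.
#' @return an object of class `descriptor_table` with fields `X` (numeric
#'   matrix), `y`, `task`, `sample_ids`, `feature_names`, `group`,
#'   `positive_label`.
#' @export
descriptor_table <- function(X, y, task = c("regression", "classification"),
                             sample_ids = NULL, group = NULL,
                             positive_label = NULL) {
  task <- match.arg(task)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (anyNA(X)) stop_("descriptor matrix contains missing values")
  n <- nrow(X)
  if (length(y) != n) stop_("length(y) [", length(y), "] != nrow(X) [", n, "]")
  sample_ids <- as.character(sample_ids %||% seq_len(n))
  if (length(sample_ids) != n) stop_("sample_ids length mismatch")
  if (anyDuplicated(sample_ids)) {
    stop_("duplicate sample ids: ",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (!is.null(group)) {
    if (length(group) != n) stop_("group length mismatch")
    group <- as.character(group)
  }
  if (task == "classification") {
    if (anyNA(y)) stop_("classification target contains missing values")
    y <- as.character(y)
    lev <- sort(unique(y))
    if (length(lev) != 2L) {
      stop_("classification target must take exactly two values, got ",
            length(lev), ": ", paste(utils::head(lev, 5), collapse = ", "))
    }
    if (is.null(positive_label)) {
      num <- suppressWarnings(as.numeric(lev))
      positive_label <- if (!anyNA(num)) lev[which.max(num)] else lev[1L]
    }
    positive_label <- as.character(positive_label)
    if (!positive_label %in% lev) {
      stop_("positive_label '", positive_label, "' not among target values")
    }
  } else {
    y <- as.numeric(y)
    if (anyNA(y)) stop_("regression target contains missing values")
    positive_label <- NULL
  }
  structure(
    list(X = X, y = y, task = task, sample_ids = sample_ids,
         feature_names = colnames(X), group = group,
         positive_label = positive_label),
    class = "descriptor_table"
  )
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("<descriptor_table> ", nrow(x$X), " samples x ", ncol(x$X),
      " descriptors, task: ", x$task, "\n", sep = "")
  if (x$task == "classification") {
    tab <- table(x$y)
    cat("  classes: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        " (positive: ", x$positive_label, ")\n", sep = "")
  }
  if (!is.null(x$group)) {
    cat("  groups: ", length(unique(x$group)), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$X)

#' Number of samples / descriptors
#' @param table a [descriptor_table].
#' @return integer count.
#' @export
n_samples <- function(table) nrow(table$X)

#' @rdname n_samples
#' @export
n_features <- function(table) ncol(table$X)

# Row subset preserving all metadata.
subset_table <- function(table, idx) {
  descriptor_table(table$X[idx, , drop = FALSE], table$y[idx],
                   task = table$task, sample_ids = table$sample_ids[idx],
                   group = if (!is.null(table$group)) table$group[idx],
                   positive_label = table$positive_label)
}

#' Read a descriptor table from delimited text
#'
#' Reads a CSV/TSV file (header row, first column = sample id unless
#' `id_column` says otherwise) into a validated [descriptor_table]. Every
#' column other than the id, target and group columns must be numeric unless
#' it is declared in `categorical_columns`, in which case it is
#' integer-encoded and the code map is recorded in the `code_maps` attribute
#' (a single solvent-species column encoded this way keeps one importance
#' score per solvent descriptor).
#'
#' @param path file path; `.tsv`/`.txt` extensions are read tab-separated,
#'   anything else comma-separated (override with `sep`).
#' @param target_column name of the target column.
#' @param task `"regression"` or `"classification"`.
#' @param id_column name of the sample-id column; defaults to the first
#'   column.
#' @param group_column optional name of a stratification-group column.
#' @param categorical_columns character vector of feature columns to
#'   integer-encode (codes assigned in sorted level order, starting at 1).
#' @param na_action `"error"` (default: any missing value is rejected) or
#'   `"drop_rows"` (rows with missing values are dropped with a message).
#' @param positive_label,sep passed through / parsing override.
#' @return a [descriptor_table]; attribute `code_maps` holds the
#'   integer-encoding maps of any categorical columns.
#' @export
read_table <- function(path, target_column, task = c("regression", "classification"),
                       id_column = NULL, group_column = NULL,
                       categorical_columns = character(),
                       na_action = c("error", "drop_rows"),
                       positive_label = NULL, sep = NULL) {
  task <- match.arg(task)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop_("file not found: ", path)
  sep <- sep %||% if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L) stop_("table needs at least an id and a target column")
  id_column <- id_column %||% names(df)[1L]
  for (col in c(id_column, target_column, group_column)) {
    if (!col %in% names(df)) stop_("column '", col, "' not found in ", path)
  }
  if (anyNA(df)) {
    if (na_action == "error") {
      stop_("missing values in ", path,
            " (use na_action = 'drop_rows' to drop incomplete rows)")
    }
    keep <- stats::complete.cases(df)
    message("read_table: dropped ", sum(!keep), " row(s) with missing values")
    df <- df[keep, , drop = FALSE]
  }
  feat_cols <- setdiff(names(df), c(id_column, target_column, group_column))
  if (!length(feat_cols)) stop_("no descriptor columns left")
  code_maps <- list()
  for (col in feat_cols) {
    v <- df[[col]]
    if (col %in% categorical_columns) {
      lev <- sort(unique(as.character(v)))
      code_maps[[col]] <- stats::setNames(seq_along(lev), lev)
      df[[col]] <- code_maps[[col]][as.character(v)]
    } else if (!is.numeric(v)) {
      stop_("column '", col, "' is not numeric and was not declared ",
            "categorical")
    }
  }
  tab <- descriptor_table(
    as.matrix(df[feat_cols]), df[[target_column]], task = task,
    sample_ids = df[[id_column]],
    group = if (!is.null(group_column)) df[[group_column]],
    positive_label = positive_label
  )
  attr(tab, "code_maps") <- code_maps
  tab
}

#' Write a descriptor table as CSV
#'
#' Inverse of [read_table()]: sample id first, then the descriptors, the
#' target (named `target` unless overridden) and, if present, the group
#' column. A read/write round trip reproduces `X`, `y` and the feature names.
#'
#' @param table a [descriptor_table].
#' @param path output file path.
#' @param target_column,group_column column names to use on disk.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, target_column = "target",
                        group_column = "group") {
  df <- data.frame(sample_id = table$sample_ids, check.names = FALSE)
  df <- cbind(df, as.data.frame(table$X, check.names = FALSE))
  df[[target_column]] <- table$y
  if (!is.null(table$group)) df[[group_column]] <- table$group
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Train/test split
#'
#' Randomly partitions a table into a training set of `floor(train_ratio * n)`
#' samples and a test set of the remainder (so 3786 samples at ratio 3:1 give
#' the 2839/947 partition). With `stratify = "by_group"` the same ratio is
#' applied within each group and the leftover training slots implied by the
#' global floor are assigned among groups at random; `"by_class"` does the
#' same using the class label as the group.
#'
#' @param table a [descriptor_table].
#' @param train_ratio fraction of samples assigned to training, in (0, 1).
#' @param stratify `"none"`, `"by_group"` or `"by_class"`.
#' @param seed integer seed; the same seed always reproduces the same split.
#' @return list with elements `train` and `test` (both [descriptor_table]s)
#'   and `assignment`, a data frame of (`sample_id`, `partition`).
#' @export
split_train_test <- function(table, train_ratio = 0.75,
                             stratify = c("none", "by_group", "by_class"),
                             seed = 0L) {
  stratify <- match.arg(stratify)
  if (!(train_ratio > 0 && train_ratio < 1)) {
    stop_("train_ratio must be in (0, 1)")
  }
  n <- n_samples(table)
  n_train <- floor(train_ratio * n)
  strata <- switch(stratify,
    none = rep("all", n),
    by_group = {
      if (is.null(table$group)) stop_("stratify = 'by_group' needs group labels")
      table$group
    },
    by_class = as.character(table$y)
  )
  train_idx <- with_seed(seed, {
    idx_by <- split(seq_len(n), strata)
    small <- names(idx_by)[lengths(idx_by) < 2L]
    if (length(small)) {
      warn_("strata with fewer than 2 samples assigned entirely to train: ",
            paste(small, collapse = ", "))
    }
    base <- lapply(idx_by, function(ix) {
      if (length(ix) < 2L) return(ix)
      sample(ix, floor(train_ratio * length(ix)))
    })
    chosen <- unlist(base, use.names = FALSE)
    deficit <- n_train - length(chosen)
    if (deficit > 0) {
      pool <- setdiff(seq_len(n), chosen)
      # favour strata whose floor dropped the most fractional mass
      chosen <- c(chosen, sample(pool, deficit))
    }
    sort(chosen)
  })
  test_idx <- setdiff(seq_len(n), train_idx)
  assignment <- data.frame(
    sample_id = table$sample_ids,
    partition = ifelse(seq_len(n) %in% train_idx, "train", "test"),
    stringsAsFactors = FALSE
  )
  list(train = subset_table(table, train_idx),
       test = subset_table(table, test_idx),
       assignment = assignment)
}

#' Write a split manifest
#'
#' @param split result of [split_train_test()].
#' @param path output CSV path (columns `sample_id`, `partition`).
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  utils::write.csv(split$assignment, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
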