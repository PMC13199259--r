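#' Names of the 21 cardiotocography summary features
#'
#' The feature layout used throughout the package: the 21 numeric columns a
#' SisPorto-style CTG feature extraction produces (baseline heart rate,
#' accelerations, decelerations, short/long-term variability summaries and
#' heart-rate histogram descriptors), in their conventional order.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' ctg_feature_names()
ctg_feature_names <- function() {
  c("LB", "AC", "FM", "UC", "DL", "DS", "DP",
    "ASTV", "MSTV", "ALTV", "MLTV",
    "Width", "Min", "Max", "Nmax", "Nzeros",
    "Mode", "Mean", "Median", "Variance", "Tendency")
}

#' Read a CTG-style feature table from CSV
#'
#' Loads a comma-delimited table with a header row, checks that every column
#' is numeric, recodes the fetal-state label to `{0, 1, 2}`
#' (0 normal, 1 suspect, 2 pathological) and drops rows with missing values,
#' reporting how many were removed.
#'
#' @param path Path to a CSV file with a header row.
#' @param label Name of the class-label column. Default `"NSP"`.
#' @param label_dialect Either `"one_based"` (labels stored as 1/2/3, the
#'   common UCI export convention, recoded to 0/1/2) or `"zero_based"`
#'   (labels already 0/1/2, kept as-is).
#' @return A tibble with the feature columns in file order followed by the
#'   integer label column. The number of dropped incomplete rows is attached
#'   as attribute `"n_dropped"`.
#' @export
read_ctg <- function(path, label = "NSP",
                     label_dialect = c("one_based", "zero_based")) {
  label_dialect <- match.arg(label_dialect)
  raw <- utils::read.csv(path, check.names = FALSE)
  if (!label %in% names(raw)) {
    abort_bad_arg(sprintf("label column '%s' not found in %s", label, path))
  }
  bad <- names(raw)[!vapply(raw, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort_bad_arg(paste0("non-numeric column(s): ", paste(bad, collapse = ", ")))
  }
  complete <- stats::complete.cases(raw)
  n_dropped <- sum(!complete)
  raw <- raw[complete, , drop = FALSE]
  if (nrow(raw) == 0) abort_bad_arg("no complete rows in input table")

  y <- raw[[label]]
  if (label_dialect == "one_based") {
    if (any(!y %in% 1:3)) abort_bad_arg("one_based labels must be in {1, 2, 3}")
    y <- as.integer(y) - 1L
  } else {
    if (any(!y %in% 0:2)) abort_bad_arg("zero_based labels must be in {0, 1, 2}")
    y <- as.integer(y)
  }
  out <- tibble::as_tibble(raw[setdiff(names(raw), label)])
  out[[label]] <- y
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Split samples into train / validation / test index sets
#'
#' Sizes follow a round-half-up rule on the validation and test fractions,
#' with the training set taking the remainder; a fraction triple of
#' (0.8, 0.1, 0.1) on 2,126 samples therefore yields 1,700 / 213 / 213.
#' The permutation is driven entirely by `seed`.
#'
#' @param n Number of samples, or a data frame (its row count is used and,
#'   when `stratify = TRUE`, its label column supplies the class labels).
#' @param fractions Numeric triple (train, validation, test) summing to 1.
#' @param seed Integer seed for the permutation.
#' @param stratify If `TRUE`, split each class separately so per-split class
#'   counts stay within one sample of the proportional value. Requires
#'   `labels` (or a data frame `n`).
#' @param labels Optional integer class vector (used only when `stratify`).
#' @param label Label column name when `n` is a data frame. Default `"NSP"`.
#' @return An object of class `"split_indices"`: a list with integer vectors
#'   `train`, `validation`, `test` that are disjoint and cover `1:n`.
#' @export
#' @examples
#' s <- split_dataset(2126, c(0.8, 0.1, 0.1), seed = 1)
#' lengths(s)
split_dataset <- function(n, fractions = c(0.8, 0.1, 0.1), seed = 1,
                          stratify = FALSE, labels = NULL, label = "NSP") {
  if (is.data.frame(n)) {
    if (is.null(labels) && label %in% names(n)) labels <- n[[label]]
    n <- nrow(n)
  }
  n <- as.integer(n)
  if (n < 3) abort_bad_arg("need at least 3 samples to split")
  if (length(fractions) != 3 || any(fractions < 0)) {
    abort_bad_arg("fractions must be three non-negative numbers")
  }
  if (abs(sum(fractions) - 1) > 1e-8) {
    abort_bad_arg("fractions must sum to 1")
  }

  round_half_up <- function(x) floor(x + 0.5)

  assign_one <- function(idx) {
    nn <- length(idx)
    n_val <- round_half_up(fractions[2] * nn)
    n_test <- round_half_up(fractions[3] * nn)
    n_train <- nn - n_val - n_test
    list(train = idx[seq_len(n_train)],
         validation = idx[seq_len(n_val) + n_train],
         test = idx[seq_len(n_test) + n_train + n_val])
  }

  set.seed(as.integer(seed))
  if (stratify) {
    if (is.null(labels)) abort_bad_arg("stratify = TRUE requires labels")
    if (length(labels) != n) abort_bad_arg("labels length must equal n")
    parts <- lapply(sort(unique(labels)), function(cl) {
      idx <- which(labels == cl)
      assign_one(idx[sample.int(length(idx))])
    })
    out <- list(train = sort(unlist(lapply(parts, `[[`, "train"))),
                validation = sort(unlist(lapply(parts, `[[`, "validation"))),
                test = sort(unlist(lapply(parts, `[[`, "test"))))
  } else {
    out <- assign_one(sample.int(n))
  }
  out <- lapply(out, as.integer)
  for (part in c("train", "validation", "test")) {
    frac <- fractions[match(part, c("train", "validation", "test"))]
    if (frac > 0 && length(out[[part]]) == 0) {
      abort_bad_arg(sprintf("'%s' split is empty although its fraction is %g",
                            part, frac))
    }
  }
  structure(out, n = n, fractions = fractions, seed = as.integer(seed),
            stratify = stratify, class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("<split_indices> n = %d  train/validation/test = %d/%d/%d (seed %d%s)\n",
              attr(x, "n"), length(x$train), length(x$validation),
              length(x$test), attr(x, "seed"),
              if (isTRUE(attr(x, "stratify"))) ", stratified" else ""))
  invisible(x)
}

#' Per-feature summary statistics
#'
#' Minimum, maximum, mean and standard deviation (sample convention, n - 1)
#' for every numeric feature column, the usual descriptive table reported for
#' CTG feature sets.
#'
#' @param data Data frame or numeric matrix of features; a label column named
#'   `label` is excluded.
#' @param label Label column name to drop. Default `"NSP"`.
#' @return A tibble with columns `feature`, `min`, `max`, `mean`, `sd`.
#' @export
summarize_features <- function(data, label = "NSP") {
  x <- as_feature_matrix(data, label = label)
  if (nrow(x) == 0) abort_bad_arg("empty table")
  tibble::tibble(
    feature = colnames(x),
    min = unname(apply(x, 2L, min)),
    max = unname(apply(x, 2L, max)),
    mean = unname(colMeans(x)),
    # single-row tables have no sample variance; report 0 rather than NA
    sd = if (nrow(x) < 2) rep(0, ncol(x)) else unname(apply(x, 2L, stats::sd))
  )
}
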