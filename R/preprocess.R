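#' Fit a feature standardizer on the training subset
#'
#' Estimates per-feature location (mean) and scale (standard deviation,
#' sample convention) on training data only, so validation and test sets can
#' be transformed without information leaking backwards. Constant features
#' are flagged and given unit scale, which maps them to exactly 0.
#'
#' @param data Training-set features: data frame or numeric matrix. A label
#'   column named `label` is excluded.
#' @param label Label column to drop when `data` is a data frame.
#' @return An object of class `"standardizer"` with fields `mean`, `scale`,
#'   `constant` (logical), `feature_names`.
#' @seealso [apply_standardizer()], [invert_standardizer()]
#' @export
fit_standardizer <- function(data, label = "NSP") {
  x <- as_feature_matrix(data, label = label)
  if (nrow(x) < 2) abort_bad_arg("need at least 2 rows to fit a standardizer")
  mu <- colMeans(x)
  sdev <- apply(x, 2L, stats::sd)
  constant <- sdev < .Machine$double.eps^0.5
  sdev[constant] <- 1
  structure(list(mean = mu, scale = sdev, constant = constant,
                 feature_names = colnames(x)),
            class = "standardizer")
}

#' @export
print.standardizer <- function(x, ...) {
  cat(sprintf("<standardizer> %d features%s\n", length(x$mean),
              if (any(x$constant))
                sprintf(" (%d constant)", sum(x$constant)) else ""))
  invisible(x)
}

#' Apply a fitted standardizer
#'
#' Transforms each feature column to `(x - mean) / scale` with the training
#' statistics held in `params`. Constant training features map to 0.
#'
#' @param data Features to transform (data frame or matrix); a label column
#'   named `label` is carried through unchanged.
#' @param params A `"standardizer"` from [fit_standardizer()].
#' @param label Label column name passed through untouched.
#' @return A tibble of transformed features (plus the untouched label column
#'   if present in `data`).
#' @export
apply_standardizer <- function(data, params, label = "NSP") {
  y <- if (is.data.frame(data) && label %in% names(data)) data[[label]] else NULL
  x <- as_feature_matrix(data, label = label)
  if (ncol(x) != length(params$mean)) {
    abort_bad_arg("column count does not match standardizer")
  }
  z <- sweep(sweep(x, 2L, params$mean, "-"), 2L, params$scale, "/")
  out <- tibble::as_tibble(as.data.frame(z))
  if (!is.null(y)) out[[label]] <- y
  out
}

#' Invert a standardizer transform
#'
#' Maps standardized values back to the original feature scale,
#' `x * scale + mean`.
#'
#' @inheritParams apply_standardizer
#' @return A tibble on the original scale.
#' @export
invert_standardizer <- function(data, params, label = "NSP") {
  y <- if (is.data.frame(data) && label %in% names(data)) data[[label]] else NULL
  x <- as_feature_matrix(data, label = label)
  if (ncol(x) != length(params$mean)) {
    abort_bad_arg("column count does not match standardizer")
  }
  z <- sweep(sweep(x, 2L, params$scale, "*"), 2L, params$mean, "+")
  out <- tibble::as_tibble(as.data.frame(z))
  if (!is.null(y)) out[[label]] <- y
  out
}

#' @export
tidy.standardizer <- function(x, ...) {
  tibble::tibble(feature = x$feature_names, mean = unname(x$mean),
                 scale = unname(x$scale), constant = unname(x$constant))
}

#' SMOTE minority oversampling
#'
#' Brings every class up to `target_count` samples by synthesising new
#' minority points as convex combinations `x_new = x_i + alpha * (x_j - x_i)`
#' of a minority sample `x_i` and one of its `k_neighbors` nearest same-class
#' neighbours `x_j` (Euclidean distance), with `alpha ~ Uniform[0, 1]`.
#' Original rows are preserved unchanged and come first in the output; the
#' generation loop cycles through minority samples in row order, so results
#' are fully determined by `seed`.
#'
#' @param data Data frame with numeric features and an integer label column,
#'   or a numeric matrix (then supply `labels`).
#' @param label Label column name. Default `"NSP"`.
#' @param labels Optional label vector when `data` is a matrix.
#' @param k_neighbors Number of nearest same-class neighbours considered per
#'   minority sample; must be smaller than every oversampled class's size.
#'   Distance ties are broken toward the lowest row index.
#' @param target_count Samples per class after oversampling. Default: the
#'   largest class count, giving fully balanced classes.
#' @param seed Integer seed driving neighbour choice and `alpha` draws.
#' @return A tibble of features plus the label column, original rows first.
#'   Attribute `"smote_log"` records, per synthetic row, the generating pair
#'   (`base_row`, `neighbor_row`, both indices into `data`) and `alpha`.
#' @export
smote_oversample <- function(data, label = "NSP", labels = NULL,
                             k_neighbors = 5, target_count = NULL, seed = 1) {
  if (is.data.frame(data) && is.null(labels)) {
    if (!label %in% names(data)) abort_bad_arg("label column not found")
    labels <- data[[label]]
  }
  if (is.null(labels)) abort_bad_arg("labels required")
  x <- as_feature_matrix(data, label = label)
  labels <- check_labels(labels)
  if (length(labels) != nrow(x)) abort_bad_arg("labels length mismatch")
  if (k_neighbors < 1) abort_bad_arg("k_neighbors must be >= 1")

  counts <- table(labels)
  if (is.null(target_count)) target_count <- max(counts)
  if (target_count < max(counts)) {
    abort_bad_arg("target_count must be at least the largest class count")
  }

  set.seed(as.integer(seed))
  new_x <- list()
  log_rows <- list()
  classes <- sort(unique(labels))
  for (cl in classes) {
    idx <- which(labels == cl)
    n_needed <- target_count - length(idx)
    if (n_needed == 0) next
    if (length(idx) < 2) {
      abort_bad_arg(sprintf("class %s has fewer than 2 samples; cannot SMOTE", cl))
    }
    if (k_neighbors >= length(idx)) {
      abort_bad_arg(sprintf(
        "k_neighbors (%d) must be smaller than class %s size (%d)",
        k_neighbors, cl, length(idx)))
    }
    xc <- x[idx, , drop = FALSE]
    d <- as.matrix(stats::dist(xc))
    # k nearest same-class neighbours per row, self excluded,
    # ties broken by lowest row index
    nn <- t(vapply(seq_along(idx), function(i) {
      ord <- order(d[i, ], seq_along(idx))
      ord[ord != i][seq_len(k_neighbors)]
    }, integer(k_neighbors)))
    if (k_neighbors == 1L) nn <- matrix(nn, ncol = 1L)

    base_seq <- rep(seq_along(idx), length.out = n_needed)
    for (s in seq_len(n_needed)) {
      i <- base_seq[s]
      j <- nn[i, sample.int(k_neighbors, 1L)]
      alpha <- stats::runif(1)
      new_x[[length(new_x) + 1L]] <- xc[i, ] + alpha * (xc[j, ] - xc[i, ])
      log_rows[[length(log_rows) + 1L]] <-
        tibble::tibble(class = cl, base_row = idx[i], neighbor_row = idx[j],
                       alpha = alpha)
    }
  }

  if (length(new_x) > 0) {
    aug <- rbind(x, do.call(rbind, new_x))
    aug_labels <- c(labels,
                    unlist(lapply(log_rows, function(r) r$class), use.names = FALSE))
    smote_log <- dplyr::bind_rows(log_rows)
    smote_log$new_row <- nrow(x) + seq_len(nrow(smote_log))
  } else {
    aug <- x
    aug_labels <- labels
    smote_log <- tibble::tibble(class = integer(), base_row = integer(),
                                neighbor_row = integer(), alpha = double(),
                                new_row = integer())
  }
  out <- tibble::as_tibble(as.data.frame(aug))
  out[[label]] <- as.integer(aug_labels)
  attr(out, "smote_log") <- smote_log
  out
}

#' Retrieve the SMOTE generation log
#'
#' @param data The tibble returned by [smote_oversample()].
#' @return Tibble with one row per synthetic sample: `class`, `base_row`,
#'   `neighbor_row`, `alpha`, `new_row`.
#' @export
smote_log <- function(data) {
  log <- attr(data, "smote_log")
  if (is.null(log)) abort_bad_arg("no SMOTE log attached to this object")
  log
}
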