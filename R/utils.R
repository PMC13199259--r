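# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_bad_arg <- function(msg) rlang::abort(msg, class = "plectabm_error")

# Coerce a data frame (dropping the label column if named) or matrix to a
# plain numeric matrix with column names.
as_feature_matrix <- function(x, label = NULL) {
  if (is.data.frame(x)) {
    if (!is.null(label) && label %in% names(x)) {
      x <- x[setdiff(names(x), label)]
    }
    bad <- names(x)[!vapply(x, is.numeric, logical(1))]
    if (length(bad) > 0) {
      abort_bad_arg(paste0("non-numeric feature column(s): ",
                           paste(bad, collapse = ", ")))
    }
    x <- as.matrix(x)
  }
  if (is.matrix(x) && ncol(x) == 0) {
    abort_bad_arg("empty table: no feature columns")
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort_bad_arg("expected a numeric matrix or data frame of features")
  }
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  storage.mode(x) <- "double"
  x
}

check_labels <- function(labels, n_classes = NULL) {
  if (anyNA(labels)) abort_bad_arg("labels contain missing values")
  labels <- as.integer(labels)
  if (any(labels < 0)) abort_bad_arg("labels must be non-negative integers")
  if (!is.null(n_classes) && any(labels >= n_classes)) {
    abort_bad_arg(sprintf("label outside 0..%d found", n_classes - 1L))
  }
  labels
}

# Deterministic per-stage seeds derived from one master seed, kept within
# 32-bit integer range.
stage_seed <- function(seed, stage) {
  offsets <- c(split = 101L, standardize = 151L, smote = 211L, bins = 257L,
               init = 307L, train = 401L, shap = 503L, simulate = 601L)
  if (!stage %in% names(offsets)) abort_bad_arg("unknown pipeline stage")
  as.integer((as.numeric(seed) + offsets[[stage]]) %% 2147483587)
}

# Row-wise softmax with max-shift stabilisation.
row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Row-wise log-sum-exp.
row_logsumexp <- function(z) {
  m <- apply(z, 1L, max)
  m + log(rowSums(exp(z - m)))
}

# (m, k, d) array <-> (m*k, d) matrix with member index varying fastest,
# i.e. flat row (i-1)*k + j holds member j of sample i.
a3_to_flat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L])
}

flat_to_a3 <- function(x, m, k) {
  aperm(array(x, c(k, m, ncol(x))), c(2L, 1L, 3L))
}

# Flatten a nested list of numeric arrays into a named flat list (depth-first,
# deterministic order) and rebuild it.  Used by the Adam optimiser.
flatten_params <- function(x, prefix = character()) {
  if (is.numeric(x)) {
    out <- list(x)
    names(out) <- paste(prefix, collapse = ".")
    return(out)
  }
  nm <- names(x) %||% as.character(seq_along(x))
  out <- list()
  for (i in seq_along(x)) {
    out <- c(out, flatten_params(x[[i]], c(prefix, nm[i])))
  }
  out
}

unflatten_params <- function(flat, skeleton) {
  idx <- 0L
  rebuild <- function(s) {
    if (is.numeric(s)) {
      idx <<- idx + 1L
      return(flat[[idx]])
    }
    out <- lapply(s, rebuild)
    names(out) <- names(s)
    out
  }
  rebuild(skeleton)
}
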