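#' Construct bin boundaries for one feature
#'
#' Divides a feature's observed range into `t_bins` intervals for the
#' piecewise linear encoding. The quantile method (default) places boundary
#' `b_t` at the empirical `t/T` quantile using the inverse-ECDF order
#' statistic (so boundaries are observed values), which adapts bin widths to
#' skewed features; the uniform method spaces boundaries evenly over
#' `[min, max]`. Duplicate boundaries are collapsed, reducing `T` for
#' features with few distinct values.
#'
#' @param x Numeric vector: one feature column of the training subset (the
#'   pipeline builds bins on standardized training values before any
#'   oversampling, so bins reflect real, not synthetic, samples).
#' @param t_bins Requested number of bins `T` (>= 1). Default 24.
#' @param method `"quantile"` or `"uniform"`.
#' @return An object of class `"bin_spec"`: the numeric vector of strictly
#'   increasing boundaries `b_0 < ... < b_T` (length `T + 1`).
#' @export
#' @examples
#' build_bins(c(0, 1, 2, 3, 4), t_bins = 4, method = "uniform")
build_bins <- function(x, t_bins = 24, method = c("quantile", "uniform")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  if (length(x) == 0) abort_bad_arg("no finite values in column")
  if (t_bins < 1) abort_bad_arg("t_bins must be >= 1")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    abort_bad_arg(paste("constant column: no bins can be built;",
                        "bypass the piecewise encoding for this feature"))
  }
  if (method == "uniform") {
    b <- seq(rng[1], rng[2], length.out = t_bins + 1)
  } else {
    b <- stats::quantile(x, probs = seq(0, 1, length.out = t_bins + 1),
                         type = 1, names = FALSE)
  }
  b <- unique(b)
  if (length(b) < 2) {
    abort_bad_arg("bins collapsed below T = 1; bypass encoding for this feature")
  }
  structure(b, class = "bin_spec")
}

#' Bin specifications for every feature column
#'
#' Applies [build_bins()] to each feature. Constant columns (which the
#' standardizer maps to exactly 0) get a degenerate single-bin spec so the
#' encoding reduces to its bias term for that feature; a warning names them.
#'
#' @param data Data frame or matrix of (typically standardized) training
#'   features; a label column named `label` is excluded.
#' @inheritParams build_bins
#' @param label Label column name to drop.
#' @return Named list of `"bin_spec"` objects, one per feature.
#' @export
build_bin_specs <- function(data, t_bins = 24, method = c("quantile", "uniform"),
                            label = "NSP") {
  method <- match.arg(method)
  x <- as_feature_matrix(data, label = label)
  specs <- vector("list", ncol(x))
  names(specs) <- colnames(x)
  const <- character()
  for (f in colnames(x)) {
    specs[[f]] <- tryCatch(
      build_bins(x[, f], t_bins = t_bins, method = method),
      plectabm_error = function(e) {
        const <<- c(const, f)
        v <- x[1, f]
        structure(c(v, v + 1), class = "bin_spec", constant = TRUE)
      })
  }
  if (length(const) > 0) {
    warning(sprintf("constant feature(s) %s: encoding degenerates to the bias",
                    paste(const, collapse = ", ")), call. = FALSE)
  }
  specs
}

#' Piecewise linear encoding of scalar values
#'
#' Encodes each value `x` against bin boundaries `b_0 < ... < b_T` as a
#' vector `(e_1, ..., e_T)` where `e_t` is the saturating progress through
#' bin `t`: 0 below the bin, 1 above it, and the linear ramp
#' `(x - b_{t-1}) / (b_t - b_{t-1})` inside. Interior components are clamped
#' to `[0, 1]`; the first bin extrapolates linearly below `b_0` and the last
#' above `b_T`, so out-of-range values remain informative, and with `T = 1`
#' the encoding is an unclamped affine function of `x`. The encoding is
#' componentwise non-decreasing in `x`.
#'
#' @param x Numeric vector of values to encode.
#' @param bins A `"bin_spec"` (or numeric vector of strictly increasing
#'   boundaries).
#' @return Numeric matrix `length(x)` x `T`.
#' @export
#' @examples
#' piecewise_encode(1.5, c(0, 1, 2, 3))  # (1, 0.5, 0)
piecewise_encode <- function(x, bins) {
  b <- as.numeric(bins)
  tt <- length(b) - 1L
  if (tt < 1 || any(diff(b) <= 0)) {
    abort_bad_arg("bins must be at least 2 strictly increasing boundaries")
  }
  e <- outer(x, seq_len(tt), function(xx, t) {
    (xx - b[t]) / (b[t + 1] - b[t])
  })
  if (tt > 1) {
    interior <- 2:(tt - 1)
    if (tt > 2) {
      e[, interior] <- pmin(pmax(e[, interior, drop = FALSE], 0), 1)
    }
    e[, 1L] <- pmin(e[, 1L], 1)      # no lower clamp: extrapolates below b_0
    e[, tt] <- pmax(e[, tt], 0)      # no upper clamp: extrapolates above b_T
  }
  e
}

# Derivative d e_t / d x of the piecewise encoding: exactly one component is
# on its linear ramp at any x (the active bin), with slope 1/(b_t - b_{t-1}).
# Returns length(x) x T matrix of slopes.
piecewise_encode_slope <- function(x, bins) {
  b <- as.numeric(bins)
  tt <- length(b) - 1L
  # active bin: the interval containing x, with the extreme bins absorbing
  # out-of-range values (matching the unclamped extrapolation)
  act <- findInterval(x, b, left.open = FALSE)
  act <- pmin(pmax(act, 1L), tt)
  s <- matrix(0, length(x), tt)
  width <- diff(b)
  s[cbind(seq_along(x), act)] <- 1 / width[act]
  s
}

#' Initialize learnable piecewise-linear embedding parameters
#'
#' Each feature gets `T` learnable bin vectors `v_1..v_T` of dimension
#' `d_embedding`, drawn uniformly from `(-1/sqrt(T), 1/sqrt(T))`, plus a zero
#' bias vector. These are trained jointly with the network.
#'
#' @param bin_specs Named list of `"bin_spec"` objects from [build_bin_specs()].
#' @param d_embedding Embedding dimension `d` per feature. Default 8.
#' @param seed Integer seed.
#' @return Object of class `"ple_params"`: per feature a list with matrix
#'   `V` (`T` x `d`) and numeric bias `b` (length `d`).
#' @export
init_ple_params <- function(bin_specs, d_embedding = 8, seed = 1) {
  set.seed(as.integer(seed))
  out <- lapply(bin_specs, function(bs) {
    tt <- length(as.numeric(bs)) - 1L
    lim <- 1 / sqrt(tt)
    list(V = matrix(stats::runif(tt * d_embedding, -lim, lim), tt, d_embedding),
         b = rep(0, d_embedding))
  })
  structure(out, d_embedding = as.integer(d_embedding), class = "ple_params")
}

#' Embed one piecewise encoding vector
#'
#' The learnable linear map on top of the encoding:
#' `bias + sum_t e_t * v_t`.
#'
#' @param pe Numeric vector `(e_1, ..., e_T)` from [piecewise_encode()].
#' @param params One feature's parameters: a list with `V` (`T` x `d`) and
#'   bias `b` (length `d`).
#' @return Numeric embedding vector of length `d`.
#' @export
ple_embed <- function(pe, params) {
  if (length(pe) != nrow(params$V)) {
    abort_bad_arg("encoding length does not match the number of bin vectors")
  }
  drop(params$b + crossprod(params$V, pe))
}

#' Encode a feature table into concatenated embeddings
#'
#' Row `i` of the result is the concatenation, in feature order, of the
#' `d`-dimensional embeddings of sample `i`'s features — the input the
#' ensemble network consumes.
#'
#' @param data Data frame or numeric matrix of features (standardized scale,
#'   matching the scale the bins were built on).
#' @param bin_specs Named list of `"bin_spec"`, one per feature.
#' @param params `"ple_params"` covering the same features.
#' @param label Label column name to drop.
#' @return Numeric matrix `n_samples` x `(n_features * d)` with columns named
#'   `<feature>_e<j>`.
#' @export
encode_table <- function(data, bin_specs, params, label = "NSP") {
  x <- as_feature_matrix(data, label = label)
  feats <- names(bin_specs)
  if (!setequal(colnames(x), feats) || length(params) != length(feats)) {
    abort_bad_arg("bin specs / parameters do not cover the feature columns")
  }
  d <- ncol(params[[1]]$V)
  blocks <- lapply(feats, function(f) {
    pe <- piecewise_encode(x[, f], bin_specs[[f]])
    emb <- pe %*% params[[f]]$V
    sweep(emb, 2L, params[[f]]$b, "+")
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- unlist(lapply(feats, function(f) paste0(f, "_e", seq_len(d))))
  out
}

# Precompute per-feature piecewise encodings once per dataset (the encodings
# depend only on the data and bins, not on trainable parameters).
precompute_pe <- function(x, bin_specs) {
  lapply(names(bin_specs), function(f) piecewise_encode(x[, f], bin_specs[[f]]))
}

# Embed from precomputed encodings with current parameters; rows optional.
embed_from_pe <- function(pe_list, ple_params, rows = NULL) {
  blocks <- lapply(seq_along(pe_list), function(i) {
    pe <- pe_list[[i]]
    if (!is.null(rows)) pe <- pe[rows, , drop = FALSE]
    sweep(pe %*% ple_params[[i]]$V, 2L, ple_params[[i]]$b, "+")
  })
  do.call(cbind, blocks)
}
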