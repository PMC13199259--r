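#' Configuration of the weight-shared MLP ensemble
#'
#' Hyperparameters of the TabM-style ensemble: `k` member MLPs share one
#' weight matrix per block and are individualised by elementwise
#' multiplicative adapter vectors and per-member biases. Defaults follow the
#' reference CTG configuration: `k = 32`, two blocks, dropout 0.1, with a
#' hidden width of 128.
#'
#' @param k Ensemble members (>= 1).
#' @param n_blocks Number of linear-ReLU-dropout blocks (>= 1).
#' @param hidden_width Units per hidden block.
#' @param dropout_rate Dropout probability in `[0, 1)`.
#' @param n_classes Number of output classes.
#' @param input_width Width of the encoded input
#'   (`n_features * d_embedding` after the piecewise linear encoding).
#' @return Object of class `"tabm_config"`.
#' @export
tabm_config <- function(k = 32, n_blocks = 2, hidden_width = 128,
                        dropout_rate = 0.1, n_classes = 3, input_width = 168) {
  if (k < 1 || n_blocks < 1) abort_bad_arg("k and n_blocks must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort_bad_arg("dropout_rate must be in [0, 1)")
  }
  structure(list(k = as.integer(k), n_blocks = as.integer(n_blocks),
                 hidden_width = as.integer(hidden_width),
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes),
                 input_width = as.integer(input_width)),
            class = "tabm_config")
}

#' Initialize ensemble parameters
#'
#' Shared weight matrices use fan-in-scaled uniform draws
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`; adapter vectors are random
#' plus/minus-1 signs (so every member starts as a sign-flipped view of the
#' shared weights); all biases start at zero. Output heads are per member,
#' making the members genuinely distinct classifiers.
#'
#' @param config A [tabm_config()].
#' @param seed Integer seed; the same seed reproduces parameters exactly.
#' @return Object of class `"tabm_params"`: `blocks`, a list per block of
#'   `W` (`out` x `in`), `adapters` (`k` x `in`), `biases` (`k` x `out`);
#'   and `heads`, a list of `k` per-member lists with `W`
#'   (`n_classes` x `hidden_width`) and `b` (`n_classes`).
#' @export
init_tabm_params <- function(config, seed = 1) {
  set.seed(as.integer(seed))
  widths <- c(config$input_width,
              rep(config$hidden_width, config$n_blocks))
  blocks <- lapply(seq_len(config$n_blocks), function(l) {
    n_in <- widths[l]
    n_out <- widths[l + 1]
    lim <- 1 / sqrt(n_in)
    list(W = matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in),
         adapters = matrix(sample(c(-1, 1), config$k * n_in, replace = TRUE),
                           config$k, n_in),
         biases = matrix(0, config$k, n_out))
  })
  lim_h <- 1 / sqrt(config$hidden_width)
  heads <- lapply(seq_len(config$k), function(j) {
    list(W = matrix(stats::runif(config$n_classes * config$hidden_width,
                                 -lim_h, lim_h),
                    config$n_classes, config$hidden_width),
         b = rep(0, config$n_classes))
  })
  structure(list(blocks = blocks, heads = heads), class = "tabm_params")
}

#' Shared-weight ensemble linear layer
#'
#' Computes, for each member `i`, `W (r_i * x_i) + b_i`: one weight matrix
#' `W` is shared across members while the elementwise adapter `r_i` and bias
#' `b_i` individualise them. Numerically identical to running `k` separate
#' linear layers with weights `W diag(r_i)`, at a fraction of the parameters.
#'
#' @param x Rank-3 array (`m` samples x `k` members x `in` width).
#' @param W Shared weight matrix (`out` x `in`).
#' @param adapters Matrix `k` x `in` of per-member adapter vectors.
#' @param biases Matrix `k` x `out` of per-member biases.
#' @return Rank-3 array (`m` x `k` x `out`).
#' @export
ensemble_linear <- function(x, W, adapters, biases) {
  d <- dim(x)
  if (length(d) != 3) abort_bad_arg("x must be a rank-3 (m, k, width) array")
  k <- d[2]
  if (nrow(adapters) != k || nrow(biases) != k || ncol(adapters) != d[3] ||
      ncol(W) != d[3] || ncol(biases) != nrow(W)) {
    abort_bad_arg("inconsistent shapes in ensemble_linear")
  }
  xf <- a3_to_flat(x)
  mi <- rep.int(seq_len(k), d[1])
  h <- tcrossprod(xf * adapters[mi, , drop = FALSE], W) +
    biases[mi, , drop = FALSE]
  flat_to_a3(h, d[1], k)
}

#' One ensemble block: linear, ReLU, dropout
#'
#' Applies the shared-weight linear layer, the ReLU nonlinearity, and —
#' during training only — inverted dropout with independent masks per
#' element (hence per member).
#'
#' @param x Rank-3 array (`m` x `k` x `in`).
#' @param block One block's parameters: list with `W`, `adapters`, `biases`.
#' @param dropout_rate Dropout probability; ignored unless `training`.
#' @param training Logical; dropout is disabled at evaluation time.
#' @return Rank-3 array (`m` x `k` x `out`).
#' @export
block_forward <- function(x, block, dropout_rate = 0, training = FALSE) {
  h <- ensemble_linear(x, block$W, block$adapters, block$biases)
  h[h < 0] <- 0
  if (training && dropout_rate > 0) {
    keep <- array(stats::runif(length(h)) >= dropout_rate, dim(h))
    h <- h * keep / (1 - dropout_rate)
  }
  h
}

#' Forward pass of the full ensemble
#'
#' Replicates the encoded batch across the `k` members, runs it through the
#' `n_blocks` shared-weight blocks and the per-member output heads, and
#' returns one logit vector per (sample, member) pair.
#'
#' @param x Numeric matrix (`m` x `input_width`) of encoded features.
#' @param params A [init_tabm_params()] object.
#' @param config The matching [tabm_config()].
#' @param mode `"eval"` (deterministic, dropout off) or `"train"`.
#' @return Rank-3 logits array (`m` x `k` x `n_classes`).
#' @export
tabm_forward <- function(x, params, config, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (ncol(x) != config$input_width) {
    abort_bad_arg(sprintf("input width %d does not match config (%d)",
                          ncol(x), config$input_width))
  }
  fw <- nn_forward(params, x, config, training = (mode == "train"))
  flat_to_a3(fw$logits, nrow(x), config$k)
}

#' Mean ensemble cross-entropy loss
#'
#' The training objective: the mean over the `k` members of each member's
#' mean cross-entropy against the labels — equivalently the mean
#' cross-entropy over all (sample, member) pairs.
#'
#' @param logits Rank-3 array (`m` x `k` x `n_classes`).
#' @param labels Integer class vector in `0..n_classes-1`, length `m`.
#' @return Scalar loss.
#' @export
ensemble_loss <- function(logits, labels) {
  d <- dim(logits)
  labels <- check_labels(labels, n_classes = d[3])
  if (length(labels) != d[1]) abort_bad_arg("labels length must match batch")
  lf <- a3_to_flat(logits)
  yf <- rep(labels, each = d[2])
  lse <- row_logsumexp(lf)
  true_logit <- lf[cbind(seq_len(nrow(lf)), yf + 1L)]
  mean(lse - true_logit)
}

#' Averaged ensemble class probabilities
#'
#' Applies softmax per member, then averages the `k` member probability
#' vectors with equal weight. Rows sum to 1.
#'
#' @param logits Rank-3 array (`m` x `k` x `n_classes`).
#' @return Matrix `m` x `n_classes` of class probabilities.
#' @export
predict_proba <- function(logits) {
  d <- dim(logits)
  if (length(d) != 3) abort_bad_arg("logits must be a rank-3 array")
  p <- row_softmax(a3_to_flat(logits))
  probs <- rowsum(p, rep(seq_len(d[1]), each = d[2])) / d[2]
  dimnames(probs) <- NULL
  probs
}

# ---------------------------------------------------------------------------
# Internal flat-layout forward/backward.  Member batches are stored as
# (m*k) x width matrices with the member index varying fastest (flat row
# (i-1)*k + j is member j of sample i), so each block is one BLAS matmul.

nn_forward <- function(params, x, config, training = FALSE, keep_cache = FALSE) {
  m <- nrow(x)
  k <- config$k
  mi <- rep.int(seq_len(k), m)
  h <- x[rep(seq_len(m), each = k), , drop = FALSE]
  caches <- if (keep_cache) vector("list", config$n_blocks) else NULL
  for (l in seq_len(config$n_blocks)) {
    blk <- params$blocks[[l]]
    xr <- h * blk$adapters[mi, , drop = FALSE]
    z <- tcrossprod(xr, blk$W) + blk$biases[mi, , drop = FALSE]
    relu_mask <- z > 0
    hnew <- z * relu_mask
    drop_mask <- NULL
    if (training && config$dropout_rate > 0) {
      drop_mask <- matrix(stats::runif(length(hnew)) >= config$dropout_rate,
                          nrow(hnew), ncol(hnew))
      hnew <- hnew * drop_mask / (1 - config$dropout_rate)
    }
    if (keep_cache) {
      caches[[l]] <- list(input = h, xr = xr, relu_mask = relu_mask,
                          drop_mask = drop_mask)
    }
    h <- hnew
  }
  logits <- matrix(0, m * k, config$n_classes)
  member_rows <- lapply(seq_len(k), function(j) seq.int(j, m * k, by = k))
  for (j in seq_len(k)) {
    hd <- params$heads[[j]]
    rows <- member_rows[[j]]
    logits[rows, ] <- tcrossprod(h[rows, , drop = FALSE], hd$W) +
      matrix(hd$b, length(rows), config$n_classes, byrow = TRUE)
  }
  list(logits = logits, hidden = h, caches = caches, mi = mi, m = m,
       member_rows = member_rows)
}

# Backward pass from d(loss)/d(logits) over the flat layout.  Returns
# parameter gradients in the same nested shape as `params` and, when
# requested, the gradient with respect to the encoded input (m x width).
nn_backward <- function(params, fw, dlogits, config,
                        need_param_grads = TRUE, need_input_grad = FALSE) {
  k <- config$k
  mi <- fw$mi
  dh <- matrix(0, nrow(dlogits), config$hidden_width)
  gheads <- if (need_param_grads) vector("list", k) else NULL
  for (j in seq_len(k)) {
    rows <- fw$member_rows[[j]]
    dlj <- dlogits[rows, , drop = FALSE]
    if (need_param_grads) {
      gheads[[j]] <- list(
        W = crossprod(dlj, fw$hidden[rows, , drop = FALSE]),
        b = colSums(dlj))
    }
    dh[rows, ] <- dlj %*% params$heads[[j]]$W
  }
  gblocks <- if (need_param_grads) vector("list", config$n_blocks) else NULL
  for (l in rev(seq_len(config$n_blocks))) {
    blk <- params$blocks[[l]]
    cache <- fw$caches[[l]]
    if (!is.null(cache$drop_mask)) {
      dh <- dh * cache$drop_mask / (1 - config$dropout_rate)
    }
    dz <- dh * cache$relu_mask
    dxr <- dz %*% blk$W
    if (need_param_grads) {
      gblocks[[l]] <- list(
        W = crossprod(dz, cache$xr),
        adapters = rowsum(dxr * cache$input, mi),
        biases = rowsum(dz, mi))
      dimnames(gblocks[[l]]$adapters) <- NULL
      dimnames(gblocks[[l]]$biases) <- NULL
    }
    dh <- dxr * blk$adapters[mi, , drop = FALSE]
  }
  out <- list()
  if (need_param_grads) out$grads <- list(blocks = gblocks, heads = gheads)
  if (need_input_grad) {
    dx <- rowsum(dh, rep(seq_len(fw$m), each = k))
    dimnames(dx) <- NULL
    out$dx <- dx
  }
  out
}
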