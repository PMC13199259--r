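#' Gradient SHAP feature attribution
#'
#' Explains model predictions by the expected path-integrated gradient
#' between background samples and the input: for feature `i` and class `c`,
#' the Monte-Carlo estimate over background draws `x'` and
#' `alpha ~ Uniform[0, 1]` of
#' `(x_i - x'_i) * dF_c(x' + alpha (x - x')) / dx_i`.
#' Attribution is taken with respect to the standardized raw features —
#' differentiating through the piecewise linear encoding — so scores align
#' with the named CTG indicators rather than embedding coordinates. The
#' attribution target `F_c` is the mean over ensemble members of the class-c
#' pre-softmax logit (or the averaged softmax probability with
#' `target = "prob"`). Dropout is disabled throughout. Within Monte-Carlo
#' error, attributions per class sum to `F_c(x)` minus the background mean
#' of `F_c` (completeness), and they are exact for linear models at any
#' sampling budget.
#'
#' @param fit A trained `"tabm_fit"`.
#' @param inputs Samples to explain (standardized scale; data frame or
#'   matrix).
#' @param background Background/reference samples, conventionally the
#'   (standardized, non-oversampled) training set. At most `n_background`
#'   rows are used, subsampled deterministically under `seed`.
#' @param n_path_samples Number of `(background, alpha)` draws per input.
#' @param n_background Cap on background rows used.
#' @param classes Integer classes (0-based) to attribute; default all.
#' @param target `"logit"` (default) or `"prob"`.
#' @param seed Integer seed; identical settings give identical results.
#' @return Object of class `"attribution_result"`: `values`, an array
#'   (`n_inputs` x `n_features` x `n_classes_attributed`);
#'   `baseline_expectation`, the background mean of the target per class;
#'   `prediction`, the target at each input; plus feature/class metadata.
#' @export
gradient_shap <- function(fit, inputs, background, n_path_samples = 256,
                          n_background = 512, classes = NULL,
                          target = c("logit", "prob"), seed = 1,
                          label = "NSP") {
  target <- match.arg(target)
  x <- as_feature_matrix(inputs, label = label)[, fit$feature_names, drop = FALSE]
  bg <- as_feature_matrix(background, label = label)[, fit$feature_names,
                                                     drop = FALSE]
  if (nrow(bg) == 0) abort_bad_arg("empty background")
  if (is.null(classes)) classes <- seq_len(fit$n_classes) - 1L
  classes <- check_labels(classes, fit$n_classes)
  n <- nrow(x)
  nf <- ncol(x)
  k <- fit$config$k

  set.seed(as.integer(seed))
  if (nrow(bg) > n_background) {
    bg <- bg[sample.int(nrow(bg), n_background), , drop = FALSE]
  }
  s <- as.integer(n_path_samples)
  if (s < 1) abort_bad_arg("n_path_samples must be >= 1")
  # joint (background index, alpha) draws, shared across the classes.
  # Backgrounds are drawn by cycling random permutations (balanced coverage)
  # and alpha is a stratified jittered sample of [0, 1], randomly paired:
  # the estimator stays unbiased while its completeness error shrinks.
  nb <- nrow(bg)
  draw_bidx <- function() {
    full <- s %/% nb
    rem <- s %% nb
    c(unlist(lapply(seq_len(full), function(i) sample.int(nb))),
      sample.int(nb, rem))
  }
  bidx <- matrix(0L, n, s)
  alphas <- matrix(0, n, s)
  weights <- matrix(0, n, s)
  for (i in seq_len(n)) {
    bidx[i, ] <- draw_bidx()
    groups <- split(seq_len(s), bidx[i, ])
    # each baseline's draws get a stratified jittered alpha sample of [0, 1],
    # and every sampled baseline carries equal total weight
    for (pos in groups) {
      g <- length(pos)
      alphas[i, pos] <- (sample.int(g) - stats::runif(g)) / g
      weights[i, pos] <- 1 / (g * length(groups))
    }
  }

  baseline <- target_values(fit, bg, classes, target)
  baseline_expectation <- colMeans(baseline)
  prediction <- target_values(fit, x, classes, target)

  values <- array(0, c(n, nf, length(classes)),
                  dimnames = list(NULL, fit$feature_names,
                                  paste0("class", classes)))
  for (i in seq_len(n)) {
    xp <- bg[bidx[i, ], , drop = FALSE]
    diff <- matrix(x[i, ], s, nf, byrow = TRUE) - xp
    z <- xp + alphas[i, ] * diff
    g <- input_gradients(fit, z, classes, target)       # list per class
    for (ci in seq_along(classes)) {
      values[i, , ci] <- colSums(weights[i, ] * diff * g[[ci]])
    }
  }
  if (!all(is.finite(values))) abort_bad_arg("non-finite gradients encountered")
  structure(list(values = values, baseline_expectation = baseline_expectation,
                 prediction = prediction, feature_names = fit$feature_names,
                 classes = classes, target = target,
                 n_path_samples = s, seed = as.integer(seed)),
            class = "attribution_result")
}

# Target F_c per sample: mean member logit (or averaged softmax probability)
# for the requested classes.  Returns n x length(classes).
target_values <- function(fit, x, classes, target) {
  logits <- model_logits(fit, x)
  if (target == "logit") {
    mean_logits <- apply(logits, c(1L, 3L), mean)
    out <- mean_logits[, classes + 1L, drop = FALSE]
  } else {
    out <- predict_proba(logits)[, classes + 1L, drop = FALSE]
  }
  out
}

# Gradients of the target with respect to the standardized raw features,
# chained through blocks and the piecewise encoding.  Returns a list (one
# n x n_features matrix per class).
input_gradients <- function(fit, x, classes, target) {
  x <- as.matrix(x)
  config <- fit$config
  k <- config$k
  n <- nrow(x)
  e <- encode_table(x, fit$bin_specs, fit$params$ple)
  fw <- nn_forward(fit$params, e, config, training = FALSE, keep_cache = TRUE)

  # slopes of the encoding wrt each raw feature, mapped through V:
  # dE_fd / dx_f = sum_t slope_t(x_f) V_td
  d <- fit$d_embedding
  slope_emb <- lapply(seq_along(fit$feature_names), function(f) {
    sl <- piecewise_encode_slope(x[, f], fit$bin_specs[[f]])
    sl %*% fit$params$ple[[f]]$V          # n x d
  })

  softmax_probs <- if (target == "prob") row_softmax(fw$logits) else NULL

  lapply(classes, function(cl) {
    if (target == "logit") {
      dlogits <- matrix(0, n * k, config$n_classes)
      dlogits[, cl + 1L] <- 1 / k
    } else {
      # d/dlogits of mean_j softmax_j[cl]: per member row,
      # p_cl * (1[c = cl] - p_c) / k
      p <- softmax_probs
      dlogits <- -p[, cl + 1L] * p / k
      dlogits[, cl + 1L] <- dlogits[, cl + 1L] + p[, cl + 1L] / k
    }
    de <- nn_backward(fit$params, fw, dlogits, config,
                      need_param_grads = FALSE, need_input_grad = TRUE)$dx
    g <- matrix(0, n, length(fit$feature_names))
    for (f in seq_along(fit$feature_names)) {
      cols <- (f - 1L) * d + seq_len(d)
      g[, f] <- rowSums(de[, cols, drop = FALSE] * slope_emb[[f]])
    }
    g
  })
}

#' @export
print.attribution_result <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<attribution_result> %d samples x %d features x %d classes (%s target, %d path samples)\n",
              d[1], d[2], d[3], x$target, x$n_path_samples))
  invisible(x)
}

#' @export
tidy.attribution_result <- function(x, ...) {
  d <- dim(x$values)
  tidyr::expand_grid(sample = seq_len(d[1]),
                     feature = factor(x$feature_names,
                                      levels = x$feature_names),
                     class = x$classes) |>
    dplyr::mutate(attribution = as.vector(x$values))
}

#' Rank features by mean absolute attribution
#'
#' Orders features by the mean over samples of the absolute attribution for
#' one class, descending — the ranking behind a feature-importance plot.
#' Ties keep the original feature order.
#'
#' @param result An `"attribution_result"`.
#' @param class_index 0-based class to rank (must have been attributed).
#' @return Tibble with `rank`, `feature`, `mean_abs_attribution`.
#' @export
feature_ranking <- function(result, class_index = 0) {
  ci <- match(class_index, result$classes)
  if (is.na(ci)) abort_bad_arg("class was not attributed")
  v <- result$values[, , ci, drop = FALSE]
  score <- colMeans(abs(matrix(v, dim(v)[1], dim(v)[2])))
  ord <- order(-score, seq_along(score))
  tibble::tibble(rank = seq_along(score),
                 feature = result$feature_names[ord],
                 mean_abs_attribution = unname(score[ord]))
}

#' Per-sample interaction records for two features
#'
#' The tidy records behind a dependence scatter: for each explained sample,
#' feature `a`'s value and attribution together with feature `b`'s value,
#' so the plot of attribution-vs-value coloured by the second feature
#' reveals how the two jointly move the prediction.
#'
#' @param result An `"attribution_result"`.
#' @param feature_a,feature_b Distinct feature names.
#' @param class_index 0-based class.
#' @param inputs The matrix/data frame of explained samples (same rows as
#'   were passed to [gradient_shap()]), supplying the raw values.
#' @return Tibble with `sample`, `value_a`, `value_b`, `attribution_a`.
#' @export
interaction_table <- function(result, feature_a, feature_b, class_index = 0,
                              inputs) {
  if (identical(feature_a, feature_b)) {
    abort_bad_arg("feature_a and feature_b must differ")
  }
  fa <- match(feature_a, result$feature_names)
  fb <- match(feature_b, result$feature_names)
  if (is.na(fa) || is.na(fb)) abort_bad_arg("unknown feature")
  ci <- match(class_index, result$classes)
  if (is.na(ci)) abort_bad_arg("class was not attributed")
  x <- as_feature_matrix(inputs)[, result$feature_names, drop = FALSE]
  if (nrow(x) != dim(result$values)[1]) {
    abort_bad_arg("inputs do not match the attribution result")
  }
  tibble::tibble(sample = seq_len(nrow(x)),
                 value_a = x[, fa], value_b = x[, fb],
                 attribution_a = result$values[, fa, ci])
}
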