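#' Training configuration
#'
#' Optimisation settings for the early-stopped Adam training loop. Defaults
#' follow the reference CTG configuration: learning rate 2e-3, weight decay
#' 1e-4, batch size 64, at most 50 epochs, and early stopping after 10
#' epochs without improvement of the monitored validation quantity.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to the gradients of weight matrices
#'   and bin-embedding vectors (not biases or adapters).
#' @param batch_size Minibatch size; the last partial batch is kept.
#' @param max_epochs Epoch cap.
#' @param patience Epochs without improvement before stopping (>= 1).
#' @param monitor `"val_loss"` (default) or `"val_macro_f1"`.
#' @param seed Master seed: drives parameter initialisation, per-epoch batch
#'   shuffling and dropout masks.
#' @return Object of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 2e-3, weight_decay = 1e-4,
                         batch_size = 64, max_epochs = 50, patience = 10,
                         monitor = c("val_loss", "val_macro_f1"), seed = 1) {
  monitor <- match.arg(monitor)
  if (patience < 1) abort_bad_arg("patience must be >= 1")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), monitor = monitor,
                 seed = as.integer(seed)),
            class = "train_config")
}

# One Adam step over the flat parameter list.  Weight decay is applied as an
# L2 term on leaves whose flat name ends in .W or .V.
adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L)
}

adam_step <- function(flat, gflat, state, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  decay <- grepl("\\.(W|V)$", names(flat))
  for (i in seq_along(flat)) {
    g <- gflat[[i]]
    if (wd > 0 && decay[i]) g <- g + wd * flat[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    flat[[i]] <- flat[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

#' Train the piecewise-linear-encoded ensemble classifier
#'
#' Fits the full model — per-feature learnable bin embeddings plus the
#' weight-shared MLP ensemble — by minibatch Adam on the mean ensemble
#' cross-entropy, monitoring a validation quantity for early stopping and
#' returning the parameters of the best validation epoch.
#'
#' Inputs are expected already standardized (and, for the training split,
#' typically SMOTE-balanced); bins are expected built on the standardized
#' training features before oversampling. [run_pipeline()] wires these
#' stages together in the canonical order.
#'
#' @param x_train,y_train Training features (matrix or data frame, encoded
#'   scale = standardized) and integer labels `0..n_classes-1`.
#' @param x_val,y_val Validation features and labels (used for early
#'   stopping; never trained on).
#' @param bin_specs Per-feature bins from [build_bin_specs()].
#' @param config A [tabm_config()]; `input_width` is derived from the data
#'   and `d_embedding`, so it may be left at its default.
#' @param train_cfg A [train_config()].
#' @param d_embedding Embedding dimension of the piecewise encoding.
#' @param label Label column name dropped when feature inputs are data frames.
#' @return Object of class `"tabm_fit"`: trained `params` (with `$ple`,
#'   `$blocks`, `$heads`), `bin_specs`, `config`, `train_config`,
#'   `feature_names`, `n_classes`, `history` (a tibble), `best_epoch`.
#' @export
tabm_train <- function(x_train, y_train, x_val, y_val, bin_specs,
                       config = tabm_config(), train_cfg = train_config(),
                       d_embedding = 8, label = "NSP") {
  xt <- as_feature_matrix(x_train, label = label)
  xv <- as_feature_matrix(x_val, label = label)
  if (nrow(xt) == 0 || nrow(xv) == 0) abort_bad_arg("empty split")
  y_train <- check_labels(y_train, config$n_classes)
  y_val <- check_labels(y_val, config$n_classes)
  if (length(unique(y_train)) < config$n_classes) {
    abort_bad_arg("training labels must cover all classes")
  }
  feats <- names(bin_specs)
  xt <- xt[, feats, drop = FALSE]
  xv <- xv[, feats, drop = FALSE]

  config$input_width <- length(feats) * as.integer(d_embedding)
  seed <- train_cfg$seed
  ple <- init_ple_params(bin_specs, d_embedding = d_embedding,
                         seed = stage_seed(seed, "init"))
  tp <- init_tabm_params(config, seed = stage_seed(seed, "init") + 1L)
  params <- list(ple = unclass(ple), blocks = tp$blocks, heads = tp$heads)

  pe_train <- precompute_pe(xt, bin_specs)
  pe_val <- precompute_pe(xv, bin_specs)

  flat <- flatten_params(params)
  skeleton <- params
  opt <- adam_init(flat)
  n <- nrow(xt)
  k <- config$k

  eval_monitor <- function(params) {
    ev <- embed_from_pe(pe_val, params$ple)
    fw <- nn_forward(params, ev, config, training = FALSE)
    logits3 <- flat_to_a3(fw$logits, nrow(ev), k)
    loss <- ensemble_loss(logits3, y_val)
    probs <- predict_proba(logits3)
    pred <- max.col(probs, ties.method = "first") - 1L
    mr <- suppressWarnings(
      metrics_from_confusion(confusion_matrix(y_val, pred, config$n_classes)))
    list(loss = loss, accuracy = mr$accuracy,
         precision = mr$macro_precision, recall = mr$macro_recall,
         f1 = mr$macro_f1)
  }

  history <- list()
  best_val <- Inf
  best_flat <- flat
  best_epoch <- 0L
  since_improve <- 0L

  for (epoch in seq_len(train_cfg$max_epochs)) {
    # per-epoch RNG stream derived from the master seed: shuffling + dropout
    set.seed(as.integer((seed + 7919 * epoch) %% 2147483587))
    params <- unflatten_params(flat, skeleton)
    perm <- sample.int(n)
    batch_starts <- seq(1L, n, by = train_cfg$batch_size)
    epoch_loss <- 0
    for (bs in batch_starts) {
      rows <- perm[bs:min(bs + train_cfg$batch_size - 1L, n)]
      m <- length(rows)
      e <- embed_from_pe(pe_train, params$ple, rows)
      fw <- nn_forward(params, e, config, training = TRUE, keep_cache = TRUE)
      p <- row_softmax(fw$logits)
      yf <- rep(y_train[rows], each = k)
      rowsel <- cbind(seq_len(m * k), yf + 1L)
      batch_loss <- -mean(log(pmax(p[rowsel], 1e-300)))
      if (!is.finite(batch_loss)) {
        abort_bad_arg(sprintf("non-finite loss at epoch %d", epoch))
      }
      epoch_loss <- epoch_loss + batch_loss * m
      dlogits <- p
      dlogits[rowsel] <- dlogits[rowsel] - 1
      dlogits <- dlogits / (m * k)
      bw <- nn_backward(params, fw, dlogits, config,
                        need_param_grads = TRUE, need_input_grad = TRUE)
      gple <- lapply(seq_along(pe_train), function(f) {
        d <- ncol(params$ple[[f]]$V)
        cols <- (f - 1L) * d + seq_len(d)
        dxf <- bw$dx[, cols, drop = FALSE]
        pef <- pe_train[[f]][rows, , drop = FALSE]
        list(V = crossprod(pef, dxf), b = colSums(dxf))
      })
      names(gple) <- names(params$ple)
      grads <- list(ple = gple, blocks = bw$grads$blocks, heads = bw$grads$heads)
      gflat <- flatten_params(grads)
      step <- adam_step(flat, gflat, opt,
                        lr = train_cfg$learning_rate,
                        wd = train_cfg$weight_decay)
      flat <- step$flat
      opt <- step$state
      params <- unflatten_params(flat, skeleton)
    }
    train_loss <- epoch_loss / n

    val <- eval_monitor(params)
    monitored <- if (train_cfg$monitor == "val_loss") val$loss else -val$f1
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = train_loss, val_loss = val$loss,
      val_accuracy = val$accuracy, val_precision = val$precision,
      val_recall = val$recall, val_f1 = val$f1)
    if (monitored < best_val - 1e-12) {
      best_val <- monitored
      best_flat <- flat
      best_epoch <- epoch
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= train_cfg$patience) break
    }
  }

  params <- unflatten_params(best_flat, skeleton)
  structure(list(params = params, bin_specs = bin_specs, config = config,
                 train_config = train_cfg,
                 d_embedding = as.integer(d_embedding),
                 feature_names = feats, n_classes = config$n_classes,
                 history = dplyr::bind_rows(history),
                 best_epoch = best_epoch, standardizer = NULL,
                 classes = seq_len(config$n_classes) - 1L),
            class = "tabm_fit")
}

#' @export
print.tabm_fit <- function(x, ...) {
  cat(sprintf(paste0("<tabm_fit> %d features, k = %d members, %d blocks, ",
                     "hidden %d, d = %d\n  trained %d epochs (best %d)\n"),
              length(x$feature_names), x$config$k, x$config$n_blocks,
              x$config$hidden_width, x$d_embedding, nrow(x$history),
              x$best_epoch))
  invisible(x)
}

# Forward from raw (standardized-scale) features through encoding + ensemble.
model_logits <- function(fit, x, label = "NSP") {
  x <- as_feature_matrix(x, label = label)
  e <- encode_table(x[, fit$feature_names, drop = FALSE], fit$bin_specs,
                    fit$params$ple)
  tabm_forward(e, fit$params, fit$config, mode = "eval")
}

#' Predict from a fitted model
#'
#' @param object A `"tabm_fit"`.
#' @param newdata Features on the scale the model was trained on; if the fit
#'   carries a standardizer (pipeline fits do), raw-scale features are
#'   standardized first.
#' @param type `"class"` (argmax of averaged member probabilities, ties
#'   toward the lower class index), `"prob"`, or `"logits"` (the rank-3
#'   member logits array).
#' @param ... Unused.
#' @return Integer classes, a probability matrix, or a logits array.
#' @export
predict.tabm_fit <- function(object, newdata, type = c("class", "prob", "logits"),
                             label = "NSP", ...) {
  type <- match.arg(type)
  if (!is.null(object$standardizer)) {
    newdata <- apply_standardizer(
      as.data.frame(as_feature_matrix(newdata, label = label))[
        , object$standardizer$feature_names, drop = FALSE],
      object$standardizer)
  }
  logits <- model_logits(object, newdata, label = label)
  if (type == "logits") return(logits)
  probs <- predict_proba(logits)
  if (type == "prob") return(probs)
  max.col(probs, ties.method = "first") - 1L
}

confusion_matrix <- function(truth, pred, n_classes) {
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth)) {
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  cm
}

#' Multiclass metrics from a confusion matrix
#'
#' Computes per-class precision (column diagonal over column sum), recall
#' (diagonal over row sum), F1 (harmonic mean) and support, together with
#' accuracy, unweighted macro averages, and balanced accuracy (the mean of
#' per-class recalls). Rows index the true class, columns the prediction.
#' A zero denominator yields 0 with a warning.
#'
#' @param confusion Square matrix of non-negative integer counts,
#'   rows = truth, columns = predicted.
#' @param class_names Optional class display names; defaults to
#'   normal/suspect/pathological for 3 classes.
#' @return Object of class `"metrics_report"`.
#' @export
#' @examples
#' m <- rbind(c(160, 6, 0), c(2, 27, 0), c(1, 0, 17))
#' r <- metrics_from_confusion(m)
#' round(c(r$accuracy, r$macro_f1, r$balanced_accuracy), 4)
metrics_from_confusion <- function(confusion, class_names = NULL) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm) || any(cm < 0)) {
    abort_bad_arg("confusion must be a square matrix of non-negative counts")
  }
  if (sum(cm) == 0) abort_bad_arg("all-zero confusion matrix")
  nc <- nrow(cm)
  if (is.null(class_names)) {
    class_names <- if (nc == 3) c("normal", "suspect", "pathological")
                   else paste0("class", seq_len(nc) - 1L)
  }
  safe_div <- function(num, den) {
    out <- ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
    if (any(den == 0)) {
      warning("zero denominator in precision/recall; reporting 0", call. = FALSE)
    }
    out
  }
  support <- unname(rowSums(cm))
  precision <- unname(safe_div(diag(cm), colSums(cm)))
  recall <- unname(safe_div(diag(cm), support))
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(
    confusion = cm,
    per_class = tibble::tibble(class = class_names, precision = precision,
                               recall = recall, f1 = f1,
                               support = as.integer(support)),
    accuracy = sum(diag(cm)) / sum(cm),
    macro_precision = mean(precision),
    macro_recall = mean(recall),
    macro_f1 = mean(f1),
    balanced_accuracy = mean(recall)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("Confusion matrix (rows = truth, cols = predicted):\n")
  cm <- x$confusion
  dimnames(cm) <- list(x$per_class$class, x$per_class$class)
  print(cm)
  cat("\nPer-class metrics:\n")
  print(as.data.frame(x$per_class), digits = digits, row.names = FALSE)
  cat(sprintf(paste0("\nAccuracy: %.*f  Macro precision: %.*f  ",
                     "Macro recall: %.*f  Macro F1: %.*f\n",
                     "Balanced accuracy: %.*f\n"),
              digits, x$accuracy, digits, x$macro_precision,
              digits, x$macro_recall, digits, x$macro_f1,
              digits, x$balanced_accuracy))
  invisible(x)
}

#' Evaluate a fitted model on labelled data
#'
#' Predicts with the averaged member probabilities and summarises the result
#' as a [metrics_from_confusion()] report.
#'
#' @param fit A `"tabm_fit"`.
#' @param x Features (standardized scale unless the fit carries a
#'   standardizer).
#' @param y Integer labels `0..n_classes-1`.
#' @return A `"metrics_report"`.
#' @export
evaluate_model <- function(fit, x, y, label = "NSP") {
  y <- check_labels(y, fit$n_classes)
  xm <- as_feature_matrix(x, label = label)
  if (nrow(xm) != length(y)) abort_bad_arg("feature/label length mismatch")
  pred <- predict(fit, xm, type = "class", label = label)
  metrics_from_confusion(confusion_matrix(y, pred, fit$n_classes))
}

#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall, macro_f1 = x$macro_f1,
                 balanced_accuracy = x$balanced_accuracy,
                 n = sum(x$confusion))
}

#' @export
tidy.tabm_fit <- function(x, ...) x$history

#' @export
glance.tabm_fit <- function(x, ...) {
  best <- x$history[x$history$epoch == x$best_epoch, ]
  tibble::tibble(n_epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_loss = best$val_loss, best_val_f1 = best$val_f1,
                 k = x$config$k, n_blocks = x$config$n_blocks,
                 hidden_width = x$config$hidden_width,
                 d_embedding = x$d_embedding)
}
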