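#' Full pipeline configuration
#'
#' One configuration object covering every stage of the canonical pipeline:
#' split, standardize, SMOTE, piecewise-linear encoding, ensemble
#' architecture, training and attribution. Defaults reproduce the reference
#' CTG setup (Adam, weight decay 1e-4, dropout 0.1, batch 64, patience 10,
#' learning rate 2e-3, k = 32, 24 bins, 2 blocks, embedding dimension 8).
#'
#' @param fractions Train/validation/test fractions summing to 1.
#' @param stratify Stratify the split by class (default `FALSE`).
#' @param standardize_mode `"train"` (fit on the training split, apply to
#'   all: the leakage-free reading, default) or `"per_set"` (fit each split
#'   on itself: the literal per-set reading).
#' @param smote List: `enabled`, `k_neighbors`, `target_count` (`NULL` =
#'   majority-class training count).
#' @param ple List: `t_bins`, `d_embedding`, `method`
#'   (`"quantile"`/`"uniform"`).
#' @param tabm List: `k`, `n_blocks`, `hidden_width`, `dropout_rate`.
#' @param train List: `learning_rate`, `weight_decay`, `batch_size`,
#'   `max_epochs`, `patience`, `monitor`.
#' @param attribution List: `enabled`, `n_path_samples`, `n_background`,
#'   `n_inputs` (cap on explained test samples), `target`.
#' @param label Label column name.
#' @param seed Master seed; each stage derives its own seed from it.
#' @return Object of class `"plectabm_config"`.
#' @export
plectabm_config <- function(fractions = c(0.8, 0.1, 0.1), stratify = FALSE,
                            standardize_mode = c("train", "per_set"),
                            smote = list(), ple = list(), tabm = list(),
                            train = list(), attribution = list(),
                            label = "NSP", seed = 1) {
  standardize_mode <- match.arg(standardize_mode)
  merge_defaults <- function(user, defaults) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad) > 0) {
      abort_bad_arg(paste0("unknown config field(s): ",
                           paste(bad, collapse = ", ")))
    }
    utils::modifyList(defaults, user)
  }
  cfg <- structure(list(
    fractions = fractions, stratify = stratify,
    standardize_mode = standardize_mode,
    smote = merge_defaults(smote, list(enabled = TRUE, k_neighbors = 5,
                                       target_count = NULL)),
    ple = merge_defaults(ple, list(t_bins = 24, d_embedding = 8,
                                   method = "quantile")),
    tabm = merge_defaults(tabm, list(k = 32, n_blocks = 2, hidden_width = 128,
                                     dropout_rate = 0.1)),
    train = merge_defaults(train, list(learning_rate = 2e-3,
                                       weight_decay = 1e-4, batch_size = 64,
                                       max_epochs = 50, patience = 10,
                                       monitor = "val_loss")),
    attribution = merge_defaults(attribution,
                                 list(enabled = TRUE, n_path_samples = 256,
                                      n_background = 512, n_inputs = 64,
                                      target = "logit")),
    label = label, seed = as.integer(seed)), class = "plectabm_config")
  # validate early, before any stage runs
  if (length(cfg$fractions) != 3 || abs(sum(cfg$fractions) - 1) > 1e-8) {
    abort_bad_arg("fractions must be three numbers that sum to 1")
  }
  if (cfg$smote$k_neighbors < 1) abort_bad_arg("smote$k_neighbors must be >= 1")
  if (cfg$ple$t_bins < 1) abort_bad_arg("ple$t_bins must be >= 1")
  invisible(tabm_config(k = cfg$tabm$k, n_blocks = cfg$tabm$n_blocks,
                        hidden_width = cfg$tabm$hidden_width,
                        dropout_rate = cfg$tabm$dropout_rate))
  invisible(train_config(learning_rate = cfg$train$learning_rate,
                         weight_decay = cfg$train$weight_decay,
                         batch_size = cfg$train$batch_size,
                         max_epochs = cfg$train$max_epochs,
                         patience = cfg$train$patience,
                         monitor = cfg$train$monitor))
  cfg
}

#' Run the full classification pipeline
#'
#' Executes the canonical stage order on a labelled feature table: split
#' into train/validation/test, standardize with training-set statistics,
#' build the encoding bins on the standardized training features, SMOTE the
#' training split to balance, train the early-stopped ensemble, evaluate on
#' the held-out test split, and (optionally) compute Gradient SHAP
#' attributions for a test subsample against the training background. Every
#' stage seed derives from the master seed, so a fixed seed reproduces the
#' run exactly.
#'
#' @param data Labelled feature table (e.g. from [read_ctg()] or
#'   [simulate_ctg()]), or the string `"simulate"` to generate the default
#'   synthetic table first.
#' @param config A [plectabm_config()].
#' @return Object of class `"plectabm_run"`: `fit` (with the standardizer
#'   attached), `split`, `standardizer`, `metrics` (test-set
#'   `"metrics_report"`), `history`, `attribution` (or `NULL`), `config`,
#'   `config_hash`, `seed`.
#' @export
run_pipeline <- function(data, config = plectabm_config()) {
  seed <- config$seed
  if (is.character(data) && identical(data, "simulate")) {
    data <- simulate_ctg(ctg_synthetic_spec(seed = stage_seed(seed, "simulate")))
  }
  label <- config$label
  if (!label %in% names(data)) abort_bad_arg("label column not found in data")
  y <- check_labels(data[[label]])
  n_classes <- max(y) + 1L
  x <- as_feature_matrix(data, label = label)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage,
                           conditionMessage(e)), class = "plectabm_error")
    })
  }

  split <- run_stage("split", split_dataset(
    nrow(x), fractions = config$fractions, seed = stage_seed(seed, "split"),
    stratify = config$stratify, labels = y))

  std <- run_stage("standardize", fit_standardizer(x[split$train, , drop = FALSE]))
  standardize <- function(rows) {
    if (config$standardize_mode == "per_set" && !identical(rows, split$train)) {
      local_std <- fit_standardizer(x[rows, , drop = FALSE])
      as.matrix(apply_standardizer(x[rows, , drop = FALSE], local_std))
    } else {
      as.matrix(apply_standardizer(x[rows, , drop = FALSE], std))
    }
  }
  xt <- standardize(split$train)
  xv <- standardize(split$validation)
  xs <- standardize(split$test)
  yt <- y[split$train]
  yv <- y[split$validation]
  ys <- y[split$test]

  # bins on real (pre-SMOTE) standardized training samples
  bin_specs <- run_stage("bins", build_bin_specs(
    xt, t_bins = config$ple$t_bins, method = config$ple$method))

  if (isTRUE(config$smote$enabled)) {
    aug <- run_stage("smote", smote_oversample(
      as.data.frame(xt), labels = yt, k_neighbors = config$smote$k_neighbors,
      target_count = config$smote$target_count,
      seed = stage_seed(seed, "smote"), label = label))
    yt_aug <- aug[[label]]
    xt_aug <- as_feature_matrix(aug, label = label)
  } else {
    xt_aug <- xt
    yt_aug <- yt
  }

  tcfg <- tabm_config(k = config$tabm$k, n_blocks = config$tabm$n_blocks,
                      hidden_width = config$tabm$hidden_width,
                      dropout_rate = config$tabm$dropout_rate,
                      n_classes = n_classes)
  trcfg <- train_config(learning_rate = config$train$learning_rate,
                        weight_decay = config$train$weight_decay,
                        batch_size = config$train$batch_size,
                        max_epochs = config$train$max_epochs,
                        patience = config$train$patience,
                        monitor = config$train$monitor,
                        seed = stage_seed(seed, "train"))
  fit <- run_stage("train", tabm_train(
    xt_aug, yt_aug, xv, yv, bin_specs = bin_specs, config = tcfg,
    train_cfg = trcfg, d_embedding = config$ple$d_embedding, label = label))
  fit$standardizer <- NULL   # inputs below are already standardized

  metrics <- run_stage("evaluate",
                       suppressWarnings(evaluate_model(fit, xs, ys)))

  attribution <- NULL
  if (isTRUE(config$attribution$enabled)) {
    n_inputs <- min(config$attribution$n_inputs, nrow(xs))
    attribution <- run_stage("explain", gradient_shap(
      fit, xs[seq_len(n_inputs), , drop = FALSE], background = xt,
      n_path_samples = config$attribution$n_path_samples,
      n_background = config$attribution$n_background,
      target = config$attribution$target,
      seed = stage_seed(seed, "shap")))
  }

  fit$standardizer <- std    # so predict() accepts raw-scale features
  structure(list(fit = fit, split = split, standardizer = std,
                 metrics = metrics, history = fit$history,
                 attribution = attribution, config = config,
                 config_hash = rlang::hash(config), seed = seed),
            class = "plectabm_run")
}

#' @export
print.plectabm_run <- function(x, ...) {
  cat(sprintf("<plectabm_run> seed %d, config %s\n", x$seed,
              substr(x$config_hash, 1, 8)))
  cat(sprintf("  splits %d/%d/%d; trained %d epochs (best %d)\n",
              length(x$split$train), length(x$split$validation),
              length(x$split$test), nrow(x$history), x$fit$best_epoch))
  cat(sprintf("  test accuracy %.4f, macro F1 %.4f, balanced accuracy %.4f\n",
              x$metrics$accuracy, x$metrics$macro_f1,
              x$metrics$balanced_accuracy))
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' Deterministic JSON for a `"metrics_report"`: the confusion matrix,
#' per-class metrics and overall summary at full precision, so identical
#' runs produce byte-identical files.
#'
#' @param report A `"metrics_report"`.
#' @param path Optional file to write; with `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
metrics_to_json <- function(report, path = NULL) {
  payload <- list(
    confusion = report$confusion,
    per_class = report$per_class,
    accuracy = report$accuracy,
    macro_precision = report$macro_precision,
    macro_recall = report$macro_recall,
    macro_f1 = report$macro_f1,
    balanced_accuracy = report$balanced_accuracy)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

# --- checkpointing: JSON manifest with numeric payloads (dims preserved) ---

pack_array <- function(a) {
  if (is.matrix(a)) list(dim = dim(a), data = as.vector(a))
  else list(dim = length(a), data = as.vector(a))
}

unpack_array <- function(p) {
  d <- unlist(p$dim)
  v <- as.numeric(unlist(p$data))
  if (length(d) == 2) matrix(v, d[1], d[2]) else v
}

#' Save a fitted model checkpoint
#'
#' Writes everything needed to restore predictions — configuration, bin
#' boundaries, encoding and ensemble parameters, the standardizer if
#' attached, and training metadata — as a single JSON file.
#'
#' @param fit A `"tabm_fit"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  pack_tree <- function(x) {
    if (is.numeric(x)) pack_array(x) else lapply(x, pack_tree)
  }
  payload <- list(
    format = "plectabm-checkpoint-1",
    config = unclass(fit$config),
    train_config = unclass(fit$train_config),
    d_embedding = fit$d_embedding,
    feature_names = fit$feature_names,
    n_classes = fit$n_classes,
    best_epoch = fit$best_epoch,
    bin_specs = lapply(fit$bin_specs, as.numeric),
    params = pack_tree(fit$params),
    standardizer = if (!is.null(fit$standardizer)) {
      list(mean = as.numeric(fit$standardizer$mean),
           scale = as.numeric(fit$standardizer$scale),
           constant = fit$standardizer$constant,
           feature_names = fit$standardizer$feature_names)
    },
    history = fit$history)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return A `"tabm_fit"` ready for [predict.tabm_fit()],
#'   [evaluate_model()] and [gradient_shap()].
#' @export
load_checkpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "plectabm-checkpoint-1")) {
    abort_bad_arg("not a plectabm checkpoint")
  }
  unpack_tree <- function(x) {
    if (is.list(x) && setequal(names(x), c("dim", "data"))) unpack_array(x)
    else lapply(x, unpack_tree)
  }
  cfg <- do.call(tabm_config, p$config[c("k", "n_blocks", "hidden_width",
                                         "dropout_rate", "n_classes",
                                         "input_width")])
  std <- NULL
  if (length(p$standardizer) > 0) {
    fn <- unlist(p$standardizer$feature_names)
    std <- structure(list(
      mean = stats::setNames(as.numeric(unlist(p$standardizer$mean)), fn),
      scale = stats::setNames(as.numeric(unlist(p$standardizer$scale)), fn),
      constant = stats::setNames(as.logical(unlist(p$standardizer$constant)), fn),
      feature_names = fn), class = "standardizer")
  }
  history <- dplyr::bind_rows(lapply(p$history, tibble::as_tibble))
  structure(list(
    params = unpack_tree(p$params),
    bin_specs = lapply(p$bin_specs,
                       function(b) structure(as.numeric(unlist(b)),
                                             class = "bin_spec")),
    config = cfg,
    train_config = do.call(train_config, p$train_config),
    d_embedding = as.integer(p$d_embedding),
    feature_names = unlist(p$feature_names),
    n_classes = as.integer(p$n_classes),
    history = history,
    best_epoch = as.integer(p$best_epoch),
    standardizer = std,
    classes = seq_len(as.integer(p$n_classes)) - 1L),
    class = "tabm_fit")
}
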