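# Independent oracles and shared fixtures for the test suite.
# Oracles are deliberately naive (loops, direct formulas) and never call the
# code paths they check.

# Naive per-member ensemble linear: loop over members, W(r_i * x_i) + b_i.
naive_ensemble_linear <- function(x, W, adapters, biases) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2], nrow(W)))
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      out[i, j, ] <- as.vector(W %*% (adapters[j, ] * x[i, j, ])) + biases[j, ]
    }
  }
  out
}

# Plain single MLP, coded independently: dense layers, ReLU between, none
# after the last hidden layer; returns logits.
plain_mlp_logits <- function(x, weights, biases, head_w, head_b) {
  h <- x
  for (l in seq_along(weights)) {
    h <- h %*% t(weights[[l]])
    h <- sweep(h, 2L, biases[[l]], "+")
    h[h < 0] <- 0
  }
  sweep(h %*% t(head_w), 2L, head_b, "+")
}

# Order-statistic quantile: inverse ECDF on the sorted vector.
order_stat_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) s[max(1L, ceiling(pp * n))], numeric(1))
}

# Per-sample counting metrics from raw truth/prediction vectors.
counting_metrics <- function(truth, pred, n_classes = 3) {
  cls <- seq_len(n_classes) - 1L
  precision <- vapply(cls, function(c) {
    denom <- sum(pred == c)
    if (denom == 0) 0 else sum(truth == c & pred == c) / denom
  }, numeric(1))
  recall <- vapply(cls, function(c) {
    denom <- sum(truth == c)
    if (denom == 0) 0 else sum(truth == c & pred == c) / denom
  }, numeric(1))
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(accuracy = mean(truth == pred),
       macro_precision = mean(precision), macro_recall = mean(recall),
       macro_f1 = mean(f1), balanced_accuracy = mean(recall),
       precision = precision, recall = recall, f1 = f1)
}

# A hand-built fit that is exactly linear over the tested input range:
# identity piecewise encoding (single bin over [-50, 50], d = 1, V chosen so
# the embedding equals the raw value), one block whose large positive biases
# keep every ReLU in its linear region, and heads holding the target weights.
make_linear_fit <- function(w = c(2, -1), offset = 500) {
  nf <- length(w)
  feature_names <- paste0("f", seq_len(nf))
  bins <- lapply(feature_names, function(f) {
    structure(c(-50, 50), class = "bin_spec")
  })
  names(bins) <- feature_names
  ple <- lapply(seq_len(nf), function(f) {
    list(V = matrix(100, 1, 1), b = -50)  # emb = -50 + (x+50)/100*100 = x
  })
  names(ple) <- feature_names
  cfg <- tabm_config(k = 1, n_blocks = 1, hidden_width = nf,
                     dropout_rate = 0, n_classes = 2, input_width = nf)
  blocks <- list(list(W = diag(nf),
                      adapters = matrix(1, 1, nf),
                      biases = matrix(offset, 1, nf)))
  # class-0 logit carries w (the offset contributes only a constant)
  heads <- list(list(W = rbind(w, -w), b = c(0, 0)))
  structure(list(params = list(ple = ple, blocks = blocks, heads = heads),
                 bin_specs = bins, config = cfg, d_embedding = 1L,
                 feature_names = feature_names, n_classes = 2L,
                 standardizer = NULL, classes = 0:1),
            class = "tabm_fit")
}

# Small trained model on synthetic data, built once and reused.
.fixture_cache <- new.env(parent = emptyenv())

small_trained_fit <- function() {
  if (!is.null(.fixture_cache$small_fit)) return(.fixture_cache$small_fit)
  cfg <- plectabm_config(
    tabm = list(k = 4, hidden_width = 24, n_blocks = 2, dropout_rate = 0.1),
    ple = list(t_bins = 8, d_embedding = 4),
    train = list(max_epochs = 12, batch_size = 64),
    attribution = list(enabled = FALSE),
    seed = 11)
  d <- simulate_ctg(ctg_synthetic_spec(n_samples = 500), seed = 11)
  run <- suppressWarnings(run_pipeline(d, cfg))
  .fixture_cache$small_fit <- run
  run
}
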