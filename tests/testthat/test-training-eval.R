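make_toy_splits <- function(n = 240, seed = 1, proportions = c(0.778, 0.142, 0.080)) {
  d <- simulate_ctg(ctg_synthetic_spec(n_samples = n,
                                       class_proportions = proportions),
                    seed = seed)
  s <- split_dataset(nrow(d), c(0.7, 0.15, 0.15),
                     seed = seed, stratify = TRUE, labels = d$NSP)
  std <- fit_standardizer(d[s$train, ])
  list(xt = as.matrix(apply_standardizer(d[s$train, ], std)[, 1:21]),
       yt = d$NSP[s$train],
       xv = as.matrix(apply_standardizer(d[s$validation, ], std)[, 1:21]),
       yv = d$NSP[s$validation],
       xs = as.matrix(apply_standardizer(d[s$test, ], std)[, 1:21]),
       ys = d$NSP[s$test])
}

toy_fit <- function(splits, max_epochs = 6, seed = 5, patience = 10,
                    lr = 2e-3) {
  bins <- suppressWarnings(build_bin_specs(splits$xt, t_bins = 6))
  suppressWarnings(tabm_train(
    splits$xt, splits$yt, splits$xv, splits$yv, bins,
    config = tabm_config(k = 3, n_blocks = 2, hidden_width = 12,
                         dropout_rate = 0.1),
    train_cfg = train_config(max_epochs = max_epochs, patience = patience,
                             learning_rate = lr, seed = seed),
    d_embedding = 3))
}

test_that("training is reproducible and returns the best-epoch parameters", {
  sp <- make_toy_splits()
  f1 <- toy_fit(sp)
  f2 <- toy_fit(sp)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_lte(nrow(f1$history), 6)
  expect_equal(f1$best_epoch,
               f1$history$epoch[which.min(f1$history$val_loss)])
  # loss should move downward on this easy problem
  expect_lt(f1$history$train_loss[nrow(f1$history)], f1$history$train_loss[1])
})

test_that("a zero learning rate cannot improve, so training stops at 1 + patience", {
  sp <- make_toy_splits(n = 150, seed = 3)
  f <- toy_fit(sp, max_epochs = 40, patience = 4, lr = 0)
  expect_equal(nrow(f$history), 1 + 4)
  expect_equal(f$best_epoch, 1)
})

test_that("the early-stop rule is respected in the history", {
  sp <- make_toy_splits(n = 200, seed = 9)
  f <- toy_fit(sp, max_epochs = 30, patience = 3)
  mon <- f$history$val_loss
  best_so_far <- cummin(mon)
  run_len <- 0
  for (i in seq_along(mon)) {
    if (i > 1 && mon[i] >= best_so_far[i - 1] - 1e-12) {
      run_len <- run_len + 1
    } else {
      run_len <- 0
    }
    expect_lte(run_len, 3)
  }
  if (nrow(f$history) < 30) expect_equal(run_len, 3)
})

test_that("training errors on invalid inputs", {
  sp <- make_toy_splits(n = 150, seed = 2)
  bins <- suppressWarnings(build_bin_specs(sp$xt, t_bins = 4))
  expect_error(tabm_train(sp$xt[0, ], integer(0), sp$xv, sp$yv, bins),
               "empty")
  only2 <- sp$yt
  only2[only2 == 2L] <- 1L
  expect_error(suppressWarnings(
    tabm_train(sp$xt, only2, sp$xv, sp$yv, bins,
               config = tabm_config(k = 2, hidden_width = 8))),
    "cover all classes")
})

test_that("a trained model beats the majority baseline by a wide margin", {
  # balanced classes so the majority baseline is ~1/3 and the margin can be
  # assessed without the imbalance ceiling
  sp <- make_toy_splits(n = 450, seed = 21, proportions = rep(1, 3) / 3)
  f <- toy_fit(sp, max_epochs = 25, seed = 2)
  rep <- suppressWarnings(evaluate_model(f, sp$xs, sp$ys))
  majority <- max(table(sp$ys)) / length(sp$ys)
  expect_gte(rep$accuracy, majority + 0.25)
})

test_that("evaluation metrics match a per-sample counting oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(50:1000, 1)
    truth <- sample(0:2, n, replace = TRUE, prob = c(0.6, 0.25, 0.15))
    pred <- ifelse(runif(n) < 0.7, truth, sample(0:2, n, replace = TRUE))
    cm <- unclass(table(factor(truth, 0:2), factor(pred, 0:2)))
    r <- suppressWarnings(metrics_from_confusion(cm))
    o <- counting_metrics(truth, pred)
    expect_equal(r$accuracy, o$accuracy, tolerance = 1e-12)
    expect_equal(r$macro_precision, o$macro_precision, tolerance = 1e-12)
    expect_equal(r$macro_recall, o$macro_recall, tolerance = 1e-12)
    expect_equal(r$macro_f1, o$macro_f1, tolerance = 1e-12)
    expect_equal(r$balanced_accuracy, o$balanced_accuracy, tolerance = 1e-12)
    expect_equal(r$per_class$precision, o$precision, tolerance = 1e-12)
    expect_equal(r$per_class$f1, o$f1, tolerance = 1e-12)
  }
})

test_that("metrics handle perfect, degenerate and zero-division cases", {
  perfect <- metrics_from_confusion(diag(c(5, 5, 5)))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$f1 == 1))

  # all-one-class predictor on balanced classes
  all0 <- matrix(0, 3, 3); all0[, 1] <- c(10, 10, 10)
  r <- suppressWarnings(metrics_from_confusion(all0))
  expect_equal(r$balanced_accuracy, 1 / 3)
  expect_warning(metrics_from_confusion(all0), "zero denominator")

  # always-wrong two-class style predictor: no division error, zeros reported
  wrong <- rbind(c(0, 5, 0), c(5, 0, 0), c(0, 0, 0))
  rw <- suppressWarnings(metrics_from_confusion(wrong))
  expect_equal(rw$accuracy, 0)
  expect_true(all(rw$per_class$precision == 0))
  expect_error(metrics_from_confusion(matrix(0, 3, 3)), "all-zero")
})

test_that("tidy and glance expose per-class and overall summaries", {
  m <- rbind(c(160, 6, 0), c(2, 27, 0), c(1, 0, 17))
  r <- metrics_from_confusion(m)
  td <- tidy(r)
  expect_equal(td$class, c("normal", "suspect", "pathological"))
  expect_equal(td$support, c(166L, 29L, 18L))
  gl <- glance(r)
  expect_equal(gl$n, 213)
  expect_equal(gl$accuracy, r$accuracy)
})

test_that("checkpoints round-trip predictions through JSON", {
  sp <- make_toy_splits(n = 150, seed = 13)
  f <- toy_fit(sp, max_epochs = 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(f, path)
  g <- load_checkpoint(path)
  expect_equal(predict(g, sp$xs, type = "prob"),
               predict(f, sp$xs, type = "prob"), tolerance = 1e-8)
  expect_equal(g$feature_names, f$feature_names)
  expect_equal(g$best_epoch, f$best_epoch)
})
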