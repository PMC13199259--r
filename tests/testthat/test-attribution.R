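test_that("attribution is exactly zero when the input equals the background", {
  fit <- make_linear_fit(w = c(2, -1, 0.5))
  x <- matrix(c(1, 1, -2), 1, 3, dimnames = list(NULL, fit$feature_names))
  res <- gradient_shap(fit, x, background = x, n_path_samples = 8, seed = 1)
  expect_true(all(res$values == 0))
})

test_that("attribution is exact on a linear model for any sampling budget", {
  w <- c(2, -1)
  fit <- make_linear_fit(w = w)
  x <- matrix(c(1, 1), 1, 2, dimnames = list(NULL, fit$feature_names))
  bg <- matrix(c(0, 0), 1, 2, dimnames = list(NULL, fit$feature_names))
  for (s in c(1, 4, 64)) {
    res <- gradient_shap(fit, x, background = bg, n_path_samples = s,
                         classes = 0L, seed = s)
    expect_equal(unname(res$values[1, , 1]), c(2, -1), tolerance = 1e-10)
  }
  # multiple baselines: attribution_i = w_i * (x_i - mean(bg_i)) in expectation,
  # and exactly for a linear model since the gradient is constant
  set.seed(2)
  bg2 <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, fit$feature_names))
  res2 <- gradient_shap(fit, x, background = bg2, n_path_samples = 2000,
                        classes = 0L, seed = 3)
  # completeness holds against the sampled background mean within MC error
  gap <- sum(res2$values[1, , 1]) -
    (res2$prediction[1, 1] - res2$baseline_expectation[1])
  expect_lt(abs(gap), 0.05)
})

test_that("attributions are seeded-deterministic", {
  run <- small_trained_fit()
  fit <- run$fit
  d <- simulate_ctg(ctg_synthetic_spec(n_samples = 40), seed = 3)
  x <- as.matrix(apply_standardizer(d, run$standardizer)[, 1:21])
  bg <- x[1:20, ]
  a <- gradient_shap(fit, x[21:25, ], bg, n_path_samples = 32, seed = 5)
  b <- gradient_shap(fit, x[21:25, ], bg, n_path_samples = 32, seed = 5)
  expect_identical(a$values, b$values)
  c2 <- gradient_shap(fit, x[21:25, ], bg, n_path_samples = 32, seed = 6)
  expect_false(identical(a$values, c2$values))
})

test_that("completeness tightens with the sampling budget on a trained model", {
  run <- small_trained_fit()
  fit <- run$fit
  d <- simulate_ctg(ctg_synthetic_spec(n_samples = 80), seed = 17)
  x <- as.matrix(apply_standardizer(d, run$standardizer)[, 1:21])
  bg <- x[1:60, ]
  inputs <- x[61:64, ]
  gap_for <- function(s) {
    res <- gradient_shap(fit, inputs, bg, n_path_samples = s,
                         classes = 2L, seed = 9)
    mean(abs(rowSums(res$values[, , 1]) -
               (res$prediction[, 1] - res$baseline_expectation[1])))
  }
  g_small <- gap_for(16)
  g_large <- gap_for(1024)
  expect_lt(g_large, g_small + 1e-9)
  expect_lt(g_large, 0.1)
})

test_that("duplicated features with halved weights split attribution equally", {
  fit <- make_linear_fit(w = c(1.5, 1.5, -2))   # f1, f2 are twins of weight 3/2
  x <- matrix(c(2, 2, 1), 1, 3, dimnames = list(NULL, fit$feature_names))
  bg <- matrix(0, 1, 3, dimnames = list(NULL, fit$feature_names))
  res <- gradient_shap(fit, x, bg, n_path_samples = 16, classes = 0L, seed = 4)
  expect_equal(res$values[1, "f1", 1], res$values[1, "f2", 1],
               tolerance = 1e-10)
})

test_that("feature_ranking orders by mean absolute attribution with stable ties", {
  res <- structure(list(
    values = array(c(0, 0, 0, 0,  1, -1, 2, -2,  0.5, 0.5, 0.5, 0.5),
                   c(4, 3, 1)),
    feature_names = c("a", "b", "c"), classes = 0L),
    class = "attribution_result")
  rk <- feature_ranking(res, class_index = 0)
  expect_equal(rk$feature, c("b", "c", "a"))
  expect_equal(rk$mean_abs_attribution, c(1.5, 0.5, 0))

  zero <- res
  zero$values[] <- 0
  rk0 <- feature_ranking(zero, 0)
  expect_equal(rk0$feature, c("a", "b", "c"))     # ties keep feature order
  expect_true(all(rk0$mean_abs_attribution == 0))
  expect_error(feature_ranking(res, class_index = 2), "not attributed")
})

test_that("a dominant planted feature is ranked first", {
  fit <- make_linear_fit(w = c(10, 0.1, -0.1))
  set.seed(5)
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, fit$feature_names))
  bg <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, fit$feature_names))
  res <- gradient_shap(fit, x, bg, n_path_samples = 64, classes = 0L, seed = 2)
  expect_equal(feature_ranking(res, 0)$feature[1], "f1")
})

test_that("interaction_table returns tidy per-sample records", {
  fit <- make_linear_fit(w = c(1, -1))
  set.seed(6)
  x <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, fit$feature_names))
  bg <- matrix(0, 2, 2, dimnames = list(NULL, fit$feature_names))
  res <- gradient_shap(fit, x, bg, n_path_samples = 8, classes = 0L, seed = 1)
  it <- interaction_table(res, "f1", "f2", class_index = 0, inputs = x)
  expect_equal(nrow(it), 6)
  expect_equal(it$value_a, unname(x[, 1]))
  expect_equal(it$value_b, unname(x[, 2]))
  expect_equal(it$attribution_a, unname(res$values[, 1, 1]))
  expect_error(interaction_table(res, "f1", "f1", 0, x), "differ")
  expect_error(interaction_table(res, "f1", "nope", 0, x), "unknown")
})

test_that("attribution sign tracks the direction a feature pushes the class", {
  # class-0 logit decreases in f1 (w = -3): attribution is negative above the
  # background and positive below it
  fit <- make_linear_fit(w = c(-3, 0.2))
  bg <- matrix(0, 1, 2, dimnames = list(NULL, fit$feature_names))
  hi <- matrix(c(2, 0), 1, 2, dimnames = list(NULL, fit$feature_names))
  lo <- matrix(c(-2, 0), 1, 2, dimnames = list(NULL, fit$feature_names))
  rhi <- gradient_shap(fit, hi, bg, n_path_samples = 8, classes = 0L, seed = 1)
  rlo <- gradient_shap(fit, lo, bg, n_path_samples = 8, classes = 0L, seed = 1)
  expect_lt(rhi$values[1, 1, 1], 0)
  expect_gt(rlo$values[1, 1, 1], 0)
})
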