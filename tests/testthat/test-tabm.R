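test_that("parameter initialization is seeded and shaped per the contract", {
  cfg <- tabm_config(k = 3, n_blocks = 2, hidden_width = 8, n_classes = 3,
                     input_width = 10)
  p1 <- init_tabm_params(cfg, seed = 4)
  p2 <- init_tabm_params(cfg, seed = 4)
  expect_identical(p1, p2)

  expect_length(p1$blocks, 2)
  expect_equal(dim(p1$blocks[[1]]$W), c(8, 10))
  expect_equal(dim(p1$blocks[[1]]$adapters), c(3, 10))
  expect_equal(dim(p1$blocks[[2]]$W), c(8, 8))
  expect_length(p1$heads, 3)
  # adapters are plus/minus-one signs; biases start at zero
  for (blk in p1$blocks) {
    expect_true(all(blk$adapters %in% c(-1, 1)))
    expect_true(all(blk$biases == 0))
  }
  k1 <- init_tabm_params(tabm_config(k = 1, input_width = 4,
                                     hidden_width = 4), seed = 1)
  expect_equal(nrow(k1$blocks[[1]]$adapters), 1)
  expect_length(k1$heads, 1)
})

test_that("ensemble_linear equals a naive per-member loop", {
  set.seed(10)
  for (rep in 1:25) {
    m <- sample(1:8, 1); k <- sample(1:8, 1)
    win <- sample(1:16, 1); wout <- sample(1:16, 1)
    x <- array(rnorm(m * k * win), c(m, k, win))
    W <- matrix(rnorm(wout * win), wout, win)
    A <- matrix(rnorm(k * win), k, win)
    B <- matrix(rnorm(k * wout), k, wout)
    expect_equal(ensemble_linear(x, W, A, B), naive_ensemble_linear(x, W, A, B),
                 tolerance = 1e-10)
  }
})

test_that("unit adapters and equal biases collapse to the shared linear map", {
  set.seed(11)
  m <- 5; k <- 4; win <- 6; wout <- 3
  xr <- matrix(rnorm(m * win), m, win)
  x <- array(0, c(m, k, win))
  for (j in 1:k) x[, j, ] <- xr
  W <- matrix(rnorm(wout * win), wout, win)
  b <- rnorm(wout)
  out <- ensemble_linear(x, W, matrix(1, k, win),
                         matrix(b, k, wout, byrow = TRUE))
  plain <- xr %*% t(W) + matrix(b, m, wout, byrow = TRUE)
  for (j in 1:k) expect_equal(out[, j, ], unname(plain), tolerance = 1e-12)
})

test_that("block_forward applies ReLU and respects dropout modes", {
  set.seed(12)
  m <- 3; k <- 2; win <- 4
  blk <- list(W = diag(win), adapters = matrix(1, k, win),
              biases = matrix(0, k, win))
  xpos <- array(abs(rnorm(m * k * win)), c(m, k, win))
  expect_equal(block_forward(xpos, blk), xpos)                  # ReLU identity
  xneg <- -xpos
  expect_true(all(block_forward(xneg, blk) == 0))               # all clipped
  expect_equal(block_forward(xpos, blk, dropout_rate = 0, training = TRUE),
               block_forward(xpos, blk))                        # rate 0 == off
  expect_equal(block_forward(xpos, blk, dropout_rate = 0.5, training = FALSE),
               xpos)                                            # eval: off
})

test_that("forward produces member logits of the right shape, deterministically", {
  cfg <- tabm_config(k = 32, n_blocks = 2, hidden_width = 16, n_classes = 3,
                     input_width = 12)
  p <- init_tabm_params(cfg, seed = 2)
  x <- matrix(rnorm(64 * 12), 64, 12)
  l1 <- tabm_forward(x, p, cfg, mode = "eval")
  expect_equal(dim(l1), c(64, 32, 3))
  expect_identical(l1, tabm_forward(x, p, cfg, mode = "eval"))

  # identical members produce identical slices
  for (l in seq_along(p$blocks)) {
    p$blocks[[l]]$adapters <- matrix(p$blocks[[l]]$adapters[1, ], cfg$k,
                                     ncol(p$blocks[[l]]$adapters), byrow = TRUE)
  }
  p$heads <- rep(p$heads[1], cfg$k)
  lsym <- tabm_forward(x, p, cfg)
  for (j in 2:cfg$k) expect_equal(lsym[, j, ], lsym[, 1, ], tolerance = 1e-12)
})

test_that("permuting members permutes logits and leaves loss/probs unchanged", {
  cfg <- tabm_config(k = 5, n_blocks = 2, hidden_width = 7, n_classes = 3,
                     input_width = 6)
  p <- init_tabm_params(cfg, seed = 3)
  x <- matrix(rnorm(10 * 6), 10, 6)
  y <- sample(0:2, 10, replace = TRUE)
  perm <- c(3, 1, 5, 2, 4)
  pp <- p
  for (l in seq_along(p$blocks)) {
    pp$blocks[[l]]$adapters <- p$blocks[[l]]$adapters[perm, , drop = FALSE]
    pp$blocks[[l]]$biases <- p$blocks[[l]]$biases[perm, , drop = FALSE]
  }
  pp$heads <- p$heads[perm]
  l0 <- tabm_forward(x, p, cfg)
  l1 <- tabm_forward(x, pp, cfg)
  expect_equal(l1, l0[, perm, ], tolerance = 1e-12)
  expect_equal(ensemble_loss(l1, y), ensemble_loss(l0, y), tolerance = 1e-12)
  expect_equal(predict_proba(l1), predict_proba(l0), tolerance = 1e-12)
})

test_that("ensemble loss has the analytic uniform and limit values", {
  logits <- array(0, c(4, 3, 3))                       # uniform over 3 classes
  expect_equal(ensemble_loss(logits, c(0, 1, 2, 0)), log(3), tolerance = 1e-12)

  strong <- array(0, c(3, 2, 3))
  y <- c(0L, 1L, 2L)
  for (i in 1:3) strong[i, , y[i] + 1] <- 50           # confident and right
  expect_lt(ensemble_loss(strong, y), 1e-9)

  # k identical members equal single-member cross-entropy
  set.seed(6)
  one <- array(rnorm(5 * 1 * 3), c(5, 1, 3))
  rep4 <- array(0, c(5, 4, 3))
  for (j in 1:4) rep4[, j, ] <- one[, 1, ]
  yy <- sample(0:2, 5, replace = TRUE)
  expect_equal(ensemble_loss(rep4, yy), ensemble_loss(one, yy),
               tolerance = 1e-12)
  expect_error(ensemble_loss(one, c(0, 1, 3, 0, 1)), "label")
})

test_that("predict_proba averages member softmaxes into a simplex", {
  set.seed(13)
  logits <- array(rnorm(6 * 4 * 3, sd = 3), c(6, 4, 3))
  pr <- predict_proba(logits)
  expect_equal(rowSums(pr), rep(1, 6), tolerance = 1e-12)
  # k = 1 is a plain softmax
  l1 <- array(rnorm(6 * 1 * 3), c(6, 1, 3))
  manual <- t(apply(l1[, 1, ], 1, function(z) exp(z) / sum(exp(z))))
  expect_equal(predict_proba(l1), manual, tolerance = 1e-12)
  # mirrored members give symmetric averaged probabilities
  l2 <- array(0, c(1, 2, 3))
  l2[1, 1, ] <- c(2, 0.5, -1)
  l2[1, 2, ] <- c(-1, 0.5, 2)
  pr2 <- predict_proba(l2)
  expect_equal(pr2[1, 1], pr2[1, 3], tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  ns <- asNamespace("plectabm")
  set.seed(42)
  x <- matrix(rnorm(8), 2, 4); colnames(x) <- paste0("f", 1:4)
  bins <- lapply(1:4, function(i) build_bins(rnorm(30), t_bins = 3))
  names(bins) <- colnames(x)
  cfg <- tabm_config(k = 2, n_blocks = 2, hidden_width = 3, dropout_rate = 0,
                     n_classes = 3, input_width = 8)
  ple <- init_ple_params(bins, d_embedding = 2, seed = 9)
  par <- c(list(ple = unclass(ple)), unclass(init_tabm_params(cfg, seed = 10)))
  y <- c(0L, 2L)
  pe <- ns$precompute_pe(x, bins)

  loss_fn <- function(par) {
    e <- ns$embed_from_pe(pe, par$ple)
    fw <- ns$nn_forward(par, e, cfg, training = FALSE)
    ensemble_loss(ns$flat_to_a3(fw$logits, 2, 2), y)
  }

  e <- ns$embed_from_pe(pe, par$ple)
  fw <- ns$nn_forward(par, e, cfg, training = FALSE, keep_cache = TRUE)
  p <- ns$row_softmax(fw$logits)
  rowsel <- cbind(1:4, rep(y, each = 2) + 1L)
  dlog <- p; dlog[rowsel] <- dlog[rowsel] - 1; dlog <- dlog / 4
  bw <- ns$nn_backward(par, fw, dlog, cfg, TRUE, TRUE)
  gple <- lapply(seq_along(pe), function(f) {
    cols <- (f - 1) * 2 + 1:2
    list(V = crossprod(pe[[f]], bw$dx[, cols]), b = colSums(bw$dx[, cols]))
  })
  names(gple) <- names(par$ple)
  fg <- ns$flatten_params(list(ple = gple, blocks = bw$grads$blocks,
                               heads = bw$grads$heads))
  fp <- ns$flatten_params(par)

  eps <- 1e-6
  maxerr <- 0
  for (i in seq_along(fp)) {
    for (j in seq_along(fp[[i]])) {
      p1 <- fp; p1[[i]][j] <- p1[[i]][j] + eps
      p2 <- fp; p2[[i]][j] <- p2[[i]][j] - eps
      num <- (loss_fn(ns$unflatten_params(p1, par)) -
                loss_fn(ns$unflatten_params(p2, par))) / (2 * eps)
      maxerr <- max(maxerr, abs(num - fg[[i]][j]))
    }
  }
  expect_lt(maxerr, 1e-5)
})
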