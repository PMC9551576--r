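test_that("class-balanced batches satisfy geometry, policy and determinism", {
  labels <- rep(sprintf("c%02d", 1:10), each = 20)
  b <- class_balanced_batches(labels, 40, 4, seed = 13)
  expect_equal(length(b), 5)   # floor(200 / 40)
  for (batch in b) {
    expect_equal(length(batch), 40)
    tab <- table(labels[batch])
    expect_equal(length(tab), 10)
    expect_true(all(tab == 4))
  }
  # determinism
  expect_identical(b, class_balanced_batches(labels, 40, 4, seed = 13))
  # rare class resampled with replacement
  labs2 <- c(rep("a", 2), rep("b", 6), rep("c", 6))
  b2 <- class_balanced_batches(labs2, 12, 4, n_batches = 3, seed = 1)
  for (batch in b2) expect_true(all(table(labs2[batch]) == 4))
  # too few classes
  expect_error(class_balanced_batches(labs2, 16, 4, seed = 1),
               "distinct classes")
  expect_error(class_balanced_batches(labels, 41, 4), "divisible")
})

test_that("every sampled batch satisfies the loss positive-precondition", {
  set.seed(2)
  labels <- sample(sprintf("c%d", 1:12), 150, replace = TRUE)
  labels <- c(labels, sprintf("c%d", 1:12))  # ensure every class exists
  for (batch in class_balanced_batches(labels, 24, 4, n_batches = 6,
                                       seed = 7)) {
    expect_true(all(table(labels[batch]) >= 2))
  }
})

test_that("two-pass chunked update reproduces the monolithic gradient", {
  set.seed(1)
  enc <- mlp(20, c(16), 8, seed = 3)
  X <- matrix(rnorm(40 * 20), 40, 20)
  labels <- rep(sprintf("c%d", 1:10), each = 4)
  cfg <- recall_config()
  mono <- encoder_loss_grad(enc, X, labels, cfg)

  tp <- two_pass_update(enc, X, labels, cfg, chunk_size = 8)
  expect_equal(tp$loss, mono$loss, tolerance = 1e-12)
  expect_lt(max(abs(tp$grad - mono$grad)) / max(abs(mono$grad)), 1e-10)

  # degenerate chunking: bitwise identical
  tp_full <- two_pass_update(enc, X, labels, cfg, chunk_size = 40)
  expect_identical(tp_full$grad, mono$grad)

  # single-precision storage between the passes
  tp32 <- two_pass_update(enc, X, labels, cfg, chunk_size = 8,
                          store_precision = "single")
  expect_lt(max(abs(tp32$grad - mono$grad)) / max(abs(mono$grad)), 1e-5)
})

test_that("learning-rate schedules follow their recipes", {
  # plateau-adaptive: decrease -> unchanged; 2 stagnant -> x0.9; 4 -> x0.81
  expect_equal(adaptive_lr(c(1.0, 0.9, 0.8), 0.01), 0.01)
  expect_equal(adaptive_lr(c(1.0, 1.1, 1.2), 0.01), 0.009)
  expect_equal(adaptive_lr(c(1.0, 1.1, 1.2, 1.3, 1.4), 0.01), 0.0081)

  # cyclic cosine: start, 20% cycle decay, cosine midpoint
  expect_equal(cyclic_cosine_lr(0, 10, 0.01), 0.01)
  expect_equal(cyclic_cosine_lr(10, 10, 0.01), 0.008)
  expect_equal(cyclic_cosine_lr(5, 10, 0.01), 0.005)

  # step decay at 0.3
  expect_equal(step_decay_lr(10, 1e-4), 1e-4)
  expect_equal(step_decay_lr(55, 1e-4), 3e-5)
  expect_equal(step_decay_lr(90, 1e-4), 9e-6)
})

test_that("augmentation is seeded, identity-able, and hits stated frequencies", {
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  a1 <- augment_image(img, seed = 5)
  a2 <- augment_image(img, seed = 5)
  expect_identical(a1, a2)
  # forced-identity configuration
  id <- augment_image(img, seed = 1, scale_range = c(1, 1), hflip_p = 0,
                      vflip_p = 0, jitter_p = 0)
  expect_equal(id, img, tolerance = 1e-12)
  # flip / jitter frequencies over many draws (checked via pixel effects)
  set.seed(42)
  n <- 2000
  probe <- array(0, c(8, 8, 1)); probe[1, 1, 1] <- 1   # corner marker
  hflips <- 0; jitters <- 0
  mid <- array(0.5, c(4, 4, 1))
  for (i in 1:n) {
    out <- augment_image(probe, scale_range = c(1, 1), vflip_p = 0,
                         jitter_p = 0)
    if (out[1, 8, 1] > 0.5) hflips <- hflips + 1
    outj <- augment_image(mid, scale_range = c(1, 1), hflip_p = 0,
                          vflip_p = 0)
    if (max(abs(outj - 0.5)) > 1e-9) jitters <- jitters + 1
  }
  expect_lt(abs(hflips / n - 0.5), 0.03)
  expect_lt(abs(jitters / n - 0.2), 0.03)
})

test_that("preprocess maps intensity extremes to [-1, 1] endpoints", {
  black <- array(0, c(16, 16, 3))
  white <- array(255, c(16, 16, 3))
  gray <- array(127.5, c(16, 16, 3))
  expect_true(all(preprocess(black, 16) == -1))
  expect_true(all(preprocess(white, 16) == 1))
  expect_lt(max(abs(preprocess(gray, 16))), 1e-12)
})

test_that("retrieval training descends and is deterministic under a seed", {
  set.seed(1)
  b <- separated_batch(6, 10, 12, noise = 0.3, seed = 4)
  enc <- mlp(12, c(10), 8, seed = 2)
  fit1 <- train_retrieval(b$E, b$labels, enc, epochs = 4, batch_size = 16,
                          chunk_size = 4, lr = 1e-2, seed = 1)
  expect_lt(fit1$loss_curve[4], fit1$loss_curve[1])
  fit2 <- train_retrieval(b$E, b$labels, enc, epochs = 4, batch_size = 16,
                          chunk_size = 4, lr = 1e-2, seed = 1)
  expect_equal(fit1$loss_curve, fit2$loss_curve, tolerance = 1e-6)
})

test_that("gradient accumulation equals one monolithic effective batch", {
  set.seed(8)
  X <- matrix(rnorm(128 * 10), 128, 10)
  y <- sample(1:4, 128, replace = TRUE)
  model <- mlp(10, c(6), 4, "logits", seed = 1)
  theta <- mlp_params(model)
  # monolithic mean gradient over the full effective batch
  fw <- mlp_forward(model, X, keep_cache = TRUE)
  sx <- softmax_xent(fw$out, y)
  gm <- mlp_grads_flatten(mlp_backward(model, fw$cache, sx$grad)) / 128
  # 4 accumulated micro-batches of 32
  gacc <- 0
  for (s in seq(1, 128, by = 32)) {
    idx <- s:(s + 31)
    fwm <- mlp_forward(model, X[idx, ], keep_cache = TRUE)
    sxm <- softmax_xent(fwm$out, y[idx])
    gacc <- gacc + mlp_grads_flatten(mlp_backward(model, fwm$cache, sxm$grad))
  }
  gacc <- gacc / 128
  expect_lt(max(abs(gacc - gm)) / max(abs(gm)), 1e-10)
})

test_that("classifier baseline fits the fixture and is exact on one-hot", {
  b <- separated_batch(5, 20, 10, noise = 0.3, seed = 6)
  model <- mlp(10, c(8), 5, "logits", seed = 2)
  fit <- train_classifier_baseline(b$E, b$labels, model, epochs = 10,
                                   effective_batch = 20, micro_batch = 10,
                                   lr = 0.1, seed = 1)
  pred <- classifier_predict(fit, b$E)
  acc <- mean(pred$posterior$class_ids[
    max.col(pred$posterior$scores, ties.method = "first")] == b$labels)
  expect_gt(acc, 0.9)
  # loss on one-hot-perfect predictions ~ 0
  perfect <- matrix(-50, 6, 3)
  perfect[cbind(1:6, rep(1:3, 2))] <- 50
  expect_lt(softmax_xent(perfect, rep(1:3, 2))$loss, 1e-8)
})
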