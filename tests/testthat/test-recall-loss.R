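test_that("exact_rank counts ties against the target (step at 0 is 1)", {
  scores <- c(a = 0.9, b = 0.5, c = 0.3)
  expect_equal(exact_rank(scores, "a"), 1L)
  expect_equal(exact_rank(c(a = 0.5, b = 0.5, c = 0.1), "a"), 2L)
  expect_error(exact_rank(c(q = 1, a = 0.5), "a", query_id = "q"),
               "own database")

  # sort-based oracle on a random score row
  set.seed(3)
  s <- runif(20)
  names(s) <- sprintf("i%02d", 1:20)
  for (t in seq_along(s)) {
    expect_equal(exact_rank(s, t), 1L + sum(s[-t] >= s[t]))
  }
})

test_that("exact recall rescales by min(k, positives) with clipping", {
  # 3 positives at ranks 1,2,3 of 10, k = 4
  s <- c(0.9, 0.8, 0.7, seq(0.6, 0.1, length.out = 7))
  mask <- c(TRUE, TRUE, TRUE, rep(FALSE, 7))
  expect_equal(exact_recall_at_k(s, mask, 4), 1.0)
  # single positive ranked last, k = 1
  s2 <- c(seq(0.9, 0.2, length.out = 9), 0.1)
  expect_equal(exact_recall_at_k(s2, c(rep(FALSE, 9), TRUE), 1), 0.0)
  # 5 positives at ranks {1,3,6,7,9}, k = 4 -> 2/4
  s3 <- sort(runif(10), decreasing = TRUE)
  mask3 <- rep(FALSE, 10)
  mask3[c(1, 3, 6, 7, 9)] <- TRUE
  expect_equal(exact_recall_at_k(s3, mask3, 4), 0.5)
  expect_error(exact_recall_at_k(s3, rep(FALSE, 10), 4), "no positives")
})

test_that("the relaxed step is a stable sigmoid", {
  expect_equal(sigmoid_relax(0, 1), 0.5)
  expect_equal(sigmoid_relax(0, 0.001), 0.5)
  expect_equal(sigmoid_relax(1, 1), 1 / (1 + exp(-1)))
  # saturation without overflow at |u|/tau = 3e5
  expect_equal(sigmoid_relax(-3, 0.01), 0)
  expect_equal(sigmoid_relax(3, 0.01), 1)
  expect_true(all(is.finite(sigmoid_relax(c(-1e4, 1e4), 1))))
})

test_that("surrogate recall has the documented boundary behavior", {
  # single positive ranked 1 of 4 (3 others), k=1: argument sits at sigma(0)
  scores <- c(0.9, 0.2, 0.1)
  mask <- c(TRUE, FALSE, FALSE)
  expect_equal(surrogate_recall_at_k(scores, mask, 1, 1e-3, 1e-3), 0.5,
               tolerance = 1e-6)
  # 3 positives ranked 1..3 with gaps >= 0.2, k=8 -> ~1
  s <- c(0.9, 0.7, 0.5, 0.1, -0.1)
  m <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(surrogate_recall_at_k(s, m, 8, 1e-3, 1e-3), 1.0,
               tolerance = 1e-3)
})

test_that("surrogate recall matches the double-loop transcription to 1e-9", {
  set.seed(11)
  E <- l2_normalize(matrix(rnorm(12 * 6), 12, 6))
  labels <- rep(c("a", "b", "c"), each = 4)
  S <- E %*% t(E)
  q <- 1
  scores <- S[q, -q]
  mask <- labels[-q] == labels[q]
  expect_equal(surrogate_recall_at_k(scores, mask, 4, 0.05, 0.05),
               oracle_surrogate_recall(scores, mask, 4, 0.05, 0.05),
               tolerance = 1e-9)
})

test_that("batch loss behaves on separated clusters and errors on singletons", {
  # 5 classes x 4 members, cross-class similarity 0 < every within-class
  # similarity, within-class scores distinctly ordered: ranks 1..3 all
  # strictly inside k = 4 for every query
  b <- fan_batch(5)
  l4 <- batch_loss(b$E, b$labels, recall_config(4, tau1 = 1e-3, tau2 = 1e-3))
  expect_lt(l4, 0.01)
  # k = 1: only the rank-1 positive contributes, and it sits on the
  # sigma(0) = 0.5 boundary -> per-query loss 1 - 0.5
  l1 <- batch_loss(b$E, b$labels, recall_config(1, tau1 = 1e-3, tau2 = 1e-3))
  expect_equal(l1, 0.5, tolerance = 0.01)
  expect_error(batch_loss(b$E, c(b$labels[-1], "lonely"),
                          recall_config()), "lonely")
})

test_that("batch loss stays in [0,1] and is permutation invariant", {
  for (seed in 1:5) {
    b <- random_batch(4, 3, 8, seed)
    cfg <- recall_config(c(1, 2, 4), tau1 = 0.5, tau2 = 0.05)
    l <- batch_loss(b$E, b$labels, cfg)
    expect_gte(l, 0)
    expect_lte(l, 1)
    set.seed(seed + 100)
    p <- sample(nrow(b$E))
    expect_lt(abs(batch_loss(b$E[p, ], b$labels[p], cfg) - l), 1e-10)
  }
})

test_that("surrogate converges to the exact metric as temperatures shrink", {
  # constructed batch: score gaps >= 0.1 and no positive at rank exactly k
  b <- separated_batch(4, 4, 8, noise = 0.01, seed = 3)
  E <- l2_normalize(b$E)
  S <- E %*% t(E)
  # positives sit at ranks 1..3 for every query, so k in {8, 16} guarantees
  # no positive at rank exactly k
  for (k in c(8, 16)) {
    for (q in seq_len(nrow(E))) {
      scores <- S[q, -q]
      mask <- b$labels[-q] == b$labels[q]
      sur <- surrogate_recall_at_k(scores, mask, k, 1e-3, 1e-3)
      ex <- exact_recall_at_k(scores, mask, k)
      expect_lt(abs(sur - ex), 1e-3)
    }
  }
})

test_that("raising a lone positive's similarity never decreases surrogate recall", {
  # with a single positive the surrogate is monotone in its similarity
  # (with several positives the smooth rank of one positive can be displaced
  # by another, so only the exact metric is monotone — checked below)
  set.seed(21)
  for (rep in 1:100) {
    n <- 10
    scores <- runif(n, -1, 1)
    mask <- rep(FALSE, n)
    x <- sample(n, 1)
    mask[x] <- TRUE
    k <- sample(c(1, 2, 4, 8), 1)
    before <- surrogate_recall_at_k(scores, mask, k, 0.5, 0.05)
    scores[x] <- scores[x] + runif(1, 0, 0.5)
    after <- surrogate_recall_at_k(scores, mask, k, 0.5, 0.05)
    expect_gte(after, before - 1e-12)
  }
})

test_that("raising any positive's similarity never decreases exact recall", {
  set.seed(22)
  for (rep in 1:100) {
    n <- 10
    scores <- runif(n, -1, 1)
    mask <- rep(FALSE, n)
    mask[sample(n, 3)] <- TRUE
    k <- sample(c(1, 2, 4, 8), 1)
    x <- sample(which(mask), 1)
    before <- exact_recall_at_k(scores, mask, k)
    scores[x] <- scores[x] + runif(1, 0, 0.5)
    after <- exact_recall_at_k(scores, mask, k)
    expect_gte(after, before)
  }
})

test_that("vectorized batch loss matches the double-loop oracle to 1e-9", {
  cfg <- recall_config(c(1, 2, 4, 8, 16), tau1 = 1, tau2 = 0.05)
  for (seed in 1:5) {
    b <- random_batch(4, 4, 8, seed)
    expect_equal(batch_loss(b$E, b$labels, cfg),
                 oracle_batch_loss(b$E, b$labels, cfg), tolerance = 1e-9)
  }
  # up to 64 samples
  b <- random_batch(8, 8, 16, 99)
  expect_equal(batch_loss(b$E, b$labels, cfg),
               oracle_batch_loss(b$E, b$labels, cfg), tolerance = 1e-9)
})

test_that("analytic gradient matches central finite differences", {
  b <- random_batch(3, 4, 8, seed = 5)
  cfg <- recall_config(c(1, 2, 4), tau1 = 1, tau2 = 0.05)
  g <- batch_loss_grad(b$E, b$labels, cfg)$grad
  h <- 1e-5
  fd <- matrix(0, nrow(b$E), ncol(b$E))
  for (i in seq_len(nrow(b$E))) {
    for (j in seq_len(ncol(b$E))) {
      Ep <- b$E; Ep[i, j] <- Ep[i, j] + h
      Em <- b$E; Em[i, j] <- Em[i, j] - h
      fd[i, j] <- (batch_loss(Ep, b$labels, cfg) -
                     batch_loss(Em, b$labels, cfg)) / (2 * h)
    }
  }
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
})
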