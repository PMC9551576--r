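# Independent reference implementations used as oracles. These deliberately
# use plain loops / exhaustive search and never call the vectorized paths
# they are checking.

# literal double-loop transcription of the smooth Recall@k batch loss:
# loops over queries, k, positives x and database items z
oracle_batch_loss <- function(E, labels, cfg) {
  E <- E / sqrt(rowSums(E^2))
  S <- E %*% t(E)
  sigm <- function(u, tau) 1 / (1 + exp(-u / tau))
  n <- nrow(E)
  total <- 0
  for (q in seq_len(n)) {
    others <- setdiff(seq_len(n), q)
    pos <- others[labels[others] == labels[q]]
    for (k in cfg$k_values) {
      ssum <- 0
      for (x in pos) {
        excess <- 0
        for (z in others) {
          if (z != x) excess <- excess + sigm(S[q, z] - S[q, x], cfg$tau2)
        }
        ssum <- ssum + sigm(k - 1 - excess, cfg$tau1)
      }
      total <- total + 1 - min(ssum, k) / min(k, length(pos))
    }
  }
  total / (n * length(cfg$k_values))
}

# same transcription for a single query's surrogate recall
oracle_surrogate_recall <- function(scores, positive_mask, k, tau1, tau2) {
  sigm <- function(u, tau) 1 / (1 + exp(-u / tau))
  pos <- which(positive_mask)
  ssum <- 0
  for (x in pos) {
    excess <- 0
    for (z in seq_along(scores)) {
      if (z != x) excess <- excess + sigm(scores[z] - scores[x], tau2)
    }
    ssum <- ssum + sigm(k - 1 - excess, tau1)
  }
  min(ssum, k) / min(k, length(pos))
}

# exhaustive similarity-sort kNN reference (ties by ascending id)
oracle_topk <- function(query, database, k) {
  scores <- as.vector(database$embeddings %*% as.numeric(query))
  ord <- order(-scores, database$ids)[seq_len(k)]
  list(ids = database$ids[ord], labels = unname(database$labels[ord]),
       scores = scores[ord])
}

# plain-loop majority vote with summed-similarity then class-id tie-break
oracle_vote <- function(labels, scores) {
  classes <- sort(unique(labels))
  cnt <- sapply(classes, function(cl) sum(labels == cl))
  ssum <- sapply(classes, function(cl) sum(scores[labels == cl]))
  best <- classes[1]
  for (cl in classes[-1]) {
    if (cnt[cl] > cnt[best] ||
        (cnt[cl] == cnt[best] && ssum[cl] > ssum[best]))
      best <- cl
  }
  best
}

# 1-D grid search for the 2-class decision-likelihood maximum
oracle_cml_2class <- function(counts, C, step = 1e-6) {
  p1 <- seq(0, 1, by = step)
  q1 <- C[1, 1] * p1 + C[1, 2] * (1 - p1)
  q2 <- C[2, 1] * p1 + C[2, 2] * (1 - p1)
  ll <- counts[1] * log(q1) + counts[2] * log(q2)
  p1[which.max(ll)]
}

# coarse simplex grid search for 3-class instances
oracle_simplex_grid_3 <- function(objective, step = 1e-3) {
  best <- NULL
  best_val <- -Inf
  for (p1 in seq(0, 1, by = step)) {
    p2 <- seq(0, 1 - p1, by = step)
    for (q in p2) {
      v <- objective(c(p1, q, 1 - p1 - q))
      if (is.finite(v) && v > best_val) {
        best_val <- v
        best <- c(p1, q, 1 - p1 - q)
      }
    }
  }
  best
}

# hand-looped evaluation metrics
oracle_evaluate <- function(pred, truth) {
  acc <- sum(pred == truth) / length(truth)
  classes <- sort(unique(truth))
  f1s <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- 0; fp <- 0; fn <- 0
    for (j in seq_along(truth)) {
      if (pred[j] == cl && truth[j] == cl) tp <- tp + 1
      if (pred[j] == cl && truth[j] != cl) fp <- fp + 1
      if (pred[j] != cl && truth[j] == cl) fn <- fn + 1
    }
    f1s[i] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  list(accuracy = acc, macro_f1 = mean(f1s))
}

# random batch with guaranteed >= 2 samples per class
random_batch <- function(n_classes, per_class, d, seed) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    E <- matrix(rnorm(n_classes * per_class * d), n_classes * per_class, d)
    labels <- rep(sprintf("c%d", seq_len(n_classes)), each = per_class)
    list(E = E, labels = labels)
  })
}

# batch whose classes occupy orthogonal subspaces, with members fanned at
# fixed angles from the class axis: within-class similarities are
# cos(a_i) cos(a_j) (distinctly ordered), cross-class similarities exactly 0
fan_batch <- function(n_classes, angles = c(0, 40, 65, 85) * pi / 180) {
  per_class <- length(angles)
  d <- n_classes * (per_class + 1)
  E <- matrix(0, n_classes * per_class, d)
  row <- 0
  for (c in seq_len(n_classes)) {
    base <- (c - 1) * (per_class + 1)
    for (j in seq_len(per_class)) {
      row <- row + 1
      E[row, base + 1] <- cos(angles[j])
      E[row, base + 1 + j] <- sin(angles[j])
    }
  }
  list(E = E, labels = rep(sprintf("c%d", seq_len(n_classes)),
                           each = per_class))
}

# batch whose classes are well separated clusters with controllable gaps
separated_batch <- function(n_classes, per_class, d, noise = 0.02, seed = 1) {
  set.seed(seed)
  centers <- diag(n_classes)[, seq_len(n_classes), drop = FALSE]
  centers <- cbind(centers, matrix(0, n_classes, d - n_classes))
  E <- centers[rep(seq_len(n_classes), each = per_class), ] +
    matrix(rnorm(n_classes * per_class * d, sd = noise),
           n_classes * per_class, d)
  list(E = E, labels = rep(sprintf("c%d", seq_len(n_classes)),
                           each = per_class))
}
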