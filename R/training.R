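#' Class-balanced mini-batch sampler
#'
#' Every batch holds `batch_size / samples_per_class` distinct classes with
#' exactly `samples_per_class` samples each, so every query is guaranteed
#' in-batch positives — the precondition of the Recall@k surrogate loss.
#' Classes with fewer members than `samples_per_class` are sampled with
#' replacement. Deterministic given the seed.
#'
#' @param labels class id per dataset sample.
#' @param batch_size total batch size; must be divisible by
#'   `samples_per_class`.
#' @param samples_per_class samples drawn per class (default 4).
#' @param n_batches number of batches; defaults to
#'   `max(1, floor(n / batch_size))` (one epoch's worth).
#' @param seed sampler seed.
#' @return list of integer index vectors into `labels`.
#' @export
class_balanced_batches <- function(labels, batch_size,
                                   samples_per_class = 4L,
                                   n_batches = NULL, seed = 1L) {
  labels <- as.character(labels)
  check(batch_size %% samples_per_class == 0,
        "batch_size (%d) must be divisible by samples_per_class (%d)",
        batch_size, samples_per_class)
  cpb <- batch_size %/% samples_per_class
  classes <- sort(unique(labels))
  check(length(classes) >= cpb,
        "need %d distinct classes per batch but only %d available",
        cpb, length(classes))
  if (is.null(n_batches))
    n_batches <- max(1L, floor(length(labels) / batch_size))
  members <- split(seq_along(labels), labels)
  with_seed(seed, lapply(seq_len(n_batches), function(b) {
    chosen <- sample(classes, cpb)
    unlist(lapply(chosen, function(cl) {
      pool <- members[[cl]]
      if (length(pool) >= samples_per_class) sample(pool, samples_per_class)
      else sample(pool, samples_per_class, replace = TRUE)
    }), use.names = FALSE)
  }))
}

#' Two-pass chunked gradient update
#'
#' Memory-bounded equivalent of a full-batch gradient step. Pass 1 embeds the
#' batch chunk by chunk, discarding intermediate activations, and computes
#' the loss together with its gradient w.r.t. every embedding vector. Pass 2
#' re-runs the forward pass per chunk with activations retained and
#' back-propagates the stored embedding-gradients, accumulating the parameter
#' gradient. Because the encoder is deterministic, the result equals the
#' monolithic full-batch gradient of [encoder_loss_grad()].
#'
#' @param model an [mlp()] encoder.
#' @param x batch inputs (rows = samples).
#' @param labels class ids.
#' @param config a [recall_config()].
#' @param chunk_size samples per chunk (default 8).
#' @param store_precision precision of the embeddings and embedding-gradients
#'   held between the two passes: `"double"` or `"single"` (4-byte floats, as
#'   a GPU implementation would store them).
#' @return list `loss`, `grad` (flat parameter gradient vector).
#' @export
two_pass_update <- function(model, x, labels, config = recall_config(),
                            chunk_size = 8L,
                            store_precision = c("double", "single")) {
  store_precision <- match.arg(store_precision)
  x <- as.matrix(x)
  n <- nrow(x)
  check(chunk_size >= 1, "chunk_size must be >= 1")
  chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))

  # pass 1: embeddings only, no retained state
  raw <- do.call(rbind, lapply(chunks, function(i)
    mlp_forward(model, x[i, , drop = FALSE])$out))
  if (store_precision == "single") raw <- quantize_float32(raw)

  lg <- batch_loss_grad(raw, labels, config, normalize = TRUE)
  gemb <- lg$grad
  if (store_precision == "single") gemb <- quantize_float32(gemb)

  # pass 2: re-embed per chunk with cache, backprop stored gradients
  acc <- NULL
  for (i in chunks) {
    fw <- mlp_forward(model, x[i, , drop = FALSE], keep_cache = TRUE)
    g <- mlp_backward(model, fw$cache, gemb[i, , drop = FALSE])
    acc <- if (is.null(acc)) g else
      Map(function(a, b) list(W = a$W + b$W, b = a$b + b$b), acc, g)
  }
  list(loss = lg$loss, grad = mlp_grads_flatten(acc))
}

# ---- learning-rate schedules ------------------------------------------------

#' Adaptive learning rate on validation-loss plateaus
#'
#' Multiplies the learning rate by `factor` (default 0.9) every time the
#' validation loss has failed to decrease for `patience` (default 2)
#' consecutive epochs. Pure function of the loss history: replayable.
#'
#' @param history numeric vector of per-epoch validation losses so far.
#' @param base_lr initial learning rate.
#' @param factor multiplicative decay.
#' @param patience consecutive non-improving epochs before a decay.
#' @return the learning rate after scanning `history`.
#' @export
adaptive_lr <- function(history, base_lr, factor = 0.9, patience = 2L) {
  lr <- base_lr
  stall <- 0L
  if (length(history) >= 2) {
    for (t in 2:length(history)) {
      if (history[t] < history[t - 1]) stall <- 0L
      else {
        stall <- stall + 1L
        if (stall >= patience) {
          lr <- lr * factor
          stall <- 0L
        }
      }
    }
  }
  lr
}

#' Cyclic cosine annealing schedule
#'
#' The schedule is split into cycles of `cycle_length` epochs; each cycle
#' starts at 80% of the previous cycle's start (a 20% decay) and decays to 0
#' within the cycle along a cosine.
#'
#' @param epoch 0-based epoch index.
#' @param cycle_length epochs per cycle.
#' @param base_lr start learning rate of cycle 0.
#' @param cycle_decay start-of-cycle decay factor (default 0.8).
#' @return learning rate (0 only at a cycle endpoint).
#' @export
cyclic_cosine_lr <- function(epoch, cycle_length, base_lr, cycle_decay = 0.8) {
  check(cycle_length >= 1, "cycle_length must be >= 1")
  cyc <- epoch %/% cycle_length
  phase <- (epoch %% cycle_length) / cycle_length
  base_lr * cycle_decay^cyc * 0.5 * (1 + cos(pi * phase))
}

#' Step-decay schedule
#'
#' @param epoch 0-based epoch index.
#' @param base_lr initial learning rate.
#' @param factor decay applied at each milestone (default 0.3).
#' @param milestones ascending epoch indices; a milestone counts as passed
#'   once `epoch >= milestone`.
#' @return `base_lr * factor^(milestones passed)`.
#' @export
step_decay_lr <- function(epoch, base_lr, factor = 0.3,
                          milestones = c(50L, 80L)) {
  base_lr * factor^sum(epoch >= milestones)
}

# ---- optimizers -------------------------------------------------------------

#' AdamW optimizer step (decoupled weight decay)
#'
#' @param theta flat parameter vector.
#' @param grad flat gradient vector.
#' @param state optimizer state (`NULL` on the first call).
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment/stability constants.
#' @param weight_decay decoupled decay coefficient.
#' @return list `theta`, `state`.
#' @export
adamw_step <- function(theta, grad, state = NULL, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 1e-4) {
  if (is.null(state))
    state <- list(m = numeric(length(theta)), v = numeric(length(theta)),
                  t = 0L)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * theta)
  list(theta = theta, state = state)
}

#' SGD with momentum step
#'
#' @inheritParams adamw_step
#' @param momentum momentum coefficient (default 0.9).
#' @return list `theta`, `state`.
#' @export
sgd_momentum_step <- function(theta, grad, state = NULL, lr,
                              momentum = 0.9) {
  if (is.null(state)) state <- list(v = numeric(length(theta)))
  state$v <- momentum * state$v + grad
  theta <- theta - lr * state$v
  list(theta = theta, state = state)
}

# ---- softmax cross-entropy (baseline classifier) ----------------------------

#' Softmax cross-entropy loss and logit gradient
#'
#' @param logits matrix (rows = samples, cols = classes).
#' @param y integer class indices (1-based) per row.
#' @return list `loss` (mean NLL), `grad` (d loss-sum / d logits; divide by
#'   the effective batch size externally when accumulating), `probs`.
#' @export
softmax_xent <- function(logits, y) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  n <- nrow(logits)
  nll <- -log(pmax(p[cbind(seq_len(n), y)], 1e-300))
  g <- p
  g[cbind(seq_len(n), y)] <- g[cbind(seq_len(n), y)] - 1
  list(loss = mean(nll), grad = g, probs = p)
}

# ---- training drivers -------------------------------------------------------

#' Train a retrieval encoder with the Recall@k surrogate loss
#'
#' Runs epochs of class-balanced batches through the two-pass chunked update
#' with AdamW and a step-decay learning-rate schedule, the recipe used for
#' the retrieval approach.
#'
#' @param x training inputs (rows = preprocessed image vectors).
#' @param labels class ids.
#' @param model an [mlp()] encoder (embedding output).
#' @param epochs number of epochs.
#' @param batch_size,samples_per_class,chunk_size sampler / update geometry;
#'   desk-scale defaults 40 / 4 / 8.
#' @param lr initial learning rate (default 1e-4 scaled up for desk-scale
#'   nets; pass explicitly to match a recipe).
#' @param weight_decay AdamW decoupled decay.
#' @param config a [recall_config()].
#' @param milestones,lr_factor step-decay schedule.
#' @param seed run seed (sampler streams derived per epoch).
#' @param log_file optional JSON-lines path; one record per epoch.
#' @return list `model` (trained), `loss_curve` (mean per-epoch loss), `lrs`.
#' @export
train_retrieval <- function(x, labels, model, epochs = 10L,
                            batch_size = 40L, samples_per_class = 4L,
                            chunk_size = 8L, lr = 1e-3,
                            weight_decay = 1e-4,
                            config = recall_config(),
                            milestones = c(50L, 80L), lr_factor = 0.3,
                            seed = 1L, log_file = NULL) {
  theta <- mlp_params(model)
  state <- NULL
  seeds <- derive_seeds(seed, epochs)
  loss_curve <- numeric(epochs)
  lrs <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    lr_ep <- step_decay_lr(ep - 1L, lr, lr_factor, milestones)
    batches <- class_balanced_batches(labels, batch_size, samples_per_class,
                                      seed = seeds[ep])
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      model <- mlp_set_params(model, theta)
      up <- two_pass_update(model, x[idx, , drop = FALSE], labels[idx],
                            config, chunk_size)
      # mean-over-queries gradient is already encoded in the loss scaling
      st <- adamw_step(theta, up$grad, state, lr_ep,
                       weight_decay = weight_decay)
      theta <- st$theta
      state <- st$state
      losses[bi] <- up$loss
    }
    loss_curve[ep] <- mean(losses)
    lrs[ep] <- lr_ep
    if (!is.null(log_file))
      cat(jsonlite::toJSON(list(epoch = ep, lr = lr_ep,
                                loss = loss_curve[ep], seed = seeds[ep]),
                           auto_unbox = TRUE, digits = NA),
          "\n", sep = "", file = log_file, append = TRUE)
  }
  model <- mlp_set_params(model, theta)
  list(model = model, loss_curve = loss_curve, lrs = lrs)
}

#' Train a softmax cross-entropy classifier baseline
#'
#' The comparator recipe: SGD with momentum 0.9, micro-batch gradients
#' accumulated to an effective batch size, and the plateau-adaptive
#' learning-rate schedule. The accumulated update over the micro-batches of
#' one effective batch equals the update a single monolithic batch would
#' produce (gradients are summed, then divided by the effective size).
#'
#' @param x training inputs.
#' @param labels class ids (the class set is `sort(unique(labels))`).
#' @param model an [mlp()] with `output_dim` = number of classes.
#' @param epochs epochs.
#' @param effective_batch total batch per update (default 128).
#' @param micro_batch samples per accumulated forward/backward (default 32).
#' @param lr base learning rate.
#' @param momentum SGD momentum.
#' @param val_x,val_labels optional validation split driving [adaptive_lr()];
#'   training loss is used when absent.
#' @param seed run seed.
#' @return list `model`, `classes`, `loss_curve`, `lrs`.
#' @export
train_classifier_baseline <- function(x, labels, model, epochs = 10L,
                                      effective_batch = 128L,
                                      micro_batch = 32L, lr = 0.05,
                                      momentum = 0.9,
                                      val_x = NULL, val_labels = NULL,
                                      seed = 1L) {
  classes <- sort(unique(as.character(labels)))
  y <- match(as.character(labels), classes)
  theta <- mlp_params(model)
  state <- NULL
  seeds <- derive_seeds(seed, epochs)
  n <- nrow(x)
  history <- numeric(0)
  loss_curve <- numeric(epochs)
  lrs <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    lr_ep <- adaptive_lr(history, lr)
    ord <- with_seed(seeds[ep], sample.int(n))
    starts <- seq(1L, n, by = effective_batch)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + effective_batch - 1L, n)]
      gsum <- NULL
      lsum <- 0
      for (ms in seq(1L, length(idx), by = micro_batch)) {
        mi <- idx[ms:min(ms + micro_batch - 1L, length(idx))]
        model <- mlp_set_params(model, theta)
        fw <- mlp_forward(model, x[mi, , drop = FALSE], keep_cache = TRUE)
        sx <- softmax_xent(fw$out, y[mi])
        g <- mlp_grads_flatten(mlp_backward(model, fw$cache, sx$grad))
        gsum <- if (is.null(gsum)) g else gsum + g
        lsum <- lsum + sx$loss * length(mi)
      }
      st <- sgd_momentum_step(theta, gsum / length(idx), state, lr_ep,
                              momentum)
      theta <- st$theta
      state <- st$state
      ep_loss <- ep_loss + lsum
    }
    loss_curve[ep] <- ep_loss / n
    lrs[ep] <- lr_ep
    model <- mlp_set_params(model, theta)
    if (!is.null(val_x)) {
      vy <- match(as.character(val_labels), classes)
      vl <- softmax_xent(mlp_forward(model, val_x)$out, vy)$loss
      history <- c(history, vl)
    } else history <- c(history, loss_curve[ep])
  }
  list(model = model, classes = classes, loss_curve = loss_curve, lrs = lrs)
}

#' Classifier predictions as a prediction matrix pair
#'
#' @param fit result of [train_classifier_baseline()].
#' @param x inputs to score.
#' @param ids sample ids.
#' @return list of two [prediction_matrix()] objects: `logit` and
#'   `posterior`.
#' @export
classifier_predict <- function(fit, x, ids = NULL) {
  logits <- mlp_forward(fit$model, as.matrix(x))$out
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(logits)))
  colnames(logits) <- fit$classes
  sm <- softmax_xent(logits, rep(1L, nrow(logits)))$probs
  list(logit = prediction_matrix(logits, mode = "logit", sample_ids = ids,
                                 class_ids = fit$classes),
       posterior = prediction_matrix(sm, mode = "posterior",
                                     sample_ids = ids,
                                     class_ids = fit$classes))
}
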