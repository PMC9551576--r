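#' Recall@k loss configuration
#'
#' @param k_values sorted positive integers; the set of k over which the loss
#'   is averaged. Default `c(1, 2, 4, 8, 16)`.
#' @param tau1 temperature of the counting sigmoid (how softly a positive's
#'   rank is compared to k). Default 1.
#' @param tau2 temperature of the ranking sigmoid (how softly score
#'   differences are counted into a rank). Default 0.01. Both temperatures are
#'   implementation choices; smaller values approach the exact metric.
#' @return object of class `recall_config`.
#' @export
recall_config <- function(k_values = c(1L, 2L, 4L, 8L, 16L),
                          tau1 = 1.0, tau2 = 0.01) {
  k_values <- sort(unique(as.integer(k_values)))
  check(length(k_values) > 0 && all(k_values >= 1L),
        "k_values must be a non-empty set of integers >= 1")
  check(tau1 > 0 && tau2 > 0, "temperatures must be strictly positive")
  structure(list(k_values = k_values, tau1 = tau1, tau2 = tau2),
            class = "recall_config")
}

#' Numerically stable sigmoid with temperature
#'
#' `sigmoid_relax(u, tau)` = 1 / (1 + exp(-u / tau)), computed in the stable
#' branch form so it saturates to 0/1 without overflow for any `|u|/tau`.
#' It is the smooth relaxation of the Heaviside step used to make ranking and
#' counting differentiable.
#'
#' @param u numeric vector/matrix.
#' @param tau positive temperature.
#' @return values in `[0, 1]`, same shape as `u`.
#' @export
sigmoid_relax <- function(u, tau) {
  check(tau > 0, "tau must be > 0")
  z <- u / tau
  out <- z
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

# derivative of sigmoid_relax w.r.t. u, given the sigmoid value s
sigmoid_relax_deriv <- function(s, tau) s * (1 - s) / tau

#' Exact retrieval rank of a database item
#'
#' The rank of target `x` for query `q` is one plus the number of other
#' database items whose similarity to `q` is greater than *or equal to* the
#' target's (the step function at zero counts as 1, so ties count against the
#' target).
#'
#' @param scores numeric vector of similarities from one query to the
#'   database, named by database ids; the query itself must not appear.
#' @param target_id id (or index) of the target item within `scores`.
#' @param query_id optional query id; if it matches a name of `scores` a
#'   self-match error is raised.
#' @return integer rank >= 1.
#' @export
exact_rank <- function(scores, target_id, query_id = NULL) {
  if (!is.null(query_id) && !is.null(names(scores)) &&
      query_id %in% names(scores))
    stop("query '", query_id, "' present in its own database", call. = FALSE)
  ti <- if (is.character(target_id)) match(target_id, names(scores)) else as.integer(target_id)
  check(!is.na(ti) && ti >= 1 && ti <= length(scores),
        "target not found in the score row")
  1L + sum(scores[-ti] >= scores[ti])
}

#' Exact (rescaled) Recall@k for one query
#'
#' Counts the positives whose rank is at most `k`, clips the count at `k`,
#' and divides by `min(k, number of positives)` so the metric lies in
#' `[0, 1]` regardless of how many positives exist.
#'
#' @param scores similarity row as in [exact_rank()].
#' @param positive_mask logical vector marking same-class database items.
#' @param k positive integer.
#' @return value in `[0, 1]`.
#' @export
exact_recall_at_k <- function(scores, positive_mask, k) {
  check(k >= 1, "k must be >= 1")
  n_pos <- sum(positive_mask)
  if (n_pos == 0)
    stop("undefined recall: query has no positives in the database",
         call. = FALSE)
  ranks <- vapply(which(positive_mask), function(i) exact_rank(scores, i),
                  integer(1))
  min(sum(ranks <= k), k) / min(k, n_pos)
}

#' Smooth surrogate Recall@k for one query
#'
#' Differentiable approximation of [exact_recall_at_k()]: the Heaviside step
#' inside the rank is replaced by a sigmoid of temperature `tau2`, the step
#' counting positives inside the top-k by a sigmoid of temperature `tau1`.
#' For each positive x the smooth rank excess is
#' `sum_{z != x} sigmoid((s_qz - s_qx)/tau2)` and its contribution is
#' `sigmoid((k - 1 - excess)/tau1)`; contributions are summed, clipped at k,
#' and rescaled by `min(k, n_positives)`.
#'
#' @param scores similarity row from the query to the batch minus the query.
#' @param positive_mask logical vector marking same-class items.
#' @param k positive integer.
#' @param tau1,tau2 temperatures (see [recall_config()]).
#' @return value in `[0, 1]`.
#' @export
surrogate_recall_at_k <- function(scores, positive_mask, k, tau1, tau2) {
  n_pos <- sum(positive_mask)
  if (n_pos == 0)
    stop("undefined recall: query has no positives in the batch",
         call. = FALSE)
  pos_idx <- which(positive_mask)
  # rows = positives x, cols = all items z; zero the z == x diagonal terms
  diffs <- outer(-scores[pos_idx], scores, `+`)     # s_qz - s_qx
  sig <- sigmoid_relax(diffs, tau2)
  sig[cbind(seq_along(pos_idx), pos_idx)] <- 0
  excess <- rowSums(sig)
  contrib <- sigmoid_relax(k - 1 - excess, tau1)
  min(sum(contrib), k) / min(k, n_pos)
}

# validate a batch for the loss: every sample needs >= 1 same-class partner
check_batch_positives <- function(labels) {
  tab <- table(labels)
  singles <- names(tab)[tab < 2]
  if (length(singles) > 0)
    stop("sampler contract violated: singleton class(es) in batch: ",
         paste(singles, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Recall@k surrogate batch loss (and its gradient)
#'
#' The training objective: every batch sample acts as a query against the
#' batch minus itself; the per-query loss is `1 - surrogate recall` averaged
#' over the configured k values, and the batch loss is the mean over queries.
#' The loss lies in `[0, 1]`.
#'
#' `batch_loss_grad()` additionally returns the analytic gradient with
#' respect to the *input* rows. When `normalize = TRUE` (the default) inputs
#' are L2-normalized internally and the gradient is chained through the
#' normalization, so callers can feed raw encoder outputs and use central
#' finite differences on them directly.
#'
#' @param embeddings numeric matrix of embeddings (rows = samples) or an
#'   `embedding_set` (in which case `labels` is taken from it).
#' @param labels class id per row.
#' @param config a [recall_config()].
#' @param normalize L2-normalize rows before computing similarities.
#' @return `batch_loss`: a scalar in `[0, 1]`. `batch_loss_grad`: list with
#'   `loss` and `grad` (matrix matching `embeddings`).
#' @export
batch_loss <- function(embeddings, labels = NULL, config = recall_config(),
                       normalize = TRUE) {
  batch_loss_core(embeddings, labels, config, normalize, want_grad = FALSE)$loss
}

#' @rdname batch_loss
#' @export
batch_loss_grad <- function(embeddings, labels = NULL,
                            config = recall_config(), normalize = TRUE) {
  batch_loss_core(embeddings, labels, config, normalize, want_grad = TRUE)
}

batch_loss_core <- function(embeddings, labels, config, normalize, want_grad) {
  if (inherits(embeddings, "embedding_set")) {
    labels <- embeddings$labels
    embeddings <- embeddings$embeddings
  }
  raw <- as.matrix(embeddings)
  labels <- as.character(labels)
  check(length(labels) == nrow(raw), "labels length must match rows")
  check_batch_positives(labels)
  E <- if (normalize) l2_normalize(raw) else raw
  n <- nrow(E)
  S <- tcrossprod(E)
  kv <- config$k_values
  tau1 <- config$tau1
  tau2 <- config$tau2
  total <- 0
  G <- if (want_grad) matrix(0, n, n) else NULL   # dL/dS

  for (q in seq_len(n)) {
    others <- setdiff(seq_len(n), q)
    pos <- others[labels[others] == labels[q]]
    s_row <- S[q, ]
    p <- length(pos)
    # diffs[x, z] = s_qz - s_qx over z in others; zero out z == x
    diffs <- outer(-s_row[pos], s_row[others], `+`)
    sig <- sigmoid_relax(diffs, tau2)
    xz_self <- cbind(seq_len(p), match(pos, others))
    sig[xz_self] <- 0
    excess <- rowSums(sig)
    for (k in kv) {
      m <- min(k, p)
      contrib <- sigmoid_relax(k - 1 - excess, tau1)
      ssum <- sum(contrib)
      total <- total + (1 - min(ssum, k) / m)
      if (want_grad && ssum < k) {
        # dL/dcontrib = -1/m (per query-and-k, scaled at the end)
        dc_dexcess <- -sigmoid_relax_deriv(contrib, tau1)   # dcontrib/dexcess
        w <- (-1 / m) * dc_dexcess                          # dL/dexcess_x
        dsig <- sigmoid_relax_deriv(sig, tau2)
        dsig[xz_self] <- 0
        # excess_x depends on s_qz (+) and s_qx (-)
        gz <- colSums(w * dsig)               # over z in others
        gx <- -w * rowSums(dsig)              # for x in pos
        G[q, others] <- G[q, others] + gz
        G[q, pos] <- G[q, pos] + gx
      }
    }
  }
  denom <- n * length(kv)
  loss <- total / denom
  out <- list(loss = loss)
  if (want_grad) {
    G <- G / denom
    gE <- (G + t(G)) %*% E                    # dL/dE through S = E E^T
    if (normalize) {
      nrm <- sqrt(rowSums(raw * raw))
      # back through e = v / ||v||: g_v = (g - (g . e) e) / ||v||
      proj <- rowSums(gE * E)
      gE <- (gE - proj * E) / nrm
    }
    dimnames(gE) <- dimnames(raw)
    out$grad <- gE
  }
  out
}
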