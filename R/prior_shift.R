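#' Per-sample class prediction matrix
#'
#' @param scores numeric matrix, rows = samples, cols = classes. In
#'   `"posterior"` mode every row must be non-negative and sum to 1 (within
#'   1e-8); `"logit"` rows are unconstrained pre-softmax activations.
#' @param mode `"posterior"` or `"logit"`.
#' @param sample_ids,class_ids identifiers (defaults from dimnames).
#' @return object of class `prediction_matrix`.
#' @export
prediction_matrix <- function(scores, mode = c("posterior", "logit"),
                              sample_ids = NULL, class_ids = NULL) {
  mode <- match.arg(mode)
  scores <- as.matrix(scores)
  if (is.null(sample_ids)) sample_ids <- rownames(scores)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(nrow(scores)))
  if (is.null(class_ids)) class_ids <- colnames(scores)
  if (is.null(class_ids)) class_ids <- sprintf("c%d", seq_len(ncol(scores)))
  check(length(sample_ids) == nrow(scores), "sample_ids length mismatch")
  check(length(class_ids) == ncol(scores), "class_ids length mismatch")
  if (mode == "posterior" && nrow(scores) > 0) {
    check(all(scores >= -1e-12), "posterior entries must be non-negative")
    check(max(abs(rowSums(scores) - 1)) < 1e-8,
          "posterior rows must sum to 1 (max deviation %.2e)",
          if (nrow(scores)) max(abs(rowSums(scores) - 1)) else 0)
  }
  dimnames(scores) <- list(sample_ids, class_ids)
  structure(list(scores = scores, mode = mode,
                 sample_ids = as.character(sample_ids),
                 class_ids = as.character(class_ids)),
            class = "prediction_matrix")
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat(sprintf("<prediction_matrix> %d samples x %d classes, mode = %s\n",
              nrow(x$scores), ncol(x$scores), x$mode))
  invisible(x)
}

#' Class prior vector on the probability simplex
#'
#' @param values non-negative numeric vector summing to 1 (within 1e-10
#'   after the internal renormalization guard).
#' @param class_ids class identifiers.
#' @return named numeric vector of class `prior_vector`.
#' @export
prior_vector <- function(values, class_ids = NULL) {
  values <- as.numeric(values)
  check(all(values >= 0), "priors must be non-negative")
  s <- sum(values)
  check(s > 0, "priors must have positive mass")
  check(abs(s - 1) < 1e-6, "priors must sum to 1 (got %.8f)", s)
  values <- values / s
  if (!is.null(class_ids)) names(values) <- class_ids
  structure(values, class = c("prior_vector", "numeric"))
}

#' Empirical class priors from labels
#'
#' @param labels class ids.
#' @param class_ids optional full class set (classes absent from `labels`
#'   get prior 0).
#' @return a [prior_vector()].
#' @export
empirical_priors <- function(labels, class_ids = NULL) {
  labels <- as.character(labels)
  if (is.null(class_ids)) class_ids <- sort(unique(labels))
  counts <- table(factor(labels, levels = class_ids))
  prior_vector(as.numeric(counts) / length(labels), class_ids)
}

#' Re-weight posteriors for a shifted test-time class prior
#'
#' For a classifier calibrated under training priors `p(c_k)`, the posterior
#' under new priors `p_e(c_k)` is proportional to
#' `p(c_k | x) * p_e(c_k) / p(c_k)`, renormalized per sample. Posteriors are
#' floored at 1e-12 before the division as a zero-probability guard.
#'
#' @param preds a posterior-mode [prediction_matrix()].
#' @param train_priors,test_priors [prior_vector()]s aligned with the
#'   prediction classes; training priors must be strictly positive wherever
#'   posterior mass exists.
#' @return adapted posterior-mode `prediction_matrix`.
#' @export
adapt_posteriors <- function(preds, train_priors, test_priors) {
  check(preds$mode == "posterior", "adaptation requires posterior mode")
  p <- pmax(preds$scores, 1e-12)
  tr <- as.numeric(train_priors)
  te <- as.numeric(test_priors)
  check(length(tr) == ncol(p) && length(te) == ncol(p),
        "prior length must equal the number of classes")
  if (any(tr <= 0 & colSums(preds$scores) > 0))
    stop("zero training prior for a class with posterior mass", call. = FALSE)
  w <- te / tr
  out <- sweep(p, 2, w, `*`)
  out <- out / rowSums(out)
  prediction_matrix(out, "posterior", preds$sample_ids, preds$class_ids)
}

#' EM estimation of unknown test-set class priors
#'
#' Maximizes the test-set likelihood over the class priors by alternating an
#' E-step (re-weight every posterior row under the current prior estimate)
#' and an M-step (average the adapted posteriors). Initialized at the
#' training priors (the no-shift start); the observed-data log-likelihood
#' `sum_i log sum_k p(c_k|x_i) phat_e(c_k) / p(c_k)` is non-decreasing and is
#' checked at every iteration.
#'
#' @param preds posterior-mode [prediction_matrix()].
#' @param train_priors training [prior_vector()].
#' @param tol stop when the max-abs prior change drops below this (1e-8).
#' @param max_iter iteration cap (1000).
#' @return list `priors` ([prior_vector()]), `trace` (data frame with
#'   iteration, max change, log-likelihood), `converged`.
#' @export
em_estimate_priors <- function(preds, train_priors, tol = 1e-8,
                               max_iter = 1000L) {
  check(preds$mode == "posterior", "EM requires posterior mode")
  P <- pmax(preds$scores, 1e-12)
  tr <- as.numeric(train_priors)
  R <- sweep(P, 2, tr, `/`)      # p(c_k|x) / p(c_k), fixed
  est <- tr
  ll_prev <- -Inf
  trace <- vector("list", max_iter)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M <- sweep(R, 2, est, `*`)
    rs <- rowSums(M)
    if (!all(is.finite(rs)) || any(rs <= 0))
      stop("non-finite EM intermediate at iteration ", it, call. = FALSE)
    ll <- sum(log(rs))
    if (ll < ll_prev - 1e-9 * max(1, abs(ll_prev)))
      stop("EM likelihood decreased at iteration ", it, call. = FALSE)
    new_est <- colMeans(M / rs)
    delta <- max(abs(new_est - est))
    trace[[it]] <- data.frame(iter = it, delta = delta, loglik = ll)
    est <- new_est
    ll_prev <- ll
    if (delta < tol) { converged <- TRUE; break }
  }
  list(priors = prior_vector(est, preds$class_ids),
       trace = do.call(rbind, trace[!vapply(trace, is.null, logical(1))]),
       converged = converged)
}

#' Estimate a (hard or soft) confusion matrix on a validation split
#'
#' Column k describes true class k: for `"hard"` the empirical frequencies
#' of the classifier's decisions; for `"soft"` the mean predicted probability
#' vector. Every class must appear in the validation labels.
#'
#' @param preds posterior-mode [prediction_matrix()] on validation samples
#'   (decisions are its row-wise argmax), or, for `kind = "hard"`, a
#'   character vector of decided class ids.
#' @param true_labels validation class ids, aligned with rows of `preds`.
#' @param kind `"hard"` or `"soft"`.
#' @param class_ids class set; defaults to the prediction classes.
#' @return object of class `confusion_matrix`: list `entries` (K x K matrix,
#'   columns sum to 1), `kind`, `class_ids`.
#' @export
estimate_confusion <- function(preds, true_labels, kind = c("hard", "soft"),
                               class_ids = NULL) {
  kind <- match.arg(kind)
  true_labels <- as.character(true_labels)
  if (inherits(preds, "prediction_matrix")) {
    if (is.null(class_ids)) class_ids <- preds$class_ids
    scores <- preds$scores
    decisions <- class_ids[max.col(scores, ties.method = "first")]
  } else {
    decisions <- as.character(preds)
    check(kind == "hard", "soft confusion needs a prediction_matrix")
    if (is.null(class_ids)) class_ids <- sort(unique(c(decisions, true_labels)))
    scores <- NULL
  }
  missing <- setdiff(class_ids, unique(true_labels))
  if (length(missing) > 0)
    stop("incomplete confusion matrix: class(es) absent from validation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  K <- length(class_ids)
  C <- matrix(0, K, K, dimnames = list(class_ids, class_ids))
  for (k in class_ids) {
    in_k <- true_labels == k
    if (kind == "hard") {
      C[, k] <- as.numeric(table(factor(decisions[in_k], levels = class_ids)))
    } else {
      C[, k] <- colSums(scores[in_k, , drop = FALSE])
    }
    C[, k] <- C[, k] / sum(C[, k])
  }
  structure(list(entries = C, kind = kind, class_ids = class_ids),
            class = "confusion_matrix")
}

# Maximize sum_k n_k log(C[k, ] %*% P) over the simplex by EM-style
# multiplicative updates (fixed point of the concave likelihood); checks the
# KKT residual at the returned point.
maximize_decision_likelihood <- function(counts, C, tol = 1e-12,
                                         max_iter = 200000L,
                                         kkt_tol = 1e-8) {
  counts <- as.numeric(counts)
  K <- ncol(C)
  N <- sum(counts)
  check(all(counts >= 0) && N > 0, "counts must be non-negative, not all zero")
  P <- rep(1 / K, K)
  feas <- as.vector(C %*% rep(1 / K, K))
  if (any(counts > 0 & feas <= 0))
    stop("infeasible likelihood: a decision class with positive count has ",
         "zero predicted probability for every prior", call. = FALSE)
  for (it in seq_len(max_iter)) {
    q <- as.vector(C %*% P)
    ratio <- ifelse(counts > 0, counts / pmax(q, 1e-300), 0)
    Pn <- P * as.vector(crossprod(C, ratio)) / N
    Pn <- Pn / sum(Pn)
    if (max(abs(Pn - P)) < tol) { P <- Pn; break }
    P <- Pn
  }
  # KKT: grad_j = sum_k n_k C[k,j] / (C[k,] P); at the max grad_j <= N with
  # equality on the support
  q <- as.vector(C %*% P)
  grad <- as.vector(crossprod(C, ifelse(counts > 0, counts / pmax(q, 1e-300), 0)))
  res <- max(c(abs(grad[P > 1e-9] / N - 1), pmax(grad[P <= 1e-9] / N - 1, 0), 0))
  list(P = P, kkt_residual = res, iterations = it)
}

#' CM-L: test priors by confusion-matrix likelihood maximization
#'
#' Given counts `n_k` of the classifier's test-set decisions and the
#' validation confusion matrix `C` (entry (i, k) = probability of deciding i
#' given true class k), estimates the priors `P` maximizing
#' `sum_k n_k log(C[k, ] . P)` subject to `P` on the simplex. The objective
#' is concave; the solver uses EM-style multiplicative updates and verifies
#' a KKT residual below 1e-8.
#'
#' @param decision_counts non-negative integer vector of decisions per class.
#' @param confusion a `confusion_matrix` (typically `kind = "hard"`).
#' @return list `priors` ([prior_vector()]), `kkt_residual`, `iterations`.
#' @export
cml_estimate_priors <- function(decision_counts, confusion) {
  C <- confusion$entries
  check(length(decision_counts) == nrow(C),
        "decision_counts length must equal the number of classes")
  sol <- maximize_decision_likelihood(decision_counts, C)
  list(priors = prior_vector(sol$P, confusion$class_ids),
       kkt_residual = sol$kkt_residual, iterations = sol$iterations)
}

#' SCM-L: test priors via the soft confusion matrix
#'
#' Soft analogue of [cml_estimate_priors()]: the hard decision counts are
#' replaced by `N` times the mean test prediction vector, and the hard
#' confusion matrix by the soft one (mean prediction vectors per true class).
#' The same solver and KKT contract apply. With one-hot predictions and a
#' hard confusion matrix this reduces exactly to CM-L.
#'
#' @param preds posterior-mode [prediction_matrix()] on the test set.
#' @param soft_confusion a `confusion_matrix` with `kind = "soft"`.
#' @return list `priors`, `kkt_residual`, `iterations`.
#' @export
scml_estimate_priors <- function(preds, soft_confusion) {
  check(preds$mode == "posterior", "SCM-L requires posterior mode")
  pbar <- colMeans(preds$scores)
  sol <- maximize_decision_likelihood(nrow(preds$scores) * pbar,
                                      soft_confusion$entries)
  list(priors = prior_vector(sol$P, soft_confusion$class_ids),
       kkt_residual = sol$kkt_residual, iterations = sol$iterations)
}

#' Estimate test priors and adapt posteriors in one call
#'
#' @param preds posterior-mode [prediction_matrix()] on the test set. When
#'   test-time augmentation is active, pass per-crop rows here and fuse
#'   afterwards — adaptation precedes any averaging.
#' @param train_priors training [prior_vector()].
#' @param method `"EM"`, `"CML"` or `"SCML"`.
#' @param confusion required for CML (hard) and SCML (soft).
#' @return list `adapted` (`prediction_matrix`), `priors`, `method`.
#' @export
adapt_pipeline <- function(preds, train_priors,
                           method = c("EM", "CML", "SCML"),
                           confusion = NULL) {
  method <- match.arg(method)
  if (method == "EM") {
    est <- em_estimate_priors(preds, train_priors)$priors
  } else {
    if (is.null(confusion))
      stop("method ", method, " requires a confusion matrix", call. = FALSE)
    if (method == "CML") {
      dec <- preds$class_ids[max.col(preds$scores, ties.method = "first")]
      counts <- as.numeric(table(factor(dec, levels = preds$class_ids)))
      est <- cml_estimate_priors(counts, confusion)$priors
    } else {
      est <- scml_estimate_priors(preds, confusion)$priors
    }
  }
  list(adapted = adapt_posteriors(preds, train_priors, est),
       priors = est, method = method)
}
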