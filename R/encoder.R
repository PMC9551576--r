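#' Fully-connected encoder / classifier network
#'
#' A small multilayer perceptron with tanh hidden activations. With
#' `output = "embedding"` the final layer feeds the L2 normalization of the
#' retrieval pipeline (normalization itself is applied by the caller /
#' [encoder_embed()]); with `output = "logits"` the raw outputs are class
#' scores for softmax cross-entropy training. The forward pass is
#' deterministic given the parameters — there are no stochastic layers, which
#' is exactly the contract the two-pass chunked update requires.
#'
#' @param input_dim number of input features (flattened image length).
#' @param hidden integer vector of hidden layer widths (may be empty).
#' @param output_dim embedding dimension d, or number of classes.
#' @param output `"embedding"` or `"logits"` (documentation of intent only;
#'   both return raw final-layer activations from [mlp_forward()]).
#' @param seed initialization seed.
#' @return object of class `mlp`: list of layers, each `list(W, b)`.
#' @export
mlp <- function(input_dim, hidden = c(64L), output_dim = 32L,
                output = c("embedding", "logits"), seed = 1L) {
  output <- match.arg(output)
  dims <- c(input_dim, hidden, output_dim)
  layers <- with_seed(seed, lapply(seq_len(length(dims) - 1L), function(i) {
    sd <- sqrt(2 / (dims[i] + dims[i + 1]))
    list(W = matrix(stats::rnorm(dims[i] * dims[i + 1], sd = sd),
                    dims[i], dims[i + 1]),
         b = numeric(dims[i + 1]))
  }))
  structure(list(layers = layers, dims = dims, output = output),
            class = "mlp")
}

#' @export
print.mlp <- function(x, ...) {
  cat(sprintf("<mlp> %s, %d parameters, output = %s\n",
              paste(x$dims, collapse = " -> "),
              length(mlp_params(x)), x$output))
  invisible(x)
}

#' Forward pass through an `mlp`
#'
#' @param model an [mlp()].
#' @param x input matrix (rows = samples).
#' @param keep_cache retain per-layer activations for [mlp_backward()]. Pass 1
#'   of the two-pass update runs with `keep_cache = FALSE` so only the output
#'   embeddings are held in memory.
#' @return list with `out` (raw final activations) and `cache` (or `NULL`).
#' @export
mlp_forward <- function(model, x, keep_cache = FALSE) {
  x <- as.matrix(x)
  check(ncol(x) == model$dims[1],
        "input has %d features, model expects %d", ncol(x), model$dims[1])
  nl <- length(model$layers)
  acts <- if (keep_cache) vector("list", nl + 1L) else NULL
  a <- x
  if (keep_cache) acts[[1L]] <- a
  for (i in seq_len(nl)) {
    z <- a %*% model$layers[[i]]$W
    z <- sweep(z, 2, model$layers[[i]]$b, `+`)
    a <- if (i < nl) tanh(z) else z
    if (keep_cache) acts[[i + 1L]] <- a
  }
  list(out = a, cache = acts)
}

#' Backward pass: parameter gradient given output gradients
#'
#' @param model an [mlp()].
#' @param cache activations from `mlp_forward(..., keep_cache = TRUE)`.
#' @param grad_out gradient of the loss w.r.t. the raw outputs.
#' @return list of per-layer gradients `list(W, b)` (summed over samples).
#' @export
mlp_backward <- function(model, cache, grad_out) {
  nl <- length(model$layers)
  grads <- vector("list", nl)
  delta <- as.matrix(grad_out)
  for (i in rev(seq_len(nl))) {
    a_prev <- cache[[i]]
    grads[[i]] <- list(W = crossprod(a_prev, delta), b = colSums(delta))
    if (i > 1L) {
      # through tanh: a_prev = tanh(z_{i-1})
      delta <- (delta %*% t(model$layers[[i]]$W)) * (1 - a_prev^2)
    }
  }
  grads
}

#' Flatten / restore `mlp` parameters
#'
#' The optimizer operates on a single flat numeric vector view of all
#' weights and biases.
#'
#' @param model an [mlp()].
#' @param theta flat numeric vector from [mlp_params()].
#' @return `mlp_params`: numeric vector; `mlp_set_params`: updated model;
#'   `mlp_grads_flatten`: flat vector for a gradient list.
#' @export
mlp_params <- function(model) {
  unlist(lapply(model$layers, function(l) c(as.vector(l$W), l$b)),
         use.names = FALSE)
}

#' @rdname mlp_params
#' @export
mlp_set_params <- function(model, theta) {
  off <- 0L
  for (i in seq_along(model$layers)) {
    nw <- length(model$layers[[i]]$W)
    nb <- length(model$layers[[i]]$b)
    model$layers[[i]]$W[] <- theta[(off + 1L):(off + nw)]
    model$layers[[i]]$b <- theta[(off + nw + 1L):(off + nw + nb)]
    off <- off + nw + nb
  }
  check(off == length(theta), "parameter vector length mismatch")
  model
}

#' @rdname mlp_params
#' @param grads gradient list from [mlp_backward()].
#' @export
mlp_grads_flatten <- function(grads) {
  unlist(lapply(grads, function(g) c(as.vector(g$W), g$b)), use.names = FALSE)
}

#' Embed samples with an encoder (unit-norm output)
#'
#' Runs the forward pass (optionally in chunks, bounding peak memory) and
#' L2-normalizes the result.
#'
#' @param model an [mlp()] encoder.
#' @param x input matrix.
#' @param chunk_size optional chunk length for the forward pass.
#' @return matrix of unit-norm embeddings.
#' @export
encoder_embed <- function(model, x, chunk_size = NULL) {
  x <- as.matrix(x)
  if (is.null(chunk_size) || chunk_size >= nrow(x)) {
    raw <- mlp_forward(model, x)$out
  } else {
    idx <- split(seq_len(nrow(x)), ceiling(seq_len(nrow(x)) / chunk_size))
    raw <- do.call(rbind, lapply(idx, function(i)
      mlp_forward(model, x[i, , drop = FALSE])$out))
  }
  rownames(raw) <- rownames(x)
  l2_normalize(raw)
}

#' Monolithic full-batch loss and parameter gradient
#'
#' Reference path: one forward pass with retained activations, the surrogate
#' loss on the (internally normalized) embeddings, one backward pass. The
#' chunked [two_pass_update()] must reproduce this gradient.
#'
#' @param model an [mlp()] encoder.
#' @param x batch inputs.
#' @param labels class ids.
#' @param config a [recall_config()].
#' @return list `loss`, `grad` (flat parameter gradient vector).
#' @export
encoder_loss_grad <- function(model, x, labels, config = recall_config()) {
  fw <- mlp_forward(model, x, keep_cache = TRUE)
  lg <- batch_loss_grad(fw$out, labels, config, normalize = TRUE)
  grads <- mlp_backward(model, fw$cache, lg$grad)
  list(loss = lg$loss, grad = mlp_grads_flatten(grads))
}
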