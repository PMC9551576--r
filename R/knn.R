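#' Retrieve the top-k database items for one query
#'
#' Exhaustive dot-product search (no approximation): returns the `k` items
#' with the highest similarity, ties broken by ascending sample id so the
#' result is a total order.
#'
#' @param query numeric embedding vector (unit norm) or a 1-row matrix.
#' @param database an [embedding_set()].
#' @param k number of neighbors; must not exceed the database size.
#' @param exclude_id optional id excluded from the search (self-queries).
#' @return object of class `retrieval_result`: list with `query_id`,
#'   `neighbor_ids`, `neighbor_labels`, `neighbor_scores` (non-increasing).
#' @export
retrieve_topk <- function(query, database, k = 10L, exclude_id = NULL) {
  ids <- database$ids
  emb <- database$embeddings
  if (!is.null(exclude_id)) {
    keep <- ids != exclude_id
    ids <- ids[keep]
    emb <- emb[keep, , drop = FALSE]
  }
  check(length(ids) > 0, "database is empty")
  check(k <= length(ids), "k (%d) exceeds database size (%d)", k, length(ids))
  q <- as.numeric(query)
  check(length(q) == ncol(emb), "dimension mismatch: query d=%d, database d=%d",
        length(q), ncol(emb))
  scores <- as.vector(emb %*% q)
  ord <- order(-scores, ids)[seq_len(k)]
  structure(list(query_id = if (!is.null(exclude_id)) exclude_id else NA_character_,
                 neighbor_ids = ids[ord],
                 neighbor_labels = unname(database$labels[ids[ord]]),
                 neighbor_scores = scores[ord]),
            class = "retrieval_result")
}

#' Majority vote over retrieved neighbors
#'
#' The class with the most neighbors wins; ties are broken by the larger
#' summed similarity, then by the lexicographically smallest class id.
#'
#' @param result a `retrieval_result`.
#' @return predicted class id (character scalar).
#' @export
majority_vote <- function(result) {
  labs <- result$neighbor_labels
  check(length(labs) >= 1, "need at least one neighbor")
  counts <- table(labs)
  sums <- tapply(result$neighbor_scores, labs, sum)
  cand <- sort(names(counts))
  ord <- order(-counts[cand], -sums[cand], cand)
  cand[ord][1]
}

#' kNN classification of an embedding set
#'
#' Every test sample is a retrieval query against the training database; the
#' ten (by default) closest training embeddings vote on the class. Neighbor
#' evidence is returned for interpretability.
#'
#' @param test,train [embedding_set()] objects from the same encoder.
#' @param k neighbors per query (default 10).
#' @param exclude_self drop a training item whose id equals the query id
#'   (for self-classification diagnostics).
#' @return list `labels` (named character vector) and `results` (list of
#'   `retrieval_result`).
#' @export
predict_knn <- function(test, train, k = 10L, exclude_self = FALSE) {
  if (length(test$ids) == 0)
    return(list(labels = character(0), results = list()))
  check(ncol(test$embeddings) == ncol(train$embeddings),
        "embedding dimension mismatch")
  results <- lapply(seq_along(test$ids), function(i) {
    r <- retrieve_topk(test$embeddings[i, ], train, k,
                       exclude_id = if (exclude_self) test$ids[i] else NULL)
    r$query_id <- test$ids[i]
    r
  })
  labels <- vapply(results, majority_vote, character(1))
  names(labels) <- test$ids
  list(labels = labels, results = results)
}

#' Write kNN predictions and neighbor evidence as TSV
#'
#' @param pred result of [predict_knn()].
#' @param out path for the decisions table (`query_id`, `predicted_class`).
#' @param evidence optional path for the per-neighbor evidence table
#'   (`query_id`, `rank`, `neighbor_id`, `neighbor_label`, `score`).
#' @return `out` invisibly.
#' @export
write_knn_predictions <- function(pred, out, evidence = NULL) {
  utils::write.table(
    data.frame(query_id = names(pred$labels),
               predicted_class = unname(pred$labels)),
    out, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(evidence)) {
    ev <- do.call(rbind, lapply(pred$results, function(r)
      data.frame(query_id = r$query_id,
                 rank = seq_along(r$neighbor_ids),
                 neighbor_id = r$neighbor_ids,
                 neighbor_label = r$neighbor_labels,
                 score = r$neighbor_scores)))
    utils::write.table(ev, evidence, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(out)
}
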