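#' L2-normalize the rows of a matrix
#'
#' Projects each row onto the unit sphere; the similarity between two
#' normalized embeddings is then their dot product (equivalently, cosine
#' similarity). A row whose norm is below `eps` signals a broken encoder and
#' raises an error rather than being silently clamped.
#'
#' @param x numeric matrix (rows are embeddings) or a single numeric vector.
#' @param eps degenerate-row guard; rows with Euclidean norm below this fail.
#' @return matrix of the same shape with unit-norm rows.
#' @examples
#' l2_normalize(matrix(c(3, 4), 1))  # -> (0.6, 0.8)
#' @export
l2_normalize <- function(x, eps = 1e-12) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  nrm <- sqrt(rowSums(x * x))
  bad <- which(nrm < eps)
  if (length(bad) > 0) {
    ids <- if (!is.null(rownames(x))) rownames(x)[bad] else as.character(bad)
    stop("degenerate embedding: zero-norm row(s) ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  x / nrm
}

#' Labeled embedding set
#'
#' Bundles an embedding matrix with class labels and sample ids. Serves both
#' as the retrieval database and as a training mini-batch.
#'
#' @param embeddings numeric matrix, one row per sample.
#' @param labels character/factor vector of class ids, one per row.
#' @param ids sample ids (unique); defaults to rownames or `s1..sn`.
#' @param normalize if `TRUE` (default) rows are L2-normalized.
#' @return object of class `embedding_set` with elements `embeddings`
#'   (rownames = ids), `labels` (character, names = ids) and `ids`.
#' @export
embedding_set <- function(embeddings, labels, ids = NULL, normalize = TRUE) {
  embeddings <- as.matrix(embeddings)
  labels <- as.character(labels)
  check(length(labels) == nrow(embeddings),
        "labels length (%d) != number of embeddings (%d)",
        length(labels), nrow(embeddings))
  if (is.null(ids)) {
    ids <- rownames(embeddings)
    if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(embeddings)))
  }
  ids <- as.character(ids)
  check(anyDuplicated(ids) == 0, "sample ids must be unique")
  if (normalize) embeddings <- l2_normalize(embeddings)
  rownames(embeddings) <- ids
  names(labels) <- ids
  structure(list(embeddings = embeddings, labels = labels, ids = ids),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> %d samples, d = %d, %d classes\n",
              nrow(x$embeddings), ncol(x$embeddings),
              length(unique(x$labels))))
  invisible(x)
}

#' @export
`[.embedding_set` <- function(x, i) {
  embedding_set(x$embeddings[i, , drop = FALSE], x$labels[i], x$ids[i],
                normalize = FALSE)
}

#' Dot-product similarity matrix between two embedding sets
#'
#' `scores[i, j]` is the inner product of query `i` and database item `j`;
#' for unit-norm embeddings every entry lies in `[-1, 1]`.
#'
#' @param queries,database `embedding_set` objects (or plain matrices) of
#'   equal dimension.
#' @return numeric matrix with query ids as rownames and database ids as
#'   colnames.
#' @export
similarity_matrix <- function(queries, database) {
  qm <- if (inherits(queries, "embedding_set")) queries$embeddings else as.matrix(queries)
  dm <- if (inherits(database, "embedding_set")) database$embeddings else as.matrix(database)
  check(ncol(qm) == ncol(dm),
        "embedding dimension mismatch: queries d=%d, database d=%d",
        ncol(qm), ncol(dm))
  tcrossprod(qm, dm)
}

#' Write / read an embedding store
#'
#' Two dialects: `tsv` — a header row `id` plus `d` numeric columns, suited to
#' small text fixtures; `bin` — 32-bit little-endian floats in row-major order
#' with a sidecar `<path>.ids` text file (one sample id per line) and a
#' `<path>.shape` line `n d`.
#'
#' @param set an `embedding_set`.
#' @param path file path.
#' @param format `"tsv"` or `"bin"`.
#' @param labels_path optional path for a two-column id/label TSV; defaults to
#'   `<path>.labels.tsv`.
#' @return `write_embeddings` returns `path` invisibly; `read_embeddings`
#'   returns an `embedding_set` (labels restored from the sidecar when
#'   present, otherwise `NA`).
#' @export
write_embeddings <- function(set, path, format = c("tsv", "bin"),
                             labels_path = NULL) {
  format <- match.arg(format)
  if (is.null(labels_path)) labels_path <- paste0(path, ".labels.tsv")
  if (format == "tsv") {
    df <- data.frame(id = set$ids, set$embeddings, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("id", sprintf("e%d", seq_len(ncol(set$embeddings))))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(t(set$embeddings)), con, size = 4L, endian = "little")
    writeLines(set$ids, paste0(path, ".ids"))
    writeLines(sprintf("%d %d", nrow(set$embeddings), ncol(set$embeddings)),
               paste0(path, ".shape"))
  }
  utils::write.table(
    data.frame(id = set$ids, label = unname(set$labels)),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path, format = c("tsv", "bin"),
                            labels_path = NULL) {
  format <- match.arg(format)
  if (is.null(labels_path)) labels_path <- paste0(path, ".labels.tsv")
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    check("id" %in% colnames(df), "embedding TSV must have an 'id' column")
    ids <- as.character(df$id)
    m <- as.matrix(df[, setdiff(colnames(df), "id"), drop = FALSE])
    storage.mode(m) <- "double"
  } else {
    shape <- scan(paste0(path, ".shape"), what = integer(), quiet = TRUE)
    ids <- readLines(paste0(path, ".ids"))
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, what = "numeric", size = 4L, n = shape[1] * shape[2],
                 endian = "little")
    m <- matrix(v, nrow = shape[1], byrow = TRUE)
  }
  labels <- rep(NA_character_, length(ids))
  if (file.exists(labels_path)) {
    lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
    labels <- as.character(lab$label[match(ids, as.character(lab$id))])
  }
  embedding_set(m, labels, ids, normalize = FALSE)
}
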