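#' Read and validate a dataset manifest
#'
#' A manifest is a UTF-8 TSV with header columns `image_path`, `class_id`,
#' `observation_id`, `split` (train/val/test). Validation enforces: unique
#' image paths; a single class per observation; and that no observation
#' spans more than one split (which would leak specimens across
#' train/test). Violations are reported with the offending ids.
#'
#' @param path manifest file path.
#' @return validated data frame.
#' @export
read_manifest <- function(path) {
  check(file.exists(path), "manifest not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("image_path", "class_id", "observation_id", "split")
  miss <- setdiff(required, colnames(df))
  check(length(miss) == 0, "manifest missing column(s): %s",
        paste(miss, collapse = ", "))
  validate_manifest(df)
}

#' @rdname read_manifest
#' @param df a manifest data frame (already parsed).
#' @export
validate_manifest <- function(df) {
  dup <- df$image_path[duplicated(df$image_path)]
  check(length(dup) == 0, "duplicate image path(s): %s",
        paste(utils::head(unique(dup), 3), collapse = ", "))
  bad_split <- setdiff(unique(df$split), c("train", "val", "test"))
  check(length(bad_split) == 0, "unknown split value(s): %s",
        paste(bad_split, collapse = ", "))
  by_obs <- split(df, df$observation_id)
  for (obs in names(by_obs)) {
    cls <- unique(by_obs[[obs]]$class_id)
    if (length(cls) > 1)
      stop("observation '", obs, "' carries conflicting class ids: ",
           paste(cls, collapse = ", "), call. = FALSE)
    sp <- unique(by_obs[[obs]]$split)
    if (length(sp) > 1)
      stop("observation '", obs, "' leaks across splits: ",
           paste(sp, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write / read a prediction table
#'
#' TSV schema: `sample_id`, `observation_id`, `crop_label`, then per-class
#' `logit_<class>` and/or `softmax_<class>` columns. Reading reconstructs
#' [prediction_matrix()] objects (one per available mode) plus the grouping
#' columns; decimal text round-trips values to 1e-6.
#'
#' @param path TSV path.
#' @param logits,softmax optional [prediction_matrix()]s sharing sample ids.
#' @param groups optional data frame (`image_id`, `observation_id`) and/or
#'   `crop_label` info; defaults to the sample id as its own observation.
#' @return `read_predictions`: list with `logit`, `posterior` (either may be
#'   `NULL`), and `groups`.
#' @export
write_predictions <- function(path, logits = NULL, softmax = NULL,
                              groups = NULL) {
  base <- if (!is.null(logits)) logits else softmax
  check(!is.null(base), "need at least one of logits / softmax")
  ids <- base$sample_ids
  if (is.null(groups))
    groups <- data.frame(image_id = ids, observation_id = ids,
                         stringsAsFactors = FALSE)
  df <- data.frame(sample_id = ids,
                   observation_id = groups$observation_id[
                     match(ids, groups$image_id)],
                   crop_label = if ("crop_label" %in% colnames(groups))
                     groups$crop_label[match(ids, groups$image_id)]
                   else "full",
                   stringsAsFactors = FALSE)
  if (!is.null(logits)) {
    m <- logits$scores
    colnames(m) <- paste0("logit_", logits$class_ids)
    df <- cbind(df, as.data.frame(m, optional = TRUE))
  }
  if (!is.null(softmax)) {
    check(softmax$mode == "posterior", "softmax argument must be posterior mode")
    m <- softmax$scores
    colnames(m) <- paste0("softmax_", softmax$class_ids)
    df <- cbind(df, as.data.frame(m, optional = TRUE))
  }
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0)
    return(list(logit = NULL, posterior = NULL,
                groups = data.frame(image_id = character(0),
                                    observation_id = character(0))))
  check(all(c("sample_id", "observation_id") %in% colnames(df)),
        "prediction table must carry sample_id and observation_id columns")
  lcols <- grep("^logit_", colnames(df), value = TRUE)
  scols <- grep("^softmax_", colnames(df), value = TRUE)
  check(length(lcols) + length(scols) > 0,
        "prediction table has neither logit_ nor softmax_ columns")
  out <- list(logit = NULL, posterior = NULL,
              groups = data.frame(image_id = df$sample_id,
                                  observation_id = df$observation_id,
                                  crop_label = if ("crop_label" %in% colnames(df))
                                    df$crop_label else "full",
                                  stringsAsFactors = FALSE))
  if (length(lcols) > 0 && nrow(df) > 0) {
    m <- as.matrix(df[, lcols, drop = FALSE])
    out$logit <- prediction_matrix(m, "logit", df$sample_id,
                                   sub("^logit_", "", lcols))
  }
  if (length(scols) > 0 && nrow(df) > 0) {
    m <- as.matrix(df[, scols, drop = FALSE])
    m <- m / rowSums(m)   # absorb decimal-text rounding
    out$posterior <- prediction_matrix(m, "posterior", df$sample_id,
                                       sub("^softmax_", "", scols))
  }
  out
}

#' Require logits from a parsed prediction table
#'
#' @param parsed result of [read_predictions()].
#' @return the logit [prediction_matrix()]; errors when the table only
#'   carried softmax columns but a logit strategy was requested.
#' @export
require_logits <- function(parsed) {
  if (is.null(parsed$logit))
    stop("logit columns absent from the prediction table but a logit ",
         "strategy was requested", call. = FALSE)
  parsed$logit
}

#' Run the full desk-scale pipeline on a synthetic image fixture
#'
#' Generates the class-pattern fixture, trains the retrieval encoder
#' (Recall@k surrogate, two-pass updates) and the cross-entropy classifier
#' baseline under identical conditions, classifies the test split (kNN for
#' retrieval, softmax for the baseline), optionally adapts the baseline
#' posteriors to the test prior, fuses per-image predictions into
#' observation decisions, and writes a metrics JSON. Fully reproducible from
#' `config` + `seed`.
#'
#' @param config named list; see [default_pipeline_config()] for keys and
#'   desk-scale defaults. Unknown keys are rejected.
#' @param out_dir artifact directory (fixture, logs, metrics.json).
#' @param seed run seed; per-stage seeds are derived from it.
#' @return list of metrics (also written to `out_dir/metrics.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("embedknn_run_"),
                         seed = 1L) {
  cfg <- default_pipeline_config()
  unknown <- setdiff(names(config), names(cfg))
  check(length(unknown) == 0, "unknown config key(s): %s",
        paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 4L)

  fixture_dir <- file.path(out_dir, "fixture")
  manifest <- make_class_images(cfg$n_classes, cfg$per_class, cfg$side,
                                cfg$images_per_observation, cfg$jitter,
                                out_dir = fixture_dir, seed = seeds[1])
  tr <- manifest[manifest$split == "train", ]
  te <- manifest[manifest$split == "test", ]
  x_tr <- load_images(tr, cfg$side, fixture_dir)
  x_te <- load_images(te, cfg$side, fixture_dir)

  enc <- mlp(ncol(x_tr), cfg$hidden, cfg$embed_dim, "embedding",
             seed = seeds[2])
  fit_r <- train_retrieval(x_tr, tr$class_id, enc, epochs = cfg$epochs,
                           batch_size = cfg$batch_size,
                           samples_per_class = cfg$samples_per_class,
                           chunk_size = cfg$chunk_size, lr = cfg$lr_retrieval,
                           seed = seeds[2],
                           log_file = file.path(out_dir, "retrieval.log.jsonl"))
  db <- embedding_set(encoder_embed(fit_r$model, x_tr, cfg$chunk_size),
                      tr$class_id, tr$image_path, normalize = FALSE)
  qs <- embedding_set(encoder_embed(fit_r$model, x_te, cfg$chunk_size),
                      te$class_id, te$image_path, normalize = FALSE)
  knn <- predict_knn(qs, db, k = min(cfg$knn_k, length(db$ids)))

  cls <- mlp(ncol(x_tr), cfg$hidden, length(unique(tr$class_id)), "logits",
             seed = seeds[3])
  fit_c <- train_classifier_baseline(x_tr, tr$class_id, cls,
                                     epochs = cfg$epochs,
                                     effective_batch = cfg$effective_batch,
                                     micro_batch = cfg$micro_batch,
                                     lr = cfg$lr_classifier, seed = seeds[3])
  pred_c <- classifier_predict(fit_c, x_te, te$image_path)

  post <- pred_c$posterior
  if (isTRUE(cfg$adapt_priors)) {
    ad <- adapt_pipeline(post, empirical_priors(tr$class_id, fit_c$classes),
                         method = "EM")
    post <- ad$adapted
  }
  groups <- data.frame(image_id = te$image_path,
                       observation_id = te$observation_id,
                       stringsAsFactors = FALSE)
  fused_r <- tapply(seq_len(nrow(te)), te$observation_id, function(rows) {
    # retrieval path: per-image kNN vote, observation by plurality of votes
    v <- knn$labels[rows]
    names(sort(table(v), decreasing = TRUE))[1]
  })
  fused_c <- fuse_observations(pred_c$logit, groups,
                               strategy = cfg$fusion_strategy,
                               pred_other = post)

  cls_labels <- post$class_ids[max.col(post$scores, ties.method = "first")]
  metrics <- list(
    retrieval = evaluate_predictions(knn$labels, te$class_id, groups,
                                     unlist(fused_r)),
    classifier = evaluate_predictions(cls_labels, te$class_id, groups,
                                      fused_c$decisions),
    config = cfg, seed = seed)
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  metrics
}

#' Desk-scale pipeline defaults
#'
#' @return named list of configuration defaults: a 10-class, 30-image
#'   fixture at 32 px, a 128-d embedding over one 64-unit hidden layer,
#'   batches of 40 with 4 samples per class in chunks of 8, 10 epochs.
#' @export
default_pipeline_config <- function() {
  list(n_classes = 10L, per_class = 30L, side = 32L,
       images_per_observation = 3L, jitter = 0.05,
       hidden = 64L, embed_dim = 128L,
       epochs = 10L, batch_size = 40L, samples_per_class = 4L,
       chunk_size = 8L, lr_retrieval = 1e-3, lr_classifier = 0.05,
       effective_batch = 128L, micro_batch = 32L,
       knn_k = 10L, fusion_strategy = "mean_logits",
       adapt_priors = FALSE)
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose top-level keys match
#'   [default_pipeline_config()].
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check(is.list(cfg), "config must be a YAML mapping")
  cfg
}
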