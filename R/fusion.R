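#' Fuse several per-image predictions into one decision
#'
#' Four strategies for combining the rows (images or crops) of a score
#' matrix: `max_softmax` / `max_logits` take the element-wise maximum of the
#' chosen score and decide its argmax ("follow the most confident
#' prediction"); `mean_softmax` / `mean_logits` average element-wise first.
#' Argmax ties break to the lexicographically smallest class id. All
#' strategies are invariant to the row order.
#'
#' @param softmax matrix of posterior rows (required by `*_softmax`).
#' @param logits matrix of logit rows (required by `*_logits`).
#' @param strategy one of `max_softmax`, `mean_softmax`, `max_logits`,
#'   `mean_logits`.
#' @return list `scores` (fused row, named by class) and `decision`.
#' @export
fuse_rows <- function(softmax = NULL, logits = NULL,
                      strategy = c("mean_logits", "max_softmax",
                                   "mean_softmax", "max_logits")) {
  strategy <- match.arg(strategy)
  m <- if (grepl("softmax$", strategy)) softmax else logits
  if (is.null(m))
    stop("strategy ", strategy, " requires ",
         if (grepl("softmax$", strategy)) "softmax" else "logit",
         " scores", call. = FALSE)
  m <- as.matrix(m)
  check(nrow(m) >= 1, "need at least one prediction row")
  fused <- if (grepl("^max", strategy)) apply(m, 2, max) else colMeans(m)
  cls <- colnames(m)
  if (is.null(cls)) cls <- sprintf("c%d", seq_along(fused))
  ord <- order(-fused, cls)
  list(scores = stats::setNames(fused, cls), decision = cls[ord][1])
}

#' Observation-level fusion of per-image predictions
#'
#' @param pred a [prediction_matrix()] (softmax or logit mode as required by
#'   the strategy; pass both via `pred` and `pred_other` when needed).
#' @param groups data frame with columns `image_id`, `observation_id`; every
#'   image id must belong to exactly one observation.
#' @param strategy see [fuse_rows()].
#' @param pred_other optional second [prediction_matrix()] carrying the other
#'   mode (so callers can hold logits and softmax side by side).
#' @return list `decisions` (named by observation id) and `scores` (matrix,
#'   one fused row per observation).
#' @export
fuse_observations <- function(pred, groups,
                              strategy = c("mean_logits", "max_softmax",
                                           "mean_softmax", "max_logits"),
                              pred_other = NULL) {
  strategy <- match.arg(strategy)
  want <- if (grepl("softmax$", strategy)) "posterior" else "logit"
  pm <- if (pred$mode == want) pred else pred_other
  if (is.null(pm) || pm$mode != want)
    stop("strategy ", strategy, " requires a ", want,
         "-mode prediction matrix", call. = FALSE)
  check(anyDuplicated(groups$image_id) == 0,
        "an image id belongs to more than one observation")
  idx <- match(groups$image_id, pm$sample_ids)
  check(!anyNA(idx), "groups reference image ids absent from predictions")
  obs <- split(idx, as.character(groups$observation_id))
  fused <- lapply(obs, function(rows) {
    m <- pm$scores[rows, , drop = FALSE]
    if (want == "posterior") fuse_rows(softmax = m, strategy = strategy)
    else fuse_rows(logits = m, strategy = strategy)
  })
  scores <- do.call(rbind, lapply(fused, `[[`, "scores"))
  rownames(scores) <- names(obs)
  decisions <- vapply(fused, `[[`, character(1), "decision")
  list(decisions = decisions, scores = scores)
}

#' 13-crop test-time augmentation battery
#'
#' Boxes (0-based, half-open, sizes floored): the full image; central crops
#' covering 90, 80, 70 and 60% of each dimension; and for each of the four
#' corners, crops covering 80 and 70% anchored at that corner.
#'
#' @param width,height image dimensions in pixels (>= 10).
#' @return data frame with columns `label`, `left`, `top`, `right`, `bottom`
#'   (exactly 13 rows, all boxes within the image).
#' @export
tta_crops <- function(width, height) {
  check(width >= 10 && height >= 10, "image must be at least 10 x 10")
  box <- function(label, l, t, w, h)
    data.frame(label = label, left = l, top = t, right = l + w, bottom = t + h)
  central <- function(f) {
    w <- floor(f * width); h <- floor(f * height)
    box(sprintf("center%d", round(100 * f)),
        floor((width - w) / 2), floor((height - h) / 2), w, h)
  }
  corner <- function(name, f) {
    w <- floor(f * width); h <- floor(f * height)
    l <- if (grepl("right", name)) width - w else 0L
    t <- if (grepl("bottom", name)) height - h else 0L
    box(sprintf("%s%d", name, round(100 * f)), l, t, w, h)
  }
  rows <- rbind(
    box("full", 0L, 0L, width, height),
    do.call(rbind, lapply(c(0.9, 0.8, 0.7, 0.6), central)),
    do.call(rbind, lapply(c("topleft", "topright", "bottomleft",
                            "bottomright"), function(nm)
      rbind(corner(nm, 0.8), corner(nm, 0.7)))))
  rownames(rows) <- NULL
  rows
}

#' Extract and preprocess the 13 TTA crops of one image
#'
#' @param img array H x W x C in `[0, 1]`.
#' @param side model input side each crop is resized to.
#' @return matrix of 13 flattened preprocessed crops (rownames = crop
#'   labels).
#' @export
tta_crop_batch <- function(img, side) {
  h <- dim(img)[1]; w <- dim(img)[2]
  crops <- tta_crops(w, h)
  m <- t(vapply(seq_len(nrow(crops)), function(i) {
    b <- crops[i, ]
    sub <- img[(b$top + 1):b$bottom, (b$left + 1):b$right, , drop = FALSE]
    as.vector(preprocess(sub, side))
  }, numeric(side * side * dim(img)[3])))
  rownames(m) <- crops$label
  m
}

#' Fuse a 13-crop prediction batch into one row
#'
#' Same combination semantics as [fuse_rows()], applied across the crops of
#' a single image. When prior adaptation is active, adapt each crop row
#' before calling this (adaptation precedes averaging).
#'
#' @param crop_scores matrix with exactly 13 rows (one per crop).
#' @param strategy see [fuse_rows()].
#' @param mode `"softmax"` or `"logits"`, describing `crop_scores`.
#' @return fused named score vector.
#' @export
fuse_tta <- function(crop_scores, strategy = "mean_logits",
                     mode = c("logits", "softmax")) {
  mode <- match.arg(mode)
  crop_scores <- as.matrix(crop_scores)
  check(nrow(crop_scores) == 13,
        "TTA fusion expects exactly 13 crop rows, got %d", nrow(crop_scores))
  if (mode == "softmax") fuse_rows(softmax = crop_scores, strategy = strategy)$scores
  else fuse_rows(logits = crop_scores, strategy = strategy)$scores
}

#' Image- and observation-level accuracy and macro-F1
#'
#' Accuracy is the fraction of correct labels. Macro-F1 is the unweighted
#' mean of per-class F1 over the classes present in the truth; a class with
#' no true positives and no predicted positives scores 0. Observation
#' accuracy is computed on fused observation decisions against the (unique)
#' truth of each observation's images.
#'
#' @param predictions per-image predicted class ids.
#' @param truth per-image true class ids (aligned).
#' @param groups optional data frame (`image_id`, `observation_id`); image
#'   order must align with `predictions` when `image_id` is absent.
#' @param observation_predictions named vector of fused decisions per
#'   observation id (e.g. from [fuse_observations()]).
#' @return list `accuracy_image`, `macro_f1`, and (when groups are given)
#'   `accuracy_observation`.
#' @export
evaluate_predictions <- function(predictions, truth, groups = NULL,
                                 observation_predictions = NULL) {
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  check(length(predictions) == length(truth),
        "predictions and truth must align")
  out <- list(accuracy_image = mean(predictions == truth),
              macro_f1 = macro_f1(predictions, truth))
  if (!is.null(groups) && !is.null(observation_predictions)) {
    obs_truth <- tapply(truth[match(groups$image_id,
                                    if (is.null(names(truth))) groups$image_id
                                    else names(truth))],
                        as.character(groups$observation_id),
                        function(v) {
                          u <- unique(v)
                          if (length(u) > 1)
                            stop("observation with conflicting truth labels",
                                 call. = FALSE)
                          u
                        })
    ids <- names(observation_predictions)
    check(all(ids %in% names(obs_truth)),
          "observation predictions reference unknown observations")
    out$accuracy_observation <-
      mean(observation_predictions == obs_truth[ids])
  }
  out
}

#' Macro-averaged F1 score
#'
#' @param predictions,truth class id vectors.
#' @return mean per-class F1 over classes present in `truth`.
#' @export
macro_f1 <- function(predictions, truth) {
  classes <- sort(unique(as.character(truth)))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(predictions == cl & truth == cl)
    fp <- sum(predictions == cl & truth != cl)
    fn <- sum(predictions != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}
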