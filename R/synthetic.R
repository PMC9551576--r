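# Synthetic fixture generators: every generator is a pure function of its
# arguments and seed (bit-identical on repeated calls).

#' Unit-norm embedding clusters with controllable separation
#'
#' Class centers are drawn uniformly on the unit sphere, rejected until all
#' pairwise Euclidean center distances reach `class_separation`; members are
#' the center plus isotropic Gaussian noise of scale `noise_scale`,
#' renormalized onto the sphere.
#'
#' @param n_classes,per_class,dim geometry (`dim >= 2`).
#' @param class_separation minimum pairwise center distance (0 disables the
#'   rejection).
#' @param noise_scale member noise standard deviation.
#' @param seed RNG seed.
#' @param max_attempts rejection budget per center before a configuration
#'   error.
#' @return an [embedding_set()]; labels `class01..`, ids `class01_001..`.
#' @export
make_embedding_clusters <- function(n_classes, per_class, dim,
                                    class_separation = 0.5,
                                    noise_scale = 0.1, seed = 1L,
                                    max_attempts = 1000L) {
  check(dim >= 2, "dim must be >= 2")
  with_seed(seed, {
    centers <- matrix(NA_real_, n_classes, dim)
    for (i in seq_len(n_classes)) {
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        cand <- l2_normalize(matrix(stats::rnorm(dim), 1))
        if (i == 1 || min(sqrt(rowSums(
          sweep(centers[seq_len(i - 1), , drop = FALSE], 2, cand)^2))) >=
          class_separation) {
          centers[i, ] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("class_separation ", class_separation,
             " infeasible after ", max_attempts, " attempts", call. = FALSE)
    }
    labels <- rep(sprintf("class%02d", seq_len(n_classes)), each = per_class)
    ids <- sprintf("%s_%03d", labels, sequence(rep(per_class, n_classes)))
    emb <- centers[rep(seq_len(n_classes), each = per_class), , drop = FALSE] +
      matrix(stats::rnorm(n_classes * per_class * dim, sd = noise_scale),
             n_classes * per_class, dim)
    embedding_set(emb, labels, ids, normalize = TRUE)
  })
}

# deterministic per-class pattern parameters
class_pattern_params <- function(class_index) {
  list(hue = (class_index * 0.618034) %% 1,
       blob_x = 0.15 + 0.7 * (((class_index * 7) %% 10) / 9),
       blob_y = 0.15 + 0.7 * (((class_index * 3) %% 10) / 9),
       stripe_freq = 1 + (class_index %% 5),
       stripe_dir = (class_index %% 2))
}

hue_to_rgb <- function(h) {
  # simple HSV(h, 1, 1) -> RGB
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  switch(as.character(i),
         "0" = c(1, f, 0), "1" = c(1 - f, 1, 0), "2" = c(0, 1, f),
         "3" = c(0, 1 - f, 1), "4" = c(f, 0, 1), c(1, 0, 1 - f))
}

render_class_image <- function(class_index, side, jitter = 0.05,
                               rng_active = TRUE) {
  p <- class_pattern_params(class_index)
  j <- function(x, s) if (rng_active) x + stats::runif(1, -s, s) else x
  gx <- matrix(rep(seq(0, 1, length.out = side), each = side), side)
  gy <- matrix(rep(seq(0, 1, length.out = side), side), side)
  bx <- j(p$blob_x, jitter); by <- j(p$blob_y, jitter)
  blob <- exp(-(((gx - bx)^2 + (gy - by)^2)) / (2 * 0.12^2))
  phase <- if (rng_active) stats::runif(1, 0, 2 * pi) else 0
  stripes <- 0.5 + 0.5 * sin(2 * pi * p$stripe_freq *
                               (if (p$stripe_dir == 0) gx else gy) + phase)
  rgb <- hue_to_rgb(j(p$hue, jitter / 2) %% 1)
  img <- array(0, c(side, side, 3))
  for (c in 1:3)
    img[, , c] <- pmin(pmax(0.15 + 0.7 * blob * rgb[c] + 0.15 * stripes, 0), 1)
  if (rng_active)
    img <- pmin(pmax(img + array(stats::rnorm(length(img), sd = 0.02),
                                 dim(img)), 0), 1)
  img
}

#' Procedural class-pattern image fixture with manifest
#'
#' Each class is a distinct procedural pattern (colored Gaussian blob whose
#' position and hue identify the class, plus stripes of class-specific
#' frequency); per-sample jitter moves the blob, shifts the stripe phase and
#' adds pixel noise. Images are grouped into observations of
#' `images_per_observation` consecutive samples, and observations are
#' assigned wholly to train/val/test splits (never split across).
#'
#' @param n_classes,per_class,side fixture geometry (`side >= 16`).
#' @param images_per_observation images per specimen observation.
#' @param jitter per-sample pattern jitter (0 makes images within a class
#'   identical).
#' @param split_fractions named fractions for train/val/test (by
#'   observation).
#' @param out_dir directory for PNGs and `manifest.tsv`.
#' @param seed RNG seed.
#' @return the manifest data frame (invisibly also written to
#'   `out_dir/manifest.tsv`).
#' @export
make_class_images <- function(n_classes, per_class, side = 32L,
                              images_per_observation = 3L, jitter = 0.05,
                              split_fractions = c(train = 0.6, val = 0.2,
                                                  test = 0.2),
                              out_dir, seed = 1L) {
  check(side >= 16, "side must be >= 16")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- with_seed(seed, {
    res <- list()
    for (ci in seq_len(n_classes)) {
      cls <- sprintf("class%02d", ci)
      n_obs <- ceiling(per_class / images_per_observation)
      # whole observations to splits, deterministically shuffled
      counts <- pmax(1L, round(split_fractions * n_obs))
      pool <- rep(names(split_fractions), times = counts)
      if (length(pool) < n_obs)
        pool <- c(pool, rep("train", n_obs - length(pool)))
      splits <- sample(pool[seq_len(n_obs)])
      for (s in seq_len(per_class)) {
        obs_i <- ceiling(s / images_per_observation)
        img <- render_class_image(ci, side, jitter, rng_active = jitter > 0)
        path <- sprintf("%s_%03d.png", cls, s)
        png::writePNG(img, file.path(out_dir, path))
        res[[length(res) + 1]] <- data.frame(
          image_path = path, class_id = cls,
          observation_id = sprintf("%s_obs%03d", cls, obs_i),
          split = splits[obs_i], stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, res)
  })
  utils::write.table(rows, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(rows)
}

#' Calibrated posterior matrix under a planted prior shift
#'
#' True labels are drawn from `test_priors` while each emitted row is the
#' exact Bayes posterior under `train_priors`: the latent score is
#' `z = class_separation * e_y + N(0, I)` and the posterior is
#' `softmax(class_separation * z + log train_priors)`. Rows are therefore
#' calibrated for the training distribution while the labels follow the
#' shifted one — exactly the identifiability setting prior-shift estimators
#' assume.
#'
#' @param train_priors,test_priors [prior_vector()]s of equal length;
#'   training priors strictly positive.
#' @param class_separation latent signal strength (larger = more one-hot
#'   rows).
#' @param n number of samples.
#' @param seed RNG seed.
#' @return list `preds` (posterior [prediction_matrix()]), `labels`
#'   (character vector of true class ids), `class_ids`.
#' @export
make_calibrated_predictions <- function(train_priors, test_priors,
                                        class_separation = 2, n = 1000L,
                                        seed = 1L) {
  K <- length(train_priors)
  check(length(test_priors) == K, "prior length mismatch")
  check(all(train_priors > 0), "train priors must be strictly positive")
  class_ids <- names(train_priors)
  if (is.null(class_ids)) class_ids <- sprintf("c%d", seq_len(K))
  with_seed(seed, {
    y <- sample.int(K, n, replace = TRUE, prob = test_priors)
    z <- matrix(stats::rnorm(n * K), n, K)
    z[cbind(seq_len(n), y)] <- z[cbind(seq_len(n), y)] + class_separation
    logits <- class_separation * z +
      matrix(log(as.numeric(train_priors)), n, K, byrow = TRUE)
    logits <- logits - apply(logits, 1, max)
    p <- exp(logits)
    p <- p / rowSums(p)
    list(preds = prediction_matrix(p, "posterior",
                                   sprintf("s%05d", seq_len(n)), class_ids),
         labels = class_ids[y], class_ids = class_ids)
  })
}

#' Per-image logits grouped into observations
#'
#' Each observation's true class is uniform; every image's logit row is
#' `signal * onehot(truth) + N(0, noise^2)`, independent across the images
#' of an observation — the independence that makes fused decisions beat
#' per-image ones.
#'
#' @param n_obs,images_per_obs,n_classes geometry.
#' @param signal,noise logit signal strength and noise sd.
#' @param seed RNG seed.
#' @return list `logits` (logit [prediction_matrix()]), `groups`
#'   (`image_id`, `observation_id`), `truth` (per image), `obs_truth`
#'   (named per observation).
#' @export
make_observation_logits <- function(n_obs, images_per_obs, n_classes,
                                    signal = 1, noise = 1, seed = 1L) {
  class_ids <- sprintf("c%d", seq_len(n_classes))
  with_seed(seed, {
    obs_y <- sample.int(n_classes, n_obs, replace = TRUE)
    n <- n_obs * images_per_obs
    y <- rep(obs_y, each = images_per_obs)
    L <- matrix(stats::rnorm(n * n_classes, sd = noise), n, n_classes)
    L[cbind(seq_len(n), y)] <- L[cbind(seq_len(n), y)] + signal
    image_ids <- sprintf("img%06d", seq_len(n))
    obs_ids <- sprintf("obs%05d", rep(seq_len(n_obs), each = images_per_obs))
    list(logits = prediction_matrix(L, "logit", image_ids, class_ids),
         groups = data.frame(image_id = image_ids, observation_id = obs_ids,
                             stringsAsFactors = FALSE),
         truth = class_ids[y],
         obs_truth = stats::setNames(class_ids[obs_y],
                                     sprintf("obs%05d", seq_len(n_obs))))
  })
}

#' Softmax of logit rows
#'
#' @param logits logit [prediction_matrix()] or plain matrix.
#' @return posterior-mode [prediction_matrix()].
#' @export
logits_to_posterior <- function(logits) {
  if (inherits(logits, "prediction_matrix")) {
    m <- logits$scores
    sids <- logits$sample_ids; cids <- logits$class_ids
  } else {
    m <- as.matrix(logits); sids <- rownames(m); cids <- colnames(m)
  }
  z <- m - apply(m, 1, max)
  p <- exp(z) / rowSums(exp(z))
  prediction_matrix(p, "posterior", sids, cids)
}
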