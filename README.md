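# embedknn

Retrieval-based fine-grained species recognition in a deep embedding space,
with class-prior-shift adaptation and observation-level prediction fusion —
as a tested, desk-scale R library plus a thin command-line surface.

## The problem

Identifying a plant species from photographs "in the wild" is a fine-grained
classification problem: thousands of visually similar classes, different
organs of the same specimen looking nothing alike, and test-time class
frequencies that differ from the training set (seasonality, geography).
`embedknn` implements a recognition pipeline built around four ideas:

1. **Recall@k surrogate training.** An encoder `f_θ` maps an image to a
   unit-norm embedding `x = f_θ(image)`; similarity is the dot product
   `s(q, x) = qᵀx`. For a query `q` with positives `P_q` in database `Ω`,

   `Recall@k(q) = Σ_{x∈P_q} H(k − r(q,x)) / |P_q|`,
   `r(q,x) = 1 + Σ_{z≠x} H(s_qz − s_qx)`,

   with `H` the Heaviside step (`H(0) = 1`, so ties count against the
   target). Both steps are replaced by sigmoids `σ_τ(u) = 1/(1+e^{−u/τ})` of
   temperatures `τ₂` (ranking) and `τ₁` (counting), the numerator is clipped
   at `k` and rescaled by `min(k, |P_q|)`, and the loss averaged over
   `k ∈ {1, 2, 4, 8, 16}` and all queries of a class-balanced mini-batch is
   minimized. The analytic gradient is implemented and verified against
   finite differences.
2. **Two-pass chunked updates.** A memory-bounded training step: pass 1
   embeds the batch in chunks without retained state and computes the loss
   gradient with respect to every embedding; pass 2 re-embeds each chunk and
   back-propagates the stored gradients. The accumulated parameter gradient
   equals the monolithic full-batch gradient (tested at double and
   emulated-single precision).
3. **kNN classification.** Each test embedding retrieves its 10 nearest
   training embeddings (exhaustive dot-product search) and a majority vote —
   ties broken by summed similarity, then class id — decides the species,
   with the neighbor evidence returned for interpretability.
4. **Prior-shift adaptation and fusion.** Classifier posteriors calibrated
   under training priors `p(c)` are re-weighted for test priors `p_e(c)` via
   `p_e(c|x) ∝ p(c|x) · p_e(c)/p(c)`; unknown test priors are estimated by
   EM (maximum likelihood on the test set), CM-L (decision-count likelihood
   through a validation confusion matrix) or SCM-L (its soft-confusion
   analogue). Per-image predictions of one specimen observation are fused by
   max/mean over softmax or logits, plus a 13-crop test-time-augmentation
   battery.

Everything is exercisable without downloads: synthetic generators produce
unit-norm embedding clusters, procedural class-pattern images grouped into
observations, calibrated posterior matrices under a planted prior shift, and
observation-grouped logits.

## Worked example

```r
library(embedknn)

# 10-class procedural image fixture, 30 images/class, 3 images/observation
dir <- tempfile()
man <- make_class_images(10, 30, side = 32, out_dir = dir, seed = 1)
tr <- man[man$split == "train", ]; te <- man[man$split == "test", ]
x_tr <- load_images(tr, 32, dir); x_te <- load_images(te, 32, dir)

# train the encoder with the Recall@k surrogate (two-pass chunked updates)
enc <- mlp(ncol(x_tr), 64, 128, "embedding", seed = 1)
fit <- train_retrieval(x_tr, tr$class_id, enc, epochs = 10,
                       batch_size = 40, chunk_size = 8, lr = 1e-3, seed = 1)
round(fit$loss_curve, 4)
#>  [1] 0.1739 0.1102 0.1085 0.1070 0.1065 0.1061 0.1047 0.1045 0.1045 0.1058

# kNN classification of the held-out split
db <- embedding_set(encoder_embed(fit$model, x_tr), tr$class_id,
                    tr$image_path, normalize = FALSE)
qs <- embedding_set(encoder_embed(fit$model, x_te), te$class_id,
                    te$image_path, normalize = FALSE)
knn <- predict_knn(qs, db, k = 10)
mean(knn$labels == te$class_id)
#> [1] 1
```

The loss starts near `1 − mean surrogate recall` of a random embedding and
drops towards its floor (the `k = 1` boundary term keeps it strictly above
0); on this well-separated fixture the held-out kNN accuracy reaches 1.0.

Prior-shift adaptation on calibrated synthetic posteriors (8 classes,
uniform training prior, Dirichlet-planted test prior, n = 10,000):

```r
tr_prior <- prior_vector(rep(1/8, 8))
set.seed(4); g <- rgamma(8, 1); planted <- prior_vector(g / sum(g))
fx <- make_calibrated_predictions(tr_prior, planted, 2, 10000, seed = 4)
est <- em_estimate_priors(fx$preds, tr_prior)
0.5 * sum(abs(as.numeric(est$priors) - as.numeric(planted)))  # TV error
#> [1] 0.01812682
```

## Command line

`inst/cli/embedknn.R` exposes the pipeline as subcommands
(`make-synthetic`, `train`, `embed`, `predict-knn`, `adapt-priors`, `fuse`,
`evaluate`, `run-pipeline`), each a thin wrapper over the functions above;
all take `--seed` and write TSV/JSON artifacts.

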