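---
title: "Retrieval-based species recognition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieval-based species recognition: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the smooth Recall@k training objective, the memory-bounded two-pass update,
nearest-neighbor classification, class-prior-shift adaptation, and
observation-level fusion — together with the parameters that matter, the
numerical choices, and what the synthetic fixtures do and do not establish.

## 1. The embedding space

An encoder maps an image to a `d`-dimensional vector which is
L2-normalized, so all embeddings live on the unit sphere and similarity is
the dot product (equivalently cosine similarity, bounded in `[-1, 1]`).
Normalization of a zero vector is a hard error rather than a clamp: a zero
raw embedding indicates a broken encoder, and silently mapping it anywhere
would poison every downstream similarity.

The embedding dimension is configurable with a desk-scale default of
`d = 128`; nothing in the method constrains `d`, and the default simply
balances capacity against the cost of the `O(|B|^2)` similarity matrices
formed during training. The encoder in this package is a small
fully-connected network (`mlp()`) with tanh hidden units and hand-derived
analytic gradients. A convolutional or transformer backbone would be the
choice at photographic scale; the training machinery only requires the
encoder contract — a deterministic forward pass (no active stochastic
layers) and a backward pass accepting embedding gradients — so the backbone
is swappable without touching the loss or the two-pass logic.

## 2. Exact Recall@k and its smooth surrogate

For query `q` with positive set `P_q` in database `Ω`, the rank of a
database item `x` is one plus the number of items scoring at least as high:
the Heaviside convention `H(0) = 1` means *ties count against the target*.
Recall@k counts the positives with rank at most `k`, clips the count at `k`
and rescales by `min(k, |P_q|)`, giving a metric in `[0, 1]` regardless of
how many positives exist.

The surrogate replaces both steps with logistic sigmoids:

- the **ranking** sigmoid of temperature `tau2` turns each pairwise score
  comparison into a soft count (the "smooth rank excess"),
- the **counting** sigmoid of temperature `tau1` turns `k - 1 - excess`
  into a soft membership of the top-k.

Defaults are `tau1 = 1` and `tau2 = 0.01`. These are implementation
choices — the method only calls for "appropriate temperatures" — and the
rationale is that a sharp ranking sigmoid keeps the soft ranks close to the
real ones while a soft counting sigmoid keeps gradients alive for positives
far outside the top-k. Both are exposed in `recall_config()`.

Two boundary facts are worth keeping in mind when reading loss values:

- A positive at exact rank `k` sits at the counting sigmoid's midpoint, so
  its contribution is 0.5, not 1: a batch whose queries all have their best
  positive at rank 1 has a `k = 1` loss of exactly 0.5. This is an
  intentional difference from the exact metric, whose step at 0 returns 1.
- Away from those boundaries (no positive at rank exactly `k`, score gaps
  large relative to `tau2`), the surrogate converges to the exact metric as
  the temperatures shrink; the suite asserts agreement within `1e-3` at
  `tau = 1e-3`.

One property the smooth objective does **not** have: with several positives
per query, increasing one positive's similarity can slightly *decrease* the
summed surrogate recall, because that positive now inflates the smooth rank
excess of its sibling positives. The exact metric is monotone (away from
ties); the surrogate is monotone when the query has a single positive. The
tests assert exactly those two true forms.

The batch loss averages `1 - surrogate recall` over `k` in
`K = {1, 2, 4, 8, 16}` and over every batch sample acting as query against
the batch minus itself; it is bounded in `[0, 1]` and permutation
invariant. The analytic gradient (including the chain through L2
normalization, which projects onto the tangent space of the sphere) is
verified against central finite differences and the loss itself against a
literal double-loop transcription.

The numerator clip `min(sum, k)` is non-differentiable at equality; the
implementation uses the subgradient that is 1 below the clip and 0 above.
Random batches hit exact equality with probability zero, and the choice is
applied consistently in the monolithic and chunked paths. The sigmoid is
computed in branch form (separate expressions for positive and negative
arguments), so it saturates to exact 0/1 without overflow at any
`|u|/tau`.

## 3. Class-balanced sampling and the two-pass update

Every batch is built from `batch_size / samples_per_class` distinct classes
with exactly `samples_per_class = 4` samples each, which guarantees the
loss precondition (every query has an in-batch positive) by construction
rather than by skipping queries. Classes with fewer members than 4 are
sampled with replacement — dropping rare species would bias exactly the
classes this field cares about. At full photographic scale the recipe uses
batches of 4,000 in chunks of 200; the desk-scale defaults are 40 and 8,
which exercise the identical code paths.

The two-pass update bounds memory at one chunk of activations: pass 1
embeds chunk by chunk, discarding intermediate state, and computes the loss
gradient with respect to the full embedding matrix; pass 2 re-embeds each
chunk with state retained and back-propagates the stored embedding
gradients. Because the encoder is deterministic in evaluation mode — a
contract this package enforces by construction, since the `mlp` has no
stochastic layers — the accumulated parameter gradient equals the
monolithic full-batch gradient up to floating-point summation order. The
suite checks relative agreement below `1e-10` in double precision, and
below `1e-5` when the stored embeddings and embedding gradients are
round-tripped through 4-byte floats (`store_precision = "single"`), which
emulates where a GPU implementation actually loses precision in this
scheme.

Optimization uses AdamW (initial learning rate `1e-4` at full scale; the
desk-scale driver defaults to `1e-3` for the much smaller network) with a
step-decay schedule of factor 0.3. The decay milestones are not part of the
published recipe; the defaults `{50, 80}` of a 100-epoch run are
configurable. The baseline classifier uses SGD with momentum 0.9, gradient
accumulation to an effective batch of 128 (4 micro-batches of 32; the
accumulated update is tested to equal the monolithic one), and the
plateau-adaptive schedule that multiplies the learning rate by 0.9 after
two consecutive non-improving validation epochs. Cyclic cosine annealing
(20% start-of-cycle decay, cosine to 0 within a cycle — the floor is a
choice, the recipe is silent on it) is provided for the fine-tuning
experiments.

Augmentation follows the standard recipe: random resized crop with area
scale 0.8–1.0, horizontal and vertical flips at p = 0.5, brightness and
contrast jitter in ±0.2 at p = 0.2; inputs are rescaled to `[0, 1]` and
normalized with mean and std 0.5 per channel. All schedules and samplers
are pure functions of `(epoch, history, config, seed)`, so every run is
replayable from its logged configuration.

## 4. kNN classification

Each test embedding retrieves its `k = 10` nearest training embeddings by
exhaustive dot-product search — at desk scale there is no reason to accept
the approximation error of an ANN index, and the contract is exact
agreement with a similarity-sort oracle. A plain majority vote decides the
class; the vote is deliberately *unweighted* (similarity enters only as a
tie-break, followed by the lexicographically smallest class id, making the
decision a total order and hence deterministic). The neighbor evidence
(ids, labels, scores) is part of the return value: the ability to show a
user the ten training specimens behind a decision is the main practical
argument for the retrieval formulation.

## 5. Prior-shift adaptation

When class-conditional appearance is unchanged but class frequencies move
(label shift), a calibrated posterior is corrected by multiplying with the
prior ratio and renormalizing. Posteriors are floored at `1e-12` before the
division; a zero *training* prior for a class with posterior mass is an
error, not a guess.

Three estimators of the unknown test priors are implemented:

- **EM** alternates re-weighting (E) and averaging (M), initialized at the
  training priors — the natural no-shift start. Stopping: max-abs prior
  change below `1e-8` or 1,000 iterations. The observed-data log-likelihood
  is checked to be non-decreasing at every iteration; a violation is a bug,
  not noise, and raises an error.
- **CM-L** maximizes the likelihood of the hard decision counts through a
  validation confusion matrix (column = true class, row = decision). The
  objective is concave on the simplex; the solver uses EM-style
  multiplicative updates (a fixed point of the stationarity condition) and
  verifies a KKT residual below `1e-8` at the returned point.
- **SCM-L** is specified in the literature only as working "analogically"
  with the soft confusion matrix. This package adopts the soft-count
  log-likelihood `N * sum_i pbar_i log((C_soft P)_i)` with `pbar` the mean
  test prediction — the direct soft analogue of the CM-L objective, solved
  by the same routine. This is an interpretation, and it is validated by
  two properties: with one-hot predictions and a hard confusion matrix it
  reduces exactly to CM-L, and on small instances it agrees with a simplex
  grid search.

Confusion matrices are estimated on a held-out validation split drawn from
the *training* distribution — never on test data, whose class distribution
is precisely what is unknown. When test-time augmentation is active,
adaptation is applied to each crop's prediction *before* any averaging.

## 6. Observation fusion, TTA and evaluation

A specimen observation is a set of images of one plant. Four fusion
strategies combine per-image predictions: element-wise max or mean over
softmax or logits, deciding the argmax (ties to the smallest class id).
All four are permutation invariant; the mean of softmax rows stays on the
simplex. Logits here are pre-softmax activations, and files must carry
logit columns for a logit strategy to be available — softmax cannot be
inverted per-row without losing the shared scale.

The 13-crop TTA battery is: the full image; central crops at 90, 80, 70
and 60% of each dimension; and 80/70% crops anchored at each of the four
corners. The published description lists "four central crops" but only
three sizes against a stated total of 13; this package resolves the
mismatch with a fourth central crop at 60%, which restores the count while
continuing the listed progression. Boxes are 0-based and half-open with
floored sizes.

Evaluation reports image-wise accuracy, observation-wise accuracy on fused
decisions (an observation's truth is the unique truth of its images;
conflicting labels are a data error, as is an observation split across
train/test), and macro-F1 averaged over the classes present in the truth —
a class with no true and no predicted positives scores 0. Macro-F1 is the
metric that exposes the cost of mimicking a long-tailed training prior,
which is where the retrieval approach earns its keep.

## 7. Synthetic fixtures: what they show and what they do not

The generators produce data with exactly the statistical structure each
method assumes:

- `make_embedding_clusters()`: unit-norm clusters with a minimum
  center-separation (rejection sampling with a bounded budget) — the
  geometry kNN assumes.
- `make_class_images()`: procedurally distinct class patterns (blob
  position/hue, stripe frequency) with per-sample jitter, grouped into
  observations and split *by observation*. A nearest-centroid pixel
  classifier already exceeds 90% on it, which is the point: it is learnable
  enough to test the training loop end to end in seconds on one CPU.
- `make_calibrated_predictions()`: labels from a planted test prior, rows
  the *analytic* Bayes posterior under the training prior (Gaussian latent
  scores), so calibration — the identifiability assumption of EM — holds
  exactly by construction rather than approximately by training.
- `make_observation_logits()`: signal-plus-independent-noise logits, where
  averaging over the 5 images of an observation cuts the noise variance by
  5 — the mechanism by which fusion beats per-image decisions.

Every generator is a pure function of its configuration and seed
(bit-identical on repeated calls), and the study conditions used by the
tests and the acceptance script are the generators' defaults: 10 classes ×
30 images at 32 px for the image fixture; 8 classes, uniform training
prior, Dirichlet-planted shift, n = 10,000 for prior recovery; 2,000
observations × 5 images, signal 1, noise 1 for fusion; latent separation 2
for calibrated posteriors (informative but far from one-hot, leaving room
for adaptation to matter).

What passing on these fixtures does *not* show: performance on photographs.
Real images violate every convenient assumption here — class-conditional
appearance drifts with season and location (breaking the label-shift
premise), posteriors of a trained network are mis-calibrated (breaking EM's
premise exactly where it is needed), intra-class variance is multimodal
(organ types), and 10,000-class retrieval needs an ANN index whose errors
this package deliberately excludes from its contracts. The fixtures
validate the *mathematics and the code paths*; claims about photographic
accuracy require the full-scale datasets and backbones, which are out of
scope here.

## 8. Desk-scale problem sizes

Chosen so the full suite runs in well under a minute of CPU apart from the
end-to-end smoke (a few seconds itself): batch 40 / chunk 8 / d = 128 /
10 epochs for training, 1,000-item databases × 100 queries for the kNN
oracle, n up to 10,000 for prior estimation. These mirror the full-scale
recipe (4,000/200, 100 epochs) at 1/100 of the batch, keeping every code
path — chunking, clipping, resampling — active.

## 9. Known limitations

- The encoder is a fully-connected network; no convolutional inductive
  bias, no pretraining. Adequate for procedural patterns, not photographs.
- The retrieval path has no posterior, so prior-shift adaptation applies
  only to the classifier branch (vote shares are not calibrated
  probabilities).
- CM-L's multiplicative updates converge linearly; for ill-conditioned
  confusion matrices near the boundary of the simplex the iteration cap may
  bind before the `1e-8` KKT residual (the residual is always reported).
- Open-set rejection — a natural strength of the retrieval formulation —
  is not implemented; no threshold on neighbor similarity is specified
  anywhere in the pipeline.
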