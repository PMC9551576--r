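Package: embedknn
Title: Retrieval-Based Fine-Grained Species Recognition in Deep Embedding Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fine-grained species recognition posed as image retrieval: an
    encoder is trained with a differentiable Recall@k surrogate loss to map
    images onto the unit sphere, test images are classified by a majority vote
    over their nearest training embeddings, classifier posteriors are adapted
    to a shifted test-time class prior (EM and confusion-matrix likelihood
    maximization), and per-image predictions are fused into observation-level
    decisions (max/mean over softmax or logits, multi-crop test-time
    augmentation). Includes a memory-bounded two-pass chunked gradient update
    equivalent to full-batch training, class-balanced batch sampling, learning
    rate schedules, evaluation metrics (image and observation accuracy,
    macro-F1), and synthetic fixture generators that emulate the statistical
    structure the methods assume.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
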