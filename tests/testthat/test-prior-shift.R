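test_that("posterior re-weighting follows the prior-ratio rule", {
  pm <- prediction_matrix(rbind(c(0.5, 0.5), c(0.6, 0.4)), "posterior",
                          c("s1", "s2"), c("a", "b"))
  tr <- prior_vector(c(0.5, 0.5))
  # identity case
  same <- adapt_posteriors(pm, tr, tr)
  expect_lt(max(abs(same$scores - pm$scores)), 1e-12)
  # (0.5, 0.5) with test (0.8, 0.2) -> (0.8, 0.2)
  ad <- adapt_posteriors(pm, tr, prior_vector(c(0.8, 0.2)))
  expect_equal(unname(ad$scores[1, ]), c(0.8, 0.2), tolerance = 1e-12)
  # (0.6, 0.4), test (0.25, 0.75) -> weights 0.3/0.6 renormalized
  ad2 <- adapt_posteriors(pm, tr, prior_vector(c(0.25, 0.75)))
  expect_equal(unname(ad2$scores[2, ]), c(1 / 3, 2 / 3), tolerance = 1e-12)
  # rows renormalize to 1
  expect_lt(max(abs(rowSums(ad2$scores) - 1)), 1e-12)
})

test_that("EM fixes at the train prior when the mean posterior matches it", {
  pm <- prediction_matrix(rbind(c(0.7, 0.3), c(0.3, 0.7)), "posterior")
  tr <- prior_vector(c(0.5, 0.5))
  est <- em_estimate_priors(pm, tr)
  expect_equal(as.numeric(est$priors), c(0.5, 0.5), tolerance = 1e-10)
  expect_lte(nrow(est$trace), 2)
})

test_that("EM recovers a planted test prior with monotone likelihood", {
  tr <- prior_vector(rep(1 / 8, 8))
  set.seed(4)
  g <- rgamma(8, 1)
  planted <- prior_vector(g / sum(g))
  fx <- make_calibrated_predictions(tr, planted, class_separation = 2,
                                    n = 10000, seed = 4)
  est <- em_estimate_priors(fx$preds, tr)
  tv <- 0.5 * sum(abs(as.numeric(est$priors) - as.numeric(planted)))
  expect_lt(tv, 0.05)
  # per-iteration log-likelihood never decreases
  expect_true(all(diff(est$trace$loglik) >= -1e-8))
  # estimate on the simplex
  expect_true(all(est$priors >= 0))
  expect_lt(abs(sum(est$priors) - 1), 1e-10)
})

test_that("EM error shrinks as the test set grows", {
  tr <- prior_vector(rep(1 / 8, 8))
  set.seed(4)
  g <- rgamma(8, 1)
  planted <- prior_vector(g / sum(g))
  mean_tv <- sapply(c(100, 1000, 10000), function(n) {
    mean(sapply(1:5, function(s) {
      fx <- make_calibrated_predictions(tr, planted, 2, n, seed = s)
      est <- em_estimate_priors(fx$preds, tr)
      0.5 * sum(abs(as.numeric(est$priors) - as.numeric(planted)))
    }))
  })
  expect_true(all(diff(mean_tv) <= 0.01))  # non-increasing within noise
})

test_that("confusion matrices match a hand loop and the stated identities", {
  fx <- make_calibrated_predictions(prior_vector(rep(1 / 3, 3)),
                                    prior_vector(rep(1 / 3, 3)),
                                    2, 600, seed = 6)
  hard <- estimate_confusion(fx$preds, fx$labels, "hard")
  soft <- estimate_confusion(fx$preds, fx$labels, "soft")
  expect_lt(max(abs(colSums(hard$entries) - 1)), 1e-12)
  expect_lt(max(abs(colSums(soft$entries) - 1)), 1e-12)
  # hand-looped soft column
  for (k in fx$class_ids) {
    rows <- fx$labels == k
    manual <- colMeans(fx$preds$scores[rows, , drop = FALSE])
    expect_equal(unname(soft$entries[, k]), unname(manual),
                 tolerance = 1e-12)
  }
  # one-hot predictions: soft == hard; perfect classifier -> identity
  onehot <- prediction_matrix(diag(3)[c(1, 2, 3, 1, 2, 3), ], "posterior",
                              class_ids = c("a", "b", "c"))
  truth <- c("a", "b", "c", "a", "b", "c")
  h2 <- estimate_confusion(onehot, truth, "hard")
  s2 <- estimate_confusion(onehot, truth, "soft")
  expect_equal(h2$entries, s2$entries, tolerance = 1e-15)
  expect_equal(unname(h2$entries), diag(3))
  expect_error(estimate_confusion(onehot, c("a", "b", "a", "a", "b", "a"),
                                  "hard"), "absent")
})

test_that("CM-L solves the decision-likelihood program", {
  # identity confusion -> decision frequencies exactly
  Cid <- estimate_confusion(
    prediction_matrix(diag(2)[c(1, 1, 2), ], "posterior",
                      class_ids = c("a", "b")),
    c("a", "a", "b"), "hard")
  r0 <- cml_estimate_priors(c(30, 70), Cid)
  expect_equal(as.numeric(r0$priors), c(0.3, 0.7), tolerance = 1e-9)

  # the 2-class instance vs a 1e-6 grid search
  C <- structure(list(entries = matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2),
                      kind = "hard", class_ids = c("a", "b")),
                 class = "confusion_matrix")
  r <- cml_estimate_priors(c(60, 40), C)
  expect_equal(as.numeric(r$priors), c(0.6, 0.4), tolerance = 1e-6)
  p1_grid <- oracle_cml_2class(c(60, 40), C$entries)
  expect_equal(as.numeric(r$priors)[1], p1_grid, tolerance = 2e-6)
  expect_lt(r$kkt_residual, 1e-8)
  # always on the simplex
  expect_true(all(r$priors >= 0))
  expect_lt(abs(sum(r$priors) - 1), 1e-10)
  expect_error(cml_estimate_priors(
    c(10, 0), structure(list(entries = matrix(c(0, 1, 0, 1), 2, 2),
                             kind = "hard", class_ids = c("a", "b")),
                        class = "confusion_matrix")), "infeasible")
})

test_that("SCM-L reduces to CM-L on one-hot input and matches a grid oracle", {
  onehot <- prediction_matrix(diag(3)[c(1, 1, 2, 3, 3, 3), ], "posterior",
                              class_ids = c("a", "b", "c"))
  truth3 <- c("a", "b", "c", "a", "b", "c")
  val <- prediction_matrix(diag(3)[c(1, 2, 3, 1, 2, 3), ], "posterior",
                           class_ids = c("a", "b", "c"))
  hard <- estimate_confusion(val, truth3, "hard")
  soft <- estimate_confusion(val, truth3, "soft")
  counts <- as.numeric(table(factor(c("a", "a", "b", "c", "c", "c"),
                                    levels = c("a", "b", "c"))))
  r_cml <- cml_estimate_priors(counts, hard)
  r_scml <- scml_estimate_priors(onehot, soft)
  expect_equal(as.numeric(r_scml$priors), as.numeric(r_cml$priors),
               tolerance = 1e-9)

  # identity soft confusion -> mean prediction vector
  fx <- make_calibrated_predictions(prior_vector(rep(1 / 3, 3)),
                                    prior_vector(c(0.2, 0.3, 0.5)),
                                    2, 400, seed = 8)
  id_soft <- structure(list(entries = diag(3), kind = "soft",
                            class_ids = fx$class_ids),
                       class = "confusion_matrix")
  r_id <- scml_estimate_priors(fx$preds, id_soft)
  expect_equal(as.numeric(r_id$priors), unname(colMeans(fx$preds$scores)),
               tolerance = 1e-8)

  # 3-class instance vs simplex grid search (step 1e-3) in total variation
  val3 <- make_calibrated_predictions(prior_vector(rep(1 / 3, 3)),
                                      prior_vector(rep(1 / 3, 3)),
                                      2, 900, seed = 80)
  soft3 <- estimate_confusion(val3$preds, val3$labels, "soft")
  r3 <- scml_estimate_priors(fx$preds, soft3)
  pbar <- colMeans(fx$preds$scores)
  obj <- function(P) {
    q <- as.vector(soft3$entries %*% P)
    if (any(q <= 0)) return(-Inf)
    nrow(fx$preds$scores) * sum(pbar * log(q))
  }
  grid <- oracle_simplex_grid_3(obj, step = 1e-3)
  expect_lt(0.5 * sum(abs(as.numeric(r3$priors) - grid)), 5e-3)
})

test_that("prior adaptation improves accuracy under shift, is inert without", {
  tr <- prior_vector(rep(1 / 8, 8))
  set.seed(4)
  g <- rgamma(8, 1)
  planted <- prior_vector(g / sum(g))
  fx <- make_calibrated_predictions(tr, planted, 2, 10000, seed = 4)
  val <- make_calibrated_predictions(tr, tr, 2, 5000, seed = 41)
  cm_hard <- estimate_confusion(val$preds, val$labels, "hard")
  cm_soft <- estimate_confusion(val$preds, val$labels, "soft")
  acc <- function(pm, y)
    mean(pm$class_ids[max.col(pm$scores, ties.method = "first")] == y)
  base <- acc(fx$preds, fx$labels)
  for (spec in list(list("EM", NULL), list("CML", cm_hard),
                    list("SCML", cm_soft))) {
    ad <- adapt_pipeline(fx$preds, tr, spec[[1]], spec[[2]])
    expect_gte(acc(ad$adapted, fx$labels), base)
    expect_lt(abs(sum(ad$priors) - 1), 1e-10)
  }
  # no shift planted: change bounded by 0.5 points
  fx0 <- make_calibrated_predictions(tr, tr, 2, 10000, seed = 4)
  ad0 <- adapt_pipeline(fx0$preds, tr, "EM")
  expect_lt(abs(acc(ad0$adapted, fx0$labels) - acc(fx0$preds, fx0$labels)),
            0.005)
  expect_error(adapt_pipeline(fx$preds, tr, "CML"), "confusion")
})
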