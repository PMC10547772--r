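test_that("AUC equals the pairwise concordance oracle", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.4, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_auc(c(0.9, 0.5, 0.5, 0.2), c(1, 1, 0, 0)), 0.875)

  withr::with_seed(21, {
    for (rep in 1:20) {
      n <- sample(4:12, 1)
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))
      p <- round(runif(n), 2)   # rounding forces ties
      expect_equal(compute_auc(p, y), brute_auc(p, y))
    }
  })

  # invariance under strictly increasing transforms
  p <- c(0.1, 0.4, 0.35, 0.8); y <- c(0, 1, 0, 1)
  expect_equal(compute_auc(plogis(10 * p), y), compute_auc(p, y))

  expect_error(compute_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("G-mean threshold matches exhaustive candidate search", {
  sep <- optimal_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(sep$G, 1)
  expect_equal(sep$threshold, 0.5)

  mixed <- optimal_threshold(c(0.1, 0.6, 0.4, 0.9), c(0, 0, 1, 1))
  oracle <- brute_threshold(c(0.1, 0.6, 0.4, 0.9), c(0, 0, 1, 1))
  expect_equal(mixed$threshold, oracle$threshold)
  expect_equal(mixed$G, oracle$G)
  expect_equal(mixed$G, sqrt(0.5))

  withr::with_seed(22, {
    for (rep in 1:20) {
      n <- sample(5:14, 1)
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))
      p <- round(runif(n), 2)
      got <- optimal_threshold(p, y)
      want <- brute_threshold(p, y)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$G, want$G)
      # consistency: G recomputed from confusion counts at t*
      pred <- as.integer(p >= got$threshold)
      sens <- sum(pred & y) / sum(y)
      spc <- sum(!pred & !y) / sum(!y)
      expect_equal(got$G, sqrt(sens * spc))
    }
  })
})

test_that("leave-one-out runs score every instance once and separate cleanly", {
  d <- sep_features(n0 = 5, n1 = 7, n_sig = 2, n_noise = 1, delta = 6,
                    seed = 30)
  cons <- rep(list(colnames(d$X)), nrow(d$X))
  run <- suppressWarnings(
    loo_run(d$X, d$y, model_spec("gaussian-naive-bayes"), smote_seed = 1,
            consensus = cons))
  expect_length(run$probs, nrow(d$X))
  expect_true(all(is.finite(run$probs) & run$probs >= 0 & run$probs <= 1))
  expect_equal(run$auc, 1.0)
  expect_equal(run$G, 1.0)

  run2 <- suppressWarnings(
    loo_run(d$X, d$y, model_spec("gaussian-naive-bayes"), smote_seed = 1,
            consensus = cons))
  expect_identical(run$probs, run2$probs)  # determinism at fixed seed
})

test_that("replicated runs share fold features and vary only with SMOTE", {
  d <- sep_features(n0 = 6, n1 = 9, n_sig = 2, n_noise = 2, delta = 3,
                    seed = 31)
  cons <- rep(list(colnames(d$X)), nrow(d$X))
  runs <- suppressWarnings(replicate_runs(
    d$X, d$y, model_spec("random-forest", ntree = 25, max_depth = 3),
    consensus = cons, n_runs = 3))
  expect_length(runs, 3)
  expect_equal(vapply(runs, `[[`, numeric(1), "smote_seed"), 1:3)
  for (r in runs) expect_identical(r$consensus, cons)
  aucs <- vapply(runs, `[[`, numeric(1), "auc")
  expect_true(all(aucs >= 0 & aucs <= 1))
})

test_that("best-model selection uses median AUC then IQR then order", {
  dists <- list(c(0.90, 0.90, 0.90), c(0.94, 0.93, 0.95), c(0.94, 0.935, 0.945))
  expect_equal(select_best_model(dists), 3)   # tie on median, lower IQR
  expect_equal(select_best_model(dists[1]), 1)
  # permuting candidates moves the winner consistently
  expect_equal(select_best_model(dists[c(2, 3, 1)]), 2)
})

test_that("aggregation produces normalized confusion and stability buckets", {
  mk_run <- function(probs, thr) structure(
    list(probs = probs, threshold = thr), class = "run_result")
  y <- c(0, 0, 1, 1)
  runs <- list(mk_run(c(0.1, 0.2, 0.8, 0.9), 0.5),
               mk_run(c(0.1, 0.2, 0.8, 0.9), 0.5))
  agg <- aggregate_results(runs, y, diagnoses = c("healthy", "benign",
                                                  "PTC", "PTC"))
  expect_equal(unname(rowSums(agg$confusion)), c(1, 1))
  expect_equal(unname(diag(agg$confusion)), c(1, 1))
  expect_true(all(agg$stability$bucket == "0%"))
  expect_equal(agg$per_diagnosis$median_prob[agg$per_diagnosis$diagnosis ==
                                               "healthy"], 0.1)

  # one instance flips between two runs: contributes 1/2 to each cell
  runs2 <- list(mk_run(c(0.1, 0.2, 0.8, 0.9), 0.5),
                mk_run(c(0.1, 0.6, 0.8, 0.9), 0.5))
  agg2 <- aggregate_results(runs2, y)
  expect_equal(unname(agg2$confusion["0", ]), c(0.75, 0.25))
  expect_equal(unname(rowSums(agg2$confusion)), c(1, 1))
  expect_equal(agg2$stability$discrepancy[2], 0.5)
})

test_that("held-out scoring reproduces a duplicated training instance", {
  d <- sep_features(n0 = 8, n1 = 10, n_sig = 3, n_noise = 2, delta = 5,
                    seed = 33)
  cons <- rep(list(colnames(d$X)), nrow(d$X))
  spec <- model_spec("gaussian-naive-bayes")
  runs <- suppressWarnings(replicate_runs(d$X, d$y, spec, cons, n_runs = 2))
  X_new <- d$X[c(1, nrow(d$X)), , drop = FALSE]
  out <- suppressWarnings(classify_held_out(
    d$X, d$y, X_new, spec, n_runs = 2, n_states = 2, y_new = c(0, 1),
    train_runs = runs, boruta_args = list(max_iter = 25, num_trees = 50)))
  expect_equal(dim(out$probs), c(2, 2))
  # a held-out copy of a class-0 instance scores like class 0
  expect_lt(mean(out$probs[1, ]), 0.5)
  expect_gt(mean(out$probs[2, ]), 0.5)
  expect_length(out$pooled_auc, 2)
  expect_true(all(out$pooled_auc <= 1 & out$pooled_auc >= 0.5))
  expect_error(
    classify_held_out(d$X, d$y, X_new[, 1:2, drop = FALSE], spec),
    "feature mismatch")
})
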