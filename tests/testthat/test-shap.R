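test_that("enumeration oracle satisfies additivity, efficiency and weights", {
  # additive value function: Shapley value of j equals its coefficient
  cc <- c(0.5, -1.2, 2.0, 0.3)
  vadd <- function(F) sum(cc[F])
  expect_equal(shap_oracle_all(vadd, 4), cc)

  # 3-feature value function given as a table, checked against the
  # permutation-average definition computed independently
  vtab <- c(0, 1, 2, 4, 3, 6, 7, 10)   # index = bitmask + 1
  vfun <- function(F) vtab[sum(2^(F - 1)) + 1]
  perms <- matrix(c(1,2,3, 1,3,2, 2,1,3, 2,3,1, 3,1,2, 3,2,1), ncol = 3,
                  byrow = TRUE)
  want <- numeric(3)
  for (r in seq_len(nrow(perms))) {
    pre <- integer(0)
    for (j in perms[r, ]) {
      want[j] <- want[j] + (vfun(c(pre, j)) - vfun(pre)) / nrow(perms)
      pre <- c(pre, j)
    }
  }
  got <- shap_oracle_all(vfun, 3)
  expect_equal(got, want)
  expect_equal(sum(got), vfun(1:3) - vfun(integer(0)))  # efficiency

  # subset weights sum to one for every |S|
  for (m in 2:6) {
    others <- seq_len(m - 1)
    w <- 0
    for (mask in 0:(2^(m - 1) - 1)) {
      f <- sum(bitwAnd(mask, 2^(others - 1)) > 0)
      w <- w + factorial(f) * factorial(m - f - 1) / factorial(m)
    }
    expect_equal(w, 1)
  }

  expect_error(exact_shap_oracle(vadd, 13, 1), "12")
})

test_that("TreeSHAP matches exact enumeration of the forest value function", {
  d <- sep_features(n0 = 20, n1 = 20, n_sig = 2, n_noise = 3, delta = 2,
                    seed = 40)
  fit <- fit_model(model_spec("random-forest", ntree = 12, max_depth = 3),
                   d$X, d$y, seed = 1)
  forest <- rf_forest(fit)
  for (i in c(1, 15, 40)) {
    x <- d$X[i, ]
    ts <- tree_shap(fit, x, forest = forest)
    vfun <- function(F) forest_expvalue(forest, x, F)
    oracle <- shap_oracle_all(vfun, ncol(d$X))
    expect_equal(unname(ts$phi), oracle, tolerance = 1e-6)
    # local accuracy against the forest's predicted vote fraction
    expect_equal(sum(ts$phi) + ts$base,
                 predict_prob(fit, matrix(x, 1,
                                          dimnames = list(NULL, colnames(d$X)))),
                 tolerance = 1e-9)
  }
})

test_that("TreeSHAP gives zero to unused features, identical twins agree", {
  d <- sep_features(n0 = 15, n1 = 15, n_sig = 1, n_noise = 1, delta = 8,
                    seed = 41)
  X <- cbind(d$X, dead = rep(1, nrow(d$X)))   # constant: never split on
  fit <- fit_model(model_spec("random-forest", ntree = 10, max_depth = 2),
                   X, d$y, seed = 2)
  s1 <- tree_shap(fit, X[1, ])
  expect_equal(unname(s1$phi["dead"]), 0)
  s2 <- tree_shap(fit, X[1, ])
  expect_identical(s1, s2)
})

test_that("interventional explainer is exact and locally accurate", {
  d <- sep_features(n0 = 12, n1 = 12, n_sig = 2, n_noise = 2, delta = 3,
                    seed = 42)
  fit <- fit_model(model_spec("gaussian-naive-bayes"), d$X, d$y)
  x <- d$X[3, ]
  sh <- shap_interventional(fit, x)
  # independent value function over the same background
  bg <- fit$X_train   # 24 rows: below the subsampling cap, used as-is
  vfun <- function(F) {
    hyb <- bg
    for (j in F) hyb[, j] <- x[j]
    mean(predict_prob(fit, hyb))
  }
  expect_equal(unname(sh$phi), shap_oracle_all(vfun, 4), tolerance = 1e-9)
  # efficiency: attributions + base reproduce the model output
  expect_equal(sum(sh$phi) + sh$base, unname(vfun(1:4)), tolerance = 1e-9)
  expect_equal(vfun(1:4), predict_prob(fit, matrix(x, 1,
                 dimnames = list(NULL, colnames(d$X)))), tolerance = 1e-9)
})

test_that("gradient-boosted attributions are locally accurate on the margin", {
  d <- sep_features(n0 = 15, n1 = 15, n_sig = 2, n_noise = 2, delta = 3,
                    seed = 43)
  fit <- fit_model(model_spec("gradient-boosted-trees", num_parallel_tree = 10,
                              max_depth = 3, nrounds = 10), d$X, d$y, seed = 1)
  sh <- shap_for_fold(fit, d$X[5, ])
  p <- predict_prob(fit, d$X[5, , drop = FALSE])
  expect_equal(sum(sh$phi) + sh$base, qlogis(p), tolerance = 1e-4)
})

test_that("run averaging zero-fills unselected features", {
  feats <- c("f1", "f2", "f3")
  run_a <- list(phi = list(c(f1 = 0.4, f2 = -0.2), c(f1 = 0.1, f2 = 0.0)),
                base = c(0.5, 0.5))
  run_b <- list(phi = list(c(f1 = 0.4), c(f1 = 0.3)), base = c(0.6, 0.6))
  e <- average_shap(list(run_a, run_b), feats)
  expect_equal(unname(e$mean_shap[1, "f1"]), 0.4)
  expect_equal(unname(e$mean_shap[1, "f2"]), -0.1)  # selected in half the runs
  expect_equal(unname(e$mean_shap[, "f3"]), c(0, 0))  # never selected
  expect_equal(e$base, c(0.5, 0.6))

  run_bad <- list(phi = list(c(f1 = 1)), base = 0.5)
  expect_error(average_shap(list(run_a, run_bad), feats), "completeness")
})

test_that("feature ranking orders by mean absolute value with directions", {
  e <- structure(list(mean_shap = cbind(
    a = c(0.1, -0.1, 0.2), b = c(0, 0, 0), c = c(0.5, 0.4, -0.6))),
    class = "shap_explanation")
  X <- cbind(a = c(1, -1, 2), b = c(1, 2, 3), c = c(5, 4, 0))
  r <- rank_features(e, X, top_n = 20)
  expect_equal(r$feature, c("c", "a", "b"))   # brute-force sort oracle
  expect_equal(r$mean_abs_shap, c(0.5, 2 / 15, 0))
  expect_equal(r$direction[1:2], c("cancer", "cancer"))
  expect_equal(r$direction[3], "flat")
  expect_equal(nrow(rank_features(e, X, top_n = 2)), 2)
})
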