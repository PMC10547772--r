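#' Exact Shapley value by subset enumeration
#'
#' Direct evaluation of the Shapley formula
#' `SHAP_j = sum_{F subset S \ {j}} |F|! (|S|-|F|-1)! / |S|! [v(F u j) - v(F)]`
#' for a value function `v` over feature subsets. Exhaustive over the
#' `2^(|S|-1)` subsets, so limited to `|S| <= 12`.
#'
#' @param vfun function taking an integer vector of feature indices
#'   (possibly empty) and returning the model value for that subset.
#' @param n_features total number of features `|S|`.
#' @param j feature index to attribute.
#' @return The exact Shapley value of feature `j`.
#' @export
exact_shap_oracle <- function(vfun, n_features, j) {
  if (n_features > 12)
    stop("exhaustive enumeration limited to 12 features", call. = FALSE)
  others <- setdiff(seq_len(n_features), j)
  total <- 0
  for (mask in 0:(2^length(others) - 1)) {
    F <- others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0]
    f <- length(F)
    w <- factorial(f) * factorial(n_features - f - 1) / factorial(n_features)
    total <- total + w * (vfun(sort(c(F, j))) - vfun(F))
  }
  total
}

#' Exact Shapley values for all features
#'
#' @inheritParams exact_shap_oracle
#' @return Numeric vector of length `n_features`.
#' @export
shap_oracle_all <- function(vfun, n_features) {
  vapply(seq_len(n_features), function(j)
    exact_shap_oracle(vfun, n_features, j), numeric(1))
}

# ---- random forest tree extraction -----------------------------------------

# One tree as parallel vectors; covers are in-bag training counts per node,
# so the conditional-expectation value function is defined by the data the
# tree was grown on.
extract_tree <- function(rf, k, X_train) {
  tr <- randomForest::getTree(rf, k, labelVar = FALSE)
  n_nodes <- nrow(tr)
  cover <- numeric(n_nodes)
  wrow <- rf$inbag[, k]
  left <- tr[, "left daughter"]; right <- tr[, "right daughter"]
  var <- tr[, "split var"]; split <- tr[, "split point"]
  stack <- list(list(node = 1L, idx = seq_len(nrow(X_train))))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    cover[top$node] <- sum(wrow[top$idx])
    if (tr[top$node, "status"] != -1L) {
      v <- var[top$node]
      goleft <- X_train[top$idx, v] <= split[top$node]
      stack[[length(stack) + 1]] <- list(node = left[top$node],
                                         idx = top$idx[goleft])
      stack[[length(stack) + 1]] <- list(node = right[top$node],
                                         idx = top$idx[!goleft])
    }
  }
  list(left = left, right = right, var = var, split = split,
       leaf = tr[, "status"] == -1L,
       value = as.numeric(tr[, "prediction"]) - 1,  # vote for class "1"
       cover = cover)
}

#' Extract a random forest as explicit tree structures
#'
#' @param model a `fitted_model` of family `"random-forest"` (fitted with
#'   in-bag counts kept, as [fit_model()] does).
#' @return List of tree structures used by [tree_shap()].
#' @export
rf_forest <- function(model) {
  stopifnot(inherits(model, "fitted_model"),
            model$spec$family == "random-forest")
  lapply(seq_len(model$fit$ntree), extract_tree, rf = model$fit,
         X_train = model$X_train)
}

# cover-weighted conditional expectation of one tree for instance x given
# the feature subset S (indices into x); the value function whose exact
# Shapley values tree_shap computes
tree_expvalue <- function(tree, x, S) {
  rec <- function(node) {
    if (tree$leaf[node]) return(tree$value[node])
    v <- tree$var[node]
    if (v %in% S) {
      if (x[v] <= tree$split[node]) rec(tree$left[node])
      else rec(tree$right[node])
    } else {
      (tree$cover[tree$left[node]] * rec(tree$left[node]) +
         tree$cover[tree$right[node]] * rec(tree$right[node])) /
        tree$cover[node]
    }
  }
  rec(1L)
}

#' Cover-conditional expectation of a forest
#'
#' Mean of [tree_expvalue()] over the forest's trees: the value function for
#' which [tree_shap()] attributions are the exact Shapley values.
#'
#' @param forest list of trees from [rf_forest()].
#' @param x instance (numeric vector over the model's features).
#' @param S integer vector of "known" feature indices.
#' @return Scalar expected vote fraction for the positive class.
#' @export
forest_expvalue <- function(forest, x, S) {
  mean(vapply(forest, tree_expvalue, numeric(1), x = x, S = S))
}

# path-dependent TreeSHAP for a single tree (polynomial-time recursion over
# the unique features on each root-leaf path, with the standard
# extend/unwind bookkeeping of permutation weights)
tree_shap_single <- function(tree, x, M) {
  phi <- numeric(M)

  unwound_sum <- function(z, o, w, ir) {
    L <- length(w)
    next_one <- w[L]
    total <- 0
    if (o[ir] != 0) {
      for (jr in (L - 1):1) {
        tmp <- next_one / (jr * o[ir])
        total <- total + tmp
        next_one <- w[jr] - tmp * z[ir] * (L - jr)
      }
    } else {
      for (jr in (L - 1):1)
        total <- total + w[jr] / (z[ir] * (L - jr))
    }
    total * L
  }

  recurse <- function(node, d, z, o, w, pz, po, pi) {
    # extend the path with (pz, po, pi)
    l <- length(d)
    d <- c(d, pi); z <- c(z, pz); o <- c(o, po)
    w <- c(w, if (l == 0) 1 else 0)
    if (l > 0) for (ir in l:1) {
      w[ir + 1] <- w[ir + 1] + po * w[ir] * ir / (l + 1)
      w[ir] <- pz * w[ir] * (l + 1 - ir) / (l + 1)
    }
    L <- length(d)
    if (tree$leaf[node]) {
      if (L >= 2) for (ir in 2:L) {
        s <- unwound_sum(z, o, w, ir)
        phi[d[ir]] <<- phi[d[ir]] + s * (o[ir] - z[ir]) * tree$value[node]
      }
      return(invisible())
    }
    v <- tree$var[node]
    lt <- tree$left[node]; rt <- tree$right[node]
    if (x[v] <= tree$split[node]) { hot <- lt; cold <- rt }
    else { hot <- rt; cold <- lt }
    iz <- 1; io <- 1
    k <- match(v, d)
    if (!is.na(k) && k >= 2) {
      iz <- z[k]; io <- o[k]
      # unwind entry k out of the path: recompute every weight below the top
      n <- w[L]
      for (jr in (L - 1):1) {
        if (io != 0) {
          t <- w[jr]
          w[jr] <- n * L / (jr * io)
          n <- t - w[jr] * iz * (L - jr) / L
        } else {
          w[jr] <- w[jr] * L / (iz * (L - jr))
        }
      }
      d <- d[-k]; z <- z[-k]; o <- o[-k]; w <- w[-L]
    }
    rc <- tree$cover[node]
    recurse(hot, d, z, o, w, iz * tree$cover[hot] / rc, io, v)
    recurse(cold, d, z, o, w, iz * tree$cover[cold] / rc, 0, v)
    invisible()
  }

  recurse(1L, integer(0), numeric(0), numeric(0), numeric(0), 1, 1, 0L)
  phi
}

#' TreeSHAP attributions for a random forest
#'
#' Path-dependent TreeSHAP: for every tree, the exact Shapley values of the
#' cover-conditional expectation value function ([tree_expvalue()]),
#' averaged over trees. Local accuracy holds against the forest's vote
#' fraction: `sum(phi) + base = predict_prob(model, x)`.
#'
#' @param model a `fitted_model` of family `"random-forest"`.
#' @param x instance to explain (vector over the model's features).
#' @param forest optional precomputed [rf_forest()] structure.
#' @return List with `phi` (named attribution vector) and `base` (expected
#'   vote fraction with no features known).
#' @export
tree_shap <- function(model, x, forest = NULL) {
  if (is.null(forest)) forest <- rf_forest(model)
  x <- as.numeric(x)
  M <- length(model$features)
  phis <- vapply(forest, tree_shap_single, numeric(M), x = x, M = M)
  phi <- rowMeans(matrix(phis, nrow = M))
  names(phi) <- model$features
  base <- forest_expvalue(forest, x, integer(0))
  list(phi = phi, base = base)
}

# ---- model-agnostic interventional explainer -------------------------------

# deterministic background subsample: evenly spaced training rows
background_rows <- function(X, max_rows = 25) {
  n <- nrow(X)
  if (n <= max_rows) return(X)
  X[round(seq(1, n, length.out = max_rows)), , drop = FALSE]
}

#' Exact interventional Shapley values for an arbitrary scorer
#'
#' Value function `v(F)` = mean over background rows `b` of the model score
#' on the hybrid instance taking features in `F` from `x` and the rest from
#' `b`. All `2^m` subsets are evaluated in one batched prediction, so `m`
#' must be at most `max_exact`.
#'
#' @param model a `fitted_model`.
#' @param x instance to explain.
#' @param background background matrix (defaults to the model's training
#'   table, subsampled to 25 rows).
#' @param max_exact maximum feature count for exhaustive enumeration.
#' @return List with `phi` (named vector) and `base` (`v(empty)`).
#' @export
shap_interventional <- function(model, x, background = NULL, max_exact = 12) {
  m <- length(model$features)
  if (m > max_exact)
    stop("interventional enumeration limited to ", max_exact, " features",
         call. = FALSE)
  if (is.null(background)) background <- background_rows(model$X_train)
  nb <- nrow(background)
  x <- as.numeric(x)
  masks <- 0:(2^m - 1)
  big <- matrix(NA_real_, length(masks) * nb, m,
                dimnames = list(NULL, model$features))
  for (i in seq_along(masks)) {
    inx <- bitwAnd(masks[i], 2^(seq_len(m) - 1)) > 0
    block <- background
    block[, inx] <- rep(x[inx], each = nb)
    big[(i - 1) * nb + seq_len(nb), ] <- block
  }
  preds <- predict_prob(model, big)
  v <- vapply(seq_along(masks), function(i)
    mean(preds[(i - 1) * nb + seq_len(nb)]), numeric(1))
  vfun <- function(S) v[sum(2^(S - 1)) + 1]
  phi <- shap_oracle_all(vfun, m)
  names(phi) <- model$features
  list(phi = phi, base = v[1])
}

# Monte-Carlo permutation fallback for wide feature sets
shap_sampling <- function(model, x, background = NULL, n_perm = 200,
                          seed = 1) {
  if (is.null(background)) background <- background_rows(model$X_train)
  m <- length(model$features)
  nb <- nrow(background)
  x <- as.numeric(x)
  phi <- numeric(m)
  base <- mean(predict_prob(model, background))
  withr::with_seed(seed, {
    for (p in seq_len(n_perm)) {
      ord <- sample.int(m)
      block <- background
      prev <- mean(predict_prob(model, block))
      for (j in ord) {
        block[, j] <- x[j]
        cur <- mean(predict_prob(model, block))
        phi[j] <- phi[j] + (cur - prev)
        prev <- cur
      }
    }
  })
  phi <- phi / n_perm
  names(phi) <- model$features
  list(phi = phi, base = base)
}

#' SHAP attribution of one held-out instance for one fold model
#'
#' Dispatches on model family: random forests use the in-package TreeSHAP;
#' gradient-boosted trees use xgboost's native TreeSHAP (`type =
#' "contrib"`); margin/probabilistic families use the exact interventional
#' explainer when the fold has at most 12 features and seeded permutation
#' sampling otherwise. Attributions explain the positive-class probability,
#' so positive values drive toward the cancer label.
#'
#' @param model a `fitted_model` from the fold's training set.
#' @param x held-out instance (vector over the fold's features).
#' @param forest optional cached [rf_forest()] for the random-forest path.
#' @return List with `phi` (named by fold features) and `base`.
#' @export
shap_for_fold <- function(model, x, forest = NULL) {
  switch(model$spec$family,
    "random-forest" = tree_shap(model, x, forest = forest),
    "gradient-boosted-trees" = {
      xm <- matrix(as.numeric(x), 1, dimnames = list(NULL, model$features))
      ctb <- stats::predict(model$fit, xm, type = "contrib")
      phi <- ctb[1, model$features]
      list(phi = phi, base = unname(ctb[1, ncol(ctb)]))
    },
    if (length(model$features) <= 12) shap_interventional(model, x)
    else shap_sampling(model, x)
  )
}

#' Run-averaged SHAP matrix with zero-fill
#'
#' Per (instance, feature): the mean over runs of the fold attribution,
#' with 0 substituted in runs where the feature was not in the instance's
#' fold consensus (features the model never saw contribute nothing).
#'
#' @param per_run list over runs; each element a list over instances of
#'   attribution vectors named by the fold's features.
#' @param all_features character vector of the full feature-table columns.
#' @return A `shap_explanation`: list with `mean_shap` (instances x all
#'   features matrix) and `base` (per-run mean base values).
#' @export
average_shap <- function(per_run, all_features) {
  n_runs <- length(per_run)
  if (!n_runs) stop("no runs to average", call. = FALSE)
  n <- length(per_run[[1]]$phi)
  if (any(vapply(per_run, function(r) length(r$phi), 1L) != n))
    stop("completeness error: runs explain different instance counts",
         call. = FALSE)
  acc <- matrix(0, n, length(all_features),
                dimnames = list(NULL, all_features))
  base <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    for (i in seq_len(n)) {
      phi <- per_run[[r]]$phi[[i]]
      acc[i, names(phi)] <- acc[i, names(phi)] + phi
    }
    base[r] <- mean(per_run[[r]]$base)
  }
  structure(list(mean_shap = acc / n_runs, base = base),
            class = "shap_explanation")
}

#' Rank features by mean absolute SHAP value
#'
#' Mean `|SHAP|` across instances, descending. The direction annotation is
#' the sign of the correlation between feature value and SHAP value across
#' instances: positive means higher feature values drive toward the cancer
#' label.
#'
#' @param e a `shap_explanation`.
#' @param X feature matrix (instances x features) aligned with `e`.
#' @param top_n number of features to report (clamped to the total).
#' @return Data frame with `rank`, `feature`, `mean_abs_shap`, `direction`
#'   (`"cancer"`, `"healthy/benign"` or `"flat"`).
#' @export
rank_features <- function(e, X, top_n = 20) {
  ma <- colMeans(abs(e$mean_shap))
  ord <- order(ma, decreasing = TRUE)
  ord <- ord[seq_len(min(top_n, length(ord)))]
  dir <- vapply(ord, function(j) {
    s <- e$mean_shap[, j]
    if (stats::sd(s) == 0 || stats::sd(X[, j]) == 0) return("flat")
    if (stats::cor(X[, j], s) > 0) "cancer" else "healthy/benign"
  }, "")
  data.frame(rank = seq_along(ord),
             feature = colnames(e$mean_shap)[ord],
             mean_abs_shap = unname(ma[ord]),
             direction = dir)
}

#' Explain the best model of an evaluation
#'
#' Computes per-fold SHAP attributions for every kept run of the best
#' model, zero-fills features outside each fold's consensus, averages over
#' runs and ranks features.
#'
#' @param ev an `evaluation_summary` from [evaluate_models()].
#' @param X the full feature matrix the evaluation used.
#' @param top_n passed to [rank_features()].
#' @return List with `explanation` (a `shap_explanation`) and `ranking`.
#' @export
explain_best_model <- function(ev, X, top_n = 20) {
  X <- as.matrix(X)
  per_run <- lapply(ev$best_runs, function(run) {
    phis <- vector("list", nrow(X))
    bases <- numeric(nrow(X))
    for (i in seq_len(nrow(X))) {
      fit <- run$models[[i]]
      if (is.null(fit))
        stop("explanation requires runs kept with keep_models = TRUE",
             call. = FALSE)
      sh <- shap_for_fold(fit, X[i, fit$features])
      phis[[i]] <- sh$phi
      bases[i] <- sh$base
    }
    list(phi = phis, base = bases)
  })
  expl <- average_shap(per_run, colnames(X))
  list(explanation = expl, ranking = rank_features(expl, X, top_n = top_n))
}
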