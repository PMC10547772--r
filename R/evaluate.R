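#' Area under the ROC curve
#'
#' Mann-Whitney concordance: (concordant pairs + half the tied pairs) /
#' (positives x negatives), computed with midranks.
#'
#' @param probs numeric scores.
#' @param labels binary labels (0/1).
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(probs, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(probs)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams compute_auc
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, one row per
#'   candidate threshold (see [optimal_threshold()]), descending threshold.
#' @export
roc_points <- function(probs, labels) {
  th <- threshold_candidates(probs)
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  pts <- t(vapply(th, function(t) {
    pred <- as.integer(probs >= t)
    c(fpr = sum(pred == 1 & labels == 0) / n0,
      tpr = sum(pred == 1 & labels == 1) / n1)
  }, numeric(2)))
  data.frame(threshold = th, fpr = pts[, "fpr"], tpr = pts[, "tpr"])[
    order(th, decreasing = TRUE), ]
}

threshold_candidates <- function(probs) {
  p <- sort(unique(probs))
  mids <- if (length(p) > 1) (p[-1] + p[-length(p)]) / 2 else numeric(0)
  sort(unique(c(0, mids, 1)))
}

#' G-mean-optimal classification threshold
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' scores plus 0 and 1; classification is positive iff `prob >= t`. Returns
#' the threshold maximising `G = sqrt(sensitivity * specificity)`; ties are
#' broken by smaller `|t - 0.5|`, then by smaller `t`.
#'
#' @inheritParams compute_auc
#' @return List with `threshold` and `G`.
#' @export
optimal_threshold <- function(probs, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("threshold undefined: both classes must be present", call. = FALSE)
  th <- threshold_candidates(probs)
  G <- vapply(th, function(t) {
    pred <- as.integer(probs >= t)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    sqrt(sens * spec)
  }, numeric(1))
  best <- which(G >= max(G) - 1e-12)
  best <- best[order(abs(th[best] - 0.5), th[best])][1]
  list(threshold = th[best], G = G[best])
}

#' One leave-one-out run at a fixed SMOTE seed
#'
#' For each instance i: restrict the training rows to fold i's Boruta
#' consensus features, SMOTE-balance them with `smote_seed`, fit the model,
#' and record the held-out positive-class probability. AUC, ROC and the
#' G-mean threshold are then computed across the n held-out probabilities.
#'
#' @param X full feature matrix (samples x features).
#' @param y binary labels (0/1).
#' @param spec a `model_spec`.
#' @param smote_seed SMOTE random state for this run.
#' @param consensus list of per-fold consensus feature sets
#'   (from [fold_consensus()]).
#' @param k_smote SMOTE neighbour count.
#' @param keep_models keep the per-fold fitted models (needed for SHAP).
#' @return A `run_result`: list with `smote_seed`, `probs`, `auc`, `roc`,
#'   `threshold`, `G`, `consensus`, and (optionally) `models`.
#' @export
loo_run <- function(X, y, spec, smote_seed, consensus, k_smote = 10,
                    keep_models = FALSE) {
  X <- as.matrix(X); y <- as.integer(y)
  n <- nrow(X)
  if (n < 4 || length(unique(y)) < 2)
    stop("leave-one-out needs n >= 4 and both classes", call. = FALSE)
  probs <- numeric(n)
  models <- if (keep_models) vector("list", n)
  for (i in seq_len(n)) {
    fs <- consensus[[i]]
    if (!length(fs)) stop("empty consensus for fold ", i, call. = FALSE)
    Xtr <- X[-i, fs, drop = FALSE]
    bal <- suppressWarnings(
      smote_oversample(Xtr, y[-i], k = k_smote, seed = smote_seed))
    fit <- fit_model(spec, bal$X, bal$y, seed = smote_seed * 1000L + i)
    probs[i] <- predict_prob(fit, X[i, fs, drop = FALSE])
    if (keep_models) models[[i]] <- fit
  }
  opt <- optimal_threshold(probs, y)
  structure(
    list(smote_seed = smote_seed, probs = probs,
         auc = compute_auc(probs, y), roc = roc_points(probs, y),
         threshold = opt$threshold, G = opt$G,
         consensus = consensus, models = models),
    class = "run_result"
  )
}

#' Replicate leave-one-out runs over SMOTE seeds
#'
#' Runs [loo_run()] for `smote_seed = 1..n_runs`, reusing the per-fold
#' Boruta consensus (it does not depend on the SMOTE seed).
#'
#' @inheritParams loo_run
#' @param n_runs number of SMOTE seeds (paper setting: 100).
#' @return List of `run_result` objects.
#' @export
replicate_runs <- function(X, y, spec, consensus, n_runs = 100, k_smote = 10,
                           keep_models = FALSE) {
  lapply(seq_len(n_runs), function(s)
    loo_run(X, y, spec, smote_seed = s, consensus = consensus,
            k_smote = k_smote, keep_models = keep_models))
}

#' Select the best model spec by median AUC, then IQR
#'
#' Argmax of the median AUC over runs; ties (within `1e-12`) are broken by
#' the smaller interquartile range, remaining ties by grid order.
#'
#' @param auc_dists list (one element per candidate) of numeric AUC vectors.
#' @return Index of the winning candidate.
#' @export
select_best_model <- function(auc_dists) {
  med <- vapply(auc_dists, stats::median, numeric(1))
  iqr <- vapply(auc_dists, stats::IQR, numeric(1))
  cand <- which(med >= max(med) - 1e-12)
  cand[order(iqr[cand], cand)][1]
}

#' Aggregate run results into an evaluation summary
#'
#' Classifications use each run's own G-optimal threshold. The confusion
#' matrix sums counts over runs and row-normalises. Per-instance stability
#' is the fraction of runs agreeing with the instance's majority class,
#' reported in the paper's discrepancy buckets (0%, <10%, 10-15%, >15%).
#' Per-diagnosis summaries give median and IQR, over the instances of each
#' diagnosis, of the per-instance median probability across runs.
#'
#' @param runs list of `run_result` objects.
#' @param labels binary labels (0/1).
#' @param diagnoses optional character vector of diagnosis tokens.
#' @return List with `confusion` (2x2 row-normalised), `stability` (data
#'   frame per instance), `stability_buckets` (named counts) and
#'   `per_diagnosis` (data frame), plus `median_probs` per instance.
#' @export
aggregate_results <- function(runs, labels, diagnoses = NULL) {
  labels <- as.integer(labels)
  n <- length(labels)
  pred <- vapply(runs, function(r) as.integer(r$probs >= r$threshold),
                 integer(n))
  pred <- matrix(pred, nrow = n)
  counts <- matrix(0, 2, 2,
                   dimnames = list(true = c("0", "1"), pred = c("0", "1")))
  for (r in seq_len(ncol(pred))) {
    counts <- counts + table(factor(labels, levels = 0:1),
                             factor(pred[, r], levels = 0:1))
  }
  confusion <- counts / rowSums(counts)
  frac_pos <- rowMeans(pred)
  majority <- as.integer(frac_pos >= 0.5)
  agree <- ifelse(majority == 1, frac_pos, 1 - frac_pos)
  disc <- 1 - agree
  bucket <- cut(disc, breaks = c(-Inf, 0, 0.1, 0.15, Inf),
                labels = c("0%", "<10%", "10-15%", ">15%"))
  prob_mat <- vapply(runs, `[[`, numeric(n), "probs")
  prob_mat <- matrix(prob_mat, nrow = n)
  med_prob <- apply(prob_mat, 1, stats::median)
  per_diag <- NULL
  if (!is.null(diagnoses)) {
    per_diag <- do.call(rbind, lapply(split(seq_len(n), diagnoses),
      function(ix) data.frame(
        diagnosis = diagnoses[ix[1]], n = length(ix),
        median_prob = stats::median(med_prob[ix]),
        iqr_prob = stats::IQR(med_prob[ix]))))
    rownames(per_diag) <- NULL
  }
  list(
    confusion = confusion,
    stability = data.frame(instance = seq_len(n), label = labels,
                           majority = majority, discrepancy = disc,
                           bucket = bucket),
    stability_buckets = table(bucket),
    median_probs = med_prob,
    per_diagnosis = per_diag
  )
}

#' Evaluate candidate models in the nested design
#'
#' Computes the per-fold Boruta consensus once, replicates SMOTE x LOO runs
#' for every candidate `model_spec`, selects the best candidate (median AUC,
#' then IQR, then grid order), reruns it with models kept for explanation,
#' and aggregates its predictions.
#'
#' @inheritParams loo_run
#' @param specs list of `model_spec` candidates.
#' @param n_runs SMOTE seeds per candidate.
#' @param n_states Boruta random states per fold.
#' @param diagnoses optional diagnosis tokens for per-diagnosis summaries.
#' @param boruta_args list of extra arguments to [boruta_select()]
#'   (e.g. `max_iter`, `num_trees`).
#' @param consensus optional precomputed [fold_consensus()] result.
#' @return An `evaluation_summary`: list with `model_table` (median/IQR per
#'   candidate), `best` (index), `best_spec`, `best_runs` (with models),
#'   `auc_dists`, `thresholds`, `aggregate`, `consensus`.
#' @export
evaluate_models <- function(X, y, specs = default_model_grid(), n_runs = 100,
                            n_states = 100, k_smote = 10, diagnoses = NULL,
                            boruta_args = list(), consensus = NULL) {
  X <- as.matrix(X); y <- as.integer(y)
  if (is.null(consensus)) {
    consensus <- do.call(fold_consensus,
                         c(list(X = X, y = y, n_states = n_states),
                           boruta_args))
  }
  auc_dists <- vector("list", length(specs))
  for (j in seq_along(specs)) {
    runs <- replicate_runs(X, y, specs[[j]], consensus, n_runs = n_runs,
                           k_smote = k_smote)
    auc_dists[[j]] <- vapply(runs, `[[`, numeric(1), "auc")
  }
  best <- select_best_model(auc_dists)
  best_runs <- replicate_runs(X, y, specs[[best]], consensus,
                              n_runs = n_runs, k_smote = k_smote,
                              keep_models = TRUE)
  model_table <- data.frame(
    model = vapply(specs, format, ""),
    median_auc = vapply(auc_dists, stats::median, numeric(1)),
    iqr_auc = vapply(auc_dists, stats::IQR, numeric(1))
  )
  structure(
    list(model_table = model_table, best = best, best_spec = specs[[best]],
         best_runs = best_runs, auc_dists = auc_dists,
         thresholds = vapply(best_runs, `[[`, numeric(1), "threshold"),
         aggregate = aggregate_results(best_runs, y, diagnoses),
         consensus = consensus),
    class = "evaluation_summary"
  )
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat("<evaluation_summary>\nbest model:", x$model_table$model[x$best], "\n")
  print(x$model_table)
  invisible(x)
}

#' Train on the full dataset and score held-out instances
#'
#' The ambiguous-sample protocol: a single Boruta consensus on all training
#' rows, then per SMOTE seed the training rows are balanced, the model is
#' fitted and every held-out instance is scored. When held-out labels are
#' given, a pooled AUC (training LOO probabilities + held-out probabilities)
#' is computed per run from `train_runs`.
#'
#' @param X_train,y_train training feature matrix and labels.
#' @param X_new held-out feature matrix (same columns).
#' @param spec a `model_spec`.
#' @param n_runs SMOTE seeds.
#' @param n_states Boruta random states.
#' @param y_new optional held-out labels (0/1).
#' @param train_runs optional list of `run_result` on the training set (for
#'   pooled AUC).
#' @param k_smote SMOTE neighbour count.
#' @param boruta_args extra arguments to [boruta_select()].
#' @return List with `probs` (matrix new instances x runs), `consensus`,
#'   and `pooled_auc` (per run, or NULL).
#' @export
classify_held_out <- function(X_train, y_train, X_new, spec, n_runs = 100,
                              n_states = 100, y_new = NULL,
                              train_runs = NULL, k_smote = 10,
                              boruta_args = list()) {
  X_train <- as.matrix(X_train)
  X_new <- as.matrix(X_new)
  miss <- setdiff(colnames(X_train), colnames(X_new))
  if (length(miss))
    stop("feature mismatch in held-out rows: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cons <- do.call(boruta_consensus,
                  c(list(X = X_train, y = y_train, n_states = n_states),
                    boruta_args))
  probs <- matrix(NA_real_, nrow(X_new), n_runs,
                  dimnames = list(rownames(X_new), NULL))
  for (s in seq_len(n_runs)) {
    bal <- suppressWarnings(smote_oversample(
      X_train[, cons, drop = FALSE], y_train, k = k_smote, seed = s))
    fit <- fit_model(spec, bal$X, bal$y, seed = s * 1000L)
    probs[, s] <- predict_prob(fit, X_new[, cons, drop = FALSE])
  }
  pooled <- NULL
  if (!is.null(y_new) && !is.null(train_runs)) {
    pooled <- vapply(seq_len(n_runs), function(s)
      compute_auc(c(train_runs[[s]]$probs, probs[, s]),
                  c(as.integer(y_train), as.integer(y_new))), numeric(1))
  }
  list(probs = probs, consensus = cons, pooled_auc = pooled)
}
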