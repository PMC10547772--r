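#' Boruta all-relevant feature selection (single run)
#'
#' Shadow-feature selection: at every iteration each candidate feature is
#' paired with a shadow copy obtained by permuting its values; a random
#' forest (ranger, impurity importance, max depth 5) is fitted on the
#' augmented table, and a feature scores a *hit* when its importance exceeds
#' the maximum shadow importance. Hits accumulate over iterations and a
#' two-sided binomial test against p = 0.5, Bonferroni-corrected over the
#' initial feature count, confirms or rejects features. Rejected features
#' leave the candidate pool; iteration stops when nothing is tentative or
#' `max_iter` is reached.
#'
#' @param X numeric matrix (samples x features) with column names.
#' @param y binary labels (0/1).
#' @param seed integer random state for this run (shuffles and forests).
#' @param max_iter maximum number of shadow iterations.
#' @param num_trees trees per internal forest.
#' @param max_depth internal forest depth cap.
#' @param alpha significance level of the binomial test.
#' @return List with `confirmed`, `tentative`, `rejected` (character
#'   vectors of feature names) and `hits` (named hit counts).
#' @export
boruta_select <- function(X, y, seed = 1, max_iter = 100, num_trees = 100,
                          max_depth = 5, alpha = 0.05) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  yf <- factor(y, levels = sort(unique(y)))
  m0 <- ncol(X)
  feats <- colnames(X)
  status <- stats::setNames(rep("tentative", m0), feats)
  hits <- stats::setNames(rep(0L, m0), feats)
  tested <- stats::setNames(rep(0L, m0), feats)
  withr::with_seed(seed, {
    for (it in seq_len(max_iter)) {
      active <- feats[status != "rejected"]
      if (!any(status == "tentative")) break
      Xa <- X[, active, drop = FALSE]
      Xs <- apply(Xa, 2, sample)
      # keep at least 5 shadow columns so max-shadow is a stable reference
      if (ncol(Xs) < 5) {
        extra <- replicate(5 - ncol(Xs),
                           sample(Xa[, sample.int(ncol(Xa), 1)]))
        Xs <- cbind(Xs, extra)
      }
      colnames(Xs) <- paste0(".shadow", seq_len(ncol(Xs)))
      rf <- ranger::ranger(
        x = cbind(Xa, Xs), y = yf, num.trees = num_trees,
        max.depth = max_depth, importance = "impurity",
        num.threads = 1, seed = sample.int(.Machine$integer.max, 1)
      )
      imp <- rf$variable.importance
      shadow_max <- max(imp[grepl("^\\.shadow", names(imp))])
      hit <- active[imp[active] > shadow_max]
      hits[hit] <- hits[hit] + 1L
      tested[active] <- tested[active] + 1L
      # two-sided binomial decisions, Bonferroni over the initial features
      tent <- feats[status == "tentative"]
      p_conf <- stats::pbinom(hits[tent] - 1L, tested[tent], 0.5,
                              lower.tail = FALSE)
      p_rej <- stats::pbinom(hits[tent], tested[tent], 0.5)
      status[tent[p_conf < alpha / m0]] <- "confirmed"
      status[tent[p_rej < alpha / m0]] <- "rejected"
    }
  })
  list(confirmed = feats[status == "confirmed"],
       tentative = feats[status == "tentative"],
       rejected = feats[status == "rejected"],
       hits = hits)
}

#' Consensus Boruta selection over many random states
#'
#' Runs [boruta_select()] with states `1..n_states` and returns the
#' intersection of the per-state selected sets (confirmed features only by
#' default). An empty intersection raises an error carrying per-feature
#' confirmation counts, unless `fallback_frac` is set, in which case
#' features selected in at least that fraction of states are returned.
#'
#' @inheritParams boruta_select
#' @param n_states number of Boruta random states (paper setting: 100).
#' @param include_tentative also count tentative features as selected.
#' @param fallback_frac optional fraction in (0, 1]; fallback consensus when
#'   the strict intersection is empty.
#' @param ... passed on to [boruta_select()].
#' @return Character vector of consensus feature names (may be reordered to
#'   the column order of `X`).
#' @export
boruta_consensus <- function(X, y, n_states = 100, include_tentative = FALSE,
                             fallback_frac = NULL, ...) {
  if (min(table(y)) < 2)
    stop("boruta_consensus needs at least 2 samples per class", call. = FALSE)
  counts <- stats::setNames(rep(0L, ncol(X)), colnames(X))
  sets <- vector("list", n_states)
  for (s in seq_len(n_states)) {
    run <- boruta_select(X, y, seed = s, ...)
    sel <- run$confirmed
    if (include_tentative) sel <- c(sel, run$tentative)
    sets[[s]] <- sel
    counts[sel] <- counts[sel] + 1L
  }
  cons <- Reduce(intersect, sets)
  if (!length(cons)) {
    if (!is.null(fallback_frac)) {
      cons <- names(counts)[counts >= fallback_frac * n_states]
    }
    if (!length(cons)) {
      err <- structure(
        class = c("boruta_consensus_empty", "error", "condition"),
        list(message = paste0(
               "empty Boruta consensus across ", n_states, " states",
               " (max per-feature confirmation count: ", max(counts), ")"),
             call = sys.call(-1), counts = counts))
      stop(err)
    }
  }
  colnames(X)[colnames(X) %in% cons]
}

#' Per-fold Boruta consensus for a leave-one-out design
#'
#' For each instance i, computes the consensus on the remaining n-1 training
#' rows. The result depends only on the split (Boruta states are fixed), so
#' it is computed once and reused across SMOTE seeds.
#'
#' @inheritParams boruta_consensus
#' @return List of length `nrow(X)`; element i is the consensus feature set
#'   of the fold holding out instance i.
#' @export
fold_consensus <- function(X, y, n_states = 100, ...) {
  lapply(seq_len(nrow(X)), function(i) {
    boruta_consensus(X[-i, , drop = FALSE], y[-i], n_states = n_states, ...)
  })
}
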