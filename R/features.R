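#' Per-interval prominences of one preprocessed spectrum
#'
#' The prominence `P_k` of interval k is the maximum unit-sum-normalised
#' intensity of the spectrum over the grid points falling in `[lo_k, hi_k]`
#' (closed). Values below `1e-12` are floored to `1e-12` to keep ratios
#' finite.
#'
#' @param g a preprocessed `grid_spectrum`.
#' @param s a finalised `interval_set`.
#' @return Numeric vector `P`, one value per interval, named `P1..Pm`.
#' @export
interval_prominences <- function(g, s) {
  stopifnot(inherits(g, "grid_spectrum"), inherits(s, "interval_set"))
  if (!isTRUE(attr(s, "finalized")))
    stop("interval set must be finalized", call. = FALSE)
  P <- vapply(seq_len(nrow(s)), function(k) {
    sel <- g$shifts >= s$lo[k] & g$shifts <= s$hi[k]
    if (!any(sel))
      stop("interval ", k, " [", s$lo[k], ", ", s$hi[k],
           "] contains no grid point of '", g$sample_id, "'", call. = FALSE)
    max(g$intensities[sel])
  }, numeric(1))
  low <- P < 1e-12
  if (any(low)) {
    warning(sum(low), " prominence value(s) floored to 1e-12 for '",
            g$sample_id, "'", call. = FALSE)
    P[low] <- 1e-12
  }
  names(P) <- paste0("P", seq_along(P))
  P
}

#' Prominence matrix for a dataset
#'
#' @param dataset list of preprocessed `grid_spectrum` objects.
#' @param s a finalised `interval_set`.
#' @return Matrix samples x intervals, rownames = sample ids.
#' @export
prominence_matrix <- function(dataset, s) {
  P <- t(vapply(dataset, interval_prominences, numeric(nrow(s)), s = s))
  rownames(P) <- vapply(dataset, `[[`, "", "sample_id")
  P
}

#' All ordered prominence-ratio features
#'
#' One feature `P{k}/P{l}` per ordered pair (k, l), k != l: m(m-1) features
#' for m intervals (812 for the 29-interval case).
#'
#' @param P prominence matrix (samples x intervals).
#' @return Matrix samples x m(m-1) with columns named `P{k}/P{l}`.
#' @export
all_ratio_features <- function(P) {
  m <- ncol(P)
  if (m < 2) stop("need at least 2 intervals for ratio features", call. = FALSE)
  pairs <- expand.grid(l = seq_len(m), k = seq_len(m))[, c("k", "l")]
  pairs <- pairs[pairs$k != pairs$l, , drop = FALSE]
  pairs <- pairs[order(pairs$k, pairs$l), , drop = FALSE]
  R <- P[, pairs$k, drop = FALSE] / P[, pairs$l, drop = FALSE]
  colnames(R) <- paste0("P", pairs$k, "/P", pairs$l)
  rownames(R) <- rownames(P)
  R
}

#' Reciprocal selection of ratio features
#'
#' For each unordered pair \{k, l\} the two orientations `P_k/P_l` and
#' `P_l/P_k` carry the same information; the one with the larger mean/sd
#' (sample sd, computed over the whole dataset) is kept. Zero sd counts as
#' infinite mean/sd; exact ties keep the `k < l` orientation. m intervals
#' yield m(m-1)/2 retained features (406 for m = 29).
#'
#' @param R ordered ratio-feature matrix from [all_ratio_features()].
#' @return A `feature_table`: matrix samples x m(m-1)/2, with attribute
#'   `selection` (data frame of both orientations' mean/sd statistics).
#' @export
select_reciprocal <- function(R) {
  if (nrow(R) < 2) stop("reciprocal selection needs at least 2 samples",
                        call. = FALSE)
  nm <- colnames(R)
  kl <- do.call(rbind, strsplit(sub("^P", "", gsub("/P", ",", nm)), ","))
  k <- as.integer(kl[, 1]); l <- as.integer(kl[, 2])
  fwd <- which(k < l)
  stat <- function(v) {
    s <- stats::sd(v)
    if (s == 0) Inf else mean(v) / s
  }
  keep <- character(length(fwd))
  sel <- data.frame(k = k[fwd], l = l[fwd], stat_fwd = NA_real_,
                    stat_rev = NA_real_, kept = NA_character_)
  for (i in seq_along(fwd)) {
    f <- fwd[i]
    r <- which(k == l[f] & l == k[f])
    sf <- stat(R[, f]); sr <- stat(R[, r])
    keep[i] <- if (sr > sf) nm[r] else nm[f]   # tie -> forward (k < l)
    sel$stat_fwd[i] <- sf; sel$stat_rev[i] <- sr; sel$kept[i] <- keep[i]
  }
  out <- R[, keep, drop = FALSE]
  structure(out, selection = sel, class = c("feature_table", class(out)))
}

#' Build the feature table for a dataset
#'
#' Convenience chain: prominences -> ordered ratios -> reciprocal selection.
#'
#' @inheritParams prominence_matrix
#' @return A `feature_table` (see [select_reciprocal()]), with the
#'   prominence matrix attached as attribute `prominences`.
#' @export
build_feature_table <- function(dataset, s) {
  P <- prominence_matrix(dataset, s)
  ft <- select_reciprocal(all_ratio_features(P))
  attr(ft, "prominences") <- P
  ft
}

#' Compute features for new spectra with a frozen selection
#'
#' Applies the training run's interval set and retained feature orientations
#' to held-out spectra (e.g. the ambiguous-sample protocol).
#'
#' @param dataset list of preprocessed `grid_spectrum` objects.
#' @param s the training `interval_set`.
#' @param feature_names column names of the training `feature_table`.
#' @return Matrix samples x length(feature_names).
#' @export
apply_feature_table <- function(dataset, s, feature_names) {
  R <- all_ratio_features(prominence_matrix(dataset, s))
  miss <- setdiff(feature_names, colnames(R))
  if (length(miss))
    stop("feature mismatch: ", paste(miss, collapse = ", "), call. = FALSE)
  R[, feature_names, drop = FALSE]
}
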