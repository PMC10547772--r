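# Independent brute-force oracles used across tests.

# pairwise-concordance AUC: enumerate all (pos, neg) pairs
brute_auc <- function(probs, labels) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# exhaustive G-mean threshold search over the same candidate set
brute_threshold <- function(probs, labels) {
  p <- sort(unique(probs))
  th <- sort(unique(c(0, if (length(p) > 1) (p[-1] + p[-length(p)]) / 2, 1)))
  G <- sapply(th, function(t) {
    pred <- as.integer(probs >= t)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    sqrt(sens * spec)
  })
  best <- which(G >= max(G) - 1e-12)
  best <- best[order(abs(th[best] - 0.5), th[best])][1]
  list(threshold = th[best], G = G[best])
}

# prominence of a local maximum by direct scan
brute_prominence <- function(y, i) {
  n <- length(y)
  left <- y[seq_len(i - 1)]
  higher_l <- which(left > y[i])
  lmin <- min(y[(if (length(higher_l)) max(higher_l) + 1 else 1):i])
  right <- y[(i + 1):n]
  higher_r <- which(right > y[i])
  rmin <- min(y[i:(i + (if (length(higher_r)) min(higher_r) - 1 else n - i))])
  y[i] - max(lmin, rmin)
}

# a small gridded spectrum built from Gaussian bumps on [lo, hi]
bump_spectrum <- function(centers, amps, widths = 10, lo = 400, hi = 1600,
                          noise = 0, seed = 1, id = "bump") {
  shifts <- seq(lo, hi, by = 1)
  y <- rep(1e-4, length(shifts))
  widths <- rep(widths, length.out = length(centers))
  for (i in seq_along(centers))
    y <- y + amps[i] * exp(-(shifts - centers[i])^2 / (2 * widths[i]^2))
  if (noise > 0) y <- y + withr::with_seed(seed, rnorm(length(y), 0, noise))
  g <- interpolate_to_grid(new_spectrum(shifts, pmax(y, 0), id))
  g$smoothed <- TRUE
  g
}

# class-separated feature table: `n_sig` informative columns (mean shift
# between classes) + `n_noise` pure-noise columns
sep_features <- function(n0 = 20, n1 = 20, n_sig = 4, n_noise = 20,
                         delta = 3, seed = 1) {
  withr::with_seed(seed, {
    X <- cbind(
      matrix(rnorm((n0 + n1) * n_sig), n0 + n1) +
        outer(rep(c(0, delta), c(n0, n1)), rep(1, n_sig)),
      matrix(rnorm((n0 + n1) * n_noise), n0 + n1)
    )
  })
  colnames(X) <- c(paste0("sig", seq_len(n_sig)),
                   paste0("noise", seq_len(n_noise)))
  list(X = X, y = rep(c(0L, 1L), c(n0, n1)))
}
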