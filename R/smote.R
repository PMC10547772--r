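#' SMOTE oversampling of the minority class
#'
#' Augments the minority class with synthetic points until the two classes
#' are balanced. Each synthetic point is a convex combination
#' `a + lambda * (b - a)`, `lambda ~ U(0, 1)`, of a randomly chosen minority
#' point `a` and one of its `k` nearest minority-class neighbours `b`
#' (Euclidean distance). If the minority class has `<= k` members, `k` is
#' reduced to `size - 1` with a warning.
#'
#' @param X numeric matrix (samples x features) of training rows.
#' @param y binary labels (0/1), length `nrow(X)`.
#' @param k number of nearest neighbours (default 10).
#' @param seed integer seed controlling all random draws.
#' @return List with balanced `X` (original rows first, synthetic appended),
#'   `y`, and `n_synthetic`.
#' @export
smote_oversample <- function(X, y, k = 10, seed = 1) {
  X <- as.matrix(X)
  y <- as.integer(y)
  tab <- table(factor(y, levels = c(0, 1)))
  if (tab[1] == tab[2])
    return(list(X = X, y = y, n_synthetic = 0L))
  minority <- as.integer(names(tab)[which.min(tab)])
  idx <- which(y == minority)
  n_min <- length(idx)
  if (n_min < 2)
    stop("oversampling error: minority class has fewer than 2 members",
         call. = FALSE)
  n_new <- as.integer(abs(tab[1] - tab[2]))
  if (n_min <= k) {
    k <- n_min - 1L
    warning("minority class of size ", n_min, ": SMOTE k reduced to ", k,
            call. = FALSE)
  }
  Xm <- X[idx, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  nn <- t(matrix(apply(D, 1, function(d) order(d)[seq_len(k)]), nrow = k))
  synth <- withr::with_seed(seed, {
    a <- sample.int(n_min, n_new, replace = TRUE)
    b <- nn[cbind(a, sample.int(k, n_new, replace = TRUE))]
    lambda <- stats::runif(n_new)
    Xm[a, , drop = FALSE] + lambda * (Xm[b, , drop = FALSE] -
                                        Xm[a, , drop = FALSE])
  })
  rownames(synth) <- paste0("smote_", seq_len(n_new))
  list(X = rbind(X, synth), y = c(y, rep(minority, n_new)),
       n_synthetic = n_new)
}
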