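#' Interpolate a spectrum onto the 1 cm^-1 integer grid
#'
#' Linear interpolation onto integer Raman shifts from `ceiling(min(shift))`
#' to `floor(max(shift))`; no extrapolation beyond the observed span.
#'
#' @param s a [new_spectrum()] object.
#' @return A `grid_spectrum`: list with `shifts` (integer-valued, spacing 1),
#'   `intensities`, `sample_id`, and logical flags `normalized`, `smoothed`.
#' @export
interpolate_to_grid <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  lo <- ceiling(min(s$shifts)); hi <- floor(max(s$shifts))
  if (hi - lo < 2)
    stop("degenerate spectrum '", s$sample_id, "': span < 2 cm^-1",
         call. = FALSE)
  grid <- seq.int(lo, hi)
  y <- stats::approx(s$shifts, s$intensities, xout = grid, method = "linear",
                     rule = 1)$y
  structure(
    list(shifts = as.numeric(grid), intensities = y,
         sample_id = s$sample_id, normalized = FALSE, smoothed = FALSE),
    class = "grid_spectrum"
  )
}

#' @export
print.grid_spectrum <- function(x, ...) {
  cat(sprintf("<grid_spectrum '%s': %d-%d cm^-1%s%s>\n", x$sample_id,
              min(x$shifts), max(x$shifts),
              if (x$normalized) ", normalized" else "",
              if (x$smoothed) ", smoothed" else ""))
  invisible(x)
}

#' Normalise a gridded spectrum to unit sum
#'
#' Divides every intensity by the total so that the sum over grid points
#' equals one (area under curve on the unit-spaced grid).
#'
#' @param g a `grid_spectrum`.
#' @return The spectrum with unit-sum intensities and `normalized = TRUE`.
#' @export
normalize_area <- function(g) {
  stopifnot(inherits(g, "grid_spectrum"))
  tot <- sum(g$intensities)
  if (!is.finite(tot) || tot <= 0)
    stop("normalization error for '", g$sample_id,
         "': non-positive total intensity", call. = FALSE)
  g$intensities <- g$intensities / tot
  g$normalized <- TRUE
  g
}

#' Cubic smoothing-spline smoothing of a gridded spectrum
#'
#' Fits a cubic smoothing spline to (shift, intensity) and returns the fitted
#' values on the same grid. `smoothing` is the spline penalty `lambda`;
#' `smoothing = 0` reproduces the input, and `smoothing = "gcv"` (default)
#' picks the penalty by generalised cross-validation.
#'
#' @param g a normalised `grid_spectrum`.
#' @param smoothing nonnegative scalar penalty, or `"gcv"`.
#' @return The spectrum with smoothed intensities and `smoothed = TRUE`.
#' @export
smooth_spectrum <- function(g, smoothing = "gcv") {
  stopifnot(inherits(g, "grid_spectrum"))
  if (is.numeric(smoothing)) {
    if (smoothing < 0) stop("smoothing must be nonnegative", call. = FALSE)
    if (smoothing == 0) {           # lambda = 0 spline interpolates the data
      g$smoothed <- TRUE
      return(g)
    }
    fit <- stats::smooth.spline(g$shifts, g$intensities, lambda = smoothing,
                                all.knots = TRUE, keep.data = FALSE)
  } else if (identical(smoothing, "gcv")) {
    # all.knots: the default reduced knot basis cannot represent sharp bands
    # and rings around them, biasing peak positions
    fit <- stats::smooth.spline(g$shifts, g$intensities, cv = FALSE,
                                all.knots = TRUE, keep.data = FALSE)
  } else {
    stop("smoothing must be a nonnegative scalar or \"gcv\"", call. = FALSE)
  }
  g$intensities <- stats::predict(fit, g$shifts)$y
  g$smoothed <- TRUE
  g
}

#' Full preprocessing chain for one spectrum
#'
#' interpolate -> area-normalise -> spline-smooth -> re-normalise. The final
#' re-normalisation restores the unit sum perturbed by smoothing, so interval
#' prominences are read from unit-sum traces.
#'
#' @param s a `spectrum`.
#' @param smoothing passed to [smooth_spectrum()].
#' @return A preprocessed `grid_spectrum`.
#' @export
preprocess_spectrum <- function(s, smoothing = "gcv") {
  g <- smooth_spectrum(normalize_area(interpolate_to_grid(s)), smoothing)
  normalize_area(g)
}

# topographic prominence of interior local maxima (scipy-style bases:
# lowest point on each side before reaching a higher point or the edge)
peak_prominences <- function(y, peaks) {
  n <- length(y)
  vapply(peaks, function(i) {
    lmin <- y[i]; j <- i - 1L
    while (j >= 1L && y[j] <= y[i]) { lmin <- min(lmin, y[j]); j <- j - 1L }
    rmin <- y[i]; j <- i + 1L
    while (j <= n && y[j] <= y[i]) { rmin <- min(rmin, y[j]); j <- j + 1L }
    y[i] - max(lmin, rmin)
  }, numeric(1))
}

#' Detect local maxima in a preprocessed spectrum
#'
#' Returns the grid shifts of interior local maxima whose topographic
#' prominence is at least `min_prominence_frac` times the spectrum's
#' intensity range. For flat-topped maxima the leftmost plateau point is
#' reported.
#'
#' @param g a smoothed `grid_spectrum`.
#' @param min_prominence_frac prominence threshold as a fraction of
#'   `max - min` intensity, in `[0, 1]`.
#' @return Numeric vector of shift positions, ascending (possibly empty).
#' @export
detect_peaks <- function(g, min_prominence_frac = 0.005) {
  stopifnot(inherits(g, "grid_spectrum"))
  if (min_prominence_frac < 0 || min_prominence_frac > 1)
    stop("min_prominence_frac must be in [0, 1]", call. = FALSE)
  y <- g$intensities; n <- length(y)
  if (n < 3L) return(numeric(0))
  # interior maxima; plateaus: strictly above the previous distinct value and
  # at least as high as the next
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(idx)) return(numeric(0))
  prom <- peak_prominences(y, idx)
  thr <- min_prominence_frac * (max(y) - min(y))
  g$shifts[idx[prom >= thr]]
}

#' Pool detected maxima across a set of spectra
#'
#' @param dataset list of preprocessed `grid_spectrum` objects.
#' @param min_prominence_frac passed to [detect_peaks()].
#' @return A `peak_set` data frame with columns `position` and `sample_id`.
#' @export
pool_maxima <- function(dataset, min_prominence_frac = 0.005) {
  stopifnot(length(dataset) > 0)
  per <- lapply(dataset, function(g) {
    p <- detect_peaks(g, min_prominence_frac)
    if (length(p)) data.frame(position = p, sample_id = g$sample_id,
                              stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  if (is.null(out) || nrow(out) == 0L)
    stop("insufficient peaks: no local maxima detected in any spectrum",
         call. = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("peak_set", "data.frame"))
}

#' Fit a univariate unequal-variance Gaussian mixture to pooled peak positions
#'
#' Fits mixtures with K = `k_min` .. `k_max` components (mclust model "V")
#' to the pooled maxima and selects K by the Bayesian Information Criterion.
#' The reported `bic` column uses the conventional orientation
#' `-2 logLik + df log(n)`, so the selected K minimises it.
#'
#' @param peaks a `peak_set` from [pool_maxima()], or a numeric vector of
#'   positions.
#' @param k_min,k_max range of component counts to try.
#' @param seed integer seed recorded for reproducibility (the mclust
#'   initialisation is itself deterministic).
#' @return A `mixture_model`: list with `components` (data frame `mu`,
#'   `sigma`, `weight`, sorted by `mu`), `K`, `bic`, and `bic_trace`
#'   (per-K conventional BIC, NA where the fit failed).
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_peak_mixture <- function(peaks, k_min = 1, k_max = 40, seed = 1) {
  x <- if (is.data.frame(peaks)) peaks$position else as.numeric(peaks)
  k_max <- min(k_max, length(unique(x)) - 1L)
  if (k_max < k_min)
    stop("too few distinct peak positions for the requested K range",
         call. = FALSE)
  if (length(x) < k_max)
    stop("pooled position count must be at least k_max", call. = FALSE)
  fit <- withr::with_seed(seed,
    mclust::Mclust(x, G = k_min:k_max, modelNames = "V", verbose = FALSE))
  if (is.null(fit))
    stop("mixture fit failed for every K in [", k_min, ", ", k_max, "]",
         call. = FALSE)
  # mclust maximises 2*logLik - df*log(n); flip to the conventional BIC
  trace <- -as.numeric(fit$BIC[, 1])
  names(trace) <- rownames(fit$BIC)
  p <- fit$parameters
  comp <- data.frame(
    mu = as.numeric(p$mean),
    sigma = sqrt(as.numeric(p$variance$sigmasq)),
    weight = as.numeric(p$pro)
  )
  if (nrow(comp) > 1 && length(p$variance$sigmasq) == 1L)
    comp$sigma <- rep(sqrt(p$variance$sigmasq), nrow(comp))
  comp <- comp[order(comp$mu), , drop = FALSE]
  rownames(comp) <- NULL
  structure(
    list(components = comp, K = fit$G,
         bic = -as.numeric(fit$bic), bic_trace = trace,
         n = length(x), seed = seed),
    class = "mixture_model"
  )
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("<mixture_model: K = %d components on %d pooled maxima, BIC = %.1f>\n",
              x$K, x$n, x$bic))
  invisible(x)
}
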