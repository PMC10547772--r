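test_that("grid interpolation is linear, unit-spaced and idempotent", {
  s <- new_spectrum(100:110, rep(1, 11))
  g <- interpolate_to_grid(s)
  expect_equal(g$shifts, as.numeric(100:110))
  expect_equal(g$intensities, rep(1, 11))
  # idempotence on already-gridded input
  g2 <- interpolate_to_grid(new_spectrum(g$shifts, g$intensities))
  expect_equal(g2$intensities, g$intensities)

  g <- interpolate_to_grid(new_spectrum(c(100, 102), c(0, 2)))
  expect_equal(g$intensities[g$shifts == 101], 1)

  g <- interpolate_to_grid(new_spectrum(c(99.4, 101.7, 104.2, 107.9),
                                        c(1, 4, 2, 8)))
  expect_equal(unique(diff(g$shifts)), 1)
  expect_true(min(g$shifts) >= 99.4 && max(g$shifts) <= 107.9)

  expect_error(interpolate_to_grid(new_spectrum(c(100, 101.2), c(1, 2))),
               "degenerate")
})

test_that("area normalization yields unit sum", {
  g <- interpolate_to_grid(new_spectrum(1:10 + 99, rep(3, 10)))
  n <- normalize_area(g)
  expect_equal(n$intensities, rep(0.1, 10))

  g$intensities <- c(1, 3, rep(0, 8))
  n <- normalize_area(g)
  expect_equal(n$intensities[1:2], c(0.25, 0.75))
  expect_lt(abs(sum(n$intensities) - 1), 1e-12)

  g$intensities <- rep(0, 10)
  expect_error(normalize_area(g), "normalization")
})

test_that("spline smoothing interpolates at zero and denoises a line", {
  g <- normalize_area(interpolate_to_grid(
    new_spectrum(400:500, withr::with_seed(1, runif(101, 1, 2)))))
  s0 <- smooth_spectrum(g, 0)
  expect_equal(s0$intensities, g$intensities, tolerance = 1e-9)
  expect_true(s0$smoothed)

  const <- normalize_area(interpolate_to_grid(new_spectrum(400:500, rep(2, 101))))
  for (sm in list(0.1, "gcv"))
    expect_equal(smooth_spectrum(const, sm)$intensities, const$intensities,
                 tolerance = 1e-9)

  # noisy straight line: the fit must be closer to the line than the data
  x <- 400:700
  line <- 0.001 + 1e-6 * (x - 400)
  noisy <- line + withr::with_seed(7, rnorm(length(x), 0, 2e-4))
  g <- interpolate_to_grid(new_spectrum(x, pmax(noisy, 0)))
  g$normalized <- TRUE   # keep the line scale; smoothing alone under test
  sm <- smooth_spectrum(g, "gcv")
  rmse <- function(y) sqrt(mean((y - line)^2))
  expect_lt(rmse(sm$intensities), rmse(g$intensities))

  expect_error(smooth_spectrum(g, -1), "nonnegative")
})

test_that("peak detection finds bump positions and respects prominence", {
  inc <- interpolate_to_grid(new_spectrum(400:500, seq(1, 2, length.out = 101)))
  expect_length(detect_peaks(inc), 0)

  one <- bump_spectrum(1000, 1, lo = 800, hi = 1200)
  expect_equal(detect_peaks(one, 0.1), 1000)

  two <- bump_spectrum(c(800, 1200), c(1, 1), lo = 600, hi = 1400)
  expect_equal(detect_peaks(two, 0.1), c(800, 1200))

  # high threshold suppresses a small bump
  mix <- bump_spectrum(c(800, 1200), c(1, 0.05), lo = 600, hi = 1400)
  expect_equal(detect_peaks(mix, 0.2), 800)
})

test_that("every detected peak is a local maximum with oracle prominence", {
  for (seed in 1:5) {
    g <- bump_spectrum(c(700, 900, 1100, 1300),
                       withr::with_seed(seed, runif(4, 0.2, 1)),
                       widths = c(8, 12, 10, 15), noise = 0.002, seed = seed)
    p <- detect_peaks(g, 0.05)
    idx <- match(p, g$shifts)
    y <- g$intensities
    expect_true(all(y[idx] >= y[idx - 1] & y[idx] >= y[idx + 1]))
    thr <- 0.05 * diff(range(y))
    for (i in idx)
      expect_gte(brute_prominence(y, i), thr)
  }
})

test_that("pooled maxima concatenate per-spectrum detections with tags", {
  a <- bump_spectrum(c(700, 1100, 1300), c(1, 1, 1), id = "a")
  b <- bump_spectrum(c(800, 900, 1000, 1200), c(1, 1, 1, 1), id = "b")
  pk <- pool_maxima(list(a, b), 0.1)
  expect_equal(nrow(pk), 7)
  expect_equal(sum(pk$sample_id == "a"), 3)
  # duplicated identical spectra contribute each position once per copy
  pk3 <- pool_maxima(list(a, a, a), 0.1)
  expect_equal(as.vector(table(pk3$position)), rep(3, 3))
  # recount oracle
  expect_equal(nrow(pk),
               length(detect_peaks(a, 0.1)) + length(detect_peaks(b, 0.1)))

  flat <- interpolate_to_grid(new_spectrum(400:500, seq(1, 2, length.out = 101)))
  expect_error(pool_maxima(list(flat)), "insufficient peaks")
})

test_that("mixture fitting recovers component count by BIC", {
  x2 <- withr::with_seed(1, c(rnorm(100, 500, 5), rnorm(100, 1500, 10)))
  m2 <- fit_peak_mixture(x2, 1, 6, seed = 1)
  expect_equal(m2$K, 2)
  expect_lt(abs(m2$components$mu[1] - 500), 3)
  expect_lt(abs(m2$components$mu[2] - 1500), 3)

  x1 <- withr::with_seed(1, rnorm(150, 1000, 8))
  expect_equal(fit_peak_mixture(x1, 1, 6, seed = 1)$K, 1)

  # model validity and BIC-argmin over the explored range
  expect_lt(abs(sum(m2$components$weight) - 1), 1e-9)
  expect_true(all(m2$components$sigma > 0))
  expect_true(all(diff(m2$components$mu) > 0))
  expect_equal(unname(which.min(m2$bic_trace)), m2$K)
  expect_equal(min(m2$bic_trace, na.rm = TRUE), m2$bic)
})
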