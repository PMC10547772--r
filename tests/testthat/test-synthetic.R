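test_that("band library encodes the expected fingerprint structure", {
  lib <- default_band_library()
  diag9 <- c(747, 1003, 1125, 1155, 1302, 1376, 1516, 1584, 1638)
  expect_true(all(diag9 %in% lib$center))
  expect_setequal(lib$tag[match(c(1003, 1155, 1516), lib$center)],
                  "carotenoid")
  expect_equal(lib$tag[lib$center == 1376], "oxidised-cyt-b")
  expect_equal(lib$tag[lib$center == 1638], "oxidised-cyt-c")
  expect_true(all(lib$tag %in% c("reduced-cyt-c", "oxidised-cyt-c",
                                 "oxidised-cyt-b", "carotenoid", "nuisance")))
  expect_gte(sum(lib$tag == "nuisance"), 6)
  expect_true(all(lib$center >= 100 & lib$center <= 3600))
  expect_true(all(lib$width > 0))

  caro <- lib$tag == "carotenoid"
  expect_true(all(lib$mu_PTC[caro] > lib$mu_healthy[caro]))
  expect_true(all(lib$mu_FVPTC[caro] > lib$mu_healthy[caro]))
  redc <- lib$tag == "reduced-cyt-c"
  expect_true(all(lib$mu_FC[redc] > lib$mu_PTC[redc]))
  oxb <- lib$tag == "oxidised-cyt-b"
  expect_true(all(lib$mu_healthy[oxb] > lib$mu_PTC[oxb]))
})

test_that("spectrum generation is deterministic and analytically checkable", {
  cfg <- synthetic_config(seed = 1, grid_range = c(400, 1800))
  s1 <- generate_spectrum("PTC", cfg, seed = 7)
  s2 <- generate_spectrum("PTC", cfg, seed = 7)
  expect_identical(s1$intensities, s2$intensities)
  expect_false(identical(
    s1$intensities, generate_spectrum("PTC", cfg, seed = 8)$intensities))

  # noiseless, jitter-free, baseline-free: analytic band sum and centred peaks
  clean <- synthetic_config(seed = 1, noise_sd = 0, jitter_sd = 0,
                            baseline_max = 0, grid_range = c(400, 1800))
  s <- generate_spectrum("healthy", clean, seed = 3)
  truth <- attr(s, "truth")
  analytic <- rep(0, length(s$shifts))
  lib <- clean$bands
  for (i in seq_len(nrow(lib)))
    analytic <- analytic + truth$amplitude[i] *
      exp(-(s$shifts - lib$center[i])^2 / (2 * lib$width[i]^2))
  expect_equal(s$intensities, analytic, tolerance = 1e-12)

  p <- detect_peaks(preprocess_spectrum(s), 0.005)
  in_range <- lib$center[lib$center >= 400 & lib$center <= 1800]
  for (cc in in_range)
    expect_true(min(abs(p - cc)) <= 1,
                label = paste("peak recovered near", cc))

  # class fingerprint: carotenoid 1155 dominates oxidised cytochrome b 1376
  # in PTC and the reverse in healthy tissue
  win_max <- function(s, c0) max(s$intensities[abs(s$shifts - c0) <= 5])
  ptc <- generate_spectrum("PTC", clean, seed = 5)
  hea <- generate_spectrum("healthy", clean, seed = 5)
  expect_gt(win_max(ptc, 1155), win_max(ptc, 1376))
  expect_gt(win_max(hea, 1376), win_max(hea, 1155))

  expect_error(generate_spectrum("FT-UMP", cfg, seed = 1), "unknown diagnosis")
})

test_that("dataset generation mirrors the study's class structure", {
  cfg <- synthetic_config(seed = 4, grid_range = c(400, 1800))
  d <- withr::local_tempdir()
  ds <- generate_dataset(cfg, out_dir = d)
  expect_length(ds$spectra, 59)
  expect_equal(sum(ds$class == 0), 25)
  expect_equal(sum(ds$class == 1), 34)
  expect_equal(as.vector(table(ds$diagnosis)[c("healthy", "benign", "PTC",
                                               "FC", "FV-PTC")]),
               c(14, 11, 25, 4, 5))
  expect_equal(length(list.files(d, pattern = "\\.txt$")), 59)

  # byte-identical regeneration from the same master seed
  d2 <- withr::local_tempdir()
  generate_dataset(cfg, out_dir = d2)
  for (f in list.files(d, pattern = "\\.txt$"))
    expect_identical(readLines(file.path(d, f)), readLines(file.path(d2, f)))

  # manifest round-trip reproduces the dataset
  m <- read_manifest(file.path(d, "manifest.csv"))
  ds2 <- load_dataset(m)
  expect_equal(ds2$sample_id, ds$sample_id)
  expect_equal(ds2$spectra[[1]]$intensities, ds$spectra[[1]]$intensities)

  # well-separated preset: positive carotenoid prominence contrast
  ws <- generate_dataset(synthetic_config("well-separated", seed = 4,
                                          grid_range = c(400, 1800)))
  caro <- subset(ws$truth, center == 1155)
  cls <- ws$class[match(caro$sample_id, ws$sample_id)]
  expect_gt(mean(log(caro$amplitude[cls == 1])) -
              mean(log(caro$amplitude[cls == 0])), 1)
})

test_that("ambiguous modes override the class fingerprint", {
  cfg <- synthetic_config(seed = 2, grid_range = c(400, 1800))
  amb <- generate_ambiguous("cancer-no-carotenoid", cfg, seed = 10)
  expect_true(amb$ambiguous)
  expect_equal(amb$diagnosis, "PTC")
  expect_equal(amb$class, 1L)

  # carotenoid amplitudes follow the healthy profile
  lib <- cfg$bands
  caro_amp <- function(s) attr(s, "truth")$amplitude[lib$tag == "carotenoid"]
  amb_draws <- unlist(lapply(1:20, function(i)
    caro_amp(generate_ambiguous("cancer-no-carotenoid", cfg, i)$spectrum)))
  hea_draws <- unlist(lapply(1:20, function(i)
    caro_amp(generate_spectrum("healthy", cfg, i))))
  ptc_draws <- unlist(lapply(1:20, function(i)
    caro_amp(generate_spectrum("PTC", cfg, i))))
  expect_lt(abs(mean(log(amb_draws)) - mean(log(hea_draws))), 0.2)
  expect_lt(mean(log(amb_draws)), mean(log(ptc_draws)) - 1)

  # attenuated oxidised cytochrome b falls below the healthy 10th percentile
  ox_amp <- function(s) attr(s, "truth")$amplitude[lib$center == 1376]
  weak <- sapply(1:20, function(i)
    ox_amp(generate_ambiguous("benign-weak-oxcytb", cfg, i)$spectrum))
  hea_ox <- sapply(1:50, function(i) ox_amp(generate_spectrum("healthy", cfg, i)))
  expect_true(all(weak < quantile(hea_ox, 0.1)))

  mut <- generate_ambiguous("benign-with-carotenoid", cfg, seed = 3)
  expect_equal(mut$class, 0L)
  expect_error(generate_ambiguous("no-such-mode", cfg, 1), "arg")
})
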