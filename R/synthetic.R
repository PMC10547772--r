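#' Default synthetic band library
#'
#' The nine diagnostic bands (reduced cytochrome c at 747, 1125, 1302 and
#' 1584 cm^-1; carotenoids at 1003, 1155 and 1516 cm^-1; oxidised
#' cytochrome b at 1376 cm^-1; oxidised cytochrome c at 1638 cm^-1) plus
#' nine class-neutral nuisance bands at common tissue Raman positions.
#' Per-class amplitudes are log-normal; the mean-log profiles encode the
#' class fingerprints: carotenoids elevated in PTC and FV-PTC (reduced in
#' FC, weak in healthy/benign), oxidised cytochromes b and c elevated in
#' healthy/benign, reduced cytochrome c prominent in FC and FV-PTC and
#' suppressed in PTC.
#'
#' @return Data frame with columns `center`, `width`, `tag` and the
#'   per-class mean-log amplitudes `mu_healthy`, `mu_benign`, `mu_PTC`,
#'   `mu_FC`, `mu_FVPTC`.
#' @export
default_band_library <- function() {
  b <- function(center, width, tag, healthy, benign, PTC, FC, FVPTC)
    data.frame(center = center, width = width, tag = tag,
               mu_healthy = healthy, mu_benign = benign, mu_PTC = PTC,
               mu_FC = FC, mu_FVPTC = FVPTC, stringsAsFactors = FALSE)
  rbind(
    b(747,  6, "reduced-cyt-c", 0.8, 0.8, -0.9, 1.3, 1.2),
    b(1003, 5, "carotenoid",    0.0, 0.2,  1.6, 0.9, 1.5),
    b(1125, 7, "reduced-cyt-c", 0.8, 0.8, -0.9, 1.3, 1.2),
    b(1155, 6, "carotenoid",    0.0, 0.2,  1.7, 1.0, 1.6),
    b(1302, 8, "reduced-cyt-c", 0.8, 0.8, -0.9, 1.3, 1.2),
    b(1376, 7, "oxidised-cyt-b", 1.4, 1.3,  0.1, 0.4, 0.3),
    b(1516, 7, "carotenoid",    0.0, 0.2,  1.6, 0.9, 1.5),
    b(1584, 8, "reduced-cyt-c", 0.9, 0.9, -0.8, 1.4, 1.3),
    b(1638, 7, "oxidised-cyt-c", 1.4, 1.3,  0.2, 0.5, 0.4),
    # class-neutral nuisance bands (lipid/protein backbone regions)
    b(620,  7,  "nuisance", 0.8, 0.8, 0.8, 0.8, 0.8),
    b(856,  8,  "nuisance", 1.0, 1.0, 1.0, 1.0, 1.0),
    b(936,  7,  "nuisance", 0.9, 0.9, 0.9, 0.9, 0.9),
    b(1066, 7,  "nuisance", 0.9, 0.9, 0.9, 0.9, 0.9),
    b(1220, 9,  "nuisance", 0.8, 0.8, 0.8, 0.8, 0.8),
    b(1445, 9,  "nuisance", 1.5, 1.5, 1.5, 1.5, 1.5),
    b(1660, 8,  "nuisance", 1.4, 1.4, 1.4, 1.4, 1.4),
    b(2850, 10, "nuisance", 1.2, 1.2, 1.2, 1.2, 1.2),
    b(2930, 11, "nuisance", 1.6, 1.6, 1.6, 1.6, 1.6)
  )
}

#' Synthetic dataset configuration
#'
#' The defaults emulate the study conditions: 59 samples (14 healthy, 11
#' benign adenoma, 25 PTC, 4 FC, 5 FV-PTC), background-subtracted spectra
#' on 100-3600 cm^-1 at 1 cm^-1 sampling (offset from the integers so the
#' regridding step is exercised), Gaussian band profiles with jittered
#' centres, log-normal class-dependent amplitudes, additive Gaussian noise
#' and a small residual polynomial baseline. The `well-separated` preset
#' shrinks amplitude dispersion and noise and widens the class contrast so
#' that ground-truth recovery is essentially deterministic.
#'
#' @param preset `"paper-like"` (default) or `"well-separated"`.
#' @param n_per_class named counts per diagnosis.
#' @param seed master seed; all per-spectrum seeds derive from it.
#' @param bands band library (see [default_band_library()]).
#' @param noise_sd,jitter_sd,amp_sdlog,baseline_max noise standard
#'   deviation (band-amplitude units), band-centre jitter sd (cm^-1),
#'   log-amplitude sd, and maximum residual-baseline coefficient; `NULL`
#'   uses the preset value.
#' @param grid_range,grid_step sampled shift range (cm^-1) and spacing.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(preset = c("paper-like", "well-separated"),
                             n_per_class = c(healthy = 14, benign = 11,
                                             PTC = 25, FC = 4, `FV-PTC` = 5),
                             seed = 1, bands = default_band_library(),
                             noise_sd = NULL, jitter_sd = NULL,
                             amp_sdlog = NULL, baseline_max = NULL,
                             grid_range = c(100, 3600), grid_step = 1) {
  preset <- match.arg(preset)
  p <- if (preset == "paper-like")
    list(noise_sd = 0.005, jitter_sd = 1.5, amp_sdlog = 0.45,
         baseline_max = 0.05, contrast = 1)
  else
    list(noise_sd = 0.002, jitter_sd = 1.0, amp_sdlog = 0.25,
         baseline_max = 0.02, contrast = 1.5)
  structure(
    list(preset = preset, n_per_class = n_per_class, seed = seed,
         bands = bands,
         noise_sd = noise_sd %||% p$noise_sd,
         jitter_sd = jitter_sd %||% p$jitter_sd,
         amp_sdlog = amp_sdlog %||% p$amp_sdlog,
         baseline_max = baseline_max %||% p$baseline_max,
         contrast = p$contrast,
         grid_range = grid_range, grid_step = grid_step),
    class = "synthetic_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-class mean-log amplitudes, with the preset contrast applied to the
# deviation of each class from the band's cross-class mean
class_meanlog <- function(config, diagnosis) {
  col <- paste0("mu_", sub("-", "", sub("FV-PTC", "FVPTC", diagnosis)))
  mu <- config$bands[[col]]
  if (is.null(mu)) stop("unknown diagnosis: ", diagnosis, call. = FALSE)
  centre <- rowMeans(config$bands[paste0("mu_", c("healthy", "benign", "PTC",
                                                  "FC", "FVPTC"))])
  centre + config$contrast * (mu - centre)
}

#' Generate one synthetic spectrum
#'
#' Sum of Gaussian band profiles (centres jittered, amplitudes drawn from
#' the class's log-normal profile) plus a low-order polynomial residual
#' baseline and additive Gaussian noise, sampled on the configured grid and
#' clipped at zero. Deterministic given (diagnosis, config, seed).
#'
#' @param diagnosis a token from [diagnosis_levels()].
#' @param config a [synthetic_config()].
#' @param seed integer seed for this spectrum.
#' @param sample_id sample identifier.
#' @param amplitude_override optional named list: `tag` -> diagnosis whose
#'   amplitude profile replaces this spectrum's own for bands with that tag,
#'   or a numeric multiplier applied to the drawn amplitudes of that tag.
#' @return A `spectrum`; the drawn band amplitudes are attached as
#'   attribute `truth`.
#' @export
generate_spectrum <- function(diagnosis, config, seed,
                              sample_id = paste0(diagnosis, "_", seed),
                              amplitude_override = NULL) {
  if (!diagnosis %in% diagnosis_levels())
    stop("unknown diagnosis token: ", diagnosis, call. = FALSE)
  bands <- config$bands
  meanlog <- class_meanlog(config, diagnosis)
  if (!is.null(amplitude_override)) {
    for (tag in names(amplitude_override)) {
      ov <- amplitude_override[[tag]]
      sel <- bands$tag == tag
      if (is.character(ov)) meanlog[sel] <- class_meanlog(config, ov)[sel]
      else meanlog[sel] <- meanlog[sel] + log(as.numeric(ov))
    }
  }
  shifts <- seq(config$grid_range[1] + 0.3, config$grid_range[2],
                by = config$grid_step)
  withr::with_seed(seed, {
    amps <- stats::rlnorm(nrow(bands), meanlog, config$amp_sdlog)
    centers <- bands$center + stats::rnorm(nrow(bands), 0, config$jitter_sd)
    y <- rep(0, length(shifts))
    for (i in seq_len(nrow(bands)))
      y <- y + amps[i] * exp(-(shifts - centers[i])^2 / (2 * bands$width[i]^2))
    t <- (shifts - config$grid_range[1]) / diff(config$grid_range)
    coef <- stats::runif(3, 0, config$baseline_max)
    y <- y + coef[1] + coef[2] * t + coef[3] * t^2
    y <- y + stats::rnorm(length(shifts), 0, config$noise_sd)
  })
  y <- pmax(y, 0)
  s <- new_spectrum(shifts, y, sample_id)
  attr(s, "truth") <- data.frame(center = bands$center, tag = bands$tag,
                                 amplitude = amps)
  s
}

#' Generate a labelled synthetic dataset
#'
#' Draws `n_per_class` spectra per diagnosis with per-spectrum seeds derived
#' from the master seed. With `out_dir` set, writes one two-column spectrum
#' file per sample, a `manifest.csv`, and a `truth.tsv` of drawn band
#' amplitudes; otherwise returns everything in memory.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional output directory.
#' @return A `labeled_dataset` (see [load_dataset()]) with an extra
#'   `truth` element (per-sample band amplitude table) and, if written,
#'   `manifest_path`.
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  n <- config$n_per_class
  diagnosis <- rep(names(n), n)
  ids <- sprintf("S%02d_%s", seq_along(diagnosis), diagnosis)
  seeds <- withr::with_seed(config$seed,
                            sample.int(2^31 - 2, length(diagnosis)))
  spectra <- Map(function(d, sd, id) generate_spectrum(d, config, sd, id),
                 diagnosis, seeds, ids)
  truth <- do.call(rbind, Map(function(s, id) {
    tr <- attr(s, "truth"); tr$sample_id <- id; tr
  }, spectra, ids))
  ds <- structure(
    list(spectra = unname(spectra), sample_id = ids, diagnosis = diagnosis,
         class = binary_class(diagnosis),
         ambiguous = rep(FALSE, length(ids)),
         truth = truth, seeds = seeds),
    class = "labeled_dataset"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- paste0(ids, ".txt")
    for (i in seq_along(ids)) {
      s <- spectra[[i]]
      writeLines(sprintf("%.17g\t%.17g", s$shifts, s$intensities),
                 file.path(out_dir, files[i]))
    }
    manifest <- data.frame(sample_id = ids, file = files,
                           diagnosis = diagnosis,
                           ambiguous = rep(FALSE, length(ids)))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    write_table(truth, file.path(out_dir, "truth.tsv"))
    ds$manifest_path <- file.path(out_dir, "manifest.csv")
  }
  ds
}

#' Generate an ambiguous synthetic spectrum
#'
#' Modes mirror the anomaly classes observed clinically:
#' `cancer-no-carotenoid` draws a PTC spectrum whose carotenoid bands follow
#' the healthy amplitude profile; `benign-weak-oxcytb` draws a benign
#' spectrum with the 1376 cm^-1 oxidised cytochrome b band attenuated
#' twenty-fold; `benign-with-carotenoid` draws a benign spectrum whose
#' carotenoid bands follow the PTC profile (the mutation-carrying
#' histologically benign case). The nominal diagnosis label is retained and
#' the ambiguous flag set.
#'
#' @param mode one of the three modes above.
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @param sample_id sample identifier.
#' @return List with `spectrum`, `diagnosis` (nominal label), `class` and
#'   `ambiguous = TRUE`.
#' @export
generate_ambiguous <- function(mode = c("cancer-no-carotenoid",
                                        "benign-weak-oxcytb",
                                        "benign-with-carotenoid"),
                               config, seed,
                               sample_id = paste0(mode, "_", seed)) {
  mode <- match.arg(mode)
  spec <- switch(mode,
    "cancer-no-carotenoid" = list(
      diagnosis = "PTC", override = list(carotenoid = "healthy")),
    "benign-weak-oxcytb" = list(
      diagnosis = "benign", override = list(`oxidised-cyt-b` = 0.05)),
    "benign-with-carotenoid" = list(
      diagnosis = "benign", override = list(carotenoid = "PTC"))
  )
  s <- generate_spectrum(spec$diagnosis, config, seed, sample_id,
                         amplitude_override = spec$override)
  list(spectrum = s, diagnosis = spec$diagnosis,
       class = binary_class(spec$diagnosis), ambiguous = TRUE)
}
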