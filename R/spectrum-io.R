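#' Raman spectrum container
#'
#' A `spectrum` is a sampled Raman trace: a vector of Raman shifts (cm^-1,
#' strictly increasing) and the matching intensities (arbitrary units,
#' background already subtracted upstream), tagged with a sample identifier.
#'
#' @param shifts numeric vector of Raman shifts in cm^-1.
#' @param intensities numeric vector of intensities, same length as `shifts`.
#' @param sample_id single string naming the sample.
#' @return An object of class `spectrum`.
#' @export
new_spectrum <- function(shifts, intensities, sample_id = "sample") {
  shifts <- as.numeric(shifts)
  intensities <- as.numeric(intensities)
  if (length(shifts) != length(intensities))
    stop("shifts and intensities must have equal length", call. = FALSE)
  if (length(shifts) < 2L)
    stop("malformed spectrum: fewer than 2 points", call. = FALSE)
  if (any(!is.finite(shifts)) || any(!is.finite(intensities)))
    stop("spectrum values must be finite", call. = FALSE)
  if (any(diff(shifts) <= 0))
    stop("shifts must be strictly increasing", call. = FALSE)
  structure(
    list(shifts = shifts, intensities = intensities,
         sample_id = as.character(sample_id)[1]),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum '%s': %d points, %.1f-%.1f cm^-1>\n",
              x$sample_id, length(x$shifts), min(x$shifts), max(x$shifts)))
  invisible(x)
}

#' Read a two-column spectrum file
#'
#' Reads delimited text (whitespace or comma separated) with two numeric
#' columns: Raman shift (cm^-1) and intensity. Lines starting with `#` are
#' comments. Rows are sorted by ascending shift; duplicated shift values are
#' collapsed by averaging their intensities.
#'
#' @param path path to the spectrum file.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @return A [new_spectrum()] object.
#' @export
read_spectrum <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("spectrum file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) < 2L)
    stop("malformed spectrum (", path, "): fewer than 2 data rows", call. = FALSE)
  parts <- strsplit(trimws(lines), "[,;[:space:]]+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad))
    stop("parse error in ", path, " at line ", lineno[bad[1]], call. = FALSE)
  shift <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  intens <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  nn <- which(is.na(shift) | is.na(intens))
  if (length(nn))
    stop("parse error: non-numeric row in ", path, " at line ", lineno[nn[1]],
         call. = FALSE)
  # collapse duplicate shifts by averaging, then sort
  if (anyDuplicated(shift)) {
    intens <- as.numeric(tapply(intens, shift, mean))
    shift <- sort(unique(shift))
  } else {
    o <- order(shift)
    shift <- shift[o]; intens <- intens[o]
  }
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  new_spectrum(shift, intens, sample_id)
}

#' Diagnosis vocabulary and binary class encoding
#'
#' The closed diagnosis vocabulary. `healthy` and `benign` map to the
#' negative class 0; the carcinoma labels `PTC`, `FC` and `FV-PTC` map to the
#' positive class 1 (so that positive SHAP values point toward cancer).
#'
#' @return Character vector of valid diagnosis tokens.
#' @export
diagnosis_levels <- function() c("healthy", "benign", "PTC", "FC", "FV-PTC")

#' Map diagnoses to the binary cancer class
#'
#' @param diagnosis character vector of diagnosis tokens.
#' @return Integer vector: 0 for healthy/benign, 1 for carcinoma.
#' @export
binary_class <- function(diagnosis) {
  bad <- setdiff(unique(diagnosis), diagnosis_levels())
  if (length(bad))
    stop("unknown diagnosis token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  as.integer(diagnosis %in% c("PTC", "FC", "FV-PTC"))
}

#' Read a dataset manifest
#'
#' The manifest is a delimited table (CSV or TSV, autodetected from the
#' extension) with columns `sample_id`, `file`, `diagnosis` and `ambiguous`.
#' Relative file paths are resolved against the manifest's directory. Row
#' order defines the canonical instance index used by the leave-one-out loop.
#'
#' @param path path to the manifest file.
#' @return A data frame of class `dataset_manifest` with columns `sample_id`,
#'   `file`, `diagnosis`, `ambiguous` and the derived `class` (0/1).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  m <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "file", "diagnosis", "ambiguous")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id in manifest: ",
         m$sample_id[duplicated(m$sample_id)][1], call. = FALSE)
  m$ambiguous <- as.logical(m$ambiguous)
  m$class <- binary_class(m$diagnosis)
  rel <- !grepl("^(/|[A-Za-z]:)", m$file)
  m$file[rel] <- file.path(dirname(path), m$file[rel])
  structure(m, class = c("dataset_manifest", "data.frame"))
}

#' Load all spectra referenced by a manifest
#'
#' @param manifest a `dataset_manifest` from [read_manifest()].
#' @return A `labeled_dataset`: list with `spectra` (list of `spectrum`, in
#'   manifest order), `diagnosis`, `class`, `ambiguous`, `sample_id`.
#' @export
load_dataset <- function(manifest) {
  spectra <- Map(read_spectrum, manifest$file, manifest$sample_id)
  names(spectra) <- manifest$sample_id
  structure(
    list(spectra = unname(spectra), sample_id = manifest$sample_id,
         diagnosis = manifest$diagnosis, class = manifest$class,
         ambiguous = manifest$ambiguous),
    class = "labeled_dataset"
  )
}

#' Write a table as full-precision TSV
#'
#' Numeric columns are written with 17 significant digits so that reading the
#' file back reproduces the values exactly (as decimal text round-trip).
#'
#' @param rows a data frame.
#' @param path output path.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.17g", out[[j]])
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write table to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path path to the TSV file.
#' @return A data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
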