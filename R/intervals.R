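#' Build candidate intervals from mixture components
#'
#' One closed interval `[mu - sigma, mu + sigma]` per mixture component,
#' sorted ascending by lower bound. `origin` records the source component
#' indices (1-based, in ascending-mu order).
#'
#' @param m a `mixture_model`, or a data frame with columns `mu` and `sigma`.
#' @return An `interval_set`: data frame with columns `lo`, `hi`, `origin`
#'   (comma-separated component indices) and attribute `finalized = FALSE`.
#' @export
build_intervals <- function(m) {
  comp <- if (inherits(m, "mixture_model")) m$components else as.data.frame(m)
  s <- data.frame(
    lo = comp$mu - comp$sigma,
    hi = comp$mu + comp$sigma,
    origin = as.character(seq_len(nrow(comp))),
    stringsAsFactors = FALSE
  )
  s <- s[order(s$lo, s$hi), , drop = FALSE]
  rownames(s) <- NULL
  structure(s, class = c("interval_set", "data.frame"), finalized = FALSE)
}

#' Build an interval set from explicit bounds
#'
#' Used to drop in externally supplied interval boundaries (e.g. published
#' supplementary tables) in place of mixture-derived ones.
#'
#' @param lo,hi numeric bounds, `lo < hi` elementwise.
#' @param origin optional origin labels.
#' @return An unfinalised `interval_set`.
#' @export
as_interval_set <- function(lo, hi, origin = as.character(seq_along(lo))) {
  s <- data.frame(lo = lo, hi = hi, origin = origin, stringsAsFactors = FALSE)
  s <- s[order(s$lo, s$hi), , drop = FALSE]
  rownames(s) <- NULL
  structure(s, class = c("interval_set", "data.frame"), finalized = FALSE)
}

# smallest original component index named in an origin string (tie-break key)
origin_min <- function(origin) {
  vapply(strsplit(origin, ","), function(v) min(as.integer(v)), integer(1))
}

#' Remove intervals entirely contained in another interval
#'
#' Drops every interval `[a, b]` for which some other interval `[c, d]`
#' satisfies `c <= a` and `b <= d`. Exact duplicates keep the copy with the
#' smallest original component index.
#'
#' @param s an unfinalised `interval_set`.
#' @return The `interval_set` without contained intervals.
#' @export
remove_contained <- function(s) {
  n <- nrow(s)
  if (n <= 1L) return(s)
  key <- origin_min(s$origin)
  drop <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (s$lo[j] <= s$lo[i] && s$hi[i] <= s$hi[j]) {
        dup <- s$lo[j] == s$lo[i] && s$hi[j] == s$hi[i]
        if (!dup || key[j] < key[i] || (key[j] == key[i] && j < i)) {
          drop[i] <- TRUE
          break
        }
      }
    }
  }
  out <- s[!drop, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(s), finalized = FALSE)
}

#' Merge partially overlapping intervals to a fixed point
#'
#' Any two closed intervals that intersect (including touching endpoints)
#' are replaced by `[min(lo), max(hi)]` with their origins united, repeated
#' until no pair intersects.
#'
#' @param s an `interval_set` with containment already removed.
#' @return A pairwise non-overlapping `interval_set`.
#' @export
merge_overlapping <- function(s) {
  lo <- s$lo; hi <- s$hi; origin <- s$origin
  repeat {
    o <- order(lo, hi)
    lo <- lo[o]; hi <- hi[o]; origin <- origin[o]
    merged <- FALSE
    i <- 1L
    while (i < length(lo)) {
      if (lo[i + 1L] <= hi[i]) {   # closed intervals: touching counts
        hi[i] <- max(hi[i], hi[i + 1L])
        origin[i] <- paste(sort(unique(c(
          strsplit(origin[i], ",")[[1]], strsplit(origin[i + 1L], ",")[[1]]
        ))), collapse = ",")
        lo <- lo[-(i + 1L)]; hi <- hi[-(i + 1L)]; origin <- origin[-(i + 1L)]
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }
  out <- data.frame(lo = lo, hi = hi, origin = origin,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = class(s), finalized = FALSE)
}

#' Finalise the interval set of a mixture model
#'
#' build -> remove contained -> merge overlapping -> reindex 1..m ascending
#' by lower bound.
#'
#' @param m a `mixture_model` or an unfinalised `interval_set`.
#' @return A finalised `interval_set` with an `index` column.
#' @export
finalize_intervals <- function(m) {
  s <- if (inherits(m, "interval_set")) m else build_intervals(m)
  s <- merge_overlapping(remove_contained(s))
  if (nrow(s) == 0L) stop("no intervals after finalization", call. = FALSE)
  out <- data.frame(index = seq_len(nrow(s)), lo = s$lo, hi = s$hi,
                    origin = s$origin, stringsAsFactors = FALSE)
  structure(out, class = c("interval_set", "data.frame"), finalized = TRUE)
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set: %d intervals%s>\n", nrow(x),
              if (isTRUE(attr(x, "finalized"))) ", finalized" else ""))
  print(as.data.frame(x))
  invisible(x)
}
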