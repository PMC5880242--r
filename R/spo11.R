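#' Raw coverage library
#'
#' Per-window read coverage for one sequencing library (SPO11-1-oligo
#' replicate or genomic-DNA control) together with its library size.
#'
#' @param label Library label.
#' @param tracks A [windowed_track()] or named list of them (counts >= 0).
#' @param library_size Total mapped reads; defaults to the sum of the
#'   coverage values.
#' @return Object of class `coverage_library`.
#' @export
coverage_library <- function(label, tracks, library_size = NULL) {
  tracks <- as_track_set(tracks)
  vals <- unlist(lapply(tracks, `[[`, "values"))
  if (any(vals < 0, na.rm = TRUE)) stop("coverage values must be >= 0")
  if (is.null(library_size)) library_size <- sum(vals, na.rm = TRUE)
  if (library_size <= 0) stop("library_size must be > 0")
  structure(list(label = label, tracks = tracks,
                 library_size = as.numeric(library_size)),
            class = "coverage_library")
}

#' @export
print.coverage_library <- function(x, ...) {
  cat(sprintf("<coverage_library> %s: %d chromosome(s), library size %.4g\n",
              x$label, length(x$tracks), x$library_size))
  invisible(x)
}

map_track_set <- function(tracks, f, kind = NULL) {
  lapply(tracks, function(tr) {
    windowed_track(tr$chrom, tr$chrom_length, tr$window_size, f(tr$values),
                   kind %||% tr$kind)
  })
}

#' Library-size normalization (reads per `scale`)
#'
#' @param lib A [coverage_library()].
#' @param scale Reads scale (default 1e6, i.e. reads per million).
#' @return Named list of [windowed_track()]s with values
#'   `coverage * scale / library_size`, kind `"RPM"`.
#' @export
normalize_library <- function(lib, scale = 1e6) {
  stopifnot(inherits(lib, "coverage_library"), scale > 0)
  map_track_set(lib$tracks, function(v) v * scale / lib$library_size, "RPM")
}

#' Per-window log2 ratio of two library-normalized tracks
#'
#' `log2((s + pseudocount) / (g + pseudocount))`; a window with zero in
#' both tracks is exactly 0.
#'
#' @param spo11,gdna [windowed_track()]s or named track sets of identical
#'   shape (library-normalized).
#' @param pseudocount Added to numerator and denominator (> 0; default 1
#'   read per `scale`).
#' @return Same structure, kind `"log2-ratio"`.
#' @export
log2_ratio <- function(spo11, gdna, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  a <- as_track_set(spo11); b <- as_track_set(gdna)
  if (!identical(sort(names(a)), sort(names(b)))) {
    stop("track sets cover different chromosomes")
  }
  lapply(setNames(names(a), names(a)), function(cn) {
    check_same_shape(a[[cn]], b[[cn]])
    windowed_track(a[[cn]]$chrom, a[[cn]]$chrom_length, a[[cn]]$window_size,
                   log2((a[[cn]]$values + pseudocount) /
                          (b[[cn]]$values + pseudocount)),
                   "log2-ratio")
  })
}

#' Genome-wide z-score standardization
#'
#' Centers and scales all non-missing windows across the whole track set
#' (one global mean and sample (n-1) standard deviation per library), so
#' that scores are the signed number of standard deviations from the mean.
#'
#' @param tracks A [windowed_track()] or named track set.
#' @return Named track set of kind `"z"`; non-missing values have mean 0
#'   and sample SD 1.
#' @export
zscore <- function(tracks) {
  single <- inherits(tracks, "windowed_track")
  ts <- as_track_set(tracks)
  vals <- unlist(lapply(ts, `[[`, "values"))
  ok <- vals[!is.na(vals)]
  if (length(ok) < 2) stop("need >= 2 non-missing windows")
  s <- stats::sd(ok)
  if (s == 0) stop("zero variance: z-score undefined")
  mu <- mean(ok)
  out <- map_track_set(ts, function(v) (v - mu) / s, "z")
  if (single) out[[1]] else out
}

rebin_track <- function(track, new_size) {
  if (new_size == track$window_size) return(track)
  if (new_size %% track$window_size != 0) {
    stop("new window size must be a multiple of the track window size")
  }
  fac <- new_size / track$window_size
  grp <- (seq_along(track$values) - 1) %/% fac
  m <- tapply(track$values, grp, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  windowed_track(track$chrom, track$chrom_length, new_size, as.numeric(m),
                 track$kind)
}

paired_values <- function(a, b) {
  a <- as_track_set(a); b <- as_track_set(b)
  if (!identical(sort(names(a)), sort(names(b)))) {
    stop("track sets cover different chromosomes")
  }
  x <- unlist(lapply(names(a), function(cn) {
    check_same_shape(a[[cn]], b[[cn]]); a[[cn]]$values
  }))
  y <- unlist(lapply(names(a), function(cn) b[[cn]]$values))
  ok <- !is.na(x) & !is.na(y)
  cbind(x = x[ok], y = y[ok])
}

#' Replicate agreement at one or more window scales
#'
#' Tracks are re-binned to each requested scale by averaging and Pearson's
#' r is computed over paired non-missing windows genome-wide.
#'
#' @param a,b [windowed_track()]s or named track sets at a common base
#'   window size.
#' @param scales Window sizes (bp), each a multiple of the base size.
#' @return Named numeric vector of Pearson r, one per scale.
#' @export
replicate_correlation <- function(a, b, scales = 10000) {
  a <- as_track_set(a); b <- as_track_set(b)
  out <- vapply(scales, function(s) {
    ra <- lapply(a, rebin_track, new_size = s)
    rb <- lapply(b, rebin_track, new_size = s)
    xy <- paired_values(ra, rb)
    if (nrow(xy) < 3) stop("fewer than 3 paired windows at scale ", s)
    stats::cor(xy[, 1], xy[, 2])
  }, numeric(1))
  setNames(out, as.character(scales))
}

#' Mutant minus wild-type signal differential
#'
#' Elementwise subtraction of z-scored signal tracks (see
#' [landscape_differential()]; missing values propagate).
#'
#' @param mutant,wild_type [windowed_track()]s or named track sets of
#'   identical shape.
#' @return Same structure with `mutant - wild_type` values.
#' @export
signal_differential <- function(mutant, wild_type) {
  landscape_differential(mutant, wild_type)
}

#' Two-sided p-value for a Pearson correlation
#'
#' From the t transform `t = r sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2`
#' degrees of freedom.
#'
#' @param r Pearson correlation coefficient.
#' @param n Number of paired observations (>= 3).
#' @return Two-sided p-value.
#' @examples
#' pearson_p(-0.93, 7)
#' @export
pearson_p <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  if (abs(r) == 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Pearson correlation between two windowed tracks
#'
#' Computed over paired non-missing windows genome-wide, with the two-sided
#' p-value from the t transform ([pearson_p()]).
#'
#' @param x,y [windowed_track()]s or named track sets of identical shape.
#' @return List with `r`, `p.value` and `n` (paired windows).
#' @export
correlate_tracks <- function(x, y) {
  xy <- paired_values(x, y)
  n <- nrow(xy)
  if (n < 3) stop("fewer than 3 paired non-missing windows")
  if (stats::sd(xy[, 1]) == 0 || stats::sd(xy[, 2]) == 0) {
    stop("constant input: correlation undefined")
  }
  r <- stats::cor(xy[, 1], xy[, 2])
  list(r = r, p.value = pearson_p(r, n), n = n)
}

#' Format a p-value the way correlation software reports it
#'
#' Values below 2.2e-16 are printed as `"< 2.2e-16"`; the raw float is kept
#' in machine-readable output.
#'
#' @param p A p-value.
#' @return Character scalar.
#' @export
format_pvalue <- function(p) {
  if (p < 2.2e-16) "< 2.2e-16" else format(p, digits = 3)
}
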