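#' Windowed genomic track
#'
#' A fixed-width adjacent-window track along one chromosome: one float per
#' window, `NA` marking windows with no data. The number of windows is
#' `ceiling(chrom_length / window_size)`; the last window is truncated at the
#' chromosome end.
#'
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param window_size Window width in bp.
#' @param values Numeric vector, one value per window (`NA` = missing).
#' @param kind Free-text label, e.g. `"CHG"`, `"SPO11-z"`, `"CO-per-F2"`.
#'   Methylation kinds (`CG`, `CHG`, `CHH`) must lie in \[0, 1\].
#' @return An object of class `windowed_track`.
#' @export
windowed_track <- function(chrom, chrom_length, window_size, values,
                           kind = "signal") {
  stopifnot(length(chrom) == 1L, chrom_length > 0, window_size > 0)
  n <- n_windows(chrom_length, window_size)
  if (length(values) != n) {
    stop("expected ", n, " windows for a ", chrom_length, "-bp chromosome at ",
         window_size, "-bp windows, got ", length(values))
  }
  values <- as.numeric(values)
  if (any(is.infinite(values))) stop("track values must be finite or NA")
  if (kind %in% c("CG", "CHG", "CHH")) {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1)) {
      stop("methylation track values must lie in [0, 1]")
    }
  }
  structure(
    list(chrom = chrom, chrom_length = as.numeric(chrom_length),
         window_size = as.numeric(window_size), values = values, kind = kind),
    class = "windowed_track"
  )
}

#' @export
print.windowed_track <- function(x, ...) {
  cat(sprintf("<windowed_track> %s: %d x %g-bp windows, kind '%s' (%d missing)\n",
              x$chrom, length(x$values), x$window_size, x$kind,
              sum(is.na(x$values))))
  invisible(x)
}

n_windows <- function(chrom_length, window_size) {
  as.integer(ceiling(chrom_length / window_size))
}

## A "track set" is a named list of windowed_track, one per chromosome.
as_track_set <- function(x) {
  if (inherits(x, "windowed_track")) return(setNames(list(x), x$chrom))
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "windowed_track")))
  setNames(x, vapply(x, `[[`, "", "chrom"))
}

check_same_shape <- function(a, b) {
  if (a$chrom != b$chrom || a$window_size != b$window_size ||
      length(a$values) != length(b$values)) {
    stop("tracks differ in chromosome, window size or window count")
  }
  invisible(TRUE)
}

#' Adjacent genomic windows
#'
#' Half-open windows `[0, w), [w, 2w), ...` covering `[0, chrom_length)`;
#' the final window is truncated at the chromosome end.
#'
#' @param chrom_length Chromosome length in bp.
#' @param window_size Window width in bp (> 0).
#' @return A data.frame with columns `start`, `end` (0-based, half-open).
#' @examples
#' make_windows(100, 30)
#' @export
make_windows <- function(chrom_length, window_size) {
  stopifnot(chrom_length > 0, window_size > 0)
  starts <- seq(0, chrom_length - 1, by = window_size)
  data.frame(start = starts,
             end = pmin(starts + window_size, chrom_length))
}

#' Centered rolling mean
#'
#' Centered moving average over `k` adjacent values (as computed by
#' `stats::filter`). The first and last `(k - 1) / 2` entries are `NA`, and
#' `NA` inputs propagate into every window that covers them.
#'
#' @param values Numeric vector.
#' @param k Odd window count, `1 <= k <= length(values)`.
#' @return Numeric vector of the same length.
#' @examples
#' rolling_mean(c(1, 2, 3, 4, 5), 3)
#' @export
rolling_mean <- function(values, k) {
  if (k %% 2 == 0) stop("k must be odd")
  stopifnot(k >= 1, k <= length(values))
  if (k == 1) return(as.numeric(values))
  as.numeric(stats::filter(as.numeric(values), rep(1 / k, k), sides = 2))
}

#' Proportional telomere-to-centromere bins for one chromosome arm
#'
#' Divides an arm into `1/fraction` bins of equal bp width (the bin nearest
#' the centromere absorbs the rounding remainder), ordered so that bin 0
#' abuts the telomere. Arms on the right side of the chromosome (telomere at
#' the high coordinate) are coordinate-reversed before binning.
#'
#' @param arm Numeric length-2, `c(start, end)` of the arm (0-based,
#'   half-open).
#' @param fraction Proportion of the arm per bin; `1/fraction` must be an
#'   integer (e.g. 0.01 for 100 bins, 0.005 for 200).
#' @param side `"left"` if the telomere is at `arm[1]`, `"right"` if at
#'   `arm[2]`.
#' @return A data.frame with columns `bin` (0-based, telomere-first),
#'   `start`, `end` (genome coordinates); bin lengths sum exactly to the arm
#'   length.
#' @examples
#' tel_cen_bins(c(0, 1003), 0.01)[c(1, 100), ]
#' @export
tel_cen_bins <- function(arm, fraction, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(length(arm) == 2, arm[1] < arm[2], fraction > 0, fraction <= 1)
  n <- 1 / fraction
  if (abs(n - round(n)) > 1e-9) stop("1/fraction must be an integer bin count")
  n <- as.integer(round(n))
  len <- arm[2] - arm[1]
  width <- len %/% n
  if (width < 1) stop("arm shorter than the requested number of bins")
  if (side == "left") {
    start <- arm[1] + (0:(n - 1)) * width
    end <- c(start[-1], arm[2])
  } else {
    end <- arm[2] - (0:(n - 1)) * width
    start <- c(end[-1], arm[1])
  }
  data.frame(bin = 0:(n - 1), start = start, end = end)
}
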