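#' Genome annotation with arm / pericentromere / centromere partition
#'
#' Chromosome names and lengths, one assembly-gap interval per chromosome,
#' and a three-class partition whose intervals are non-overlapping, sorted,
#' and tile `[0, length)` on every chromosome. Each chromosome has exactly
#' one centromere interval containing its assembly gap; pericentromere
#' intervals (0-2 per chromosome) are adjacent to the centromere.
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp), in
#'   chromosome order.
#' @param gaps data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open), one row per chromosome.
#' @param partition data.frame with columns `chrom`, `start`, `end`,
#'   `class` (one of `"arm"`, `"pericentromere"`, `"centromere"`).
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(chromosomes, gaps, partition) {
  stopifnot(all(c("name", "length") %in% names(chromosomes)),
            all(c("chrom", "start", "end") %in% names(gaps)),
            all(c("chrom", "start", "end", "class") %in% names(partition)))
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name)) stop("duplicate chromosome names")
  if (!all(partition$class %in% c("arm", "pericentromere", "centromere"))) {
    stop("partition classes must be arm / pericentromere / centromere")
  }
  for (cn in chromosomes$name) {
    len <- chromosomes$length[chromosomes$name == cn]
    p <- partition[partition$chrom == cn, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (nrow(p) == 0) stop("no partition intervals for ", cn)
    if (p$start[1] != 0 || p$end[nrow(p)] != len ||
        any(p$start[-1] != p$end[-nrow(p)])) {
      stop("partition does not tile [0, length) on ", cn)
    }
    if (any(p$end <= p$start)) stop("empty partition interval on ", cn)
    cen <- p[p$class == "centromere", , drop = FALSE]
    if (nrow(cen) != 1) stop("expected exactly one centromere on ", cn)
    g <- gaps[gaps$chrom == cn, , drop = FALSE]
    if (nrow(g) != 1) stop("expected exactly one assembly gap on ", cn)
    if (g$start < cen$start || g$end > cen$end) {
      stop("centromere does not contain the assembly gap on ", cn)
    }
    peri <- p[p$class == "pericentromere", , drop = FALSE]
    if (nrow(peri) > 2) stop("more than two pericentromeres on ", cn)
    if (nrow(peri) > 0 &&
        !all(peri$end == cen$start | peri$start == cen$end)) {
      stop("pericentromere not adjacent to the centromere on ", cn)
    }
  }
  partition <- partition[order(match(partition$chrom, chromosomes$name),
                               partition$start), ]
  rownames(partition) <- NULL
  structure(list(chromosomes = chromosomes, gaps = gaps,
                 partition = partition),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  lens <- region_lengths(x)
  cat(sprintf("<genome_annotation> %d chromosomes, %.3g Mb total\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6))
  cat(sprintf("  arm %.3g Mb | pericentromere %.3g Mb | centromere %.3g Mb\n",
              lens["arm"] / 1e6, lens["pericentromere"] / 1e6,
              lens["centromere"] / 1e6))
  invisible(x)
}

#' Total bp per partition class
#'
#' @param annotation A [genome_annotation()].
#' @return Named numeric vector of class lengths (bp) for `arm`,
#'   `pericentromere`, `centromere`.
#' @export
region_lengths <- function(annotation) {
  p <- annotation$partition
  out <- c(arm = 0, pericentromere = 0, centromere = 0)
  got <- tapply(p$end - p$start, p$class, sum)
  out[names(got)] <- got
  out
}

#' Genetically define a centromere from a wild-type crossover desert
#'
#' The centromere is the maximal run of adjacent `scan_window`-sized windows
#' containing the assembly gap in which no wild-type crossover midpoint
#' falls, converted to bp (the run is seeded from the gap-overlapping
#' windows and extended outward, so the result always contains the gap).
#'
#' @param wt_crossover_midpoints Numeric vector of wild-type crossover
#'   midpoints (bp) on this chromosome; may be empty.
#' @param gap Numeric length-2 assembly-gap interval `c(start, end)`.
#' @param chrom_length Chromosome length in bp.
#' @param scan_window Scan resolution in bp (default 10 kb, the same
#'   granularity as the landscape windows).
#' @return Numeric length-2 centromere interval (0-based, half-open),
#'   clipped to `[0, chrom_length)`.
#' @examples
#' define_centromere(c(100500, 900500), c(500000, 510000), 1e6, 1e4)
#' @export
define_centromere <- function(wt_crossover_midpoints, gap, chrom_length,
                              scan_window = 10000) {
  stopifnot(length(gap) == 2, gap[1] < gap[2], gap[1] >= 0,
            gap[2] <= chrom_length, scan_window > 0)
  m <- wt_crossover_midpoints
  if (any(m >= gap[1] & m < gap[2])) {
    stop("wild-type crossover midpoint inside the assembly gap: ",
         "inconsistent input")
  }
  nw <- n_windows(chrom_length, scan_window)
  counts <- tabulate(floor(m / scan_window) + 1L, nbins = nw)
  lo <- floor(gap[1] / scan_window) + 1L
  hi <- floor((gap[2] - 1) / scan_window) + 1L
  while (lo > 1L && counts[lo - 1L] == 0L) lo <- lo - 1L
  while (hi < nw && counts[hi + 1L] == 0L) hi <- hi + 1L
  c((lo - 1L) * scan_window, min(hi * scan_window, chrom_length))
}

#' Define pericentromeres by above-average DNA methylation
#'
#' Starting from each centromere edge, extends outward window by window
#' while the window's methylation value is strictly greater than the
#' chromosome-wide mean of the track (missing windows stop the extension).
#'
#' @param methylation A [windowed_track()] of methylation proportions
#'   covering the chromosome.
#' @param centromere Numeric length-2 centromere interval from
#'   [define_centromere()].
#' @return List with elements `left` and `right`, each a numeric length-2
#'   interval or `NULL` if the flank is empty.
#' @export
define_pericentromere <- function(methylation, centromere) {
  stopifnot(inherits(methylation, "windowed_track"),
            length(centromere) == 2, centromere[1] < centromere[2])
  v <- methylation$values
  if (all(is.na(v))) stop("all-missing methylation track")
  mu <- mean(v, na.rm = TRUE)
  w <- methylation$window_size
  len <- methylation$chrom_length
  nw <- length(v)
  above <- function(i) i >= 1L && i <= nw && !is.na(v[i]) && v[i] > mu

  ## windows fully left of the centromere, scanned outward
  i <- floor(centromere[1] / w)            # last window with end <= cen start
  left <- NULL
  j <- i
  while (above(j)) j <- j - 1L
  if (j < i) left <- c((j) * w, centromere[1])

  ## first window starting at or after the centromere end
  i <- floor(centromere[2] / w) + 1L + (centromere[2] %% w > 0)
  right <- NULL
  j <- i
  while (above(j)) j <- j + 1L
  if (j > i) right <- c(centromere[2], min((j - 1L) * w, len))
  list(left = left, right = right)
}

#' Average methylation-context tracks into one track
#'
#' Unweighted per-window mean of the given context tracks (a window missing
#' in any context is missing in the mean).
#'
#' @param tracks List of [windowed_track()]s with identical shape (e.g. CG,
#'   CHG and CHH for one chromosome).
#' @return A [windowed_track()] of kind `"meth-mean"`.
#' @export
average_context_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  t1 <- tracks[[1]]
  for (tk in tracks[-1]) check_same_shape(t1, tk)
  m <- rowMeans(do.call(cbind, lapply(tracks, `[[`, "values")))
  windowed_track(t1$chrom, t1$chrom_length, t1$window_size, m, "meth-mean")
}

#' Build the arm / pericentromere / centromere partition for a genome
#'
#' Per chromosome: the centromere is the wild-type crossover desert
#' containing the assembly gap ([define_centromere()]); pericentromeres
#' extend from its edges while methylation exceeds the chromosome average
#' ([define_pericentromere()]); arms are the remainder.
#'
#' @param chromosomes data.frame with columns `name`, `length`.
#' @param gaps data.frame with columns `chrom`, `start`, `end`.
#' @param wt_midpoints Named list (by chromosome) of wild-type crossover
#'   midpoint vectors.
#' @param methylation Named list (by chromosome); each element is either a
#'   single [windowed_track()] or a named list of context tracks
#'   (`CG`, `CHG`, `CHH`).
#' @param scan_window Centromere scan resolution in bp.
#' @param context_mode Which methylation context drives the pericentromere
#'   rule: `"mean"` (unweighted mean of the supplied contexts) or one of
#'   `"CG"`, `"CHG"`, `"CHH"`.
#' @return A [genome_annotation()].
#' @export
build_partition <- function(chromosomes, gaps, wt_midpoints, methylation,
                            scan_window = 10000,
                            context_mode = c("mean", "CG", "CHG", "CHH")) {
  context_mode <- match.arg(context_mode)
  rows <- list()
  for (k in seq_len(nrow(chromosomes))) {
    cn <- chromosomes$name[k]
    len <- chromosomes$length[k]
    g <- gaps[gaps$chrom == cn, ]
    if (nrow(g) != 1) stop("expected exactly one assembly gap on ", cn)
    cen <- define_centromere(wt_midpoints[[cn]] %||% numeric(0),
                             c(g$start, g$end), len, scan_window)
    meth <- methylation[[cn]]
    if (inherits(meth, "windowed_track")) {
      track <- meth
    } else if (context_mode == "mean") {
      track <- average_context_tracks(meth)
    } else {
      track <- meth[[context_mode]]
      if (is.null(track)) stop("no ", context_mode, " track for ", cn)
    }
    peri <- define_pericentromere(track, cen)
    lo <- if (is.null(peri$left)) cen[1] else peri$left[1]
    hi <- if (is.null(peri$right)) cen[2] else peri$right[2]
    seg <- function(s, e, cls) {
      if (e > s) data.frame(chrom = cn, start = s, end = e, class = cls)
    }
    rows <- c(rows, list(
      seg(0, lo, "arm"),
      if (!is.null(peri$left)) seg(peri$left[1], peri$left[2], "pericentromere"),
      seg(cen[1], cen[2], "centromere"),
      if (!is.null(peri$right)) seg(peri$right[1], peri$right[2], "pericentromere"),
      seg(hi, len, "arm")
    ))
  }
  genome_annotation(chromosomes, gaps, do.call(rbind, Filter(Negate(is.null), rows)))
}

#' Chromosome arms with telomere orientation
#'
#' @param annotation A [genome_annotation()].
#' @return data.frame with columns `chrom`, `start`, `end`, `side`
#'   (`"left"` arms have the telomere at `start`, `"right"` at `end`).
#' @export
arms_from_annotation <- function(annotation) {
  p <- annotation$partition
  out <- list()
  for (cn in annotation$chromosomes$name) {
    cen <- p[p$chrom == cn & p$class == "centromere", ]
    arms <- p[p$chrom == cn & p$class == "arm", ]
    if (nrow(arms) == 0) next
    arms$side <- ifelse(arms$end <= cen$start, "left", "right")
    out[[cn]] <- arms[, c("chrom", "start", "end", "side")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
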