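#' The CEN180 centromeric satellite consensus
#'
#' The 178-bp *Arabidopsis thaliana* centromeric satellite consensus
#' sequence shipped with the package.
#'
#' @return A `Biostrings::DNAString` of length 178.
#' @export
cen180_consensus <- function() {
  f <- system.file("extdata", "cen180_consensus.fa", package = "pericentrec",
                   mustWork = TRUE)
  Biostrings::readDNAStringSet(f)[[1]]
}

#' Strand-aware approximate matches of a satellite consensus
#'
#' Reports every start position on both strands whose Hamming distance to
#' the consensus is at most `max_mismatch` (substitutions only, no indels;
#' `Biostrings::matchPattern` with `with.indels = FALSE, fixed = TRUE`, so
#' `N` and other ambiguity codes always count as mismatches). Reverse-strand
#' matches are matches of the reverse-complemented consensus, reported in
#' forward coordinates. Overlapping matches are all retained; matches
#' overhanging a sequence end are not reported.
#'
#' @param genome A `Biostrings::DNAStringSet`, or the path to a FASTA file.
#' @param consensus The consensus as a `DNAString` or character string
#'   (default [cen180_consensus()]).
#' @param max_mismatch Mismatch budget (default 90; must be smaller than
#'   the consensus length).
#' @return A data.frame of class `repeat_match_set` with columns `chrom`,
#'   `start`, `end` (0-based, half-open; `end - start` = consensus length),
#'   `strand` (`"+"`/`"-"`) and `mismatches`.
#' @export
find_consensus_matches <- function(genome, consensus = cen180_consensus(),
                                   max_mismatch = 90) {
  if (is.character(genome) && length(genome) == 1) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (is.character(consensus)) consensus <- Biostrings::DNAString(consensus)
  L <- length(consensus)
  stopifnot(L > 0, max_mismatch >= 0, max_mismatch < L)
  names(genome) <- sub("\\s.*$", "", names(genome))
  pats <- list(`+` = consensus,
               `-` = Biostrings::reverseComplement(consensus))
  rows <- list()
  for (cn in names(genome)) {
    subj <- genome[[cn]]
    if (length(subj) < L) next
    for (strand in names(pats)) {
      m <- Biostrings::matchPattern(pats[[strand]], subj,
                                    max.mismatch = max_mismatch,
                                    with.indels = FALSE, fixed = TRUE)
      keep <- BiocGenerics::start(m) >= 1 &
        BiocGenerics::end(m) <= length(subj)
      starts <- BiocGenerics::start(m)[keep]
      if (!length(starts)) next
      mm <- Biostrings::neditStartingAt(pats[[strand]], subj,
                                        starting.at = starts,
                                        with.indels = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cn, start = starts - 1L, end = starts - 1L + L,
        strand = strand, mismatches = as.integer(mm))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), mismatches = integer(0))
  }
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("repeat_match_set", "data.frame"),
            consensus_length = L, max_mismatch = max_mismatch)
}

#' Count satellite matches
#'
#' @param matches A `repeat_match_set` from [find_consensus_matches()].
#' @param dedup Count each distinct (chromosome, start) once, collapsing
#'   strand duplicates and overlapping reports at the same start.
#' @return Integer count.
#' @export
n_matches <- function(matches, dedup = FALSE) {
  if (!dedup) return(nrow(matches))
  nrow(unique(as.data.frame(matches)[, c("chrom", "start")]))
}

#' Mean signal metaprofile around anchor positions
#'
#' For each anchor midpoint, extracts the (piecewise-constant) track signal
#' in `[mid - flank, mid + flank)`, averages it in `bin`-bp bins
#' (orientation-flipping minus-strand anchors), and averages across
#' anchors. Anchors whose window exceeds the chromosome bounds are dropped
#' and counted.
#'
#' @param tracks A [windowed_track()] or named track set carrying the
#'   signal.
#' @param anchors A `repeat_match_set`, or a data.frame with columns
#'   `chrom`, `midpoint` and optionally `strand`.
#' @param flank Half-window in bp (> 0).
#' @param bin Bin width in bp; must divide `2 * flank`.
#' @param control Flag recorded on the result (e.g. for random-position
#'   profiles).
#' @return Object of class `meta_profile` with `offsets` (bin centers
#'   relative to the anchor midpoint), `mean_signal`, `n_anchors`,
#'   `n_dropped` and `control`.
#' @export
metaprofile <- function(tracks, anchors, flank = 10000, bin = 50,
                        control = FALSE) {
  stopifnot(flank > 0, bin > 0, (2 * flank) %% bin == 0)
  tracks <- as_track_set(tracks)
  if (inherits(anchors, "repeat_match_set")) {
    anchors <- data.frame(chrom = anchors$chrom,
                          midpoint = floor((anchors$start + anchors$end) / 2),
                          strand = anchors$strand)
  }
  if (is.null(anchors$strand)) anchors$strand <- "+"
  nb <- as.integer(2 * flank / bin)
  acc <- numeric(nb)
  nobs <- numeric(nb)
  n_used <- 0L
  n_dropped <- 0L
  for (i in seq_len(nrow(anchors))) {
    cn <- anchors$chrom[i]
    tr <- tracks[[cn]]
    mid <- anchors$midpoint[i]
    if (is.null(tr) || mid - flank < 0 || mid + flank > tr$chrom_length) {
      n_dropped <- n_dropped + 1L
      next
    }
    pos <- (mid - flank):(mid + flank - 1)
    v <- tr$values[pos %/% tr$window_size + 1]
    if (anchors$strand[i] == "-") v <- rev(v)
    bv <- colMeans(matrix(v, nrow = bin))
    ok <- !is.na(bv)
    acc[ok] <- acc[ok] + bv[ok]
    nobs <- nobs + ok
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no valid anchors within chromosome bounds")
  mean_signal <- ifelse(nobs > 0, acc / nobs, NA_real_)
  structure(list(offsets = seq(-flank, flank - bin, by = bin) + bin / 2,
                 mean_signal = mean_signal, n_anchors = n_used,
                 n_dropped = n_dropped, flank = flank, bin = bin,
                 control = control),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("<meta_profile> %d anchors (%d dropped), +/-%g bp in %g-bp bins%s\n",
              x$n_anchors, x$n_dropped, x$flank, x$bin,
              if (x$control) " [control]" else ""))
  invisible(x)
}

#' Random control positions over the mappable genome
#'
#' Uniformly distributed positions over all chromosomes excluding the
#' assembly gaps, reproducible given a seed. Used as the control anchor set
#' matching the number of satellite matches.
#'
#' @param annotation A [genome_annotation()].
#' @param n Number of positions (>= 1); typically `n_matches(...)`.
#' @param seed Optional integer seed (the caller's RNG state is restored
#'   afterwards).
#' @return data.frame with columns `chrom`, `midpoint`, `strand` (`"+"`),
#'   directly usable as [metaprofile()] anchors.
#' @export
random_control_positions <- function(annotation, n, seed = NULL) {
  stopifnot(n >= 1)
  segs <- list()
  for (k in seq_len(nrow(annotation$chromosomes))) {
    cn <- annotation$chromosomes$name[k]
    len <- annotation$chromosomes$length[k]
    g <- annotation$gaps[annotation$gaps$chrom == cn, ]
    segs[[cn]] <- data.frame(
      chrom = cn,
      start = c(0, g$end),
      end = c(g$start, len))
  }
  segs <- do.call(rbind, segs)
  segs <- segs[segs$end > segs$start, ]
  cw <- cumsum(segs$end - segs$start)
  draw <- function() {
    u <- runif(n) * cw[length(cw)]
    i <- findInterval(u, cw) + 1L        # segment whose cumulative span holds u
    data.frame(chrom = segs$chrom[i],
               midpoint = floor(segs$start[i] + (u - c(0, cw)[i])),
               strand = "+")
  }
  with_seed(seed, draw())
}

## Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
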