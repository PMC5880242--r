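#' Crossover population mapped by genotyping-by-sequencing
#'
#' A genotype label, an individual roster, and SNP-bounded crossover
#' uncertainty intervals with midpoints. Individuals with zero crossovers
#' stay in the roster and count toward per-individual means.
#'
#' @param genotype Genotype label, e.g. `"wild_type"`.
#' @param individuals Character vector of individual ids (the roster).
#' @param intervals data.frame with columns `individual`, `chrom`, `start`,
#'   `end` (0-based, half-open).
#' @return An object of class `crossover_population`.
#' @export
crossover_population <- function(genotype, individuals, intervals) {
  stopifnot(length(individuals) >= 1)
  individuals <- as.character(individuals)
  if (anyDuplicated(individuals)) stop("duplicate individual ids")
  if (nrow(intervals) > 0) {
    stopifnot(all(c("individual", "chrom", "start", "end") %in%
                    names(intervals)))
    if (any(intervals$start < 0) || any(intervals$end <= intervals$start)) {
      stop("crossover intervals must satisfy 0 <= start < end")
    }
    bad <- setdiff(intervals$individual, individuals)
    if (length(bad)) {
      stop("interval individual(s) not in the roster: ",
           paste(utils::head(bad, 3), collapse = ", "))
    }
  } else {
    intervals <- data.frame(individual = character(0), chrom = character(0),
                            start = numeric(0), end = numeric(0))
  }
  intervals$midpoint <- floor((intervals$start + intervals$end) / 2)
  rownames(intervals) <- NULL
  structure(list(genotype = genotype, individuals = individuals,
                 n_individuals = length(individuals), intervals = intervals),
            class = "crossover_population")
}

#' @export
print.crossover_population <- function(x, ...) {
  cat(sprintf("<crossover_population> %s: %d crossovers in %d individuals (mean %.2f)\n",
              x$genotype, nrow(x$intervals), x$n_individuals,
              nrow(x$intervals) / x$n_individuals))
  invisible(x)
}

#' Crossovers per individual, zeros included
#'
#' @param pop A [crossover_population()].
#' @return Named integer vector over the full roster.
#' @export
per_individual_counts <- function(pop) {
  stopifnot(inherits(pop, "crossover_population"))
  tab <- table(factor(pop$intervals$individual, levels = pop$individuals))
  setNames(as.integer(tab), pop$individuals)
}

#' Mean crossovers per individual
#'
#' Total crossovers divided by the roster size (individuals with zero
#' crossovers included).
#'
#' @param pop A [crossover_population()].
#' @return A single number.
#' @export
mean_crossovers_per_individual <- function(pop) {
  stopifnot(inherits(pop, "crossover_population"))
  nrow(pop$intervals) / pop$n_individuals
}

#' Count crossovers per region class by midpoint
#'
#' Each crossover is assigned by its midpoint to exactly one partition
#' interval (half-open, start-inclusive); counts sum to the total number of
#' crossovers.
#'
#' @param pop A [crossover_population()].
#' @param annotation A [genome_annotation()] covering every chromosome in
#'   `pop`.
#' @return Named counts for `arm`, `pericentromere`, `centromere`.
#' @export
count_by_region <- function(pop, annotation) {
  stopifnot(inherits(pop, "crossover_population"),
            inherits(annotation, "genome_annotation"))
  out <- c(arm = 0L, pericentromere = 0L, centromere = 0L)
  iv <- pop$intervals
  for (cn in unique(iv$chrom)) {
    p <- annotation$partition[annotation$partition$chrom == cn, , drop = FALSE]
    if (nrow(p) == 0) stop("partition has no intervals for chromosome ", cn)
    mids <- iv$midpoint[iv$chrom == cn]
    idx <- findInterval(mids, p$start)
    if (any(idx == 0) || any(mids >= p$end[pmax(idx, 1L)])) {
      stop("crossover midpoint outside the partition on ", cn,
           " (partition incomplete)")
    }
    tab <- table(factor(p$class[idx], levels = names(out)))
    out <- out + as.integer(tab)
  }
  out
}

#' Chi-square test of region counts against physical-distance expectation
#'
#' Goodness-of-fit chi-square of observed per-class crossover counts
#' against expectations proportional to class physical length
#' (`expected_i = total * length_i / genome length`), df = classes - 1.
#'
#' @param observed Named counts per region class.
#' @param annotation A [genome_annotation()] supplying class lengths.
#' @return List with `statistic`, `df`, `p.value`, `expected`.
#' @export
region_chisq_vs_random <- function(observed, annotation) {
  stopifnot(sum(observed) > 0)
  lens <- region_lengths(annotation)[names(observed)]
  if (any(is.na(lens))) stop("unknown region class in observed counts")
  if (any(lens == 0 & observed > 0)) {
    stop("nonzero observed count in a class with zero physical length")
  }
  keep <- lens > 0
  ht <- suppressWarnings(
    stats::chisq.test(observed[keep], p = lens[keep] / sum(lens[keep])))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, expected = ht$expected)
}

#' Chi-square genotype comparison of in-class versus out-of-class crossovers
#'
#' Default is a 2x2 chi-square (df 1, no continuity correction) on
#' (in-class, out-of-class) x (genotype A, genotype B). The alternative
#' `"homogeneity"` method tests the full class distribution (df =
#' classes - 1).
#'
#' @param countsA,countsB Named per-class counts for the two genotypes.
#' @param class Region class tested in the 2x2 method.
#' @param method `"two_by_two"` (default) or `"homogeneity"`.
#' @return List with `statistic`, `df`, `p.value`, `table`.
#' @export
genotype_region_chisq <- function(countsA, countsB,
                                  class = "pericentromere",
                                  method = c("two_by_two", "homogeneity")) {
  method <- match.arg(method)
  stopifnot(sum(countsA) > 0, sum(countsB) > 0)
  if (method == "two_by_two") {
    stopifnot(class %in% names(countsA), class %in% names(countsB))
    tab <- rbind(A = c(sum(countsA[class]), sum(countsA) - sum(countsA[class])),
                 B = c(sum(countsB[class]), sum(countsB) - sum(countsB[class])))
    colnames(tab) <- c("in_class", "out_of_class")
  } else {
    tab <- rbind(A = countsA, B = countsB)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("expected cell count of zero")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, table = tab)
}

#' Mann-Whitney U comparison of per-individual crossover counts
#'
#' Two-sided Mann-Whitney-Wilcoxon test: exact when both samples have at
#' most 20 observations and there are no ties, otherwise the normal
#' approximation with tie correction (no continuity correction).
#'
#' @param countsA,countsB Numeric vectors of per-individual crossover
#'   counts (see [per_individual_counts()]).
#' @return List with `U` and `p.value`.
#' @export
compare_counts_mannwhitney <- function(countsA, countsB) {
  stopifnot(length(countsA) > 0, length(countsB) > 0)
  exact <- min(length(countsA), length(countsB)) <= 20 &&
    !anyDuplicated(c(countsA, countsB))
  ht <- suppressWarnings(
    stats::wilcox.test(countsA, countsB, exact = exact, correct = FALSE))
  list(U = unname(ht$statistic), p.value = ht$p.value)
}

#' Normalized windowed crossover landscape
#'
#' Midpoint tallies in adjacent windows divided by the number of F2
#' individuals, plus a rolling-mean smoothed copy. `smooth_k` is clamped to
#' the largest odd window count available on short chromosomes.
#'
#' @param pop A [crossover_population()].
#' @param chromosomes data.frame with columns `name`, `length`.
#' @param window_size Window width in bp (default 10 kb).
#' @param smooth_k Rolling-mean span in windows (odd; default 9, i.e.
#'   90 kb at 10-kb windows).
#' @return Named list per chromosome, each `list(raw = , smoothed = )` of
#'   [windowed_track()]s of kind `"CO-per-F2"`.
#' @export
crossover_landscape <- function(pop, chromosomes, window_size = 10000,
                                smooth_k = 9) {
  stopifnot(inherits(pop, "crossover_population"), window_size > 0)
  out <- list()
  for (k in seq_len(nrow(chromosomes))) {
    cn <- chromosomes$name[k]
    len <- chromosomes$length[k]
    nw <- n_windows(len, window_size)
    mids <- pop$intervals$midpoint[pop$intervals$chrom == cn]
    vals <- tabulate(floor(mids / window_size) + 1L, nbins = nw) /
      pop$n_individuals
    raw <- windowed_track(cn, len, window_size, vals, "CO-per-F2")
    kk <- min(smooth_k, nw)
    if (kk %% 2 == 0) kk <- kk - 1L
    sm <- windowed_track(cn, len, window_size, rolling_mean(vals, kk),
                         "CO-per-F2")
    out[[cn]] <- list(raw = raw, smoothed = sm)
  }
  out
}

#' Windowed differential (mutant minus wild type)
#'
#' Elementwise subtraction of two tracks (or two named track sets) of
#' identical shape; missing values propagate.
#'
#' @param mutant,wild_type [windowed_track()]s, or named lists of them.
#' @return The same structure, with values `mutant - wild_type` and kind
#'   `"delta-<kind>"`.
#' @export
landscape_differential <- function(mutant, wild_type) {
  if (inherits(mutant, "windowed_track")) {
    check_same_shape(mutant, wild_type)
    return(windowed_track(mutant$chrom, mutant$chrom_length,
                          mutant$window_size,
                          mutant$values - wild_type$values,
                          paste0("delta-", mutant$kind)))
  }
  a <- as_track_set(mutant); b <- as_track_set(wild_type)
  if (!identical(sort(names(a)), sort(names(b)))) {
    stop("track sets cover different chromosomes")
  }
  lapply(setNames(names(a), names(a)),
         function(cn) landscape_differential(a[[cn]], b[[cn]]))
}

## shared binning over one arm: per-bin crossover counts, or
## overlap-weighted means of window values (so bins narrower than the
## track window still inherit a value)
bin_values_one_arm <- function(bins, positions = NULL, track = NULL) {
  n <- nrow(bins)
  out <- numeric(n)
  if (!is.null(positions)) {
    for (i in seq_len(n)) {
      out[i] <- sum(positions >= bins$start[i] & positions < bins$end[i])
    }
  } else {
    w <- track$window_size
    ws <- (seq_along(track$values) - 1) * w
    we <- pmin(ws + w, track$chrom_length)
    for (i in seq_len(n)) {
      ov <- pmin(we, bins$end[i]) - pmax(ws, bins$start[i])
      sel <- ov > 0 & !is.na(track$values)
      out[i] <- if (any(sel)) {
        sum(ov[sel] * track$values[sel]) / sum(ov[sel])
      } else NA_real_
    }
  }
  out
}

spline_smooth_profile <- function(raw, spar = NULL) {
  ok <- which(!is.na(raw))
  if (length(ok) < 10) return(raw)
  fit <- if (is.null(spar)) {
    stats::smooth.spline(ok, raw[ok])
  } else {
    stats::smooth.spline(ok, raw[ok], spar = spar)
  }
  stats::predict(fit, x = seq_along(raw))$y
}

tel_cen_profile_obj <- function(mat, fraction, kind, spar) {
  raw <- rowMeans(mat, na.rm = TRUE)
  raw[is.nan(raw)] <- NA_real_
  structure(list(n_bins = length(raw), fraction = fraction, kind = kind,
                 n_arms = ncol(mat), raw = raw,
                 smoothed = spline_smooth_profile(raw, spar)),
            class = "tel_cen_profile")
}

#' @export
print.tel_cen_profile <- function(x, ...) {
  cat(sprintf("<tel_cen_profile> %s: %d bins (fraction %g) over %d arms\n",
              x$kind, x$n_bins, x$fraction, x$n_arms))
  invisible(x)
}

#' Telomere-centromere crossover profile
#'
#' Each arm is oriented telomere-to-centromere and divided into
#' `1/fraction` proportional bins; per-bin crossover counts are divided by
#' the number of F2 individuals, averaged across all arms with equal
#' weight, and smoothed with a cubic smoothing spline
#' (`stats::smooth.spline`, generalized cross-validation by default).
#'
#' @param pop A [crossover_population()].
#' @param annotation A [genome_annotation()] defining the arms.
#' @param fraction Proportion of each arm per bin (default 0.01 = 100 bins).
#' @param spar Optional `smooth.spline` smoothing parameter.
#' @return Object of class `tel_cen_profile` with `raw` and `smoothed`
#'   per-bin values, bin 0 abutting the telomere.
#' @export
tel_cen_profile_crossovers <- function(pop, annotation, fraction = 0.01,
                                       spar = NULL) {
  arms <- arms_from_annotation(annotation)
  mat <- vapply(seq_len(nrow(arms)), function(i) {
    bins <- tel_cen_bins(c(arms$start[i], arms$end[i]), fraction,
                         arms$side[i])
    mids <- pop$intervals$midpoint[pop$intervals$chrom == arms$chrom[i]]
    bin_values_one_arm(bins, positions = mids) / pop$n_individuals
  }, numeric(as.integer(round(1 / fraction))))
  tel_cen_profile_obj(mat, fraction, "CO-per-F2", spar)
}

#' Telomere-centromere profile of a windowed track
#'
#' Window values (assigned by window midpoint) are averaged within
#' proportional telomere-to-centromere bins on each arm, then averaged
#' across arms with equal weight and spline-smoothed.
#'
#' @param tracks Named list of [windowed_track()]s (one per chromosome).
#' @param annotation A [genome_annotation()] defining the arms.
#' @param fraction Proportion of each arm per bin (default 0.005 = 200
#'   bins).
#' @param spar Optional `smooth.spline` smoothing parameter.
#' @return Object of class `tel_cen_profile`.
#' @export
tel_cen_profile_track <- function(tracks, annotation, fraction = 0.005,
                                  spar = NULL) {
  tracks <- as_track_set(tracks)
  arms <- arms_from_annotation(annotation)
  arms <- arms[arms$chrom %in% names(tracks), , drop = FALSE]
  if (nrow(arms) == 0) stop("no arms covered by the supplied tracks")
  mat <- vapply(seq_len(nrow(arms)), function(i) {
    bins <- tel_cen_bins(c(arms$start[i], arms$end[i]), fraction,
                         arms$side[i])
    bin_values_one_arm(bins, track = tracks[[arms$chrom[i]]])
  }, numeric(as.integer(round(1 / fraction))))
  tel_cen_profile_obj(mat, fraction, tracks[[1]]$kind, spar)
}
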