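#' Fluorescence class counts from one FTL scoring experiment
#'
#' Seed mode scores selfed progeny of a hemizygous two-color FTL for the
#' union of colors over the two inherited gametes; pollen mode scores
#' gametes directly by flow cytometry.
#'
#' @param mode `"seed"` or `"pollen"`.
#' @param counts Named nonnegative vector (integers from real scoring;
#'   exact expected counts may be fractional). Seed mode classes:
#'   `both`, `green_only`, `red_only`, `neither`. Pollen mode classes:
#'   `parental_two_color`, `parental_colorless`, `single_color_1`,
#'   `single_color_2`.
#' @return An object of class `fluor_counts` with a `total` field.
#' @export
fluor_counts <- function(mode = c("seed", "pollen"), counts) {
  mode <- match.arg(mode)
  need <- if (mode == "seed") {
    c("both", "green_only", "red_only", "neither")
  } else {
    c("parental_two_color", "parental_colorless",
      "single_color_1", "single_color_2")
  }
  if (!all(need %in% names(counts))) {
    stop("counts must be named: ", paste(need, collapse = ", "))
  }
  counts <- counts[need]
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be nonnegative")
  }
  structure(list(mode = mode, counts = counts, total = sum(counts)),
            class = "fluor_counts")
}

#' @export
print.fluor_counts <- function(x, ...) {
  cat(sprintf("<fluor_counts> %s mode, total %d\n", x$mode, x$total))
  print(x$counts)
  invisible(x)
}

#' Genetic distance from a recombinant fraction
#'
#' @param r Recombinant fraction in `[0, 1)`.
#' @param n_scored Number of seeds or gametes scored.
#' @return Object of class `genetic_distance` with fields `cM` (`= 100 r`),
#'   `r` and `n_scored`.
#' @export
genetic_distance <- function(r, n_scored) {
  stopifnot(r >= 0, r < 1, n_scored > 0)
  structure(list(cM = 100 * r, r = r, n_scored = n_scored),
            class = "genetic_distance")
}

#' @export
print.genetic_distance <- function(x, ...) {
  cat(sprintf("<genetic_distance> %.3f cM (r = %.5f, n = %d)\n",
              x$cM, x$r, as.integer(x$n_scored)))
  invisible(x)
}

#' Expected seed fluorescence class probabilities
#'
#' Forward model for the selfed hemizygous two-color FTL: gametes are
#' `RG` and colorless parentals with probability `(1 - r)/2` each, and `R`
#' and `G` single-color recombinants with probability `r/2` each; the seed
#' phenotype is the union of colors over two independent gametes.
#'
#' @param r Recombinant fraction in `[0, 1)`.
#' @return Named probabilities `both`, `green_only`, `red_only`, `neither`,
#'   summing to 1. `green_only = red_only = (1 - (1 - r)^2)/4`.
#' @examples
#' seed_class_probabilities(0)     # 3:1 both:neither
#' seed_class_probabilities(0.1)[["green_only"]]  # 0.0475
#' @export
seed_class_probabilities <- function(r) {
  if (length(r) != 1 || is.na(r) || r < 0 || r >= 1) {
    stop("r must lie in [0, 1)")
  }
  p_none <- (1 - r) / 2      # colorless parental gamete
  p_g <- r / 2               # green-only gamete
  green_only <- (p_none + p_g)^2 - p_none^2   # >=1 green, no red
  neither <- p_none^2
  c(both = 1 - 2 * green_only - neither,
    green_only = green_only, red_only = green_only, neither = neither)
}

#' Genetic distance from seed fluorescence counts
#'
#' Closed-form inversion of [seed_class_probabilities()]: with
#' `f = (n_green_only + n_red_only)/total`, the estimator is
#' `r = 1 - sqrt(1 - 2 f)` and `cM = 100 r`.
#'
#' @param counts A seed-mode [fluor_counts()].
#' @return A [genetic_distance()].
#' @examples
#' cm_from_seed_counts(fluor_counts("seed",
#'   c(both = 715, green_only = 47, red_only = 48, neither = 190)))
#' @export
cm_from_seed_counts <- function(counts) {
  stopifnot(inherits(counts, "fluor_counts"))
  if (counts$mode != "seed") stop("seed-mode counts required")
  if (counts$total == 0) stop("total count is zero")
  f <- (counts$counts[["green_only"]] + counts$counts[["red_only"]]) /
    counts$total
  if (2 * f >= 1) {
    stop("2(NG + NR)/NT >= 1: estimator undefined (mis-scored input?)")
  }
  genetic_distance(1 - sqrt(1 - 2 * f), counts$total)
}

#' Genetic distance from pollen fluorescence counts
#'
#' Gametes are scored directly: the recombinant fraction is the proportion
#' of single-color pollen.
#'
#' @param counts A pollen-mode [fluor_counts()].
#' @param include_colorless Keep colorless parental pollen in the
#'   denominator (default; flow counting scores all alive pollen). Set
#'   `FALSE` for assays that cannot score colorless grains.
#' @return A [genetic_distance()].
#' @export
cm_from_pollen_counts <- function(counts, include_colorless = TRUE) {
  stopifnot(inherits(counts, "fluor_counts"))
  if (counts$mode != "pollen") stop("pollen-mode counts required")
  n_rec <- counts$counts[["single_color_1"]] + counts$counts[["single_color_2"]]
  denom <- if (include_colorless) counts$total else
    counts$total - counts$counts[["parental_colorless"]]
  if (denom <= 0) stop("no scorable pollen")
  genetic_distance(n_rec / denom, denom)
}

recombinant_parental <- function(counts) {
  k <- counts$counts
  if (counts$mode == "seed") {
    c(recombinant = k[["green_only"]] + k[["red_only"]],
      parental = k[["both"]] + k[["neither"]])
  } else {
    c(recombinant = k[["single_color_1"]] + k[["single_color_2"]],
      parental = k[["parental_two_color"]] + k[["parental_colorless"]])
  }
}

#' Chi-square comparison of crossover frequency between genotypes
#'
#' 2x2 chi-square (df 1, no continuity correction) on pooled
#' recombinant-class versus parental-class counts. With `stratified = TRUE`,
#' `countsA` and `countsB` are lists of per-replicate [fluor_counts()] and a
#' Cochran-Mantel-Haenszel test (no continuity correction) is used instead.
#'
#' @param countsA,countsB [fluor_counts()] of the same mode (or lists of
#'   them when `stratified = TRUE`).
#' @param stratified Stratify by replicate instead of pooling.
#' @return List with `statistic`, `p.value` and the contingency `table`.
#' @examples
#' a <- fluor_counts("pollen", c(parental_two_color = 5, parental_colorless = 5,
#'                               single_color_1 = 5, single_color_2 = 5))
#' b <- fluor_counts("pollen", c(parental_two_color = 35, parental_colorless = 35,
#'                               single_color_1 = 15, single_color_2 = 15))
#' compare_genotypes_chisq(a, b)
#' @export
compare_genotypes_chisq <- function(countsA, countsB, stratified = FALSE) {
  if (stratified) {
    stopifnot(is.list(countsA), is.list(countsB),
              length(countsA) == length(countsB))
    tab <- vapply(seq_along(countsA), function(i) {
      rbind(recombinant_parental(countsA[[i]]),
            recombinant_parental(countsB[[i]]))
    }, matrix(0, 2, 2))
    ht <- stats::mantelhaen.test(tab, correct = FALSE)
    return(list(statistic = unname(ht$statistic), p.value = ht$p.value,
                table = tab))
  }
  tab <- rbind(A = recombinant_parental(countsA),
               B = recombinant_parental(countsB))
  if (any(rowSums(tab) == 0)) stop("a genotype has zero total count")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("expected cell count of zero")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value, table = tab)
}
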