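## Independent oracles and small fixture builders used across the suite.

## Naive per-position Hamming scan of a consensus over both strands of one
## sequence (character scalar). Independent of the Biostrings-based matcher.
naive_hamming_matches <- function(seq_str, cons_str, budget) {
  revcomp_chr <- function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  scan_one <- function(subject, pattern) {
    s <- strsplit(subject, "")[[1]]
    p <- strsplit(pattern, "")[[1]]
    L <- length(p)
    n <- length(s)
    if (n < L) return(data.frame(start = integer(0), mismatches = integer(0)))
    mism <- integer(n - L + 1)
    for (d in seq_len(L)) {
      win <- s[d:(n - L + d)]
      mism <- mism + (win != p[d] | !(win %in% c("A", "C", "G", "T")))
    }
    hit <- which(mism <= budget)
    data.frame(start = hit - 1L, mismatches = mism[hit])  # 0-based
  }
  plus <- scan_one(seq_str, cons_str)
  minus <- scan_one(seq_str, revcomp_chr(cons_str))
  out <- rbind(
    if (nrow(plus)) cbind(plus, strand = "+"),
    if (nrow(minus)) cbind(minus, strand = "-"))
  if (is.null(out)) {
    out <- data.frame(start = integer(0), mismatches = integer(0),
                      strand = character(0))
  }
  out[order(out$start, out$strand), c("start", "strand", "mismatches")]
}

## Chi-square statistics from the definition (sum (O-E)^2 / E).
chisq_gof_hand <- function(observed, probs) {
  expected <- sum(observed) * probs
  stat <- sum((observed - expected)^2 / expected)
  list(statistic = stat, df = length(observed) - 1,
       p.value = stats::pchisq(stat, length(observed) - 1,
                               lower.tail = FALSE))
}

chisq_2x2_hand <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat,
       p.value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Mutate exactly k positions of a sequence (character scalar).
mutate_exactly <- function(seq_str, k) {
  s <- strsplit(seq_str, "")[[1]]
  at <- sample(length(s), k)
  s[at] <- vapply(s[at], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(s, collapse = "")
}

## Toy annotation: one chromosome with given arm / peri / cen / peri / arm
## spans (peri2/arm2 may be 0 to drop the right-hand intervals).
toy_annotation <- function(arm1, peri1, cen, peri2 = peri1, arm2 = arm1,
                           chrom = "chr1") {
  b <- cumsum(c(0, arm1, peri1, cen, peri2, arm2))
  part <- data.frame(
    chrom = chrom,
    start = b[-length(b)], end = b[-1],
    class = c("arm", "pericentromere", "centromere", "pericentromere", "arm"))
  part <- part[part$end > part$start, ]
  gapw <- max(2, floor(cen / 10))
  mid <- (b[3] + b[4]) / 2
  gaps <- data.frame(chrom = chrom, start = floor(mid - gapw / 2),
                     end = floor(mid + gapw / 2))
  genome_annotation(data.frame(name = chrom, length = b[length(b)]),
                    gaps, part)
}

## Small simulation config shared by the synthetic-data tests.
small_cfg <- function(seed, ...) {
  sim_config(seed, chrom_length = 4e5, gap_span = 2e4, cen180_flank = 1e4,
             peri_span = 8e4, ...)
}
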