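test_that("exact and reverse-complement plants are found on the right strand", {
  set.seed(11)
  cons <- as.character(cen180_consensus())
  bg <- rand_dna(5000)
  plant_at <- 2000  # 0-based
  seq_plus <- paste0(substr(bg, 1, plant_at), cons,
                     substr(bg, plant_at + 1, 5000 - nchar(cons)))
  g <- Biostrings::DNAStringSet(c(chrA = seq_plus))
  m <- find_consensus_matches(g, cons, max_mismatch = 0)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, plant_at)
  expect_equal(m$strand, "+")
  expect_equal(m$mismatches, 0L)

  rc <- as.character(Biostrings::reverseComplement(cen180_consensus()))
  seq_minus <- paste0(substr(bg, 1, plant_at), rc,
                      substr(bg, plant_at + 1, 5000 - nchar(cons)))
  m <- find_consensus_matches(Biostrings::DNAStringSet(c(chrA = seq_minus)),
                              cons, max_mismatch = 0)
  expect_equal(m$strand, "-")
  expect_equal(m$start, plant_at)
})

test_that("matches at known mutation loads respect the budget exactly", {
  set.seed(12)
  cons <- as.character(cen180_consensus())
  L <- nchar(cons)
  n_mut <- c(0, 15, 30, 60, 89, 90, 91, 95)
  bg <- rand_dna(100e3)
  gap <- 500
  seqs <- character(0)
  starts <- integer(0)
  pos <- 1000
  for (k in n_mut) {
    starts <- c(starts, pos)
    pos <- pos + L + gap
  }
  s <- strsplit(bg, "")[[1]]
  for (i in seq_along(n_mut)) {
    copy <- mutate_exactly(cons, n_mut[i])
    s[(starts[i] + 1):(starts[i] + L)] <- strsplit(copy, "")[[1]]
  }
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(s, collapse = "")))
  m <- find_consensus_matches(genome, cons, max_mismatch = 90)
  ## every planted copy within budget is reported at its exact position
  within <- starts[n_mut <= 90]
  expect_true(all(within %in% m$start[m$strand == "+"]))
  expect_false(any(starts[n_mut > 90] %in% m$start))
  ## reported mismatch counts equal the planted loads
  got <- m$mismatches[match(within, m$start)]
  expect_equal(got, n_mut[n_mut <= 90])
  ## and the matcher agrees with the naive Hamming oracle in full
  oracle <- naive_hamming_matches(paste(s, collapse = ""), cons, 90)
  expect_equal(m$start, oracle$start)
  expect_equal(m$strand, oracle$strand)
  expect_equal(m$mismatches, oracle$mismatches)
})

test_that("matcher equals the naive Hamming scan on random genomes", {
  set.seed(13)
  cons <- as.character(cen180_consensus())
  for (i in 1:10) {
    n <- sample(2000:30000, 1)
    budget <- sample(c(40, 70, 90, 110, 130), 1)  # includes >50% of length
    s <- strsplit(rand_dna(n), "")[[1]]
    ## plant a few partially mutated copies on both strands
    for (j in 1:3) {
      at <- sample(n - 200, 1)
      copy <- mutate_exactly(cons, sample(0:120, 1))
      if (runif(1) < 0.5) {
        copy <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(copy)))
      }
      s[at:(at + 177)] <- strsplit(copy, "")[[1]]
    }
    seq_str <- paste(s, collapse = "")
    m <- find_consensus_matches(Biostrings::DNAStringSet(c(c1 = seq_str)),
                                cons, budget)
    oracle <- naive_hamming_matches(seq_str, cons, budget)
    expect_equal(m$start, oracle$start)
    expect_equal(m$strand, oracle$strand)
    expect_equal(m$mismatches, oracle$mismatches)
  }
})

test_that("a consensus longer than the chromosome yields no matches", {
  g <- Biostrings::DNAStringSet(c(tiny = "ACGTACGT"))
  m <- find_consensus_matches(g, cen180_consensus(), 90)
  expect_equal(nrow(m), 0)
})

test_that("N bases always count as mismatches", {
  cons <- "ACGTACGTAC"
  seqs <- c(x = paste0("TTTT", "ACGTACGTAC", "TTTT"))
  m <- find_consensus_matches(Biostrings::DNAStringSet(seqs), cons, 0)
  expect_equal(nrow(m), 1)
  seqs_n <- c(x = paste0("TTTT", "ACGTNCGTAC", "TTTT"))
  m0 <- find_consensus_matches(Biostrings::DNAStringSet(seqs_n), cons, 0)
  m1 <- find_consensus_matches(Biostrings::DNAStringSet(seqs_n), cons, 1)
  expect_equal(nrow(m0), 0)
  expect_true(4 %in% m1$start)
  expect_equal(m1$mismatches[m1$start == 4], 1L)
})

test_that("metaprofile averages signal around anchors with orientation", {
  ## constant signal -> flat profile at that constant
  tr <- list(chr1 = windowed_track("chr1", 1e5, 50, rep(2.5, 2000)))
  anchors <- data.frame(chrom = "chr1", midpoint = c(3e4, 5e4, 7e4),
                        strand = "+")
  prof <- metaprofile(tr, anchors, flank = 1e4, bin = 50)
  expect_equal(length(prof$mean_signal), 400)
  expect_true(all(abs(prof$mean_signal - 2.5) < 1e-12))
  expect_equal(prof$n_anchors, 3)

  ## single anchor: profile equals the extracted window
  v <- rnorm(2000)
  tr <- list(chr1 = windowed_track("chr1", 1e5, 50, v))
  one <- data.frame(chrom = "chr1", midpoint = 5e4, strand = "+")
  prof <- metaprofile(tr, one, flank = 1e3, bin = 50)
  expected <- v[(5e4 - 1e3) / 50 + seq_len(40)]
  expect_equal(prof$mean_signal, expected)

  ## minus-strand anchors are orientation-flipped
  rev_prof <- metaprofile(tr, transform(one, strand = "-"),
                          flank = 1e3, bin = 50)
  expect_equal(rev_prof$mean_signal, rev(expected))

  ## out-of-bounds anchors are dropped and counted
  edge <- data.frame(chrom = "chr1", midpoint = c(100, 5e4), strand = "+")
  prof <- metaprofile(tr, edge, flank = 1e3, bin = 50)
  expect_equal(prof$n_anchors, 1)
  expect_equal(prof$n_dropped, 1)
  expect_error(metaprofile(tr, transform(one, midpoint = 10),
                           flank = 1e3, bin = 50), "anchors")
  expect_error(metaprofile(tr, one, flank = 1e3, bin = 7), "%%")
})

test_that("random control positions are seeded, gap-free and length-weighted", {
  ann <- genome_annotation(
    data.frame(name = c("chr1", "chr2"), length = c(3e5, 1e5)),
    data.frame(chrom = c("chr1", "chr2"), start = c(1.4e5, 4e4),
               end = c(1.6e5, 6e4)),
    rbind(data.frame(chrom = "chr1", start = c(0, 1e5, 2e5),
                     end = c(1e5, 2e5, 3e5),
                     class = c("arm", "centromere", "arm")),
          data.frame(chrom = "chr2", start = c(0, 3e4, 7e4),
                     end = c(3e4, 7e4, 1e5),
                     class = c("arm", "centromere", "arm"))))
  a <- random_control_positions(ann, 500, seed = 21)
  b <- random_control_positions(ann, 500, seed = 21)
  expect_identical(a, b)
  expect_false(identical(a, random_control_positions(ann, 500, seed = 22)))
  ## no position inside an assembly gap
  in_gap <- (a$chrom == "chr1" & a$midpoint >= 1.4e5 & a$midpoint < 1.6e5) |
    (a$chrom == "chr2" & a$midpoint >= 4e4 & a$midpoint < 6e4)
  expect_false(any(in_gap))
  ## chromosome usage proportional to mappable length (280 kb vs 80 kb)
  big <- random_control_positions(ann, 1e5, seed = 23)
  obs <- table(factor(big$chrom, levels = c("chr1", "chr2")))
  p <- chisq.test(obs, p = c(2.8e5, 0.8e5) / 3.6e5)$p.value
  expect_gt(p, 0.001)
})

test_that("match counting distinguishes raw from start-deduplicated", {
  df <- data.frame(chrom = c("c1", "c1", "c1"), start = c(5, 5, 9),
                   end = c(15, 15, 19), strand = c("+", "-", "+"),
                   mismatches = c(3L, 4L, 0L))
  ms <- structure(df, class = c("repeat_match_set", "data.frame"))
  expect_equal(n_matches(ms), 3)
  expect_equal(n_matches(ms, dedup = TRUE), 2)
})
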