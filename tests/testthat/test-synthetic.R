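test_that("generators are pure functions of config and seed", {
  cfg <- small_cfg(31)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$planted, g2$planted)
  p1 <- simulate_crossovers(cfg, "wild_type", 50)
  p2 <- simulate_crossovers(cfg, "wild_type", 50)
  expect_identical(p1$intervals, p2$intervals)
  s1 <- simulate_spo11(cfg, "wild_type")
  s2 <- simulate_spo11(cfg, "wild_type")
  expect_identical(s1$rep1$tracks$chr1$values, s2$rep1$tracks$chr1$values)
  ## a different seed changes the draw
  expect_false(identical(
    p1$intervals, simulate_crossovers(small_cfg(32), "wild_type", 50)$intervals))
})

test_that("planted satellite copies round-trip through the matcher", {
  ## zero mutation rate: every copy is an exact match at budget 0
  cfg0 <- small_cfg(33, cen180_mutation_rate = 0)
  gen <- make_genome(cfg0)
  m <- find_consensus_matches(gen$genome, max_mismatch = 0)
  key <- function(df) paste(df$chrom, df$start, df$strand)
  expect_true(all(key(gen$planted) %in% key(m)))
  ## at the default rate, copies within budget are recovered with their loads
  cfg <- small_cfg(34)
  gen <- make_genome(cfg)
  m <- find_consensus_matches(gen$genome, max_mismatch = 90)
  expect_true(all(gen$planted$n_mutations <= 90))  # rate 0.10 stays well under
  hit <- match(key(gen$planted), key(m))
  expect_false(any(is.na(hit)))
  expect_equal(m$mismatches[hit], gen$planted$n_mutations)
  ## the truth record and the gap tile the centromere correctly
  expect_equal(nrow(gen$planted),
               2 * 3 * floor(cfg$cen180_flank / 178))
})

test_that("crossover populations hit their expected mean and structure", {
  cfg <- small_cfg(35)
  pop <- simulate_crossovers(cfg, "wild_type", 437)
  m <- mean_crossovers_per_individual(pop)
  expect_lt(abs(m - 7.6), 3 * sqrt(7.6 / 437))
  ## wild type is crossover-free in the centromere class
  ann <- truth_annotation(cfg)
  counts <- count_by_region(pop, ann)
  expect_equal(unname(counts["centromere"]), 0L)
  ## no midpoint inside the assembly gap in any genotype
  g <- cfg$chrom_length / 2 + c(-1, 1) * cfg$gap_span / 2
  mut <- simulate_crossovers(cfg, "cmt3", 384)
  mids <- mut$intervals$midpoint
  expect_false(any(mids >= g[1] + 500 & mids < g[2] - 500))
  ## pericentromeric share sits near its target
  share <- counts["pericentromere"] / sum(counts)
  expect_lt(abs(share - 0.246), 0.05)
})

test_that("methylation tracks encode genotype and recover the truth", {
  cfg <- small_cfg(36)
  wt <- simulate_methylation(cfg, "wild_type")
  cmt3 <- simulate_methylation(cfg, "cmt3")
  kss <- simulate_methylation(cfg, "kyp_suvh5_suvh6")
  ## CG is drawn from a genotype-independent stream
  expect_identical(wt$CG$chr1$values, cmt3$CG$chr1$values)
  expect_identical(wt$CG$chr1$values, kss$CG$chr1$values)
  ## cmt3 ablates CHG genome-wide; kyp suvh5 suvh6 ablates CHG and CHH
  expect_lt(mean(unlist(lapply(cmt3$CHG, `[[`, "values"))), 0.05)
  expect_gt(mean(unlist(lapply(cmt3$CHH, `[[`, "values"))), 0.03)
  expect_lt(mean(unlist(lapply(kss$CHG, `[[`, "values"))), 0.05)
  expect_lt(mean(unlist(lapply(kss$CHH, `[[`, "values"))), 0.05)
  ## wild-type pericentromere methylation recovers the true boundaries
  pop <- simulate_crossovers(cfg, "wild_type", 437)
  chroms <- data.frame(name = paste0("chr", 1:3), length = cfg$chrom_length)
  g <- cfg$chrom_length / 2 + c(-1, 1) * cfg$gap_span / 2
  gaps <- data.frame(chrom = chroms$name, start = g[1], end = g[2])
  mids <- split(pop$intervals$midpoint, pop$intervals$chrom)
  mbc <- lapply(setNames(chroms$name, chroms$name),
                function(cn) lapply(wt, function(ts) ts[[cn]]))
  ann <- build_partition(chroms, gaps, mids, mbc,
                         scan_window = cfg$window_size)
  truth <- true_regions(cfg)
  w <- cfg$window_size
  for (cn in chroms$name) {
    est <- ann$partition[ann$partition$chrom == cn &
                           ann$partition$class == "pericentromere", ]
    tru <- truth[truth$chrom == cn & truth$class == "pericentromere", ]
    expect_equal(nrow(est), 2)
    expect_lt(max(abs(sort(est$start) - sort(tru$start))), 2 * w + 1)
    expect_lt(max(abs(sort(est$end) - sort(tru$end))), 2 * w + 1)
  }
})

test_that("SPO11 libraries carry the planted enrichment and replicate noise", {
  cfg <- small_cfg(37)
  wt <- simulate_spo11(cfg, "wild_type")
  mut <- simulate_spo11(cfg, "kyp_suvh5_suvh6")
  ## distinct library sizes by construction
  expect_false(wt$rep1$library_size == wt$rep2$library_size)
  ## replicates agree strongly at the native window scale
  r <- replicate_correlation(normalize_library(wt$rep1),
                             normalize_library(wt$rep2),
                             scales = cfg$window_size)
  expect_gt(unname(r), 0.9)
  ## the full chain: normalize -> log2 -> z -> differential
  chain <- function(libs) {
    zscore(log2_ratio(normalize_library(libs$rep1),
                      normalize_library(libs$gdna)))
  }
  dz <- signal_differential(chain(mut), chain(wt))
  truth <- true_regions(cfg)
  r1 <- truth[truth$chrom == "chr1", ]
  w <- cfg$window_size
  nw <- length(dz$chr1$values)
  wmid <- (seq_len(nw) - 1) * w + w / 2
  cls <- r1$class[findInterval(wmid, r1$start)]
  delta <- unlist(lapply(dz, `[[`, "values"))
  cls <- rep(cls, length(dz))
  expect_gt(mean(delta[cls == "centromere"], na.rm = TRUE),
            mean(delta[cls == "arm"], na.rm = TRUE))
  ## enrichment factor 1 leaves the differential centered on zero
  cfg_null <- small_cfg(37, spo11_enrichment = c(centromere = 1,
                                                 pericentromere = 1))
  wt0 <- simulate_spo11(cfg_null, "wild_type")
  mut0 <- simulate_spo11(cfg_null, "kyp_suvh5_suvh6")
  dz0 <- signal_differential(chain(mut0), chain(wt0))
  d0 <- unlist(lapply(dz0, `[[`, "values"))
  expect_lt(abs(mean(d0, na.rm = TRUE)), 0.1)
})

test_that("FTL count draws respect the forward model", {
  cts <- simulate_fluor_counts(0, 1000, "seed", seed = 38)
  expect_equal(cts$counts[["green_only"]] + cts$counts[["red_only"]], 0)
  expect_equal(cts$total, 1000)
  cts <- simulate_fluor_counts(0, 500, "pollen", seed = 38)
  expect_equal(cts$counts[["single_color_1"]] +
                 cts$counts[["single_color_2"]], 0)
  ## estimator round trip at r = 0.1
  cts <- simulate_fluor_counts(0.1, 1e6, "seed", seed = 39)
  expect_lt(abs(cm_from_seed_counts(cts)$cM - 10), 0.2)
})
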