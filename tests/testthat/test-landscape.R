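mk_pop <- function(mids, n_ind, chrom = "chr1", genotype = "wild_type") {
  iv <- data.frame(individual = rep("ind0001", length(mids)), chrom = chrom,
                   start = mids, end = mids + 1)
  crossover_population(genotype, sprintf("ind%04d", seq_len(n_ind)), iv)
}

test_that("count_by_region assigns midpoints to half-open intervals", {
  ann <- toy_annotation(50e3, 30e3, 20e3, 0, 0)  # arm[0,50k) peri[50k,80k) cen[80k,100k)
  pop <- mk_pop(c(10e3, 60e3, 60e3, 90e3, 49999), 5)
  counts <- count_by_region(pop, ann)
  expect_equal(unname(counts), c(2L, 2L, 1L))
  expect_equal(sum(counts), nrow(pop$intervals))
  ## boundary midpoint belongs to the start-inclusive right-hand interval
  expect_equal(unname(count_by_region(mk_pop(50e3, 1), ann)),
               c(0L, 1L, 0L))
  ## incomplete partition is an error
  pop_out <- mk_pop(10e3, 1, chrom = "chr9")
  expect_error(count_by_region(pop_out, ann), "partition")
})

test_that("region chi-square vs physical expectation matches the definition", {
  ann <- toy_annotation(50e3, 30e3, 20e3, 0, 0)  # length shares 0.5/0.3/0.2
  obs <- c(arm = 50, pericentromere = 30, centromere = 20)
  res <- region_chisq_vs_random(obs, ann)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  obs <- c(arm = 60, pericentromere = 40, centromere = 0)
  res <- region_chisq_vs_random(obs, ann)
  expect_equal(res$statistic, 25.33333, tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$p.value, 3.1545e-6, tolerance = 1e-4)

  ## statistic grows monotonically as counts pile into a small class
  stats <- vapply(c(5, 10, 20), function(n) {
    region_chisq_vs_random(c(arm = 0, pericentromere = 0, centromere = n),
                           ann)$statistic
  }, numeric(1))
  expect_true(all(diff(stats) > 0))
})

test_that("region chi-square agrees with hand computation on random inputs", {
  set.seed(202)
  for (i in 1:100) {
    spans <- sample(1e4:1e5, 3)
    ann <- toy_annotation(spans[1], spans[2], spans[3], 0, 0)
    obs <- c(arm = sample(0:200, 1), pericentromere = sample(0:200, 1),
             centromere = sample(1:200, 1))
    res <- region_chisq_vs_random(obs, ann)
    hand <- chisq_gof_hand(obs, spans / sum(spans))
    expect_equal(res$statistic, hand$statistic, tolerance = 1e-10)
    expect_equal(res$p.value, hand$p.value, tolerance = 1e-10)
  }
})

test_that("genotype region chi-square reproduces the 2x2 computation", {
  a <- c(arm = 2203, pericentromere = 817, centromere = 300)
  b <- c(arm = 1874, pericentromere = 779, centromere = 150)
  res <- genotype_region_chisq(a, b)
  hand <- chisq_2x2_hand(rbind(c(817, 2503), c(779, 2024)))
  expect_equal(res$statistic, hand$statistic)
  expect_equal(res$p.value, hand$p.value)
  ## frozen from the reconstructed wild-type/cmt3 pericentromere table
  expect_equal(res$statistic, 7.991252, tolerance = 1e-6)
  expect_equal(res$p.value, 4.700389e-3, tolerance = 1e-6)
  ## swapping genotype rows changes nothing
  res_swap <- genotype_region_chisq(b, a)
  expect_equal(res_swap$statistic, res$statistic)
  ## equal proportions give a null result
  res0 <- genotype_region_chisq(c(arm = 100, pericentromere = 50,
                                  centromere = 10),
                                c(arm = 200, pericentromere = 100,
                                  centromere = 20))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  ## 3-class homogeneity alternative has df = 2
  expect_equal(genotype_region_chisq(a, b, method = "homogeneity")$df, 2)
})

test_that("mean crossovers per individual keeps zero-crossover individuals", {
  pop <- mk_pop(c(1e3, 2e3, 3e3), 4)
  expect_equal(mean_crossovers_per_individual(pop), 0.75)
  counts <- per_individual_counts(pop)
  expect_equal(length(counts), 4)
  expect_equal(unname(counts), c(3L, 0L, 0L, 0L))
  empty <- crossover_population("wild_type", "ind0001",
                                data.frame(individual = character(0),
                                           chrom = character(0),
                                           start = numeric(0),
                                           end = numeric(0)))
  expect_equal(mean_crossovers_per_individual(empty), 0)
})

test_that("Mann-Whitney comparison handles exact and tied cases", {
  res <- compare_counts_mannwhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p.value, 0.1)  # exact: 2/choose(6,3)*... enumerated
  ## identical samples: no shift
  res <- compare_counts_mannwhitney(c(5, 7, 7, 9), c(5, 7, 7, 9))
  expect_equal(res$p.value, 1)
  ## shift invariance
  a <- c(3, 9, 4, 8, 1)
  b <- c(2, 7, 7, 5, 6)
  expect_equal(compare_counts_mannwhitney(a + 10, b + 10)$p.value,
               compare_counts_mannwhitney(a, b)$p.value)
})

test_that("crossover landscape tallies windows and divides by population size", {
  chroms <- data.frame(name = "chr1", length = 1e5)
  pop <- mk_pop(c(5e3, 15e3), 2)
  land <- crossover_landscape(pop, chroms, 1e4, smooth_k = 1)
  expect_equal(land$chr1$raw$values, c(0.5, 0.5, rep(0, 8)))
  ## doubling the population halves the normalized values
  pop4 <- mk_pop(c(5e3, 15e3), 4)
  land4 <- crossover_landscape(pop4, chroms, 1e4, smooth_k = 1)
  expect_equal(land4$chr1$raw$values, land$chr1$raw$values / 2)
  ## an empty population gives an all-zero track
  empty <- crossover_population("wild_type", "ind0001",
                                data.frame(individual = character(0),
                                           chrom = character(0),
                                           start = numeric(0),
                                           end = numeric(0)))
  expect_equal(crossover_landscape(empty, chroms, 1e4)$chr1$raw$values,
               rep(0, 10))
})

test_that("landscape differential subtracts wild type from mutant", {
  mk <- function(v) windowed_track("chr1", length(v) * 1e4, 1e4, v)
  expect_equal(landscape_differential(mk(c(1, 2)), mk(c(0.5, 3)))$values,
               c(0.5, -1))
  a <- mk(c(0.4, NA, 1.2))
  b <- mk(c(0.1, 0.2, 0.5))
  expect_equal(landscape_differential(a, a)$values, c(0, NA, 0))
  ## antisymmetry
  expect_equal(landscape_differential(a, b)$values,
               -landscape_differential(b, a)$values)
  expect_error(landscape_differential(mk(c(1, 2)), mk(c(1, 2, 3))), "differ")
})

test_that("telomere-centromere crossover profile bins proportionally", {
  ann <- toy_annotation(100e3, 30e3, 40e3)  # symmetric 300-kb chromosome
  ## one crossover at the center of every 1% bin of each arm -> flat profile
  arms <- arms_from_annotation(ann)
  mids <- unlist(lapply(seq_len(nrow(arms)), function(i) {
    b <- tel_cen_bins(c(arms$start[i], arms$end[i]), 0.01, arms$side[i])
    floor((b$start + b$end) / 2)
  }))
  pop <- mk_pop(mids, 10)
  prof <- tel_cen_profile_crossovers(pop, ann, 0.01)
  expect_equal(prof$n_bins, 100)
  expect_equal(prof$raw, rep(0.1, 100))

  ## crossovers only in the telomere-proximal 10% of each arm
  mids <- c(seq(1e3, 9e3, by = 1e3),                 # left arm telomere end
            seq(291e3, 299e3, by = 1e3))             # right arm telomere end
  prof <- tel_cen_profile_crossovers(mk_pop(mids, 10), ann, 0.01)
  expect_true(all(prof$raw[1:10] > 0))
  expect_true(all(prof$raw[11:100] == 0))
})

test_that("telomere-centromere track profile uses 0.5% bins by default", {
  ann <- toy_annotation(100e3, 30e3, 40e3)
  set.seed(77)
  v <- runif(30, 0.2, 0.8)
  tr <- list(chr1 = windowed_track("chr1", 300e3, 1e4, v, "CHG"))
  prof <- tel_cen_profile_track(tr, ann, 0.005)
  expect_equal(prof$n_bins, 200)
  expect_equal(prof$kind, "CHG")
  expect_true(all(is.finite(prof$raw)))   # overlap weighting fills every bin
  ## a constant track yields a constant profile
  trc <- list(chr1 = windowed_track("chr1", 300e3, 1e4, rep(0.4, 30), "CHG"))
  prof <- tel_cen_profile_track(trc, ann, 0.01)
  expect_true(all(abs(prof$raw - 0.4) < 1e-12))
  ## windows fully inside one bin reproduce their window value: use a fine
  ## track whose windows nest in the 1%-of-arm bins
  vf <- rep(seq(0.1, 0.5, length.out = 100), each = 3)
  fine <- list(chr1 = windowed_track("chr1", 300e3, 1e3, vf, "CHG"))
  pf <- tel_cen_profile_track(fine, ann, 0.01)
  expect_equal(pf$raw[1], mean(c(vf[1], vf[300])), tolerance = 1e-12)
})
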