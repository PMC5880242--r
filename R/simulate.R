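#' Simulation configuration for the toy study system
#'
#' Defines a multi-chromosome toy genome — a central assembly gap flanked by
#' a CEN180-like tandem satellite array inside the centromere, a
#' methylation-dense pericentromere, and euchromatic arms — together with
#' the generating parameters for crossover populations, methylation tracks,
#' SPO11/gDNA coverage and FTL counts. Defaults emulate the study system at
#' reduced scale: wild-type populations average 7.6 crossovers per F2
#' individual with a 24.6% pericentromeric share and a crossover-free
#' centromere; the *cmt3*-like mutant averages 7.3 with a 27.8%
#' pericentromeric share and a small centromeric share (13/2803); *cmt3*
#' ablates CHG methylation and the *kyp suvh5 suvh6*-like triple mutant
#' ablates CHG and CHH, with CG unchanged; the mutant SPO11 landscape is
#' enriched 3x in the centromere and 1.8x in the pericentromere.
#'
#' @param seed Integer seed; mandatory, every generator is a pure function
#'   of (config, seed).
#' @param n_chromosomes,chrom_length Genome shape (default 3 x 2 Mb).
#' @param window_size Track window width in bp (default 10 kb).
#' @param gap_span Central assembly-gap span in bp.
#' @param cen180_flank CEN180 array span flanking the gap on each side
#'   (centromere = gap + both flanks).
#' @param peri_span Pericentromere span on each side of the centromere.
#' @param cen180_mutation_rate Per-base substitution probability per
#'   planted satellite copy.
#' @param co_interval_width Width of the reported crossover uncertainty
#'   interval (bp), emulating SNP-bounded resolution.
#' @param e_crossovers Expected crossovers per F2 individual, per genotype.
#' @param peri_share,cen_share Expected proportion of crossovers in the
#'   pericentromere / centromere classes, per genotype.
#' @param meth_means Nested list genotype -> context -> per-class mean
#'   methylation (see defaults in the source).
#' @param beta_concentration Beta noise concentration for methylation.
#' @param spo11_region_intensity Relative wild-type DSB intensity per
#'   region class.
#' @param spo11_enrichment Mutant multiplier on centromere / pericentromere
#'   SPO11 intensity.
#' @param spo11_window_shape Gamma shape of the shared per-window intensity
#'   noise (mean 1).
#' @param spo11_depth Mean reads per window for the two SPO11 replicates
#'   and the gDNA control.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 3,
                       chrom_length = 2e6,
                       window_size = 1e4,
                       gap_span = 6e4,
                       cen180_flank = 7e4,
                       peri_span = 3e5,
                       cen180_mutation_rate = 0.10,
                       co_interval_width = 1000,
                       e_crossovers = c(wild_type = 7.6, cmt3 = 7.3,
                                        kyp_suvh5_suvh6 = 7.6),
                       peri_share = c(wild_type = 0.246, cmt3 = 0.278,
                                      kyp_suvh5_suvh6 = 0.278),
                       cen_share = c(wild_type = 0, cmt3 = 13 / 2803,
                                     kyp_suvh5_suvh6 = 13 / 2803),
                       meth_means = NULL,
                       beta_concentration = 20,
                       spo11_region_intensity = c(arm = 1.2,
                                                  pericentromere = 0.7,
                                                  centromere = 0.35),
                       spo11_enrichment = c(centromere = 3,
                                            pericentromere = 1.8),
                       spo11_window_shape = 4,
                       spo11_depth = c(rep1 = 150, rep2 = 220, gdna = 180)) {
  if (missing(seed)) stop("seed is mandatory")
  cen_span <- gap_span + 2 * cen180_flank
  if (cen_span + 2 * peri_span >= chrom_length) {
    stop("centromere + pericentromere spans exceed the chromosome length")
  }
  if (is.null(meth_means)) {
    wt <- list(CG = c(arm = 0.15, pericentromere = 0.75, centromere = 0.85),
               CHG = c(arm = 0.05, pericentromere = 0.45, centromere = 0.55),
               CHH = c(arm = 0.03, pericentromere = 0.12, centromere = 0.15))
    cmt3 <- wt
    cmt3$CHG[] <- 0.015
    kss <- wt
    kss$CHG[] <- 0.01
    kss$CHH[] <- 0.01
    meth_means <- list(wild_type = wt, cmt3 = cmt3, kyp_suvh5_suvh6 = kss)
  }
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 chrom_length = chrom_length, window_size = window_size,
                 gap_span = gap_span, cen180_flank = cen180_flank,
                 peri_span = peri_span,
                 cen180_mutation_rate = cen180_mutation_rate,
                 co_interval_width = co_interval_width,
                 e_crossovers = e_crossovers, peri_share = peri_share,
                 cen_share = cen_share, meth_means = meth_means,
                 beta_concentration = beta_concentration,
                 spo11_region_intensity = spo11_region_intensity,
                 spo11_enrichment = spo11_enrichment,
                 spo11_window_shape = spo11_window_shape,
                 spo11_depth = spo11_depth),
            class = "sim_config")
}

sim_chrom_names <- function(config) paste0("chr", seq_len(config$n_chromosomes))

sim_chromosomes <- function(config) {
  data.frame(name = sim_chrom_names(config), length = config$chrom_length)
}

sim_gap <- function(config) {
  c(config$chrom_length / 2 - config$gap_span / 2,
    config$chrom_length / 2 + config$gap_span / 2)
}

#' True region boundaries of the simulated genome
#'
#' @param config A [sim_config()].
#' @return data.frame with columns `chrom`, `start`, `end`, `class` — the
#'   generating (truth) partition, identical on every chromosome.
#' @export
true_regions <- function(config) {
  g <- sim_gap(config)
  cen <- c(g[1] - config$cen180_flank, g[2] + config$cen180_flank)
  peri_l <- c(cen[1] - config$peri_span, cen[1])
  peri_r <- c(cen[2], cen[2] + config$peri_span)
  L <- config$chrom_length
  do.call(rbind, lapply(sim_chrom_names(config), function(cn) {
    data.frame(chrom = cn,
               start = c(0, peri_l[1], cen[1], peri_r[1], peri_r[2]),
               end = c(peri_l[1], peri_l[2], cen[2], peri_r[2], L),
               class = c("arm", "pericentromere", "centromere",
                         "pericentromere", "arm"))
  }))
}

#' Truth genome annotation of the simulated genome
#'
#' @param config A [sim_config()].
#' @return A [genome_annotation()] built from [true_regions()].
#' @export
truth_annotation <- function(config) {
  g <- sim_gap(config)
  gaps <- data.frame(chrom = sim_chrom_names(config), start = g[1],
                     end = g[2])
  genome_annotation(sim_chromosomes(config), gaps, true_regions(config))
}

genotype_offset <- function(genotype) sum(utf8ToInt(genotype)) %% 10000L

#' Simulate a toy genome with planted satellite arrays
#'
#' Random arm/pericentromere sequence, a central run of `N` as the assembly
#' gap, and tandem arrays of independently mutated consensus copies
#' (random strand per copy) filling the centromeric flanks.
#'
#' @param config A [sim_config()].
#' @param consensus Satellite unit sequence (default [cen180_consensus()]).
#' @return List with `genome` (`DNAStringSet`), `annotation` (truth
#'   [genome_annotation()]), `planted` (data.frame `chrom`, `start`,
#'   `strand`, `n_mutations` — the truth record) and `config`.
#' @export
make_genome <- function(config, consensus = cen180_consensus()) {
  stopifnot(inherits(config, "sim_config"))
  cons <- strsplit(as.character(consensus), "")[[1]]
  L <- length(cons)
  rc <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste(cons, collapse = "")))), "")[[1]]
  bases <- c("A", "C", "G", "T")
  g <- sim_gap(config)
  with_seed(config$seed + 1L, {
    seqs <- character(config$n_chromosomes)
    planted <- list()
    for (k in seq_len(config$n_chromosomes)) {
      cn <- sim_chrom_names(config)[k]
      s <- sample(bases, config$chrom_length, replace = TRUE)
      s[(g[1] + 1):g[2]] <- "N"
      n_copies <- floor(config$cen180_flank / L)
      for (side in c(-1, 1)) {
        array_start <- if (side < 0) g[1] - n_copies * L else g[2]
        for (j in seq_len(n_copies)) {
          st <- array_start + (j - 1) * L          # 0-based copy start
          strand <- sample(c("+", "-"), 1)
          copy <- if (strand == "+") cons else rc
          n_mut <- rbinom(1, L, config$cen180_mutation_rate)
          if (n_mut > 0) {
            at <- sample.int(L, n_mut)
            copy[at] <- vapply(copy[at], function(b) {
              sample(setdiff(bases, b), 1)
            }, "")
          }
          s[(st + 1):(st + L)] <- copy
          planted[[length(planted) + 1L]] <- data.frame(
            chrom = cn, start = st, strand = strand, n_mutations = n_mut)
        }
      }
      seqs[k] <- paste(s, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(setNames(seqs, sim_chrom_names(config)))
    planted <- do.call(rbind, planted)
    planted <- planted[order(planted$chrom, planted$start), ]
    rownames(planted) <- NULL
    list(genome = genome, annotation = truth_annotation(config),
         planted = planted, config = config)
  })
}

## per-interval sampling regions with per-individual crossover rates;
## centromere intervals exclude the assembly gap
co_sampling_regions <- function(config, genotype) {
  regions <- true_regions(config)
  g <- sim_gap(config)
  cen <- regions[regions$class == "centromere", ][1, ]
  rows <- regions[regions$class != "centromere", ]
  for (cn in sim_chrom_names(config)) {
    rows <- rbind(rows,
                  data.frame(chrom = cn, start = cen$start, end = g[1],
                             class = "centromere"),
                  data.frame(chrom = cn, start = g[2], end = cen$end,
                             class = "centromere"))
  }
  class_len <- tapply(rows$end - rows$start, rows$class, sum)
  shares <- c(arm = 1 - config$peri_share[[genotype]] -
                config$cen_share[[genotype]],
              pericentromere = config$peri_share[[genotype]],
              centromere = config$cen_share[[genotype]])
  e_total <- config$e_crossovers[[genotype]]
  rows$lambda <- e_total * shares[rows$class] *
    (rows$end - rows$start) / class_len[rows$class]
  rows
}

#' Simulate a crossover population
#'
#' Per-individual crossover counts are Poisson with a region-structured
#' intensity (no interference); positions are uniform within regions,
#' weighted by intensity, and the assembly gap never receives events. Each
#' event is reported as an uncertainty interval of `co_interval_width` bp
#' around the true point.
#'
#' @param config A [sim_config()].
#' @param genotype `"wild_type"`, `"cmt3"` or `"kyp_suvh5_suvh6"`.
#' @param n_individuals Number of F2 individuals.
#' @param seed Optional override seed (default derives from the config seed
#'   and the genotype).
#' @return A [crossover_population()].
#' @export
simulate_crossovers <- function(config, genotype = "wild_type",
                                n_individuals = 437, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), n_individuals >= 1)
  regions <- co_sampling_regions(config, genotype)
  ids <- sprintf("ind%04d", seq_len(n_individuals))
  hw <- config$co_interval_width / 2
  L <- config$chrom_length
  with_seed(seed %||% (config$seed + 2L + genotype_offset(genotype)), {
    rows <- lapply(seq_len(nrow(regions)), function(i) {
      nco <- rpois(1, n_individuals * regions$lambda[i])
      if (nco == 0) return(NULL)
      pos <- floor(runif(nco, regions$start[i], regions$end[i]))
      start <- pmax(0, pos - hw)
      data.frame(individual = ids[sample.int(n_individuals, nco,
                                             replace = TRUE)],
                 chrom = regions$chrom[i], start = start,
                 end = pmin(L, start + config$co_interval_width))
    })
    rows <- do.call(rbind, Filter(Negate(is.null), rows))
    if (is.null(rows)) {
      rows <- data.frame(individual = character(0), chrom = character(0),
                         start = numeric(0), end = numeric(0))
    }
    crossover_population(genotype, ids, rows)
  })
}

#' Simulate per-context methylation tracks
#'
#' Beta-distributed window values around region/context/genotype means
#' (concentration `beta_concentration`). The CG track is drawn from a
#' genotype-independent stream, so it is identical across genotypes at the
#' same seed; *cmt3* ablates CHG and *kyp suvh5 suvh6* ablates CHG and CHH.
#'
#' @param config A [sim_config()].
#' @param genotype Genotype label (a name of `config$meth_means`).
#' @param seed Optional override base seed (default: config seed).
#' @return Named list `CG`, `CHG`, `CHH`; each a named track set (one
#'   [windowed_track()] per chromosome).
#' @export
simulate_methylation <- function(config, genotype = "wild_type",
                                 seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  means <- config$meth_means[[genotype]]
  if (is.null(means)) stop("unknown genotype: ", genotype)
  base <- seed %||% config$seed
  regions <- true_regions(config)
  w <- config$window_size
  nw <- n_windows(config$chrom_length, w)
  wmid <- (seq_len(nw) - 1) * w + w / 2
  r1 <- regions[regions$chrom == sim_chrom_names(config)[1], ]
  cls <- r1$class[findInterval(wmid, r1$start)]
  conc <- config$beta_concentration
  draw_context <- function(ctx) {
    m <- means[[ctx]][cls]
    lapply(setNames(sim_chrom_names(config), sim_chrom_names(config)),
           function(cn) {
             v <- rbeta(nw, m * conc, (1 - m) * conc)
             windowed_track(cn, config$chrom_length, w, v, ctx)
           })
  }
  out <- list()
  out$CG <- with_seed(base + 3L, draw_context("CG"))
  out[c("CHG", "CHH")] <- with_seed(
    base + 4L + genotype_offset(genotype),
    list(draw_context("CHG"), draw_context("CHH")))
  out
}

## shared per-window relative DSB intensity (genotype-independent stream)
spo11_window_intensity <- function(config) {
  regions <- true_regions(config)
  g <- sim_gap(config)
  w <- config$window_size
  nw <- n_windows(config$chrom_length, w)
  wmid <- (seq_len(nw) - 1) * w + w / 2
  r1 <- regions[regions$chrom == sim_chrom_names(config)[1], ]
  cls <- r1$class[findInterval(wmid, r1$start)]
  base <- config$spo11_region_intensity[cls]
  in_gap <- wmid >= g[1] & wmid < g[2]
  with_seed(config$seed + 5L, {
    lapply(setNames(sim_chrom_names(config), sim_chrom_names(config)),
           function(cn) {
             shape <- config$spo11_window_shape
             int <- base * stats::rgamma(nw, shape = shape, rate = shape)
             int[in_gap] <- 0          # unmappable N run
             list(intensity = int, class = cls)
           })
  })
}

#' Simulate SPO11-1-oligo replicate libraries and a gDNA control
#'
#' Per-window Poisson read counts around a region-structured intensity
#' with shared (seeded) window-level gamma noise; replicates share the
#' underlying intensity and differ only in depth and Poisson noise; mutant
#' genotypes multiply centromere and pericentromere intensity by the
#' configured enrichment factors. The gDNA control is flat apart from its
#' own mappability noise and is genotype-independent. Assembly-gap windows
#' receive zero coverage in all libraries.
#'
#' @param config A [sim_config()].
#' @param genotype `"wild_type"` or a mutant label (any non-wild-type
#'   genotype gets the enrichment factors).
#' @param seed Optional override seed for the read noise.
#' @return List of [coverage_library()]s: `rep1`, `rep2`, `gdna`.
#' @export
simulate_spo11 <- function(config, genotype = "wild_type", seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  shared <- spo11_window_intensity(config)
  w <- config$window_size
  mk_lib <- function(label, depth, intensity_of) {
    tracks <- lapply(names(shared), function(cn) {
      windowed_track(cn, config$chrom_length, w,
                     rpois(length(shared[[cn]]$intensity),
                           depth * intensity_of(shared[[cn]])),
                     "coverage")
    })
    coverage_library(label, setNames(tracks, names(shared)))
  }
  spo11_int <- function(sh) {
    int <- sh$intensity
    if (genotype != "wild_type") {
      for (cls in names(config$spo11_enrichment)) {
        int[sh$class == cls] <- int[sh$class == cls] *
          config$spo11_enrichment[[cls]]
      }
    }
    int
  }
  base <- seed %||% (config$seed + 6L + genotype_offset(genotype))
  out <- list()
  out$rep1 <- with_seed(base + 1L, mk_lib(paste0(genotype, "_rep1"),
                                          config$spo11_depth[["rep1"]],
                                          spo11_int))
  out$rep2 <- with_seed(base + 2L, mk_lib(paste0(genotype, "_rep2"),
                                          config$spo11_depth[["rep2"]],
                                          spo11_int))
  ## gDNA: genotype-independent stream, flat mean with mild mappability
  ## noise; gap windows (the only windows with zero shared intensity) stay 0
  out$gdna <- with_seed(config$seed + 7L, {
    mk_lib("gdna", config$spo11_depth[["gdna"]], function(sh) {
      g <- stats::rgamma(length(sh$intensity), shape = 30, rate = 30)
      g[sh$intensity == 0] <- 0
      g
    })
  })
  out
}

#' Simulate FTL fluorescence class counts
#'
#' A multinomial draw from the forward model: seed mode uses
#' [seed_class_probabilities()]; pollen mode uses the four gamete
#' probabilities directly (`(1-r)/2` each parental, `r/2` each
#' single-color).
#'
#' @param r True recombinant fraction in `[0, 1)`.
#' @param total Number of seeds or gametes scored.
#' @param mode `"seed"` or `"pollen"`.
#' @param seed Optional seed.
#' @return A [fluor_counts()].
#' @export
simulate_fluor_counts <- function(r, total, mode = c("seed", "pollen"),
                                  seed = NULL) {
  mode <- match.arg(mode)
  if (length(r) != 1 || is.na(r) || r < 0 || r >= 1) {
    stop("r must lie in [0, 1)")
  }
  stopifnot(total >= 1)
  p <- if (mode == "seed") {
    seed_class_probabilities(r)
  } else {
    c(parental_two_color = (1 - r) / 2, parental_colorless = (1 - r) / 2,
      single_color_1 = r / 2, single_color_2 = r / 2)
  }
  k <- with_seed(seed, as.vector(rmultinom(1, total, p)))
  fluor_counts(mode, setNames(k, names(p)))
}
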