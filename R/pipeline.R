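#' Pipeline parameters
#'
#' Defaults reproduce the standard analysis settings: 10-kb windows, 9-window
#' rolling mean, telomere-centromere fractions of 1% (crossovers) and 0.5%
#' (methylation), pseudocount 1 read-per-million, genome-wide z-scoring,
#' satellite mismatch budget 90, and +/-10-kb metaprofile windows.
#'
#' @param window_size Track window width in bp.
#' @param smooth_k Rolling-mean span in windows (odd).
#' @param telcen_fraction_co,telcen_fraction_meth Proportional bin fractions.
#' @param pseudocount log2-ratio pseudocount (in reads per `scale`).
#' @param scale Library-size normalization scale.
#' @param max_mismatch Satellite mismatch budget.
#' @param flank,bin Metaprofile half-window and bin width in bp.
#' @param context_mode Methylation context for the pericentromere rule.
#' @param seed Seed for the random control positions.
#' @return A named list of class `pipeline_params`.
#' @export
pipeline_params <- function(window_size = 10000, smooth_k = 9,
                            telcen_fraction_co = 0.01,
                            telcen_fraction_meth = 0.005,
                            pseudocount = 1, scale = 1e6,
                            max_mismatch = 90, flank = 10000, bin = 50,
                            context_mode = "mean", seed = 17) {
  structure(list(window_size = window_size, smooth_k = smooth_k,
                 telcen_fraction_co = telcen_fraction_co,
                 telcen_fraction_meth = telcen_fraction_meth,
                 pseudocount = pseudocount, scale = scale,
                 max_mismatch = max_mismatch, flank = flank, bin = bin,
                 context_mode = context_mode, seed = seed),
            class = "pipeline_params")
}

#' Write a full synthetic dataset to a directory
#'
#' Emits every input the analysis pipeline reads — genome FASTA, chromosome
#' sizes, assembly-gap BED, true-region BED, crossover TSVs for wild type
#' and mutant, per-context methylation bedGraphs per genotype, SPO11
#' replicate and gDNA coverage bedGraphs with a library-size table — plus
#' `truth.json` recording the generating parameters.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param n_wt,n_mut Population sizes for the wild-type and *cmt3*-like
#'   crossover populations.
#' @return The directory path, invisibly; see `truth.json` for the truth
#'   record.
#' @export
simulate_to_dir <- function(config, dir, n_wt = 437, n_mut = 384) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  chroms <- sim_chromosomes(config)

  gen <- make_genome(config)
  Biostrings::writeXStringSet(gen$genome, p("genome.fa"))
  write_chrom_sizes(chroms, p("chrom.sizes"))
  g <- sim_gap(config)
  gaps_df <- data.frame(chrom = chroms$name, start = g[1], end = g[2])
  rtracklayer::export(df_to_granges(gaps_df), p("gaps.bed"), format = "BED")
  write_partition_bed(gen$annotation, p("regions_true.bed"))

  pops <- list(wild_type = simulate_crossovers(config, "wild_type", n_wt),
               cmt3 = simulate_crossovers(config, "cmt3", n_mut))
  for (gt in names(pops)) {
    write_crossovers(pops[[gt]], p(paste0("crossovers_", gt, ".tsv")))
    writeLines(pops[[gt]]$individuals,
               p(paste0("individuals_", gt, ".txt")))
  }

  for (gt in c("wild_type", "cmt3", "kyp_suvh5_suvh6")) {
    meth <- simulate_methylation(config, gt)
    for (ctx in names(meth)) {
      write_bedgraph(meth[[ctx]],
                     p(sprintf("meth_%s_%s.bedgraph", gt, ctx)))
    }
  }

  libsizes <- list()
  for (gt in c("wild_type", "kyp_suvh5_suvh6")) {
    libs <- simulate_spo11(config, gt)
    for (rep in c("rep1", "rep2")) {
      f <- sprintf("spo11_%s_%s.bedgraph", gt, rep)
      write_bedgraph(libs[[rep]]$tracks, p(f))
      libsizes[[f]] <- libs[[rep]]$library_size
    }
    if (gt == "wild_type") {
      write_bedgraph(libs$gdna$tracks, p("gdna.bedgraph"))
      libsizes[["gdna.bedgraph"]] <- libs$gdna$library_size
    }
  }
  jsonlite::write_json(libsizes, p("library_sizes.json"), auto_unbox = TRUE,
                       digits = NA)

  truth <- list(
    config = unclass(config),
    regions = true_regions(config),
    n_individuals = list(wild_type = n_wt, cmt3 = n_mut),
    n_planted_repeats = nrow(gen$planted),
    planted = gen$planted)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

pipeline_stage <- function(name, quiet) {
  if (!quiet) message("[pericentrec] ", name)
}

#' Run the two end-to-end landscape analyses
#'
#' Orchestrates the crossover arm (partition from wild-type crossover
#' deserts and methylation, normalized landscapes, mutant differential,
#' telomere-centromere profiles, region chi-square tests, Mann-Whitney
#' comparison) and the SPO11 arm (library-size normalization, log2 ratio
#' against gDNA, z-scoring, replicate correlations, mutant differential,
#' correlation with methylation differentials, satellite matching and
#' metaprofiles against random controls) over a directory of input files
#' as written by [simulate_to_dir()].
#'
#' @param dir Input directory (`genome.fa`, `chrom.sizes`, `gaps.bed`,
#'   `crossovers_wild_type.tsv`, `crossovers_cmt3.tsv`, optional
#'   `individuals_<genotype>.txt` rosters listing every sequenced F2
#'   including zero-crossover individuals,
#'   `meth_<genotype>_<context>.bedgraph`,
#'   `spo11_<genotype>_rep<1|2>.bedgraph`, `gdna.bedgraph`,
#'   `library_sizes.json`).
#' @param out_dir Output directory (created if needed).
#' @param params A [pipeline_params()].
#' @param quiet Suppress stage messages.
#' @return The summary list (also written to `summary.json`), invisibly.
#' @export
run_pipeline <- function(dir, out_dir, params = pipeline_params(),
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  o <- function(...) file.path(out_dir, ...)
  w <- params$window_size
  summary <- list(params = unclass(params),
                  package_version = as.character(
                    utils::packageVersion("pericentrec")))

  pipeline_stage("reading inputs", quiet)
  chroms <- read_chrom_sizes(p("chrom.sizes"))
  gaps <- read_gaps_bed(p("gaps.bed"))
  libsizes <- jsonlite::read_json(p("library_sizes.json"))
  read_pop <- function(gt) {
    roster_file <- p(paste0("individuals_", gt, ".txt"))
    roster <- if (file.exists(roster_file)) readLines(roster_file)
    read_crossovers(p(paste0("crossovers_", gt, ".tsv")), gt,
                    individuals = roster)
  }
  pops <- list(wild_type = read_pop("wild_type"), cmt3 = read_pop("cmt3"))
  meth <- list()
  for (gt in c("wild_type", "cmt3", "kyp_suvh5_suvh6")) {
    meth[[gt]] <- lapply(
      setNames(c("CG", "CHG", "CHH"), c("CG", "CHG", "CHH")),
      function(ctx) {
        read_bedgraph(p(sprintf("meth_%s_%s.bedgraph", gt, ctx)),
                      chroms, w, kind = ctx)
      })
  }

  pipeline_stage("partitioning the genome", quiet)
  wt_mids <- split(pops$wild_type$intervals$midpoint,
                   pops$wild_type$intervals$chrom)
  meth_by_chrom <- lapply(setNames(chroms$name, chroms$name), function(cn) {
    lapply(meth$wild_type, `[[`, cn)
  })
  annotation <- build_partition(chroms, gaps, wt_mids, meth_by_chrom,
                                scan_window = w,
                                context_mode = params$context_mode)
  write_partition_bed(annotation, o("partition.bed"))

  pipeline_stage("crossover landscapes and region statistics", quiet)
  landscapes <- list()
  for (gt in names(pops)) {
    landscapes[[gt]] <- crossover_landscape(pops[[gt]], chroms, w,
                                            params$smooth_k)
    write_bedgraph(lapply(landscapes[[gt]], `[[`, "raw"),
                   o(sprintf("landscape_%s.bedgraph", gt)))
    counts <- count_by_region(pops[[gt]], annotation)
    vs_rand <- region_chisq_vs_random(counts, annotation)
    summary[[gt]] <- list(
      n_individuals = pops[[gt]]$n_individuals,
      n_crossovers = nrow(pops[[gt]]$intervals),
      mean_crossovers_per_individual =
        mean_crossovers_per_individual(pops[[gt]]),
      region_counts = as.list(counts),
      region_shares = as.list(counts / sum(counts)),
      region_chisq_vs_random = list(statistic = vs_rand$statistic,
                                    df = vs_rand$df,
                                    p.value = vs_rand$p.value))
  }
  delta_land <- landscape_differential(
    lapply(landscapes$cmt3, `[[`, "raw"),
    lapply(landscapes$wild_type, `[[`, "raw"))
  write_bedgraph(delta_land, o("landscape_delta.bedgraph"))

  gt_chi <- genotype_region_chisq(
    count_by_region(pops$wild_type, annotation),
    count_by_region(pops$cmt3, annotation))
  mwu <- compare_counts_mannwhitney(per_individual_counts(pops$wild_type),
                                    per_individual_counts(pops$cmt3))
  summary$genotype_comparison <- list(
    pericentromere_chisq = list(statistic = gt_chi$statistic,
                                p.value = gt_chi$p.value),
    mannwhitney = list(U = mwu$U, p.value = mwu$p.value))

  pipeline_stage("telomere-centromere profiles", quiet)
  for (gt in names(pops)) {
    prof <- tel_cen_profile_crossovers(pops[[gt]], annotation,
                                       params$telcen_fraction_co)
    write_tel_cen_profile(prof, o(sprintf("telcen_co_%s.tsv", gt)))
  }
  prof_chg <- tel_cen_profile_track(meth$wild_type$CHG, annotation,
                                    params$telcen_fraction_meth)
  write_tel_cen_profile(prof_chg, o("telcen_chg_wild_type.tsv"))

  pipeline_stage("SPO11 normalization chain", quiet)
  gdna <- coverage_library("gdna", read_bedgraph(p("gdna.bedgraph"),
                                                 chroms, w),
                           libsizes[["gdna.bedgraph"]])
  gdna_norm <- normalize_library(gdna, params$scale)
  z <- list()
  for (gt in c("wild_type", "kyp_suvh5_suvh6")) {
    reps <- lapply(c(rep1 = "rep1", rep2 = "rep2"), function(rep) {
      f <- sprintf("spo11_%s_%s.bedgraph", gt, rep)
      coverage_library(f, read_bedgraph(p(f), chroms, w), libsizes[[f]])
    })
    rr <- replicate_correlation(normalize_library(reps$rep1, params$scale),
                                normalize_library(reps$rep2, params$scale),
                                scales = w)
    ## replicates agree; pool them for the genotype-level signal
    pooled <- coverage_library(
      gt, lapply(setNames(chroms$name, chroms$name), function(cn) {
        a <- reps$rep1$tracks[[cn]]; b <- reps$rep2$tracks[[cn]]
        windowed_track(cn, a$chrom_length, w, a$values + b$values,
                       "coverage")
      }))
    lr <- log2_ratio(normalize_library(pooled, params$scale), gdna_norm,
                     params$pseudocount)
    z[[gt]] <- zscore(lr)
    write_bedgraph(z[[gt]], o(sprintf("spo11_z_%s.bedgraph", gt)))
    summary$spo11[[gt]] <- list(
      replicate_correlation_10kb = unname(rr[1]))
  }
  delta_z <- signal_differential(z$kyp_suvh5_suvh6, z$wild_type)
  write_bedgraph(delta_z, o("spo11_delta.bedgraph"))

  pipeline_stage("methylation differentials and correlations", quiet)
  for (ctx in c("CHG", "CHH")) {
    dm <- landscape_differential(meth$kyp_suvh5_suvh6[[ctx]],
                                 meth$wild_type[[ctx]])
    cc <- correlate_tracks(delta_z, dm)
    summary$delta_correlations[[ctx]] <-
      list(r = cc$r, p.value = cc$p.value, p.printed = format_pvalue(cc$p.value),
           n = cc$n)
  }

  pipeline_stage("satellite matching and metaprofiles", quiet)
  matches <- find_consensus_matches(p("genome.fa"),
                                    max_mismatch = params$max_mismatch)
  write_matches_bed(matches, o("cen180_matches.bed"))
  profs <- list()
  for (gt in c("wild_type", "kyp_suvh5_suvh6")) {
    profs[[gt]] <- metaprofile(z[[gt]], matches, params$flank, params$bin)
    write_metaprofile(profs[[gt]], o(sprintf("metaprofile_%s.tsv", gt)))
  }
  controls <- random_control_positions(annotation, n_matches(matches),
                                       seed = params$seed)
  ctrl_prof <- metaprofile(z$kyp_suvh5_suvh6, controls, params$flank,
                           params$bin, control = TRUE)
  write_metaprofile(ctrl_prof, o("metaprofile_random.tsv"))
  center <- abs(profs$wild_type$offsets) <= 1000
  summary$satellite <- list(
    n_matches = n_matches(matches),
    n_matches_dedup = n_matches(matches, dedup = TRUE),
    metaprofile_center_mean = list(
      wild_type = mean(profs$wild_type$mean_signal[center], na.rm = TRUE),
      kyp_suvh5_suvh6 = mean(profs$kyp_suvh5_suvh6$mean_signal[center],
                             na.rm = TRUE),
      random_control = mean(ctrl_prof$mean_signal[center], na.rm = TRUE)))

  jsonlite::write_json(summary, o("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  pipeline_stage("done", quiet)
  invisible(summary)
}
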