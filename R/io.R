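#' Read a two-column chromosome sizes TSV
#'
#' @param path File with columns name, length (no header).
#' @return data.frame with columns `name`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", col.names = c("name", "length"),
                          colClasses = c("character", "numeric"))
  if (any(df$length <= 0)) stop("non-positive chromosome length in ", path)
  df
}

#' Write chromosome sizes as a two-column TSV
#'
#' @param chromosomes data.frame with columns `name`, `length`.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(chromosomes, path) {
  utils::write.table(chromosomes[, c("name", "length")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,   # to 0-based half-open
             end = BiocGenerics::end(gr))
}

df_to_granges <- function(df, extra = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
  for (nm in names(extra)) S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
  gr
}

#' Read a BED3 of assembly-gap intervals
#'
#' @param path BED3 file (0-based, half-open).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_gaps_bed <- function(path) {
  granges_to_df(rtracklayer::import(path, format = "BED"))
}

#' Write the region partition as BED4
#'
#' The BED name column carries the region class.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @export
write_partition_bed <- function(annotation, path) {
  p <- annotation$partition
  gr <- df_to_granges(p, extra = list(name = p$class))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED4 region partition
#'
#' @param path BED4 file whose name column is the region class.
#' @return data.frame with columns `chrom`, `start`, `end`, `class`.
#' @export
read_partition_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- granges_to_df(gr)
  df$class <- S4Vectors::mcols(gr)$name
  df
}

#' Read crossover intervals into a population
#'
#' `tiger_tsv` is a headered TSV with columns `individual`, `chromosome`,
#' `start`, `end` in 1-based inclusive coordinates (the dialect of the
#' upstream crossover caller), converted to 0-based half-open on read.
#' `bed` is BED4 with the individual id in the name column.
#'
#' @param path Input file.
#' @param genotype Genotype label for the population.
#' @param dialect `"tiger_tsv"` or `"bed"`.
#' @param individuals Optional full roster (ids with zero crossovers);
#'   defaults to the ids present in the file.
#' @return A [crossover_population()].
#' @export
read_crossovers <- function(path, genotype,
                            dialect = c("tiger_tsv", "bed"),
                            individuals = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tiger_tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("individual", "chromosome", "start", "end")
    if (!all(need %in% names(df))) {
      stop(path, ": expected columns ", paste(need, collapse = ", "))
    }
    bad <- which(df$start > df$end | df$start < 1)
    if (length(bad)) {
      stop(path, ": malformed interval at line ", bad[1] + 1L,
           " (1-based inclusive start must satisfy 1 <= start <= end)")
    }
    iv <- data.frame(individual = df$individual, chrom = df$chromosome,
                     start = df$start - 1L, end = df$end)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    iv <- granges_to_df(gr)
    iv$individual <- S4Vectors::mcols(gr)$name
  }
  if (nrow(iv) == 0) {
    warning(path, ": no crossover records")
    if (is.null(individuals)) {
      stop("empty crossover file and no roster supplied")
    }
  }
  crossover_population(genotype,
                       individuals %||% sort(unique(iv$individual)), iv)
}

#' Write crossover intervals
#'
#' @param pop A [crossover_population()].
#' @param path Output file.
#' @param dialect `"tiger_tsv"` (1-based inclusive TSV) or `"bed"` (BED4).
#' @export
write_crossovers <- function(pop, path, dialect = c("tiger_tsv", "bed")) {
  dialect <- match.arg(dialect)
  iv <- pop$intervals
  if (dialect == "tiger_tsv") {
    out <- data.frame(individual = iv$individual, chromosome = iv$chrom,
                      start = iv$start + 1L, end = iv$end)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    gr <- df_to_granges(iv, extra = list(name = iv$individual))
    rtracklayer::export(gr, path, format = "BED")
  }
  invisible(path)
}

#' Read a bedGraph into fixed-width windowed tracks
#'
#' Each window's value is the coverage-weighted mean of the records
#' overlapping it (weighted over covered bases only); windows with no
#' coverage are missing. Overlapping records are an error.
#'
#' @param path bedGraph file (0-based, half-open).
#' @param chromosomes data.frame with columns `name`, `length`.
#' @param window_size Window width in bp.
#' @param kind Track kind label.
#' @return Named track set (one [windowed_track()] per chromosome).
#' @export
read_bedgraph <- function(path, chromosomes, window_size, kind = "signal") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  sl <- setNames(as.integer(chromosomes$length), chromosomes$name)
  if (!all(as.character(GenomeInfoDb::seqnames(gr)) %in% names(sl))) {
    stop(path, ": record on a chromosome absent from the sizes table")
  }
  cov <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                IRanges::ranges(gr),
                                seqlengths = sl)
  if (sum(GenomicRanges::countOverlaps(cov, cov) > 1) > 0) {
    stop(path, ": overlapping bedGraph records")
  }
  windows <- GenomicRanges::tileGenome(sl, tilewidth = window_size,
                                       cut.last.tile.in.chrom = TRUE)
  hits <- GenomicRanges::findOverlaps(windows, cov)
  ov <- GenomicRanges::pintersect(windows[S4Vectors::queryHits(hits)],
                                  cov[S4Vectors::subjectHits(hits)])
  w <- BiocGenerics::width(ov)
  val <- S4Vectors::mcols(gr)$score[S4Vectors::subjectHits(hits)]
  num <- tapply(w * val, S4Vectors::queryHits(hits), sum)
  den <- tapply(w, S4Vectors::queryHits(hits), sum)
  means <- rep(NA_real_, length(windows))
  means[as.integer(names(num))] <- num / den
  wchrom <- as.character(GenomeInfoDb::seqnames(windows))
  out <- lapply(seq_len(nrow(chromosomes)), function(k) {
    cn <- chromosomes$name[k]
    windowed_track(cn, chromosomes$length[k], window_size,
                   means[wchrom == cn], kind)
  })
  setNames(out, chromosomes$name)
}

#' Write windowed tracks as bedGraph
#'
#' Missing windows are omitted from the output.
#'
#' @param tracks A [windowed_track()] or named track set.
#' @param path Output path.
#' @export
write_bedgraph <- function(tracks, path) {
  tracks <- as_track_set(tracks)
  dfs <- lapply(tracks, function(tr) {
    wd <- make_windows(tr$chrom_length, tr$window_size)
    keep <- !is.na(tr$values)
    data.frame(chrom = tr$chrom, start = wd$start[keep],
               end = wd$end[keep], score = tr$values[keep])
  })
  df <- do.call(rbind, dfs)
  gr <- df_to_granges(df, extra = list(score = df$score))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a telomere-centromere profile as TSV
#'
#' @param profile A `tel_cen_profile`.
#' @param path Output path.
#' @export
write_tel_cen_profile <- function(profile, path) {
  utils::write.table(
    data.frame(bin = seq_len(profile$n_bins) - 1L,
               value_raw = profile$raw,
               value_smoothed = profile$smoothed),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write satellite matches as BED6
#'
#' The BED score column carries the mismatch count.
#'
#' @param matches A `repeat_match_set`.
#' @param path Output path.
#' @export
write_matches_bed <- function(matches, path) {
  df <- as.data.frame(matches)
  gr <- df_to_granges(df, extra = list(name = "satellite",
                                       score = df$mismatches))
  BiocGenerics::strand(gr) <- df$strand
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a metaprofile as TSV
#'
#' @param profile A `meta_profile`.
#' @param path Output path.
#' @export
write_metaprofile <- function(profile, path) {
  utils::write.table(
    data.frame(offset = profile$offsets, mean_signal = profile$mean_signal,
               n = profile$n_anchors),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
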