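Package: pericentrec
Title: Pericentromeric Meiotic Recombination Landscape Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of meiotic crossover and DNA double-strand-break
    landscapes around plant centromeres. Estimates genetic distance from
    fluorescent-tagged-line (FTL) seed and pollen counts, partitions
    chromosomes into arm, pericentromere and centromere classes from
    wild-type crossover deserts and DNA-methylation window tracks, builds
    normalized crossover landscapes, differentials and
    telomere-centromere metaprofiles, implements the SPO11-1-oligonucleotide
    normalization chain (library-size scaling, log2 ratio against a genomic
    DNA control, z-score standardization) with replicate and differential
    correlation statistics, matches centromeric satellite consensus
    sequences under a substitution-only mismatch budget, and ships a seeded
    synthetic-data generator emulating all of these inputs so the full
    pipeline is testable at toy scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
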