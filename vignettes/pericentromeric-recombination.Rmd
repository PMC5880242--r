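---
title: "Methods: pericentromeric recombination landscape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pericentromeric recombination landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pericentrec)
```

# The scientific problem

Plant centromeres are flanked by transposon-dense, heavily DNA-methylated
pericentromeric heterochromatin in which meiotic crossovers are strongly
suppressed. Mutants of the H3K9me2 / non-CG methylation maintenance
pathway (e.g. *cmt3*, which removes CHG methylation, or the *kyp suvh5
suvh6* triple mutant, which removes H3K9me2 and both CHG and CHH
methylation) relieve this suppression: crossovers rise in the
pericentromeres and SPO11-1-dependent double-strand breaks (DSBs) rise in
the centromeres. `pericentrec` implements the computational chain needed
to quantify these effects from standard inputs: crossover interval calls
from genotyping-by-sequencing (GBS) of F2 populations, fluorescence class
counts from fluorescent tagged lines (FTLs), per-context methylation
window tracks, SPO11-1-oligonucleotide coverage with a genomic-DNA
control, and a genome sequence with its centromeric satellite consensus.

# Estimating genetic distance from FTL counts

An FTL hemizygote carries two linked transgenes expressing different
fluorophores. Gametes are parental (both colors, or neither) or
recombinant (a single color), with probabilities $(1-r)/2$ and $r/2$
respectively for recombinant fraction $r$.

*Pollen mode* scores gametes directly by flow cytometry, so
$\hat r = (N_{s1} + N_{s2}) / N_T$ and $\mathrm{cM} = 100\,\hat r$.
Colorless gametes stay in the denominator by default because flow
counting scores all alive pollen; `include_colorless = FALSE` supports
assays that cannot score them.

*Seed mode* scores selfed progeny, each the union of two independent
gametes. The class probabilities are
$P(\text{green only}) = P(\text{red only}) = \tfrac14\left(1-(1-r)^2\right)$,
$P(\text{neither}) = \tfrac14 (1-r)^2$, and the closed-form inverse is

$$\hat r = 1 - \sqrt{1 - 2\,(N_G + N_R)/N_T}.$$

The estimator is undefined when $2(N_G+N_R)/N_T \ge 1$, which signals
mis-scored input and raises an error. `seed_class_probabilities()` is the
forward model, so the estimator is self-verifying: applied to exact
expected counts it returns $100r$ to numerical precision (this is a unit
test).

Genotypes are compared by a 2x2 chi-square on pooled recombinant versus
parental classes, df 1, without continuity correction. We pool replicates
by default; `stratified = TRUE` provides a Cochran-Mantel-Haenszel
alternative for workflows that prefer replicate stratification. The
choice of the pooled 2x2 (rather than a 4-class test) matches the degrees
of freedom implied by published FTL chi-square usage.

# Partitioning chromosomes into arm, pericentromere, centromere

The partition is data-defined, not coordinate-defined:

* **Centromere** — the maximal run of adjacent scan windows containing
  the assembly gap in which no *wild-type* crossover midpoint falls. The
  scan resolution defaults to the 10-kb landscape window; the definition
  guarantees the centromere class has zero wild-type crossovers and
  always contains the gap. A wild-type midpoint inside the gap itself is
  inconsistent input and raises an error.
* **Pericentromere** — from each centromere edge, extend outward window
  by window while methylation is *strictly above* the chromosome-wide
  mean of the track. Extension stops at the first non-exceeding window
  (no gap tolerance): this is the simplest reading of "contiguous
  regions with higher-than-average methylation", and it makes the
  boundary deterministic.
* **Arm** — the remainder.

Two choices here were genuinely open. First, which methylation context
drives the pericentromere rule: we default to the unweighted per-window
mean of CG, CHG and CHH (`context_mode = "mean"`), since "DNA
methylation" unqualified most naturally means the aggregate; individual
contexts are selectable. Second, whether "average" is per chromosome or
genome-wide: we use the per-chromosome mean, because chromosome arms
differ in baseline methylation and a genome-wide threshold would let a
methylation-rich chromosome bleed its pericentromere outward; this is
configurable by supplying a pre-thresholded track. On synthetic data with
known boundaries, the rule recovers the true pericentromere edges to
within two windows.

Coordinates are 0-based and half-open everywhere internally; the TIGER
crossover dialect (1-based inclusive TSV) and BED/bedGraph conventions
are converted at the I/O boundary only.

# Crossover landscapes and statistics

All assignment is by crossover **midpoint** (the middle of the
SNP-bounded uncertainty interval): this is the explicit convention for
region counting, and we extend it to window tallies for consistency.
Landscapes are midpoint tallies in 10-kb adjacent windows divided by the
number of F2 individuals (zero-crossover individuals stay in the
denominator — they exist in real GBS populations and affect means), then
smoothed with a centered rolling mean (`stats::filter`). The smoothing
span defaults to 9 windows (90 kb), a value chosen once for legible toy
plots; the source analyses do not state their span, so it is exposed as
a parameter. Differentials are elementwise mutant minus wild type.

Region counts are tested against the physical-distance expectation
($E_i = N \cdot L_i / L$) with a goodness-of-fit chi-square, and between
genotypes with a 2x2 in-class/out-of-class chi-square (df 1, no
continuity correction). Whether the published genotype comparison used
the 2x2 or a 3-class homogeneity test is not stated; both are provided
and the 2x2 is the default. Per-individual count distributions are
compared with a two-sided Mann-Whitney test: exact when both samples
have at most 20 observations without ties, otherwise the normal
approximation with tie correction and no continuity correction (the
source names only the test).

Telomere-centromere profiles orient every arm telomere-first, divide it
into proportional bins (1% for crossovers, 0.5% for methylation), average
across arms with equal weight, and smooth with `stats::smooth.spline`
under generalized cross-validation (only the function, not its
smoothness, is prescribed; GCV avoids a hand-picked parameter). Window
values are assigned to proportional bins by overlap-weighted averaging,
so bins narrower than a track window still inherit a defined value. The
bin nearest the centromere absorbs the integer-division remainder, so
bin lengths always sum exactly to the arm length.

# The SPO11-1-oligonucleotide normalization chain

The chain is: per-library scaling to reads-per-million
(`value * scale / library_size`), then
$\log_2\left((s + c)/(g + c)\right)$ against the gDNA control with
pseudocount $c$ = 1 read-per-million (zero-gDNA windows are not stated
to be handled in any particular way; the symmetric pseudocount makes a
0/0 window exactly 0), then z-score standardization using one global
mean and sample (n-1) SD across all non-missing windows genome-wide per
library — "signed number of standard deviations from the mean" implies a
single mean, not per-chromosome recentering. The chain is deterministic
and the z step is invariant to positive affine rescaling of its input
(both are tested properties).

Replicate agreement is Pearson's r between libraries after mean-rebinning
to each requested scale. Differential analysis subtracts wild-type from
mutant z-tracks and correlates against methylation differentials;
p-values come from the t transform $t = r\sqrt{n-2}/\sqrt{1-r^2}$.
Values below 2.2e-16 are printed as "< 2.2e-16" in text output, with the
raw float preserved in machine-readable output.

# Satellite consensus matching and metaprofiles

Matching uses `Biostrings::matchPattern` with `with.indels = FALSE` and
`fixed = TRUE`: substitution-only Hamming distance, with `N` and other
ambiguity codes always counting as mismatches. This matters at a budget
of 90 mismatches over a 178-bp unit — under edit distance such a budget
would behave very differently. Both strands are scanned (the reverse
strand as the reverse-complemented consensus, reported in forward
coordinates); all overlapping matches are retained, and matches
overhanging a sequence end are not reported. A naive vectorized Hamming
scan serves as the independent oracle in the test suite; the matcher and
oracle agree exactly on planted-motif genomes, including budgets above
half the consensus length. Counting reports both raw and
start-deduplicated numbers, since published repeat totals may or may not
collapse strand duplicates.

Metaprofiles anchor at the match **midpoint** (the choice between start
and midpoint was open; the midpoint makes plus- and minus-strand anchors
symmetric), extract signal in a +/-10-kb window, flip minus-strand
anchors, and average within 50-bp bins across anchors. Control profiles
use the same number of uniform random positions over the gap-excluded
genome, drawn reproducibly from a caller-supplied seed.

# The synthetic-data generator

The generator exists so that every stage of the pipeline is testable
without downloads, with truth records sufficient to predict every
pipeline quantity in expectation. Defaults were fixed once, before any
acceptance measurement, at the study's own operating points:

* Genome: 3 chromosomes x 2 Mb at 10-kb windows (full pipeline in about
  a minute; real-genome scale is configuration, not code). Each
  chromosome has a central 60-kb `N` gap flanked by 70-kb tandem arrays
  of the 178-bp consensus (random strand per copy, per-base mutation
  rate 0.10 so copies sit well under the budget of 90), 300-kb
  pericentromeres, and euchromatic arms.
* Crossovers: per-individual counts are Poisson around region-structured
  intensities solved from the targets E[CO/F2] = 7.6 (wild type) / 7.3
  (*cmt3*), pericentromeric shares 24.6% / 27.8%, and centromeric shares
  0 / 13 of 2803. No crossover interference is simulated — interference
  is probed genetically in the source system, not modeled — so the
  per-individual variance is Poisson. Events are reported as 1-kb
  uncertainty intervals (emulating the ~0.9-kb GBS resolution), and the
  assembly gap never receives events.
* Methylation: per-window Beta noise (concentration 20) around
  region/context/genotype means; CG is drawn from a genotype-independent
  stream so it is bit-identical across genotypes at a given seed;
  *cmt3* sets CHG near zero and *kyp suvh5 suvh6* sets CHG and CHH near
  zero.
* SPO11/gDNA: shared per-window gamma intensity (shape 4) around
  region-level means, Poisson reads at replicate-specific depths (150
  and 220 reads per window; gDNA 180 with milder gamma noise), mutant
  centromere x3 and pericentromere x1.8. At these depths Poisson noise
  is small against the shared intensity variance, which is what puts
  replicate correlations above 0.9 at the 10-kb scale — emulating the
  0.91-0.99 range observed in the real libraries.

What the generator does **not** emulate: linkage disequilibrium and SNP
ascertainment in the F2s, crossover interference, bisulfite conversion
errors, mappability structure beyond the gap, higher-order satellite
array structure, and structural polymorphism between parental
accessions (the feature that likely suppresses centromeric crossovers in
real hybrids). Tests passing on this generator therefore validate the
*computational chain* — estimators, partition rules, normalizations,
statistics, matching — not biological discovery on real data.

# Numerical and degenerate-input policy

* Missing windows (`NA`) are excluded from means, SDs and correlations
  and propagate through rolling means, differentials and metaprofile
  bins.
* Zero-variance input to z-scoring or correlation is an error, not a
  silent `NaN`; an all-missing methylation track is an error.
* A midpoint on a partition boundary belongs to the start-inclusive
  right-hand interval (half-open convention).
* `smooth.spline` needs enough distinct bins; profiles with fewer than
  ten non-missing bins are returned unsmoothed.
* Every generator is a pure function of (config, seed): outputs are
  byte-identical on re-run, and the pipeline's JSON summary is
  byte-identical across runs on identical inputs.

# Problem sizes used by the test suite

The suite exercises the estimators at scoring sizes of 10^3 to 10^6,
population contrasts at the study's n = 437 / 384 over 100 seeded
replicates, matcher-oracle equivalence on 50 planted-motif genomes of 10
to 200 kb, and the end-to-end pipeline on 0.6-2 Mb toy chromosomes —
sizes chosen so the whole suite runs in about a minute while every
contract is still exercised at the study's own operating points.

# Known limitations

* The genetically defined centromere is only as tight as the wild-type
  crossover density allows: sparse populations widen the desert and
  hence the centromere class.
* The pericentromere rule's single-window stopping criterion is
  sensitive to window noise when methylation contrast is weak; the
  context-mean default mitigates this by averaging three contexts.
* The satellite matcher's budget semantics are substitution-only;
  diverged copies with indels will be missed or mis-scored relative to
  an alignment-based definition.
* Reproducing the published reference-genome repeat count requires the
  reference FASTA, which is not shipped; point
  `options(pericentrec.tair10 = ...)` at a local copy to run that check.
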