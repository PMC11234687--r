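---
title: "Models and methods behind scMethCap"
author: "scMethCap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scMethCap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

scMethCap processes combinatorially indexed single-cell bisulfite
sequencing libraries, with or without hybridization-capture enrichment of
regulatory regions, from raw paired FASTQ to cluster-specific
differentially methylated regions (DMRs). This vignette explains the
models, defaults and numerical choices; the README shows a worked run.

# The read structure and demultiplexing

Cell identity is encoded by three barcodes: two PCR indices carried in the
FASTQ header comment (`...:INDEX1+INDEX2`, the post-basecall demultiplexed
convention; separate index-read files are also accepted) and an 8-bp
tagmentation index at the start of read 2. Bases 9–29 of read 2 carry the
transposase mosaic-end recognition sequence and are discarded; the
remainder of read 2 is genomic. A read pair is assigned to a cell only
when all three indices match their whitelists uniquely within a Hamming
distance of 2. Ties at the minimal distance are treated as ambiguous and
discarded — a conservative choice: rescuing ties would trade a small gain
in yield for a risk of cross-cell contamination. Cell ids are always built
from the corrected whitelist entries, never from observed sequences.

The matcher uses an exact-match fast path (hash lookup) before the full
scan. This is provably equivalent to the exhaustive scan because whitelist
entries are unique, and the equivalence is exercised against a full-scan
oracle in the test suite.

# Bisulfite alignment

Unmethylated cytosines read as thymine, so alignment happens in a reduced
alphabet: a read's C→T reduction is matched against the C→T-reduced Watson
strand and, through its reverse complement, the G→A-reduced Crick strand,
in both orientations. The built-in aligner does exact full-length matching
(Aho–Corasick over all reads) with a pigeonhole-seeded rescue stage
allowing up to 2 substitutions and no indels: three disjoint exact seeds
guarantee that any placement with at most two mismatches is found. A
unique best hit is required; equal-score candidates leave the read
unaligned and counted. This aligner is intended for synthetic references
up to a few Mbp; real data enters through the SAM/BAM import adapter,
which accepts cell barcodes in a `CB` tag or as the first `:`-separated
read-name token. The mate-swap convention of tagmentation-based libraries
(the tagmentation end plays the role of a conventional read 1) is a single
switch, `swapMates`, on by default.

Coordinates follow the Bioconductor convention (1-based, closed
`GRanges`) throughout the package; BED and bedgraph writers convert to
0-based half-open on output.

# Duplicate removal and call extraction

PCR duplicates are removed per cell: reads sharing a fragment signature
(cell, chromosome, fragment start, fragment end, strand) collapse to the
first occurrence. The signature is configurable (`key = "mate1"`) because
the equivalent field tools differ on this point; fragment signature is the
default as it is strictly more specific. Identical coordinates in
different cells are never collapsed.

Methylation calls are extracted against the reference: on the Watson
strand a read C at a reference C is methylated and a read T unmethylated;
on Crick, read G at reference G is methylated, read A unmethylated. Any
other base is counted as a mismatch, not a call. Context (CG vs CH) is
determined from the reference only, and Crick CG calls are reported at the
position of the reference G so both strands of a CpG remain
distinguishable. Where mates overlap, mate 1 wins, so a molecule
contributes one observation per site. Contexts involving ambiguity codes
are dropped and counted.

# Capture enrichment QC

A fragment counts on-target when it overlaps a merged probe interval by at
least 1 bp. Fold enrichment is the observed on-target fraction divided by
the panel's fraction of the genome; the genome denominator includes all
bases of the main-series chromosomes (configurable), which is the
convention under which the package's worked examples reproduce published
fold/percentage pairs for the 123 Mbp human methylome panel. Because the
fraction-to-fold transform is monotone, the median per-cell fold equals
the fold of the median fraction. Shadow coverage repeats the accounting
after padding probes by ±200 bp and re-merging, capturing the halo of
fragments partially pulled down by a probe. Strand and conversion-track
balance is reported overall and by target status, with exact binomial
tests against 50:50. Site-level correlations between callsets are
computed on shared CG sites with coverage ≥ 5 in both sets (the
threshold is exposed; 5 keeps single-cell aggregate comparisons usable),
overall, by target status, and within the top and bottom GC-content
quartiles of non-overlapping 2-kbp bins.

# Window matrices

Three window families cover the standard analyses: genome tiling (50-kbp
CG or 250-kbp CH matrices for clustering), 1500-bp windows sliding by
500 bp (DMR calling), and target windows (the merged probe intervals).
Tiling windows partition each chromosome exactly, the last window
truncated; sliding windows start every step while the start is inside the
chromosome and are truncated at the end — truncated terminal windows are
kept, a choice pinned by enumeration tests since upstream conventions are
unpublished. A call is credited to every window containing it, so
sliding windows multiply-assign. The container stores methylated and
total call counts (sparse, windows × cells); percentages and the
coverage filter are materialized on demand (`methPct(x, minCalls)`), with
sub-threshold entries explicitly missing rather than zero, so that
mean-imputation before SVD is not biased toward 0% methylation.
`minCalls` defaults to 1 for clustering matrices (maximizing retained
cells) and DMR testing uses aggregate coverage ≥ 10 per group.

# Dimensionality reduction and clustering

Missing window percentages are imputed to the per-window mean, windows
are centred, and a truncated SVD retains the first 50 components (the
`irlba` solver; exact `svd` for small inputs). The first component is
retained by default with a `dropFirst` switch, since some methylome
pipelines discard a coverage-correlated leading component. For combined
CG-target + CH-tile analyses, two 25-dimension blocks are concatenated
after scaling each block to unit total variance so neither signal
dominates; this scaling is this package's choice — the source convention
is unpublished.

Clustering builds a k-nearest-neighbour graph (Euclidean, k = 20 by
default), weights edges by shared-neighbour Jaccard similarity and
applies Louvain community detection; UMAP is used for visualization only.
k, resolution and seed are recorded on the result. All stochastic steps
are seeded, and fixed seeds give bit-identical labels and embeddings on
one platform. Cluster agreement between runs or conditions is summarized
by the contingency table and the adjusted Rand index, computed in closed
form from the table and cross-checked in the tests against an independent
implementation.

# DMR calling

For each cluster, window counts are aggregated across its cells, and the
rest of the dataset is pooled into a single aggregate rather than kept as
per-cluster tracks — uniting tracks would let any single low-coverage
cluster knock windows out of every comparison. Windows with total
coverage below 10 in either group are untested. Tested windows get a
two-sided Fisher's exact test on the 2×2 methylated/unmethylated table.
Fisher's exact test is used deliberately (the popular methylKit stack
defaults to a logistic-regression/SLIM pipeline): it is exact at any
coverage, assumption-free, and independently verifiable against
hypergeometric enumeration, which the test suite does for all tables with
totals ≤ 100. q-values are Benjamini–Hochberg within each focal cluster's
test family (each one-vs-rest scan is its own family). Windows pass at
q ≤ 1e-4 and |difference| ≥ 25 percentage points; the q threshold is
exposed because both 1e-4 and 1e-5 appear in field usage, and the default
follows the stricter-documented processing convention (1e-4). All passing
windows are retained — including overlaps and windows significant in more
than one cluster — for comparability across conditions; merged per-cluster
regions are reported alongside. Merging is per cluster, never across
clusters. Regions are annotated by ≥ 1 bp overlap against user-supplied
annotation sets with a documented precedence for the primary label, and
per-cluster bedgraph tracks are emitted on the central 500-bp third of
each sliding window so adjacent records do not overlap.

# The synthetic experiment generator

Every stage is testable without external data because the generator emits
a complete experiment with known truth. Defaults describe the emulated
study conditions at desk scale:

* genome: 2 chromosomes × 1 Mbp; CpG dinucleotides planted explicitly at
  rate 0.02/bp (chance CGs are removed first, so planted sites are
  exactly the CpG universe and context truth is exact);
* probe panel: 500-bp intervals, one per uniform genome slot, covering 4%
  of the genome — the panel-to-genome ratio of the 123 Mbp human
  methylome panel;
* cells: 4 types × 50 cells; 40 DMRs of 1500 bp with methylation
  difference 0.5 against a 0.8 CG baseline (hypo- or hypermethylated,
  whichever direction fits [0,1] without clipping), 80% of DMRs centred
  on probes; CH methylation 1%;
* reads: 1000 pairs per cell (negative binomial across cells, dispersion
  10), 100-bp paired reads, log-normal inserts (median 250 bp); one PCR
  duplicate per ten unique fragments (≈ 91% unique reads, matching
  reported per-cell uniqueness); bisulfite conversion 99%, sequencing
  error 0.1%.

Per-cell read counts at full experimental scale are ~150k; scaling them
proportionally to a 2 Mbp genome would leave each cell a statistically
empty profile, so the desk-scale default (1000 reads/cell) is chosen to
preserve the per-cell information content that drives clustering —
hundreds of on-target CG observations per cell — rather than the genome
coverage ratio. This choice was made once, from the power reasoning
above.

Capture is modelled as a two-component mixture: with probability
`w·t/(w·t + 1 − t)` (capture weight `w`, target fraction `t`) a fragment
is drawn uniformly among placements overlapping a probe, otherwise
uniformly among placements clear of all probes. The observed ≥ 1 bp
on-target fraction therefore equals the closed form in expectation, and
`w = 1` reduces exactly to the panel's bp fraction (fold enrichment 1).
Duplicates are exact re-emissions of a fragment (conversion and errors
are molecular, pre-PCR, in this model). Fragments shorter than the read
length are skipped and counted.

What the generator does not emulate: base-quality variation, chimeric
fragments, copy-number variation, context-dependent conversion failure,
probe-to-probe capture efficiency differences, and realistic genome
composition (CpG islands, repeats). Passing recovery tests therefore
demonstrates the correctness of the pipeline's logic under its stated
model, not robustness to every artefact of real libraries.

# Numerical and design notes

* All randomness flows from one integer seed; stage-specific streams are
  derived deterministically, and sub-seeds stay below 2^31.
* Two-sided Fisher p-values sum hypergeometric probabilities ≤ the
  observed one with a 1 + 1e-7 relative slack, matching `fisher.test`.
* Degenerate inputs: empty probe sets error; empty strata in correlation
  reports are `NA`; cells with zero calls get explicit zero QC rows;
  `d` above the matrix rank is clipped with a warning; `k` must be below
  the cell count.
* Problem sizes in the tests (a 200-cell, 2 Mbp default scenario for
  recovery checks; smaller genomes for property tests) were chosen so
  that planted effects are recoverable with comfortable statistical
  margins at desk scale.
* The spec-level interfaces map to Bioconductor idioms: window matrices
  are `RangedSummarizedExperiment` subclasses, probe panels and DMR
  regions are `GRanges`, reads are `DNAStringSet`s; per-call tables use
  `data.table` for volume.

# Known limitations

The built-in aligner ignores indels and is not intended for real genomes;
no batch correction, smoothing-based DMR calling, CH-context DMRs, or
quality-aware barcode assignment. The logistic-regression DMR test
remains a stub by design. UMAP and Louvain internals are external,
contractual dependencies (`uwot`, `igraph`), as is the SVD solver
(`irlba`).
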