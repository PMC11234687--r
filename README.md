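# scMethCap

Processing and evaluation of capture-enriched single-cell bisulfite
sequencing data in R.

Single-cell DNA methylation assays based on combinatorial indexing encode
cell identity in three barcodes (two PCR indices plus a tagmentation
index at the start of read 2) and need millions of reads per cell to
cover enough CG dinucleotides for cell-type assignment. Hybridization
capture with a regulatory-region probe panel (~123 Mbp, ~4% of the human
genome) concentrates reads where methylation is most informative, cutting
the required depth by an order of magnitude. scMethCap implements the
full computational side of such experiments, for method developers and
analysts who need a tested, seedable, end-to-end pipeline:

* **demux** — three-barcode demultiplexing with Hamming-distance ≤ 2
  whitelist correction and read-2 restructuring (8-bp barcode; bases
  9–29, the mosaic end, removed);
* **align** — a built-in bisulfite-aware aligner for synthetic
  references (C→T / G→A reduced-alphabet matching, both strands and
  orientations, unique-best-hit) plus a SAM/BAM import adapter for
  external aligners honoring the mate-swap convention;
* **rmdup / extract** — per-cell PCR duplicate removal on fragment
  signatures and reference-driven methylation calls split by CG/CH
  context and chromosome;
* **enrich** — capture QC: on-target fractions (≥ 1 bp overlap), fold
  enrichment, ±200 bp shadow coverage, strand/conversion-track balance,
  site-level correlations stratified by target status and 2-kbp GC
  quartiles;
* **matrix / cluster** — windowed methylation matrices (tiling, 1500/500
  sliding, target windows) as `RangedSummarizedExperiment`s; truncated
  SVD (50 dims), kNN/Louvain clustering, UMAP, adjusted-Rand concordance;
* **dmr** — cluster-vs-rest-aggregate Fisher testing on 1500/500 sliding
  windows (coverage ≥ 10 per group), Benjamini–Hochberg q ≤ 1e-4 and
  |Δmeth| ≥ 25 percentage-point filters, region merging, annotation,
  bedgraph export, and multi-set overlap partitions;
* **simulate** — a synthetic experiment generator (planted cell types,
  DMRs, capture oversampling, PCR duplication, incomplete conversion)
  with complete ground truth, so every stage above is verifiable.

The core quantitative conventions: a read is **on-target** when it
overlaps a merged probe interval by at least 1 bp; **fold enrichment** is
the on-target fraction divided by the panel's fraction of the genome,

```
fold = (on-target fraction) / (panel bp / genome bp)
```

and a **DMR** is a run of merged 1500-bp windows in which one cluster's
aggregate CG methylation differs from the pooled rest of the cells at
q ≤ 1e-4 with |difference| ≥ 25%.

## Worked example

A complete synthetic experiment at desk scale — 4 cell types × 50 cells,
a 2 × 1 Mbp genome, a 4% probe panel with 10× capture oversampling —
through the whole pipeline:

```r
library(scMethCap)
res <- runPipeline(list(global = list(seed = 7)), outDir = "run")
```

```
[..] stage: simulate
[..] stage: demux
...
[..] stage: dmr
```

Headline numbers from that run (see `run/enrichment.json`,
`run/clusters.tsv`, `run/dmr_windows.tsv`):

```r
res$enrich$pctOnTargetPost   # 29.35761 -- % unique reads on target
res$enrich$foldPost          # 7.339403 -- fold enrichment over the 4% panel
nlevels(res$cluster$labels)  # 4        -- clusters recovered
sum(res$dmr$windows$pass)    # 142      -- passing 1500-bp DMR windows
length(res$dmr$regions)      # 39       -- merged cluster-specific regions
```

The on-target fraction sits at the capture-mixture expectation
`w·t/(w·t+1−t) = 10·0.04/(10·0.04+0.96) ≈ 0.294`, the fold enrichment is
that fraction over the panel fraction (0.294/0.04 ≈ 7.3), the four
clusters match the planted cell types (the cell table in
`simTruth(res$simulate$reads)` carries the truth), the per-cell QC
(`run/cell_qc.tsv`) shows a median 90.9% of reads unique, and the 142
passing windows merge into 39 regions sitting on the 40 planted DMRs.

The same arithmetic reproduces published human-panel worked examples:

```r
foldEnrichment(0.294, totalBp = 123043166,
               genomeBp = sum(hg38MainChromSizes()))
#> 7.379  (printed as 7.4-fold at 29.4% on target)
```

A thin CLI wrapper is installed with the package
(`system.file("scripts", "scmethcap", package = "scMethCap")`):

```sh
scmethcap pipeline --config cfg.yaml --out run/
scmethcap simulate --config cfg.yaml --out simdata/
```

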