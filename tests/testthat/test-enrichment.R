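library(GenomicRanges)

gr0 <- function(chrom, start0, end0) {
  # convenience: build from 0-based half-open coordinates
  GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
}

test_that("probe merging matches the worked example and a bitmap oracle", {
  probes <- gr0("chr1", c(100, 150, 400), c(200, 300, 500))
  ps <- buildProbeSet(probes, c(chr1 = 1000))
  expect_equal(length(ps), 2)
  expect_equal(probeTotalBp(ps), 300)
  expect_error(buildProbeSet(GRanges(), c(chr1 = 1000)), "empty")
  # random sets against a per-base bitmap
  set.seed(41)
  sizes <- c(c1 = 5000, c2 = 3000)
  for (rep in 1:5) {
    n <- 30
    ch <- sample(names(sizes), n, TRUE)
    s <- vapply(ch, function(c) sample(sizes[[c]] - 100, 1), numeric(1))
    raw <- GRanges(ch, IRanges::IRanges(s, s + sample(20:150, n, TRUE)))
    ps <- buildProbeSet(raw, sizes)
    expect_equal(probeTotalBp(ps), bitmapBp(bitmapOf(raw, sizes)))
  }
})

test_that("on-target accounting honors the 1-bp half-open overlap rule", {
  probes <- buildProbeSet(gr0("chr1", 100, 200), c(chr1 = 1000))
  mk <- function(s0, e0, id) {
    gr <- gr0("chr1", s0, e0)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      readId = id, cell = "c1", mate = 1L, track = "CT", orient = "F",
      seq = "A", nmm = 0L, score = 60L, fragStart = s0 + 1L, fragEnd = e0,
      paired = TRUE)
    gr
  }
  on <- onTargetFraction(c(mk(95, 105, "a"), mk(0, 100, "b")), probes)
  expect_equal(on$nOnTarget, 1L)   # 5-bp overlap counts; bookended does not
  expect_equal(on$fraction, 0.5)
  # chromosome absent from the probe set counts off-target
  far <- mk(95, 105, "c")
  GenomeInfoDb::seqlevels(far) <- "chrX"
  suppressWarnings(off <- onTargetFraction(far, probes))
  expect_equal(off$nOnTarget, 0L)
})

test_that("fold enrichment arithmetic and degenerate cases behave", {
  ps <- buildProbeSet(gr0("chr1", 0, 40), c(chr1 = 1000))
  expect_equal(foldEnrichment(40 / 1000, ps), 1.0)
  expect_equal(foldEnrichment(0.5, totalBp = 100, genomeBp = 1000), 5)
  expect_error(foldEnrichment(0.5, totalBp = 0, genomeBp = 10), "zero-size")
})

test_that("shadow padding expands, re-merges, clips and never lowers the fraction", {
  ps <- buildProbeSet(gr0("chr1", c(1000, 50), c(1100, 100)),
                      c(chr1 = 5000))
  sh <- shadowCoverage(GRanges(seqinfo = GenomeInfoDb::seqinfo(ps)), ps,
                       pad = 200)
  pp <- sh$paddedProbes
  expect_equal(BiocGenerics::start(pp), c(1, 801))
  expect_equal(BiocGenerics::end(pp), c(300, 1300))
  # property: padded on-target fraction >= unpadded, random inputs
  set.seed(42)
  sizes <- c(c1 = 20000)
  for (rep in 1:5) {
    pr <- buildProbeSet(GRanges("c1", IRanges::IRanges(
      sample(19000, 10), width = sample(50:200, 10, TRUE))), sizes)
    n <- 200
    s <- sample(19000, n, TRUE)
    gr <- GRanges("c1", IRanges::IRanges(s, s + 120))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      readId = paste0("r", seq_len(n)), cell = "c1", mate = 1L,
      track = "CT", orient = "F", seq = "A", nmm = 0L, score = 60L,
      fragStart = s, fragEnd = s + 120, paired = TRUE)
    f0 <- onTargetFraction(gr, pr)$fraction
    f1 <- shadowCoverage(gr, pr, pad = 200)$fraction
    expect_gte(f1, f0)
    # bitmap oracle for the >= 1 bp overlap rule
    bm <- bitmapOf(pr, sizes)
    want <- mean(vapply(seq_len(n), function(i)
      bitmapOverlaps(bm, "c1", s[i], s[i] + 120), logical(1)))
    expect_equal(f0, want)
  }
})

test_that("strand and track fractions stratify and conserve counts", {
  sh <- getSharedSim()
  probes <- buildProbeSet(probeSet(sh$sim$genome),
                          c(chr1 = sh$cfg@chromLength))
  bal <- strandTrackBalance(sh$rd$alignments, probes)
  all <- bal[bal$stratum == "all"]
  expect_equal(all$nWatson + all$nCrick,
               sum(bal$nWatson[bal$stratum != "all"] +
                     bal$nCrick[bal$stratum != "all"]))
  # simulator draws strands symmetrically: 50:50 within 4 SE
  n <- all$nWatson + all$nCrick
  expect_lt(abs(all$watsonFraction - 0.5), 4 * sqrt(0.25 / n))
  expect_lt(abs(all$ctFraction - 0.5), 4 * sqrt(0.25 / n))
  # single-read input gives degenerate fractions
  one <- strandTrackBalance(sh$rd$alignments[1], probes)
  expect_true(all(one$watsonFraction[one$stratum == "all"] %in% c(0, 1)))
})

test_that("site correlations are exact on degenerate inputs", {
  sh <- getSharedSim()
  calls <- sh$ex$calls
  probes <- buildProbeSet(probeSet(sh$sim$genome),
                          c(chr1 = sh$cfg@chromLength))
  sc <- siteCorrelation(calls, calls, probes, sh$sim$genome, minCov = 3)
  nonEmpty <- sc[sc$nSites >= 2]
  expect_true(all(abs(nonEmpty$r - 1) < 1e-12))
  # anti-correlated toy vectors
  mk <- function(meth) data.table::data.table(
    cell = "c", chrom = "chr1", pos = rep(c(10L, 20L, 30L, 40L), each = 10),
    strand = "+", context = "CG",
    meth = rep(meth, each = 10))
  a <- mk(c(TRUE, TRUE, FALSE, FALSE))
  b <- mk(c(FALSE, FALSE, TRUE, TRUE))
  sc2 <- siteCorrelation(a, b, probes, sh$sim$genome, minCov = 3)
  expect_equal(sc2$r[sc2$stratum == "all"], -1)
})

test_that("independent replicate callsets correlate at covered sites", {
  # one cell type with many strong DMRs gives sites a wide spread of true
  # methylation levels, so replicate agreement is informative
  base <- SimConfig(nChromosomes = 1L, chromLength = 5e4, nCellTypes = 1L,
                    cellsPerType = 8L, readsPerCell = 1500, errorRate = 0,
                    conversionEfficiency = 1, nDMRs = 12L,
                    dmrOnTargetFrac = 0, seed = 61L)
  runOne <- function(seed) {
    cfg <- base
    cfg@seed <- seed
    g <- simulateGenome(base)          # same genome both runs
    m <- plantMethylomes(base, g)
    reads <- emitReads(cfg, g, m)
    dx <- demultiplex(reads@read1, reads@read2,
                      comment = reads@headerComment,
                      whitelists = simTruth(reads)@whitelists)
    al <- alignPairsToy(dx$read1, dx$read2genomic, dx$cells, g)
    extractCalls(rmdupPE(al$alignments)$alignments, g)$calls
  }
  c1 <- runOne(61L)
  c2 <- runOne(62L)
  g <- simulateGenome(base)
  probes <- buildProbeSet(probeSet(g), c(chr1 = 5e4))
  sc <- siteCorrelation(c1, c2, probes, g, minCov = 10)
  expect_gt(sc$r[sc$stratum == "all"], 0.8)
})
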