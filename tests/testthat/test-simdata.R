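test_that("probe panel covers the requested genome fraction", {
  cfg <- SimConfig(nChromosomes = 2L, chromLength = 1e6,
                   targetFraction = 0.04, readsPerCell = 10)
  g <- simulateGenome(cfg)
  bp <- sum(BiocGenerics::width(probeSet(g)))
  expect_gte(bp, 2 * 4e4 * 0.98)
  expect_lte(bp, 2 * 4e4 * 1.02)
  # merged, sorted, non-overlapping
  expect_identical(probeSet(g), sort(probeSet(g)))
  expect_identical(probeSet(g), GenomicRanges::reduce(probeSet(g)))
})

test_that("cpgRate 0 emits no CpG sites and the genome has no chance CGs", {
  cfg <- SimConfig(nChromosomes = 1L, chromLength = 5e4, cpgRate = 0,
                   nDMRs = 2L, readsPerCell = 10)
  g <- simulateGenome(cfg)
  expect_length(cpgSites(g), 0)
  expect_equal(Biostrings::countPattern("CG", refSeqs(g)[[1]]), 0)
})

test_that("fixed seed reproduces the simulation byte for byte", {
  cfg <- SimConfig(nChromosomes = 1L, chromLength = 3e4, cellsPerType = 3L,
                   readsPerCell = 40, nDMRs = 2L, seed = 99L)
  s1 <- simulateExperiment(cfg)
  s2 <- simulateExperiment(cfg)
  expect_identical(as.character(refSeqs(s1$genome)),
                   as.character(refSeqs(s2$genome)))
  expect_identical(as.character(s1$reads@read1), as.character(s2$reads@read1))
  expect_identical(as.character(s1$reads@read2), as.character(s2$reads@read2))
  expect_identical(s1$reads@headerComment, s2$reads@headerComment)
  d1 <- tempfile(); d2 <- tempfile()
  writeSimOutputs(s1, d1); writeSimOutputs(s2, d2)
  expect_identical(readLines(file.path(d1, "reference.fa")),
                   readLines(file.path(d2, "reference.fa")))
})

test_that("planted methylomes follow baseline, delta and direction rules", {
  cfg <- SimConfig(nChromosomes = 1L, chromLength = 2e5, baselineMeth = 0.8,
                   dmrDelta = 0.5, nDMRs = 6L, readsPerCell = 10)
  g <- simulateGenome(cfg)
  m <- plantMethylomes(cfg, g)
  d <- dmrTruth(m)
  # 0.8 + 0.5 does not fit in [0,1]: every DMR must be hypomethylated at 0.3
  expect_equal(S4Vectors::mcols(d)$methAffected, rep(0.3, length(d)))
  expect_equal(S4Vectors::mcols(d)$methOthers, rep(0.8, length(d)))
  # exactly one type differs inside each DMR; all types share the baseline
  # outside
  ov <- GenomicRanges::findOverlaps(cpgSites(g), d)
  inside <- unique(S4Vectors::queryHits(ov))
  outside <- setdiff(seq_along(cpgSites(g)), inside)
  expect_true(all(m@prob[, outside] == 0.8))
  nDiffer <- colSums(abs(m@prob[, inside, drop = FALSE] - 0.8) > 1e-9)
  expect_true(all(nDiffer == 1))
})

test_that("zero delta produces no effective DMRs", {
  cfg <- SimConfig(nChromosomes = 1L, chromLength = 1e5, dmrDelta = 0,
                   nDMRs = 4L, readsPerCell = 10)
  g <- simulateGenome(cfg)
  m <- plantMethylomes(cfg, g)
  expect_true(all(m@prob == cfg@baselineMeth))
})

test_that("scanning the probability tracks recovers the planted intervals", {
  cfg <- SimConfig(nChromosomes = 2L, chromLength = 2e5, nDMRs = 10L,
                   readsPerCell = 10)
  g <- simulateGenome(cfg)
  m <- plantMethylomes(cfg, g)
  # positions whose probability differs across types, found by brute scan
  differs <- which(apply(m@prob, 2L, function(p) diff(range(p)) > 1e-9))
  fromScan <- sort(unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(cpgSites(g), dmrTruth(m)))))
  expect_identical(differs, as.integer(fromScan))
})

test_that("fully methylated genome with perfect conversion leaves no converted base", {
  cfg <- SimConfig(nChromosomes = 1L, chromLength = 5e4, cellsPerType = 2L,
                   baselineMeth = 1, chMeth = 1, dmrDelta = 0, nDMRs = 1L,
                   conversionEfficiency = 1, errorRate = 0,
                   readsPerCell = 100)
  sim <- simulateExperiment(cfg)
  dm <- duplicateMap(simTruth(sim$reads))
  # every read must equal the raw reference fragment (no C->T, no G->A)
  ref <- refSeqs(sim$genome)[[1]]
  for (i in seq_len(50)) {
    frag <- as.character(Biostrings::subseq(ref, dm$fragStart[i], dm$fragEnd[i]))
    r1 <- as.character(sim$reads@read1[[i]])
    if (dm$strand[i] == "+")
      r1 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(r1)))
    expect_true(grepl(r1, frag, fixed = TRUE))
  }
})

test_that("duplicate map is a bijection when dupRate is zero", {
  cfg <- SimConfig(nChromosomes = 1L, chromLength = 5e4, cellsPerType = 2L,
                   dupRate = 0, readsPerCell = 60, nDMRs = 3L)
  sim <- simulateExperiment(cfg)
  dm <- duplicateMap(simTruth(sim$reads))
  expect_equal(anyDuplicated(dm$fragId), 0)
  expect_equal(anyDuplicated(dm$readId), 0)
})

test_that("expected on-target fraction follows the capture mixture closed form", {
  tr <- simTruth(getSharedSim()$sim$reads)
  w <- 10; t <- 0.04
  expect_equal(tr@expectedOnTargetFraction, w * t / (w * t + 1 - t))
  dm <- duplicateMap(tr)
  # observed fraction of emitted fragments overlapping probes by >= 1 bp
  frag <- GenomicRanges::GRanges(dm$chrom,
                                 IRanges::IRanges(dm$fragStart, dm$fragEnd))
  obs <- mean(IRanges::overlapsAny(frag, tr@probes))
  p0 <- tr@expectedOnTargetFraction
  se <- sqrt(p0 * (1 - p0) / nrow(dm))
  expect_lt(abs(obs - p0), 3.5 * se)
})

test_that("emitted per-CpG methylation matches the planted probabilities", {
  sh <- getSharedSim()
  tr <- simTruth(sh$sim$reads)
  cellType <- setNames(tr@cellTable$type, tr@cellTable$cell)
  calls <- sh$ex$calls[sh$ex$calls$context == "CG"]
  calls$type <- cellType[calls$cell]
  cpg <- cpgSites(sh$sim$genome)
  # map each stranded call position back to its CpG site index
  siteOfPos <- integer(max(BiocGenerics::end(cpg)) + 1L)
  siteOfPos[BiocGenerics::start(cpg)] <- seq_along(cpg)
  siteOfPos[BiocGenerics::start(cpg) + 1L] <- seq_along(cpg)
  calls$site <- siteOfPos[calls$pos]
  expect_true(all(calls$site > 0))
  agg <- calls[, .(obs = mean(meth), n = .N), by = .(site, type)]
  typeIdx <- as.integer(sub("type", "", agg$type))
  p <- sh$sim$methylomes@prob[cbind(typeIdx, agg$site)]
  big <- agg$n >= 25
  dev <- abs(agg$obs[big] - p[big])
  bound <- 4 * sqrt(p[big] * (1 - p[big]) / agg$n[big]) + 1e-9
  expect_gt(mean(dev <= bound), 0.995)
})

test_that("invalid configurations are rejected", {
  expect_error(SimConfig(targetFraction = 0), "targetFraction")
  expect_error(SimConfig(captureWeight = 0.5), "captureWeight")
  expect_error(SimConfig(readLength = 20), "readLength")
  expect_error(SimConfig(nDMRs = 1e5, dmrLength = 1500L,
                         nChromosomes = 1L, chromLength = 1e6),
               "exceed")
  cfg <- SimConfig(nChromosomes = 1L, chromLength = 2000, probeLength = 1900L,
                   nDMRs = 1L, dmrLength = 100L, readsPerCell = 10)
  expect_error(simulateGenome(cfg), "configuration error")
})
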