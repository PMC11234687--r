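mkAln <- function(chrom, start, seq, track = "CT", cell = "c1",
                  readId = "r1", mate = 1L, fragStart = start,
                  fragEnd = start + nchar(seq) - 1L) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start,
                                                start + nchar(seq) - 1L),
                               strand = ifelse(track == "CT", "+", "-"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    readId = readId, cell = cell, mate = mate, track = track,
    orient = "F", seq = seq, nmm = 0L, score = 60L,
    fragStart = fragStart, fragEnd = fragEnd, paired = TRUE)
  gr
}

test_that("duplicate removal is per cell and idempotent", {
  a <- c(mkAln("chr1", 100, "ACGT", cell = "c1", readId = "r1"),
         mkAln("chr1", 100, "ACGT", cell = "c1", readId = "r2"),
         mkAln("chr1", 100, "ACGT", cell = "c2", readId = "r3"))
  rd <- rmdupPE(a)
  m <- S4Vectors::mcols(rd$alignments)
  # same fragment twice in c1 collapses; the c2 copy survives
  expect_setequal(unique(m$cell), c("c1", "c2"))
  expect_equal(length(unique(m$readId[m$cell == "c1"])), 1)
  expect_equal(rd$nDuplicates, 1)
  rd2 <- rmdupPE(rd$alignments)
  expect_equal(rd2$nDuplicates, 0)
  expect_identical(rd2$alignments, rd$alignments)
})

test_that("retained fragment count matches simulator truth under heavy duplication", {
  cfg <- SimConfig(nChromosomes = 1L, chromLength = 1e5, cellsPerType = 3L,
                   dupRate = 1, readsPerCell = 150, errorRate = 0, nDMRs = 5L,
                   conversionEfficiency = 1, seed = 21L)
  sim <- simulateExperiment(cfg)
  dx <- demultiplexSim(sim$reads)
  al <- alignPairsToy(dx$read1, dx$read2genomic, dx$cells, sim$genome)
  rd <- rmdupPE(al$alignments)
  dm <- duplicateMap(simTruth(sim$reads))
  nTrue <- length(unique(dm$fragId))
  nKept <- length(unique(S4Vectors::mcols(rd$alignments)$readId))
  # fragments sharing coordinates by chance can collapse below the truth
  expect_lte(nKept, nTrue)
  expect_gte(nKept, nTrue * 0.99)
})

test_that("call extraction follows the strand-specific base rules", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTT"))
  ex <- extractCalls(mkAln("chr1", 1, "ACGTT"), ref)
  cg <- ex$calls[ex$calls$strand == "+"]
  expect_equal(cg$pos, 2L)
  expect_equal(cg$context, "CG")
  expect_true(cg$meth)
  # the Crick C of the same CpG sits at the reference G
  ga <- extractCalls(mkAln("chr1", 1, "ACGTT", track = "GA"), ref)$calls
  expect_equal(ga$pos, 3L)
  expect_equal(ga$strand, "-")
  expect_equal(ga$context, "CG")
  expect_true(ga$meth)

  ref2 <- Biostrings::DNAStringSet(c(chr1 = "ACATG"))
  ex2 <- extractCalls(mkAln("chr1", 1, "ATATG"), ref2)
  expect_equal(ex2$calls$pos, 2L)
  expect_equal(ex2$calls$context, "CH")
  expect_false(ex2$calls$meth)
  # a non-C/T base at a cytosine position is a counted mismatch, not a call
  ex3 <- extractCalls(mkAln("chr1", 1, "AGATG"), ref2)
  expect_equal(nrow(ex3$calls), 0)
  expect_equal(ex3$nMismatch, 1)
})

test_that("context assignment equals a brute-force reference scan", {
  set.seed(31)
  s <- paste0(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  ref <- Biostrings::DNAStringSet(c(chrZ = s))
  ctx <- referenceContextTable(ref)
  v <- strsplit(s, "")[[1]]
  for (i in sample(2000, 200)) {
    rows <- ctx[ctx$pos == i]
    if (v[i] == "C" && i < 2000) {
      expect_equal(rows[rows$strand == "+", context],
                   ifelse(v[i + 1] == "G", "CG", "CH"))
    } else if (v[i] == "G" && i > 1) {
      expect_equal(rows[rows$strand == "-", context],
                   ifelse(v[i - 1] == "C", "CG", "CH"))
    } else if (!v[i] %in% c("C", "G")) {
      expect_equal(nrow(rows), 0)
    }
  }
})

test_that("overlapping mates contribute a single call per site", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "AACGTTAACGTT"))
  a <- c(mkAln("chr1", 1, "AACGTTAACGTT", readId = "p", mate = 1L,
               fragStart = 1, fragEnd = 12),
         mkAln("chr1", 3, "TGTTAACGTT", readId = "p", mate = 2L,
               fragStart = 1, fragEnd = 12))
  ex <- extractCalls(a, ref)
  # CpG Watson Cs at 3 and 9: each counted once; mate 1 wins at pos 3
  cg <- ex$calls[ex$calls$strand == "+" & ex$calls$context == "CG"]
  expect_equal(cg$pos, c(3L, 9L))
  expect_true(cg$meth[cg$pos == 3])   # mate 1 read C, mate 2 read T
})

test_that("calls are conserved through chromosome and context splitting", {
  sh <- getSharedSim()
  calls <- sh$ex$calls
  d <- tempfile()
  paths <- writeCallFiles(calls, d)
  nLines <- function(p) {
    con <- gzfile(p); on.exit(close(con))
    length(readLines(con)) - 1L   # header
  }
  n <- sum(vapply(paths, nLines, numeric(1)))
  expect_equal(n, nrow(calls))
  # per-context totals also conserved
  byCtx <- table(calls$context)
  gotCtx <- vapply(c("CG", "CH"), function(ctx)
    sum(vapply(grep(ctx, paths, value = TRUE), nLines, numeric(1))),
    numeric(1))
  expect_equal(as.numeric(byCtx[names(gotCtx)]), as.numeric(gotCtx))
})

test_that("cell QC counts distinct stranded CG sites and survives empty cells", {
  calls <- data.table::data.table(
    cell = "c1", chrom = "chr1", pos = c(10L, 10L, 50L),
    strand = c("+", "+", "-"), context = "CG", meth = c(TRUE, TRUE, FALSE))
  qc <- cellQC(calls, rawReads = c(c1 = 10, empty = 5))
  expect_equal(qc$unique_cg_sites[qc$cell == "c1"], 2)
  expect_equal(qc$cg_meth_pct[qc$cell == "c1"], 100 * 2 / 3)
  row0 <- qc[qc$cell == "empty"]
  expect_equal(row0$unique_cg_sites, 0)
  expect_equal(row0$cg_per_raw_read, 0)
})

test_that("extraction recovers simulator truth per cell QC expectations", {
  sh <- getSharedSim()
  qc <- cellQC(sh$ex$calls, sh$al$alignments, sh$rd$alignments)
  expect_true(all(qc$unique_reads <= qc$aligned_reads))
  expect_true(all(qc$pct_unique >= 0 & qc$pct_unique <= 100))
  # independent set-based recount for one cell
  cell1 <- qc$cell[1]
  sub <- sh$ex$calls[sh$ex$calls$cell == cell1 & sh$ex$calls$context == "CG"]
  expect_equal(qc$unique_cg_sites[1],
               nrow(unique(sub[, c("chrom", "pos", "strand")])))
})
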