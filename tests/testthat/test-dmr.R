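library(GenomicRanges)

# build a cluster-aggregated matrix directly from count matrices
mkAgg <- function(meth, total, windows, kind = "sliding", size = 1500,
                  step = 500) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(meth = methods::as(Matrix::Matrix(meth, sparse = TRUE),
                                     "CsparseMatrix"),
                  total = methods::as(Matrix::Matrix(total, sparse = TRUE),
                                      "CsparseMatrix")),
    rowRanges = windows,
    colData = S4Vectors::DataFrame(cell = colnames(meth),
                                   row.names = colnames(meth)))
  new("MethWindowMatrix", se, windowKind = kind, windowSize = size,
      windowStep = step, context = "CG")
}

test_that("rest aggregation pools the non-focal clusters and conserves counts", {
  w <- makeWindows(c(chr = 1500), "tiling", 1500)
  meth <- cbind(A = 5, B = 10, C = 0)
  total <- cbind(A = 10, B = 10, C = 10)
  agg <- mkAgg(meth, total, w, kind = "tiling", size = 1500, step = 1500)
  r <- buildRestAggregate(agg, "A")
  expect_equal(r$methRest, 10)
  expect_equal(r$unmethRest, 10)
  expect_equal(r$methFocal + r$methRest, sum(meth))
  # two clusters: the rest is just the other cluster
  agg2 <- mkAgg(meth[, 1:2, drop = FALSE], total[, 1:2, drop = FALSE], w,
                kind = "tiling", size = 1500, step = 1500)
  r2 <- buildRestAggregate(agg2, "A")
  expect_equal(r2$methRest, 10)
  agg1 <- mkAgg(meth[, 1, drop = FALSE], total[, 1, drop = FALSE], w,
                kind = "tiling", size = 1500, step = 1500)
  expect_error(buildRestAggregate(agg1, "A"), "two clusters")
})

test_that("window tests match exact hypergeometric enumeration", {
  r <- testWindow(0, 20, 20, 0)
  expect_equal(r$methDiff, -100)
  expect_equal(r$p, 2 / choose(40, 20))
  r2 <- testWindow(5, 5, 50, 50)
  expect_equal(r2$methDiff, 0)
  expect_equal(r2$p, 1)
  r3 <- testWindow(4, 4, 100, 100)
  expect_false(r3$tested)
  expect_true(is.na(r3$p))
  # random 2x2 tables with totals <= 100 against stats::fisher.test
  set.seed(81)
  for (i in 1:200) {
    x <- sample(0:25, 4, TRUE)
    if (x[1] + x[2] < 10 || x[3] + x[4] < 10) next
    got <- testWindow(x[1], x[2], x[3], x[4])$p
    want <- stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("DMR calling filters, retains multi-cluster windows, and merges regions", {
  w <- makeWindows(c(chr = 4000), "sliding", 1500, 500)
  nw <- length(w)
  # two overlapping windows carry a strong focal hypomethylation
  meth <- matrix(80, nw, 3, dimnames = list(NULL, c("A", "B", "C")))
  total <- matrix(100, nw, 3, dimnames = list(NULL, c("A", "B", "C")))
  hot <- which(start(w) %in% c(1001, 1501))
  meth[hot, "A"] <- 0
  agg <- mkAgg(meth, total, w)
  dm <- callDMRs(agg)
  pass <- dm$windows[dm$windows$pass == TRUE]
  expect_setequal(pass$start[pass$cluster == "A"], c(1001, 1501))
  # rest aggregation makes B and C see the same contrast; both retained
  expect_true(all(c("B", "C") %in% pass$cluster))
  regA <- dm$regions[S4Vectors::mcols(dm$regions)$cluster == "A"]
  expect_equal(length(regA), 1)
  expect_equal(start(regA), 1001)
  expect_equal(end(regA), 3000)
  expect_equal(S4Vectors::mcols(regA)$nWindows, 2)
})

test_that("coverage gates windows out of testing", {
  w <- makeWindows(c(chr = 1500), "tiling", 1500)
  meth <- cbind(A = 0, B = 50)
  total <- cbind(A = 9, B = 100)
  agg <- mkAgg(meth, total, w, kind = "tiling", size = 1500, step = 1500)
  dm <- callDMRs(agg, minCov = 10)
  expect_true(all(!dm$windows$tested[dm$windows$cluster == "A"]))
})

test_that("null data produce essentially no discoveries at the q threshold", {
  cfg <- SimConfig(nChromosomes = 1L, chromLength = 3e5, cellsPerType = 8L,
                   dmrDelta = 0, readsPerCell = 500, nDMRs = 10L, seed = 83L)
  sim <- simulateExperiment(cfg)
  dx <- demultiplexSim(sim$reads)
  al <- alignPairsToy(dx$read1, dx$read2genomic, dx$cells, sim$genome)
  ex <- extractCalls(rmdupPE(al$alignments)$alignments, sim$genome)
  tr <- simTruth(sim$reads)
  tt <- setNames(tr@cellTable$type, tr@cellTable$cell)
  w <- makeWindows(c(chr1 = 3e5), "sliding", 1500, 500)
  wm <- meth2mtx(ex$calls, w, "CG")
  agg <- aggregateByCluster(wm, factor(tt))
  dm <- callDMRs(agg)
  # BH at q <= 1e-4 under a complete null: expect (almost surely) nothing
  expect_lte(sum(dm$windows$pass), 1)
})

test_that("annotation labels follow overlap and precedence rules", {
  ann <- list(promoter = GRanges("chr", IRanges::IRanges(1000, 2000)),
              enhancer = GRanges("chr", IRanges::IRanges(1500, 2500)))
  regions <- GRanges("chr", IRanges::IRanges(c(1600, 2100, 5000),
                                             c(1700, 2200, 5100)))
  got <- annotateDMRs(regions, ann)
  expect_equal(S4Vectors::mcols(got)$annotation,
               c("promoter", "enhancer", "intergenic"))
  expect_equal(S4Vectors::mcols(got)$annotationAll[1], "promoter,enhancer")
  expect_warning(annotateDMRs(regions, list()), "unannotated")
  # bitmap oracle over random annotation sets
  set.seed(84)
  sizes <- c(chr = 10000)
  for (rep in 1:3) {
    ann <- list(x = GRanges("chr", IRanges::IRanges(sample(9000, 5),
                                                    width = 400)),
                y = GRanges("chr", IRanges::IRanges(sample(9000, 5),
                                                    width = 250)))
    reg <- GRanges("chr", IRanges::IRanges(sample(9500, 20), width = 120))
    got <- annotateDMRs(reg, ann)
    bmx <- bitmapOf(ann$x, sizes); bmy <- bitmapOf(ann$y, sizes)
    for (i in seq_along(reg)) {
      hx <- bitmapOverlaps(bmx, "chr", start(reg)[i], end(reg)[i])
      hy <- bitmapOverlaps(bmy, "chr", start(reg)[i], end(reg)[i])
      want <- if (hx) "x" else if (hy) "y" else "intergenic"
      expect_equal(S4Vectors::mcols(got)$annotation[i], want)
    }
  }
})

test_that("bedgraph export centers records on the middle 500-bp third", {
  w <- makeWindows(c(chr = 4000), "sliding", 1500, 500)
  nw <- length(w)
  meth <- matrix(75, nw, 1, dimnames = list(NULL, "k1"))
  total <- matrix(100, nw, 1, dimnames = list(NULL, "k1"))
  agg <- mkAgg(meth, total, w)
  d <- tempfile()
  paths <- exportBedgraph(agg, d)
  bg <- data.table::fread(paths[1])
  expect_equal(bg$V2[1], 500)    # 0-based half-open central third
  expect_equal(bg$V3[1], 1000)
  expect_equal(bg$V4[1], 75)
  # adjacent windows yield non-overlapping records
  expect_true(all(bg$V2[-1] >= bg$V3[-nrow(bg)]))
  # round trip preserves values
  expect_equal(bg$V4, rep(75, nrow(bg)))
  tile <- makeWindows(c(chr = 4000), "tiling", 1500)
  aggBad <- mkAgg(meth[seq_along(tile), , drop = FALSE],
                  total[seq_along(tile), , drop = FALSE], tile,
                  kind = "tiling", size = 1500, step = 1500)
  expect_error(exportBedgraph(aggBad, d), "1500")
})

test_that("DMR set comparison partitions loci like a per-base oracle", {
  a <- GRanges("chr", IRanges::IRanges(c(100, 500), c(200, 700)))
  b <- a
  got <- compareDMRSets(list(A = a, B = b))
  expect_true(all(S4Vectors::mcols(got$loci)$label == "A&B"))
  dis <- compareDMRSets(list(A = GRanges("chr", IRanges::IRanges(1, 50)),
                             B = GRanges("chr", IRanges::IRanges(100, 150))))
  expect_setequal(as.character(S4Vectors::mcols(dis$loci)$label), c("A", "B"))
  expect_error(compareDMRSets(list(A = a)), "at least two")
  set.seed(85)
  sizes <- c(chr = 20000)
  for (rep in 1:3) {
    sets <- list(
      A = GRanges("chr", IRanges::IRanges(sample(19000, 8), width = 300)),
      B = GRanges("chr", IRanges::IRanges(sample(19000, 8), width = 200)),
      C = GRanges("chr", IRanges::IRanges(sample(19000, 4), width = 500)))
    got <- compareDMRSets(sets)
    # oracle: per-base union components and their set membership
    bmAll <- bitmapOf(do.call(c, unname(sets)), sizes)$chr
    r <- rle(bmAll)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    comp <- data.frame(start = starts[r$values], end = ends[r$values])
    expect_equal(length(got$loci), nrow(comp))
    bms <- lapply(sets, bitmapOf, chromSizes = sizes)
    for (i in seq_len(nrow(comp))) {
      member <- vapply(bms, bitmapOverlaps, logical(1), ch = "chr",
                       s = comp$start[i], e = comp$end[i])
      expect_equal(S4Vectors::mcols(got$loci)$label[i],
                   paste(names(sets)[member], collapse = "&"))
    }
  }
})
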