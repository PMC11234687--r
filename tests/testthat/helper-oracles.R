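# Independent brute-force oracles used across test files. These stay naive
# on purpose: per-base bitmaps for interval arithmetic, full distance scans
# for barcode matching, quadratic recounts for window assignment.

# per-base bitmap of a GRanges over a toy genome; returns a list of logical
# vectors, one per chromosome
bitmapOf <- function(gr, chromSizes) {
  out <- lapply(chromSizes, function(L) logical(L))
  for (i in seq_along(gr)) {
    ch <- as.character(GenomicRanges::seqnames(gr))[i]
    s <- max(1L, GenomicRanges::start(gr)[i])
    e <- min(chromSizes[[ch]], GenomicRanges::end(gr)[i])
    if (s <= e) out[[ch]][s:e] <- TRUE
  }
  out
}

bitmapBp <- function(bm) sum(vapply(bm, sum, numeric(1)))

# brute-force overlap (>= minOverlap bases) of one interval with a bitmap
bitmapOverlaps <- function(bm, ch, s, e, minOverlap = 1) {
  v <- bm[[ch]]
  s <- max(1L, s); e <- min(length(v), e)
  if (s > e) return(FALSE)
  sum(v[s:e]) >= minOverlap
}

# exhaustive Hamming matcher: unique minimal-distance entry within maxDist
bruteMatch <- function(obs, whitelist, maxDist = 2) {
  om <- strsplit(obs, "")
  wm <- strsplit(whitelist, "")
  t(vapply(om, function(o) {
    d <- vapply(wm, function(w) sum(o != w), numeric(1))
    mn <- min(d)
    if (mn > maxDist) return(c(NA_real_, NA_real_))    # nomatch
    if (sum(d == mn) > 1) return(c(-1, mn))            # ambiguous
    c(which.min(d), mn)
  }, numeric(2)))
}

# quadratic per-window recount of methylation calls
bruteWindowCount <- function(calls, windows, context) {
  cw <- as.character(GenomicRanges::seqnames(windows))
  ws <- GenomicRanges::start(windows)
  we <- GenomicRanges::end(windows)
  cells <- sort(unique(calls$cell))
  meth <- matrix(0, length(windows), length(cells),
                 dimnames = list(NULL, cells))
  tot <- meth
  sub <- calls[calls$context == context, ]
  for (r in seq_len(nrow(sub))) {
    hits <- which(cw == sub$chrom[r] & ws <= sub$pos[r] & we >= sub$pos[r])
    j <- match(sub$cell[r], cells)
    tot[hits, j] <- tot[hits, j] + 1
    meth[hits, j] <- meth[hits, j] + as.numeric(sub$meth[r])
  }
  list(meth = meth, total = tot)
}

# exhaustive bisulfite-aware substring search over a toy reference: all
# placements of the reduced read over both conversion tracks/orientations
# with <= maxMM mismatches
bruteAlign <- function(read, seqs, maxMM = 0) {
  hits <- list()
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  for (ch in names(seqs)) {
    g <- as.character(seqs[[ch]])
    gct <- chartr("C", "T", g)
    gga <- chartr("G", "A", g)
    for (case in list(list(q = chartr("C", "T", read), s = gct, lab = "CT.F"),
                      list(q = chartr("C", "T", rc),   s = gct, lab = "CT.R"),
                      list(q = chartr("G", "A", read), s = gga, lab = "GA.F"),
                      list(q = chartr("G", "A", rc),   s = gga, lab = "GA.R"))) {
      w <- nchar(case$q)
      qv <- strsplit(case$q, "")[[1]]
      sv <- strsplit(case$s, "")[[1]]
      nPlace <- length(sv) - w + 1L
      mm <- integer(nPlace)
      for (j in seq_len(w))
        mm <- mm + (sv[j:(j + nPlace - 1L)] != qv[j])
      ok <- which(mm <= maxMM)
      if (length(ok))
        hits[[length(hits) + 1L]] <- data.frame(chrom = ch, start = ok,
                                                space = case$lab,
                                                nmm = mm[ok])
    }
  }
  do.call(rbind, c(hits, list(data.frame(chrom = character(),
                                         start = integer(),
                                         space = character(),
                                         nmm = integer()))))
}

# one shared small simulated experiment, computed once per test run
sharedSimEnv <- new.env()
getSharedSim <- function() {
  if (is.null(sharedSimEnv$sim)) {
    cfg <- SimConfig(nChromosomes = 1L, chromLength = 2e5,
                     nCellTypes = 4L, cellsPerType = 10L,
                     nDMRs = 8L, readsPerCell = 400,
                     conversionEfficiency = 1, errorRate = 0, seed = 42L)
    sim <- simulateExperiment(cfg)
    dx <- demultiplexSim(sim$reads)
    al <- alignPairsToy(dx$read1, dx$read2genomic, dx$cells, sim$genome)
    rd <- rmdupPE(al$alignments)
    ex <- extractCalls(rd$alignments, sim$genome)
    sharedSimEnv$sim <- list(cfg = cfg, sim = sim, dx = dx, al = al,
                             rd = rd, ex = ex)
  }
  sharedSimEnv$sim
}
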