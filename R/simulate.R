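#' @importFrom GenomicRanges GRanges reduce findOverlaps seqnames start end width
#'   strand tileGenome slidingWindows countOverlaps
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits DataFrame
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels Seqinfo
NULL

# 21-base spacer standing in for the transposase mosaic-end recognition
# sequence that occupies bases 9-29 of read 2
.ME_SPACER <- "CTGTCTCTTATACACATCTGA"

#' Simulate a reference genome with CpG sites and a capture-probe panel
#'
#' Generates random chromosome sequences in which every CpG dinucleotide is
#' planted explicitly at rate \code{cpgRate} (guanines that would form a
#' chance CpG behind a background cytosine are re-drawn), so the planted
#' set is exactly the set of CpGs present. Probe intervals of
#' \code{probeLength} bp are placed one per equal-sized genome slot at a
#' random offset, giving a merged, sorted, non-overlapping panel whose
#' total width is within 1\% of \code{targetFraction} of the genome.
#'
#' @param config a \code{\link{SimConfig}}.
#' @return A \code{\link{SimGenome}}.
#' @export
#' @examples
#' g <- simulateGenome(SimConfig(nChromosomes = 1, chromLength = 5e4))
#' sum(BiocGenerics::width(probeSet(g))) / 5e4
simulateGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  L <- as.integer(config@chromLength)
  nProbesTotal <- round(config@targetFraction * config@nChromosomes * L /
                          config@probeLength)
  if (nProbesTotal < 1)
    stop("configuration error: target fraction too small to place one probe")
  nProbes <- max(1L, round(nProbesTotal / config@nChromosomes))
  slot <- L %/% nProbes
  if (slot <= config@probeLength + 2L)
    stop("configuration error: probes longer than available genome slots")

  withSeed(deriveSeed(config@seed, "genome"), {
    chromNames <- paste0("chr", seq_len(config@nChromosomes))
    seqs <- vector("list", config@nChromosomes)
    cpgList <- vector("list", config@nChromosomes)
    probeList <- vector("list", config@nChromosomes)
    for (ci in seq_len(config@nChromosomes)) {
      base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      # remove chance CpGs: any G directly following a C is re-drawn
      bad <- which(base[-L] == "C" & base[-1] == "G") + 1L
      while (length(bad)) {
        base[bad] <- sample(c("A", "C", "T"), length(bad), replace = TRUE)
        bad <- which(base[-L] == "C" & base[-1] == "G") + 1L
      }
      # plant CpG dinucleotides; thin overlapping/adjacent candidates
      cand <- which(runif(L - 2L) < config@cpgRate)
      if (length(cand)) {
        keep <- cand[c(TRUE, diff(cand) > 1L)]
        base[keep] <- "C"
        base[keep + 1L] <- "G"
        # planting may create a new CG immediately left/right; re-scan
        cpg <- which(base[-L] == "C" & base[-1] == "G")
      } else cpg <- integer()
      seqs[[ci]] <- paste0(base, collapse = "")
      cpgList[[ci]] <- cpg      # 1-based Watson C position
      starts <- (seq_len(nProbes) - 1L) * slot +
        sample.int(slot - config@probeLength - 1L, nProbes, replace = TRUE)
      probeList[[ci]] <- starts # 1-based start
    }
    dna <- Biostrings::DNAStringSet(unlist(seqs))
    names(dna) <- chromNames
    si <- Seqinfo(seqnames = chromNames, seqlengths = rep(L, length(chromNames)))
    cpgGR <- GRanges(rep(chromNames, lengths(cpgList)),
                     IRanges(unlist(cpgList), width = 2), seqinfo = si)
    probeGR <- reduce(GRanges(rep(chromNames, lengths(probeList)),
                              IRanges(unlist(probeList),
                                      width = config@probeLength),
                              seqinfo = si))
    new("SimGenome", seq = dna, cpgSites = cpgGR, probes = probeGR)
  })
}

#' Plant cell-type-specific methylomes
#'
#' Assigns every CpG the baseline methylation probability for every cell
#' type, then plants \code{nDMRs} non-overlapping DMR intervals of
#' \code{dmrLength} bp in which exactly one cell type differs by
#' \code{dmrDelta} (hypo- or hypermethylated, whichever direction fits in
#' \[0,1\] without clipping; clipped otherwise). A fraction
#' \code{dmrOnTargetFrac} of DMRs is centred on probe intervals, the rest
#' placed off-target.
#'
#' @param config a \code{\link{SimConfig}}.
#' @param genome a \code{\link{SimGenome}} from \code{\link{simulateGenome}}.
#' @return A \code{\link{SimMethylomes}}.
#' @export
plantMethylomes <- function(config, genome) {
  stopifnot(is(config, "SimConfig"), is(genome, "SimGenome"))
  cpg <- genome@cpgSites
  probes <- genome@probes
  nT <- config@nCellTypes
  withSeed(deriveSeed(config@seed, "methylomes"), {
    prob <- matrix(config@baselineMeth, nrow = nT, ncol = length(cpg),
                   dimnames = list(paste0("type", seq_len(nT)), NULL))
    nOn <- round(config@nDMRs * config@dmrOnTargetFrac)
    nOff <- config@nDMRs - nOn
    half <- config@dmrLength %/% 2L
    # on-target: centre a DMR on a sampled probe interval
    if (nOn > length(probes))
      stop("n_dmrs exceeds placeable on-target loci")
    onIdx <- sample(length(probes), nOn)
    onGR <- GenomicRanges::resize(probes[onIdx], width = config@dmrLength,
                                  fix = "center")
    onGR <- GenomicRanges::trim(onGR)
    # off-target: random starts rejected until clear of probes and other DMRs
    offGR <- GRanges(seqinfo = GenomeInfoDb::seqinfo(probes))
    L <- config@chromLength
    tries <- 0L
    while (length(offGR) < nOff) {
      tries <- tries + 1L
      if (tries > 200L) stop("n_dmrs exceeds placeable off-target loci")
      need <- nOff - length(offGR)
      cand <- GRanges(sample(seqlevels(probes), need, replace = TRUE),
                      IRanges(sample.int(as.integer(L) - config@dmrLength,
                                         need, replace = TRUE),
                              width = config@dmrLength),
                      seqinfo = GenomeInfoDb::seqinfo(probes))
      ok <- !overlapsAny(cand, probes) & !overlapsAny(cand, onGR) &
        !overlapsAny(cand, offGR)
      cand <- cand[ok]
      cand <- cand[!duplicated(cand)]
      if (length(cand)) {
        keep <- !overlapsAny(cand, cand, type = "any") |
          countOverlaps(cand, cand) == 1L
        offGR <- c(offGR, cand[keep])
      }
    }
    offGR <- head(offGR, nOff)
    dmrs <- c(onGR, offGR)
    mcols(dmrs)$onTarget <- rep(c(TRUE, FALSE), c(length(onGR), length(offGR)))
    # drop any residual overlaps among on-target DMRs (possible when probes
    # sit closer than dmrLength)
    keep <- rep(TRUE, length(dmrs))
    ov <- findOverlaps(dmrs, dmrs)
    ov <- ov[queryHits(ov) < subjectHits(ov)]
    if (length(ov)) keep[subjectHits(ov)] <- FALSE
    dmrs <- dmrs[keep]
    dmrs <- sort(dmrs)

    types <- rep_len(seq_len(nT), length(dmrs))[sample.int(length(dmrs))]
    base <- config@baselineMeth
    up <- base + config@dmrDelta <= 1
    dn <- base - config@dmrDelta >= 0
    dirs <- vapply(seq_along(dmrs), function(i) {
      if (up && dn) sample(c(1, -1), 1) else if (dn) -1 else if (up) 1 else
        sample(c(1, -1), 1)
    }, numeric(1))
    affected <- pmin(1, pmax(0, base + dirs * config@dmrDelta))
    mcols(dmrs)$type <- paste0("type", types)
    mcols(dmrs)$methAffected <- affected
    mcols(dmrs)$methOthers <- base
    ov <- findOverlaps(cpg, dmrs)
    if (length(ov))
      prob[cbind(types[subjectHits(ov)], queryHits(ov))] <-
        affected[subjectHits(ov)]
    new("SimMethylomes", prob = prob, dmrs = dmrs)
  })
}

#' Generate Hamming-separated barcode whitelists
#'
#' Three whitelists mirroring the combinatorial-index design: two 10-bp PCR
#' indices and the 8-bp tagmentation index. Entries are sampled greedily to
#' keep all pairwise Hamming distances >= 3 so that single-substitution
#' errors are uniquely correctable.
#'
#' @param n1,n2,n3 whitelist sizes for index 1, 2 and 3.
#' @param len1,len2,len3 barcode lengths.
#' @param seed RNG seed.
#' @return List of three character vectors.
#' @export
makeWhitelists <- function(n1 = 8, n2 = 12, n3 = 96,
                           len1 = 10, len2 = 10, len3 = 8, seed = 1L) {
  gen <- function(n, len) {
    out <- character(0)
    mat <- NULL
    while (length(out) < n) {
      cand <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
      cc <- strsplit(cand, "")[[1]]
      if (is.null(mat) || all(.hammingToEntry(mat, cc) >= 3)) {
        out <- c(out, cand)
        mat <- rbind(mat, cc)
      }
    }
    out
  }
  withSeed(deriveSeed(seed, "whitelists"),
           list(index1 = gen(n1, len1), index2 = gen(n2, len2),
                index3 = gen(n3, len3)))
}

# sample fragment start positions: capture is modelled as a two-component
# mixture -- with probability w*t/(w*t + 1 - t) a fragment overlapping a probe
# (uniform over such placements), otherwise a fragment clear of all probes --
# so the expected on-target fraction equals the closed form exactly and a
# captureWeight of 1 reduces to the panel's bp fraction
.sampleFragments <- function(n, inserts, genome, pOn) {
  chromNames <- names(genome@seq)
  L <- Biostrings::width(genome@seq)
  onTarget <- runif(n) < pOn
  chromIdx <- integer(n)
  startPos <- integer(n)   # 0-based
  pr <- genome@probes
  prChrom <- as.character(seqnames(pr))
  prStart <- start(pr) - 1L   # 0-based
  prEnd <- end(pr)            # 0-based half-open end
  idxOn <- which(onTarget)
  if (length(idxOn)) {
    # choose a probe weighted by the number of overlapping placements
    wts <- function(ins) (prEnd - prStart) + ins - 1L
    ins <- inserts[idxOn]
    # placements per probe depend on the fragment's insert; sample probe by
    # weight for each fragment individually (weights vary little, use mean)
    p <- sample.int(length(pr), length(idxOn), replace = TRUE,
                    prob = (prEnd - prStart) + mean(ins))
    Lp <- L[match(prChrom[p], chromNames)]
    lo <- pmax(0L, prStart[p] - ins + 1L)
    hi <- pmin(prEnd[p] - 1L, Lp - ins)
    s <- lo + floor(runif(length(idxOn)) * (pmax(hi - lo, 0L) + 1L))
    chromIdx[idxOn] <- match(prChrom[p], chromNames)
    startPos[idxOn] <- as.integer(s)
  }
  idxOff <- which(!onTarget)
  while (length(idxOff)) {
    ci <- sample.int(length(chromNames), length(idxOff), replace = TRUE,
                     prob = L)
    s <- floor(runif(length(idxOff)) * (L[ci] - inserts[idxOff]))
    cand <- GRanges(chromNames[ci], IRanges(s + 1L, width = inserts[idxOff]))
    bad <- overlapsAny(cand, pr)
    ok <- which(!bad)
    chromIdx[idxOff[ok]] <- ci[ok]
    startPos[idxOff[ok]] <- as.integer(s[ok])
    idxOff <- idxOff[bad]
  }
  data.table(chrom = chromIdx, start = startPos, insert = inserts,
             onTarget = onTarget)
}

# apply bisulfite conversion and sequencing errors to a batch of extracted
# spans held as an n x w character matrix, in genome (Watson) orientation.
# watson: logical per row (TRUE = Watson/C->T fragment). typeIdx: cell-type
# row index into probTrack lookup. posToSiteW/posToSiteC: per-chromosome
# integer lookups position -> CpG column (0 = non-CpG cytosine).
.convertMatrix <- function(mat, spanStart, chromIdx, watson, typeIdx,
                           posLookupW, posLookupC, prob, chMeth, convEff,
                           errRate) {
  w <- ncol(mat)
  n <- nrow(mat)
  tgt <- ifelse(watson, "C", "G")
  isTgt <- mat == tgt
  idx <- which(isTgt)
  if (length(idx)) {
    row <- ((idx - 1L) %% n) + 1L
    col <- ((idx - 1L) %/% n) + 1L
    pos <- spanStart[row] + col    # 1-based genome position
    site <- integer(length(idx))
    for (ci in seq_along(posLookupW)) {
      sel <- chromIdx[row] == ci
      if (!any(sel)) next
      selW <- sel & watson[row]
      selC <- sel & !watson[row]
      if (any(selW)) site[selW] <- posLookupW[[ci]][pos[selW]]
      if (any(selC)) site[selC] <- posLookupC[[ci]][pos[selC]]
    }
    p <- rep(chMeth, length(idx))
    cp <- site > 0L
    if (any(cp)) p[cp] <- prob[cbind(typeIdx[row[cp]], site[cp])]
    meth <- runif(length(idx)) < p
    conv <- !meth & (runif(length(idx)) < convEff)
    if (any(conv)) {
      rep1 <- ifelse(watson[row[conv]], "T", "A")
      mat[idx[conv]] <- rep1
    }
  }
  if (errRate > 0) {
    ne <- rbinom(1L, n * w, errRate)
    if (ne > 0) {
      eidx <- sample.int(n * w, ne)
      cur <- mat[eidx]
      alt <- vapply(cur, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
        USE.NAMES = FALSE)
      mat[eidx] <- alt
    }
  }
  mat
}

#' Emit paired bisulfite reads with ground truth
#'
#' Samples per-cell fragment counts (negative binomial), fragment positions
#' (capture-weighted mixture, log-normal inserts, both strands equally),
#' applies bisulfite conversion against the planted methylomes (methylated
#' cytosines protected; unmethylated converted with probability
#' \code{conversionEfficiency}), adds sequencing errors, replicates PCR
#' duplicates as exact re-emissions, and assembles the combinatorial-index
#' read structure: read 1 genomic, read 2 = 8-bp tagmentation barcode +
#' 21-bp mosaic-end spacer + genomic, PCR indices in the header comment.
#'
#' @param config a \code{\link{SimConfig}}.
#' @param genome a \code{\link{SimGenome}}.
#' @param meth a \code{\link{SimMethylomes}}.
#' @param whitelists optional list from \code{\link{makeWhitelists}}.
#' @return A \code{\link{SimReads}} (reads plus \code{\link{SimTruth}}).
#' @export
emitReads <- function(config, genome, meth, whitelists = NULL) {
  stopifnot(is(config, "SimConfig"), is(genome, "SimGenome"),
            is(meth, "SimMethylomes"))
  if (is.null(whitelists)) whitelists <- makeWhitelists(seed = config@seed)
  nCells <- config@nCellTypes * config@cellsPerType
  combos <- expand.grid(i3 = seq_along(whitelists$index3),
                        i2 = seq_along(whitelists$index2),
                        i1 = seq_along(whitelists$index1))
  if (nCells > nrow(combos)) stop("whitelists too small for requested cells")
  rl <- config@readLength
  g2len <- rl - 29L
  t <- config@targetFraction
  wgt <- config@captureWeight
  pOn <- wgt * t / (wgt * t + 1 - t)

  withSeed(deriveSeed(config@seed, "reads"), {
    pick <- sample.int(nrow(combos), nCells)
    cellBC <- data.frame(
      i1 = whitelists$index1[combos$i1[pick]],
      i2 = whitelists$index2[combos$i2[pick]],
      i3 = whitelists$index3[combos$i3[pick]])
    cellBC$cell <- paste0(cellBC$i1, cellBC$i2, cellBC$i3)
    type <- rep(seq_len(config@nCellTypes), each = config@cellsPerType)
    cellTab <- data.frame(cell = cellBC$cell, type = paste0("type", type),
                          index1 = cellBC$i1, index2 = cellBC$i2,
                          index3 = cellBC$i3, stringsAsFactors = FALSE)

    nRaw <- rnbinom(nCells, size = config@readDispersion,
                    mu = config@readsPerCell)
    nRaw <- pmax(nRaw, 1L)
    nUniq <- pmax(1L, round(nRaw / (1 + config@dupRate)))
    totUniq <- sum(nUniq)
    cellIdx <- rep.int(seq_len(nCells), nUniq)
    inserts <- pmax(as.integer(round(rlnorm(totUniq, config@insertMean,
                                            config@insertSd))), 1L)
    skip <- inserts < rl
    nSkipped <- sum(skip)
    cellIdx <- cellIdx[!skip]
    inserts <- inserts[!skip]
    totUniq <- length(inserts)
    frags <- .sampleFragments(totUniq, inserts, genome, pOn)
    frags[, `:=`(cell = cellIdx, watson = runif(.N) < 0.5,
                 fragId = seq_len(.N))]
    copies <- 1L + rpois(totUniq, config@dupRate)

    # genome-coordinate spans of the two sequenced segments (1-based here)
    # watson: r2 = [start, start+g2len) fwd ; r1 = [start+ins-rl, start+ins) rev
    # crick : r2 = [start+ins-g2len, start+ins) rev ; r1 = [start, start+rl) fwd
    s <- frags$start   # 0-based
    ins <- frags$insert
    r2s <- ifelse(frags$watson, s, s + ins - g2len) + 1L
    r1s <- ifelse(frags$watson, s + ins - rl, s) + 1L
    chromNames <- names(genome@seq)

    # CpG position lookups per chromosome (Watson C at start, Crick C at
    # start+1), value = column of the probability matrix
    cpg <- genome@cpgSites
    posLookupW <- posLookupC <- vector("list", length(chromNames))
    for (ci in seq_along(chromNames)) {
      lw <- integer(Biostrings::width(genome@seq)[ci])
      lc <- lw
      onC <- which(as.character(seqnames(cpg)) == chromNames[ci])
      lw[start(cpg)[onC]] <- onC
      lc[start(cpg)[onC] + 1L] <- onC
      posLookupW[[ci]] <- lw
      posLookupC[[ci]] <- lc
    }

    extractSpans <- function(starts, width) {
      out <- character(length(starts))
      for (ci in seq_along(chromNames)) {
        sel <- which(frags$chrom == ci)
        if (!length(sel)) next
        v <- Biostrings::extractAt(
          genome@seq[[ci]], IRanges(starts[sel], width = width))
        out[sel] <- as.character(v)
      }
      out
    }
    typeIdx <- type[frags$cell]
    convertGroup <- function(starts, width) {
      mat <- .charMatrix(extractSpans(starts, width), width)
      .convertMatrix(mat, starts - 1L, frags$chrom, frags$watson, typeIdx,
                     posLookupW, posLookupC, meth@prob, config@chMeth,
                     config@conversionEfficiency, config@errorRate)
    }
    m1 <- convertGroup(r1s, rl)
    m2 <- convertGroup(r2s, g2len)
    r1g <- .collapseRows(m1)
    r2g <- .collapseRows(m2)
    # orientation: read 1 is reverse for Watson fragments, read 2 reverse for
    # Crick fragments
    flip1 <- frags$watson
    if (any(flip1)) r1g[flip1] <- .revcompChar(r1g[flip1])
    flip2 <- !frags$watson
    if (any(flip2)) r2g[flip2] <- .revcompChar(r2g[flip2])

    # expand PCR duplicates (exact re-emissions), shuffle read order
    expIdx <- rep.int(seq_len(totUniq), copies)
    expIdx <- expIdx[sample.int(length(expIdx))]
    nReads <- length(expIdx)
    readId <- sprintf("R%07d", seq_len(nReads))
    i3 <- cellBC$i3[frags$cell[expIdx]]
    read2full <- paste0(i3, .ME_SPACER, r2g[expIdx])
    read1full <- r1g[expIdx]
    # sequencing errors on the barcode bases of read 2 and the header indices
    mutate <- function(x, rate) {
      if (rate <= 0) return(x)
      m <- .charMatrix(x)
      ne <- rbinom(1L, length(m), rate)
      if (ne > 0) {
        ei <- sample.int(length(m), ne)
        m[ei] <- vapply(m[ei], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
          USE.NAMES = FALSE)
      }
      .collapseRows(m)
    }
    i1obs <- mutate(cellBC$i1[frags$cell[expIdx]], config@errorRate)
    i2obs <- mutate(cellBC$i2[frags$cell[expIdx]], config@errorRate)
    bc3 <- substr(read2full, 1L, 8L)
    bc3 <- mutate(bc3, config@errorRate)
    substr(read2full, 1L, 8L) <- bc3
    hdr <- paste0("1:N:0:", i1obs, "+", i2obs)

    r1set <- Biostrings::DNAStringSet(read1full)
    r2set <- Biostrings::DNAStringSet(read2full)
    names(r1set) <- names(r2set) <- readId

    truth <- new("SimTruth", cellTable = cellTab, dmrs = meth@dmrs,
                 probes = genome@probes,
                 expectedOnTargetFraction = pOn,
                 duplicateMap = data.frame(readId = readId,
                                           fragId = frags$fragId[expIdx],
                                           cell = cellTab$cell[frags$cell[expIdx]],
                                           chrom = chromNames[frags$chrom[expIdx]],
                                           fragStart = frags$start[expIdx] + 1L,
                                           fragEnd = frags$start[expIdx] +
                                             frags$insert[expIdx],
                                           strand = ifelse(frags$watson[expIdx],
                                                           "+", "-"),
                                           onTarget = frags$onTarget[expIdx],
                                           stringsAsFactors = FALSE),
                 whitelists = whitelists, nSkipped = as.integer(nSkipped))
    new("SimReads", read1 = r1set, read2 = r2set, headerComment = hdr,
        truth = truth)
  })
}

#' Run the full simulation
#'
#' Convenience wrapper: genome, methylomes, reads.
#'
#' @param config a \code{\link{SimConfig}}.
#' @return List with \code{genome}, \code{methylomes}, \code{reads}.
#' @export
#' @examples
#' sim <- simulateExperiment(SimConfig(nChromosomes = 1, chromLength = 5e4,
#'   cellsPerType = 5, readsPerCell = 50, nDMRs = 4L))
#' sim$reads
simulateExperiment <- function(config) {
  genome <- simulateGenome(config)
  meth <- plantMethylomes(config, genome)
  reads <- emitReads(config, genome, meth)
  list(genome = genome, methylomes = meth, reads = reads)
}

#' Write simulator outputs to disk
#'
#' FASTA reference, gzipped paired FASTQ, probe BED (0-based half-open),
#' and TSV truth tables.
#'
#' @param sim list from \code{\link{simulateExperiment}}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
writeSimOutputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ref = file.path(dir, "reference.fa"),
             r1 = file.path(dir, "reads_R1.fastq.gz"),
             r2 = file.path(dir, "reads_R2.fastq.gz"),
             probes = file.path(dir, "probes.bed"),
             cells = file.path(dir, "cell_table.tsv"),
             dmrs = file.path(dir, "dmr_truth.tsv"),
             dupmap = file.path(dir, "duplicate_map.tsv"),
             wl1 = file.path(dir, "whitelist_index1.txt"),
             wl2 = file.path(dir, "whitelist_index2.txt"),
             wl3 = file.path(dir, "whitelist_index3.txt"))
  Biostrings::writeXStringSet(sim$genome@seq, paths["ref"])
  writeFastq(sim$reads@read1, paths["r1"],
             comment = sim$reads@headerComment)
  writeFastq(sim$reads@read2, paths["r2"],
             comment = sim$reads@headerComment)
  writeBed(sim$genome@probes, paths["probes"])
  tr <- sim$reads@truth
  fwrite(tr@cellTable, paths["cells"], sep = "\t")
  dm <- as.data.frame(tr@dmrs)
  dm$start <- dm$start - 1L  # BED-style 0-based half-open in the truth table
  fwrite(dm, paths["dmrs"], sep = "\t")
  fwrite(tr@duplicateMap, paths["dupmap"], sep = "\t")
  writeLines(tr@whitelists$index1, paths["wl1"])
  writeLines(tr@whitelists$index2, paths["wl2"])
  writeLines(tr@whitelists$index3, paths["wl3"])
  invisible(paths)
}

#' Write a BED file (0-based half-open) from a GRanges
#' @param gr a \code{GRanges}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a GRanges
#' @param path BED path (first three columns used).
#' @return A \code{GRanges} (1-based internally).
#' @export
readBed <- function(path) {
  df <- fread(path, header = FALSE)
  GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]))
}
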