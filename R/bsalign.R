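.asGenomeSeq <- function(genome) {
  if (is(genome, "SimGenome")) return(genome@seq)
  if (is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  stop("genome must be a SimGenome, DNAStringSet or FASTA path")
}

.genomeSeqinfo <- function(seqs) {
  Seqinfo(seqnames = names(seqs), seqlengths = Biostrings::width(seqs))
}

# exact hits of reduced queries (character, constant width) against reduced
# chromosome subjects; returns data.table(readIdx, chrom, start)
.exactHits <- function(queries, subjects) {
  if (!length(queries))
    return(data.table(readIdx = integer(), chrom = integer(),
                      start = integer()))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(queries))
  out <- vector("list", length(subjects))
  for (ci in seq_along(subjects)) {
    m <- Biostrings::matchPDict(pd, subjects[[ci]])
    nh <- S4Vectors::elementNROWS(m)
    if (sum(nh) == 0) next
    u <- unlist(m)
    out[[ci]] <- data.table(readIdx = rep.int(seq_along(nh), nh),
                            chrom = ci, start = BiocGenerics::start(u))
  }
  rbindlist(out)
}

# pigeonhole seeded search allowing <= maxMM mismatches: three disjoint exact
# seeds generate candidate placements which are then verified in full
.seededHits <- function(queries, subjects, subjChar, maxMM) {
  w <- nchar(queries[1])
  sw <- w %/% 3L
  if (sw < 8L) return(data.table())
  offs <- c(0L, sw, 2L * sw)
  cand <- vector("list", length(offs))
  for (k in seq_along(offs)) {
    seeds <- substr(queries, offs[k] + 1L, offs[k] + sw)
    h <- .exactHits(seeds, subjects)
    if (nrow(h)) {
      h[, start := start - offs[k]]
      cand[[k]] <- h
    }
  }
  cand <- rbindlist(cand)
  if (!nrow(cand)) return(cand)
  cand <- unique(cand)
  maxLen <- nchar(subjChar)
  cand <- cand[start >= 1L & start + w - 1L <= maxLen[chrom]]
  if (!nrow(cand)) return(cand)
  ref <- substring(subjChar[cand$chrom], cand$start, cand$start + w - 1L)
  qm <- .charMatrix(queries[cand$readIdx], w)
  rm_ <- .charMatrix(ref, w)
  cand[, nmm := rowSums(qm != rm_)]
  cand[nmm <= maxMM]
}

#' Bisulfite-aware toy alignment of demultiplexed read pairs
#'
#' Aligns each mate by exact matching of its C-to-T-reduced form against
#' the C-to-T-reduced genome (Watson strand / C-to-T conversion track) and
#' of its reverse complement's G-to-A-reduced form against the
#' G-to-A-reduced genome (Crick strand / G-to-A track), in both
#' orientations; reads without an exact hit are rescued by a pigeonhole
#' seeded search allowing up to \code{maxMismatch} substitutions (no
#' indels). A unique best hit is required; equal-score multi-mappers are
#' discarded and counted. Mates are then paired (same chromosome, same
#' strand/track, opposite orientations, insert at most \code{maxInsert})
#' and fragment coordinates recorded.
#'
#' The \code{swapMates} switch encodes the adapter convention of
#' combinatorially indexed libraries, where the tagmentation end (the
#' genomic portion of raw read 2) plays the role that read 1 plays in a
#' conventional bisulfite library: with \code{swapMates = TRUE} (default)
#' it is reported as mate 1.
#'
#' @param read1 \code{DNAStringSet} of read-1 sequences (named by read id).
#' @param read2genomic \code{DNAStringSet} of restructured read-2 genomic
#'   portions.
#' @param cells per-pair cell ids.
#' @param genome \code{SimGenome}, \code{DNAStringSet} or FASTA path.
#' @param maxMismatch maximum substitutions in the rescue stage (default 2).
#' @param swapMates see above.
#' @param maxInsert maximum fragment length when pairing.
#' @return List: \code{alignments} (a \code{GRanges}, one range per aligned
#'   mate; strand \code{+} = Watson; metadata \code{readId}, \code{cell},
#'   \code{mate}, \code{track}, \code{orient}, \code{seq} in genome
#'   orientation, \code{nmm}, \code{score}, \code{fragStart},
#'   \code{fragEnd} 1-based inclusive) and \code{stats} (aligned /
#'   multi-mapped / unaligned mate counts, paired fragment count).
#' @export
alignPairsToy <- function(read1, read2genomic, cells, genome,
                          maxMismatch = 2, swapMates = TRUE,
                          maxInsert = 2000) {
  seqs <- .asGenomeSeq(genome)
  si <- .genomeSeqinfo(seqs)
  chromNames <- names(seqs)
  gChar <- as.character(seqs)
  gCTchar <- chartr("C", "T", gChar)
  gGAchar <- chartr("G", "A", gChar)
  gCT <- lapply(gCTchar, Biostrings::DNAString)
  gGA <- lapply(gGAchar, Biostrings::DNAString)

  if (swapMates) {
    mates <- list(`1` = read2genomic, `2` = read1)
  } else {
    mates <- list(`1` = read1, `2` = read2genomic)
  }
  readIds <- names(read1)
  if (is.null(readIds)) readIds <- sprintf("R%07d", seq_along(read1))

  alignMate <- function(reads) {
    qc <- as.character(reads)
    res <- vector("list", 0L)
    for (grpW in sort(unique(nchar(qc)))) {
      sel <- which(nchar(qc) == grpW)
      q <- qc[sel]
      qrc <- .revcompChar(q)
      spaces <- list(
        list(qr = chartr("C", "T", q),   subj = gCT, schar = gCTchar,
             strand = "+", track = "CT", orient = "F"),
        list(qr = chartr("C", "T", qrc), subj = gCT, schar = gCTchar,
             strand = "+", track = "CT", orient = "R"),
        list(qr = chartr("G", "A", q),   subj = gGA, schar = gGAchar,
             strand = "-", track = "GA", orient = "F"),
        list(qr = chartr("G", "A", qrc), subj = gGA, schar = gGAchar,
             strand = "-", track = "GA", orient = "R"))
      hits <- vector("list", length(spaces))
      for (sp in seq_along(spaces)) {
        s <- spaces[[sp]]
        h <- .exactHits(s$qr, s$subj)
        if (nrow(h)) h[, nmm := 0L] else h <- data.table(
          readIdx = integer(), chrom = integer(), start = integer(),
          nmm = integer())
        hits[[sp]] <- h[, space := sp]
      }
      hi <- rbindlist(hits)
      found <- unique(hi$readIdx)
      miss <- setdiff(seq_along(q), found)
      if (length(miss) && maxMismatch > 0) {
        resc <- vector("list", length(spaces))
        for (sp in seq_along(spaces)) {
          s <- spaces[[sp]]
          h <- .seededHits(s$qr[miss], s$subj, s$schar, maxMismatch)
          if (nrow(h)) {
            h[, readIdx := miss[readIdx]]
            resc[[sp]] <- h[, space := sp]
          }
        }
        hi <- rbindlist(list(hi, rbindlist(resc)), use.names = TRUE)
      }
      if (!nrow(hi)) next
      # unique best hit per read across all spaces
      setorder(hi, readIdx, nmm)
      hi[, rank := seq_len(.N), by = readIdx]
      nBest <- hi[, sum(nmm == nmm[1]), by = readIdx]
      bestUnique <- nBest$readIdx[nBest$V1 == 1L]
      hi <- hi[rank == 1L]
      hi[, multi := !(readIdx %in% bestUnique)]
      hi[, globalIdx := sel[readIdx]]
      hi[, width := grpW]
      res[[length(res) + 1L]] <- hi
    }
    rbindlist(res)
  }

  buildMate <- function(hi, reads, mateNo) {
    if (!nrow(hi)) return(NULL)
    aln <- hi[multi == FALSE]
    sp <- aln$space
    orient <- c("F", "R", "F", "R")[sp]
    strnd <- c("+", "+", "-", "-")[sp]
    seqChar <- as.character(reads)[aln$globalIdx]
    flipped <- orient == "R"
    if (any(flipped)) seqChar[flipped] <- .revcompChar(seqChar[flipped])
    data.table(readId = readIds[aln$globalIdx],
               cell = cells[aln$globalIdx],
               chrom = chromNames[aln$chrom], start = aln$start,
               end = aln$start + aln$width - 1L,
               strand = strnd, track = c("CT", "CT", "GA", "GA")[sp],
               orient = orient, mate = mateNo, nmm = aln$nmm,
               seq = seqChar,
               nMulti = sum(hi$multi))
  }

  h1 <- alignMate(mates[[1]])
  h2 <- alignMate(mates[[2]])
  a1 <- buildMate(h1, mates[[1]], 1L)
  a2 <- buildMate(h2, mates[[2]], 2L)
  nMulti <- sum(c(if (nrow(h1)) sum(h1$multi) else 0L,
                  if (nrow(h2)) sum(h2$multi) else 0L))
  both <- rbindlist(list(a1, a2))
  if (is.null(both) || !nrow(both)) {
    return(list(alignments = GRanges(seqinfo = si),
                stats = list(nPairs = 0L, alignedMates = 0L,
                             multiMates = nMulti,
                             unalignedMates = 2L * length(read1),
                             pairedFragments = 0L, discordant = 0L)))
  }
  both[, nMulti := NULL]
  # pair mates: same chrom, same strand/track, opposite orientation, close
  wide <- merge(both[mate == 1L], both[mate == 2L], by = "readId",
                suffixes = c(".1", ".2"))
  ok <- wide[chrom.1 == chrom.2 & strand.1 == strand.2 &
               orient.1 != orient.2 &
               abs(pmax(end.1, end.2) - pmin(start.1, start.2)) <= maxInsert]
  ok[, `:=`(fragStart = pmin(start.1, start.2),
            fragEnd = pmax(end.1, end.2))]
  discordant <- nrow(wide) - nrow(ok)
  frag <- ok[, .(readId, fragStart, fragEnd)]
  paired <- merge(both, frag, by = "readId")
  # mates whose partner failed remain as single-end records
  single <- both[!readId %in% frag$readId]
  if (nrow(single)) {
    single[, `:=`(fragStart = start, fragEnd = end)]
    single[, paired := FALSE]
    paired[, paired := TRUE]
    allm <- rbindlist(list(paired, single), use.names = TRUE)
  } else {
    paired[, paired := TRUE]
    allm <- paired
  }
  setorder(allm, chrom, start, readId, mate)
  gr <- GRanges(allm$chrom, IRanges(allm$start, allm$end),
                strand = allm$strand, seqinfo = si)
  mcols(gr) <- DataFrame(readId = allm$readId, cell = allm$cell,
                         mate = allm$mate, track = allm$track,
                         orient = allm$orient, seq = allm$seq,
                         nmm = allm$nmm,
                         score = ifelse(allm$nmm == 0L, 60L, 40L),
                         fragStart = allm$fragStart, fragEnd = allm$fragEnd,
                         paired = allm$paired)
  list(alignments = gr,
       stats = list(nPairs = length(read1),
                    alignedMates = nrow(both),
                    multiMates = nMulti,
                    unalignedMates = 2L * length(read1) - nrow(both) - nMulti,
                    pairedFragments = nrow(ok),
                    discordant = discordant))
}

#' Export alignments as SAM
#'
#' Minimal SAM export of the toy aligner's records: one line per mate,
#' cell barcode both as a \code{qname} prefix (\code{cell:readId}) and a
#' \code{CB} tag; conversion track in \code{XT}, mismatch count in
#' \code{XM}, mate number in \code{XR}, fragment coordinates in
#' \code{XS}/\code{XE}. Coordinates convert to SAM's 1-based convention.
#'
#' @param aln \code{GRanges} from \code{\link{alignPairsToy}}.
#' @param path output SAM path.
#' @return Invisibly, \code{path}.
#' @export
exportSAM <- function(aln, path) {
  si <- GenomeInfoDb::seqinfo(aln)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", seqnames(si), "\tLN:",
                  GenomeInfoDb::seqlengths(si)))
  m <- mcols(aln)
  flag <- ifelse(m$orient == "R", 16L, 0L)
  lines <- paste(paste0(m$cell, ":", m$readId), flag,
                 as.character(seqnames(aln)), start(aln), m$score,
                 paste0(width(aln), "M"), "*", 0L, 0L, m$seq,
                 strrep("I", width(aln)),
                 paste0("CB:Z:", m$cell), paste0("XT:Z:", m$track),
                 paste0("XM:i:", m$nmm), paste0("XR:i:", m$mate),
                 paste0("XS:i:", m$fragStart), paste0("XE:i:", m$fragEnd),
                 sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Import external alignments
#'
#' Normalizes name-sorted (or any-order) SAM/BAM records into the package's
#' alignment representation, reading the cell barcode from the \code{CB}
#' tag or, failing that, from the first \code{:}-separated token of the
#' read name; records with neither are skipped and counted. Conversion
#' track is taken from the \code{XT} tag when present, otherwise inferred
#' from the strand flag (forward = C-to-T / Watson).
#'
#' @param path SAM or BAM file.
#' @param barcodeFrom \code{"auto"}, \code{"tag"} or \code{"qname"}.
#' @return List: \code{alignments} \code{GRanges} grouped by cell, and
#'   \code{nSkipped}.
#' @export
importAlignments <- function(path, barcodeFrom = c("auto", "tag", "qname")) {
  barcodeFrom <- match.arg(barcodeFrom)
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to import SAM/BAM")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "seq", "mapq"),
    tag = c("CB", "XT", "XM", "XR", "XS", "XE"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$qname)
  cellTag <- b$tag$CB
  if (is.null(cellTag)) cellTag <- rep(NA_character_, n)
  qTok <- sub(":.*$", "", b$qname)
  hasTok <- grepl(":", b$qname, fixed = TRUE)
  cell <- switch(barcodeFrom,
                 tag = cellTag,
                 qname = ifelse(hasTok, qTok, NA_character_),
                 auto = ifelse(!is.na(cellTag), cellTag,
                               ifelse(hasTok, qTok, NA_character_)))
  keep <- !is.na(cell) & !is.na(b$pos)
  nSkipped <- sum(!keep)
  rev <- bitwAnd(b$flag[keep], 16L) > 0L
  track <- b$tag$XT[keep]
  if (is.null(track)) track <- ifelse(rev, "GA", "CT")
  track[is.na(track)] <- ifelse(rev[is.na(track)], "GA", "CT")
  readId <- sub("^[^:]*:", "", b$qname[keep])
  mate <- b$tag$XR[keep]
  if (is.null(mate)) mate <- rep(1L, sum(keep))
  nmm <- b$tag$XM[keep]
  if (is.null(nmm)) nmm <- rep(0L, sum(keep))
  st <- b$pos[keep]
  en <- st + b$qwidth[keep] - 1L
  fs <- b$tag$XS[keep]
  fe <- b$tag$XE[keep]
  if (is.null(fs)) fs <- st
  if (is.null(fe)) fe <- en
  fs[is.na(fs)] <- st[is.na(fs)]
  fe[is.na(fe)] <- en[is.na(fe)]
  gr <- GRanges(as.character(b$rname[keep]), IRanges(st, en),
                strand = ifelse(track == "GA", "-", "+"))
  mcols(gr) <- DataFrame(readId = readId, cell = cell[keep],
                         mate = as.integer(mate), track = track,
                         orient = ifelse(rev, "R", "F"),
                         seq = as.character(b$seq[keep]),
                         nmm = as.integer(nmm),
                         score = b$mapq[keep],
                         fragStart = as.integer(fs), fragEnd = as.integer(fe),
                         paired = rep(TRUE, sum(keep)))
  ord <- order(mcols(gr)$cell, as.character(seqnames(gr)), start(gr))
  list(alignments = gr[ord], nSkipped = nSkipped)
}
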