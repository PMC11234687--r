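#' Reference cytosine context table
#'
#' Enumerates every cytosine position on both strands of a reference with
#' its context: Watson rows are reference \code{C} positions (CG when
#' followed by \code{G}, else CH); Crick rows are reference \code{G}
#' positions (CG when preceded by \code{C}, else CH), reported at the
#' position of the G, i.e. the Crick-strand C. Contexts involving
#' \code{N} or other ambiguity codes are dropped and counted in the
#' \code{nAmbiguous} attribute.
#'
#' @param genome \code{SimGenome}, \code{DNAStringSet} or FASTA path.
#' @return \code{data.table} with columns \code{chrom}, \code{pos}
#'   (1-based), \code{strand} (\code{+} Watson / \code{-} Crick),
#'   \code{context} (\code{CG}/\code{CH}).
#' @export
referenceContextTable <- function(genome) {
  seqs <- .asGenomeSeq(genome)
  out <- vector("list", length(seqs))
  nAmb <- 0L
  rC <- charToRaw("C"); rG <- charToRaw("G")
  rA <- charToRaw("A"); rT <- charToRaw("T")
  for (ci in seq_along(seqs)) {
    r <- charToRaw(as.character(seqs[[ci]]))
    L <- length(r)
    good <- r == rC | r == rG | r == rA | r == rT
    posC <- which(r == rC)
    posG <- which(r == rG)
    # Watson C context from the next base
    nxt <- ifelse(posC < L, posC + 1L, NA_integer_)
    ctxC <- rep("CH", length(posC))
    ctxC[!is.na(nxt) & r[pmin(nxt, L)] == rG] <- "CG"
    ambC <- is.na(nxt) | !good[pmin(nxt, L)]
    # Crick C (reference G) context from the previous base
    prv <- ifelse(posG > 1L, posG - 1L, NA_integer_)
    ctxG <- rep("CH", length(posG))
    ctxG[!is.na(prv) & r[pmax(prv, 1L)] == rC] <- "CG"
    ambG <- is.na(prv) | !good[pmax(prv, 1L)]
    nAmb <- nAmb + sum(ambC) + sum(ambG)
    out[[ci]] <- data.table(
      chrom = names(seqs)[ci],
      pos = c(posC[!ambC], posG[!ambG]),
      strand = rep(c("+", "-"), c(sum(!ambC), sum(!ambG))),
      context = c(ctxC[!ambC], ctxG[!ambG]))
  }
  res <- rbindlist(out)
  setkey(res, chrom, pos, strand)
  setattr(res, "nAmbiguous", nAmb)
  res
}

#' Per-cell PCR duplicate removal (paired-end)
#'
#' Duplicates are reads sharing an identical fragment signature within the
#' same cell; the first occurrence is kept. Identical coordinates in
#' different cells are retained: deduplication is strictly per cell.
#' Unpaired mates are treated single-end (their own coordinates form the
#' signature) and counted.
#'
#' @param aln alignment \code{GRanges} from \code{\link{alignPairsToy}} or
#'   \code{\link{importAlignments}}.
#' @param key \code{"fragment"} (default; cell, chromosome, fragment start,
#'   fragment end, strand) or \code{"mate1"} (cell, chromosome, mate-1
#'   coordinates, strand).
#' @return List: \code{alignments} (deduplicated \code{GRanges}),
#'   \code{nDuplicates} (read pairs removed), \code{nSingleEnd},
#'   \code{keptReadIds}.
#' @export
rmdupPE <- function(aln, key = c("fragment", "mate1")) {
  key <- match.arg(key)
  m <- mcols(aln)
  dt <- data.table(readId = m$readId, cell = m$cell,
                   chrom = as.character(seqnames(aln)),
                   start = start(aln), end = end(aln),
                   strand = as.character(strand(aln)),
                   mate = m$mate, fragStart = m$fragStart,
                   fragEnd = m$fragEnd, paired = m$paired,
                   ord = seq_along(aln))
  nSingle <- length(unique(dt[paired == FALSE, readId]))
  if (key == "fragment") {
    frag <- dt[, .(cell = cell[1], chrom = chrom[1], ks = fragStart[1],
                   ke = fragEnd[1], strand = strand[1], ord = min(ord)),
               by = readId]
  } else {
    m1 <- dt[mate == 1L]
    frag <- m1[, .(cell = cell[1], chrom = chrom[1], ks = start[1],
                   ke = end[1], strand = strand[1], ord = min(ord)),
               by = readId]
    # reads with no mate 1 fall back to their own coordinates
    rest <- dt[!readId %in% m1$readId,
               .(cell = cell[1], chrom = chrom[1], ks = start[1],
                 ke = end[1], strand = strand[1], ord = min(ord)),
               by = readId]
    frag <- rbindlist(list(frag, rest))
  }
  setorder(frag, ord)
  keep <- frag[!duplicated(frag, by = c("cell", "chrom", "ks", "ke",
                                        "strand")), readId]
  list(alignments = aln[m$readId %in% keep],
       nDuplicates = nrow(frag) - length(keep),
       nSingleEnd = nSingle,
       keptReadIds = keep)
}

#' Extract methylation calls from alignments
#'
#' For Watson-strand (C-to-T track) alignments, a read \code{C} at a
#' reference \code{C} is a methylated call and a read \code{T}
#' unmethylated; for Crick-strand (G-to-A track) alignments, read \code{G}
#' at a reference \code{G} is methylated and read \code{A} unmethylated.
#' Context (CG/CH) comes from the reference, never the read. Crick CG
#' calls are reported at the position of the reference G (the Crick C).
#' Any other read base at a cytosine position is ignored and counted as a
#' mismatch. Where mates of a pair overlap, mate 1 wins and the mate-2
#' observation is dropped, so each molecule contributes one call per site.
#'
#' @param aln alignment \code{GRanges} (typically deduplicated).
#' @param genome reference (\code{SimGenome}, \code{DNAStringSet}, path).
#' @param contextTable optional precomputed
#'   \code{\link{referenceContextTable}}.
#' @return List: \code{calls} (\code{data.table}: \code{cell},
#'   \code{chrom}, \code{pos} 1-based, \code{strand}, \code{context},
#'   \code{meth} logical; sorted by chrom, context, position) and
#'   \code{nMismatch}.
#' @export
extractCalls <- function(aln, genome, contextTable = NULL) {
  if (is.null(contextTable)) contextTable <- referenceContextTable(genome)
  seqs <- .asGenomeSeq(genome)
  if (length(aln) &&
      max(end(aln)) > max(Biostrings::width(seqs)))
    stop("alignment beyond reference end")
  m <- mcols(aln)
  adt <- data.table(idx = seq_along(aln), cell = m$cell,
                    chrom = as.character(seqnames(aln)),
                    start = start(aln), end = end(aln),
                    track = m$track, readId = m$readId, mate = m$mate,
                    seq = m$seq)
  pieces <- vector("list", 2L)
  for (k in 1:2) {
    trk <- c("CT", "GA")[k]
    strnd <- c("+", "-")[k]
    sub <- adt[track == trk]
    if (!nrow(sub)) next
    sites <- contextTable[strand == strnd]
    res <- vector("list", length(seqs))
    for (ci in names(seqs)) {
      a <- sub[chrom == ci]
      s <- sites[chrom == ci]
      if (!nrow(a) || !nrow(s)) next
      ov <- findOverlaps(IRanges(s$pos, s$pos), IRanges(a$start, a$end))
      if (!length(ov)) next
      si <- queryHits(ov); ai <- subjectHits(ov)
      off <- s$pos[si] - a$start[ai] + 1L
      base <- substring(a$seq[ai], off, off)
      res[[ci]] <- data.table(cell = a$cell[ai], chrom = ci,
                              pos = s$pos[si], strand = strnd,
                              context = s$context[si], base = base,
                              readId = a$readId[ai], mate = a$mate[ai])
    }
    pieces[[k]] <- rbindlist(res)
  }
  obs <- rbindlist(pieces)
  if (!nrow(obs))
    return(list(calls = data.table(cell = character(), chrom = character(),
                                   pos = integer(), strand = character(),
                                   context = character(), meth = logical()),
                nMismatch = 0L))
  # overlapping mates: keep mate 1's observation
  setorder(obs, readId, pos, strand, mate)
  obs <- obs[!duplicated(obs, by = c("readId", "chrom", "pos", "strand"))]
  methBase <- ifelse(obs$strand == "+", "C", "G")
  unmethBase <- ifelse(obs$strand == "+", "T", "A")
  isMeth <- obs$base == methBase
  isUnmeth <- obs$base == unmethBase
  nMismatch <- sum(!isMeth & !isUnmeth)
  calls <- obs[isMeth | isUnmeth,
               .(cell, chrom, pos, strand, context,
                 meth = base == ifelse(strand == "+", "C", "G"))]
  setorder(calls, chrom, context, pos, strand)
  list(calls = calls, nMismatch = nMismatch)
}

#' Write chromosome- and context-split call files
#'
#' One sorted TSV per chromosome per context (\code{cell}, \code{pos},
#' \code{strand}, \code{meth}), gzip-compressed.
#'
#' @param calls call table from \code{\link{extractCalls}}.
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
writeCallFiles <- function(calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (ctx in unique(calls$context)) {
    for (ch in unique(calls$chrom)) {
      sub <- calls[calls$context == ctx & calls$chrom == ch]
      if (!nrow(sub)) next
      p <- file.path(dir, paste0(ch, ".", ctx, ".tsv.gz"))
      fwrite(sub[, c("cell", "pos", "strand", "meth")], p, sep = "\t")
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Per-cell QC summary
#'
#' Counts raw, aligned and unique read pairs per cell, the percentage
#' unique, the number of distinct CG sites observed (chromosome, position
#' and strand distinguish sites), CG and CH methylation percentages, and
#' CG sites gained per raw read.
#'
#' @param calls call table from \code{\link{extractCalls}} (post-dedup).
#' @param aln pre-dedup alignment \code{GRanges} (for aligned counts).
#' @param dedupAln post-dedup alignment \code{GRanges}.
#' @param rawReads named vector of raw read-pair counts per cell
#'   (optional; defaults to aligned counts).
#' @return \code{data.table}, one row per cell.
#' @export
cellQC <- function(calls, aln = NULL, dedupAln = NULL, rawReads = NULL) {
  perCellPairs <- function(a) {
    if (is.null(a) || !length(a)) return(NULL)
    m <- mcols(a)
    dt <- data.table(cell = m$cell, readId = m$readId)
    dt[, .(n = length(unique(readId))), by = cell]
  }
  alignedTab <- perCellPairs(aln)
  uniqueTab <- perCellPairs(dedupAln)
  cells <- sort(unique(c(calls$cell, alignedTab$cell, uniqueTab$cell,
                         names(rawReads))))
  out <- data.table(cell = cells)
  addCount <- function(tab, nm) {
    v <- rep(0L, length(cells))
    if (!is.null(tab)) v[match(tab$cell, cells)] <- tab$n
    out[, (nm) := v]
  }
  addCount(alignedTab, "aligned_reads")
  addCount(uniqueTab, "unique_reads")
  if (is.null(rawReads)) {
    out[, raw_reads := aligned_reads]
  } else {
    v <- as.integer(rawReads[match(cells, names(rawReads))])
    v[is.na(v)] <- 0L
    out[, raw_reads := v]
  }
  out[, pct_unique := ifelse(aligned_reads > 0,
                             100 * unique_reads / aligned_reads, 0)]
  if (nrow(calls)) {
    cg <- calls[context == "CG",
                .(unique_cg_sites = nrow(unique(.SD[, .(chrom, pos, strand)])),
                  cg_meth_pct = 100 * mean(meth)), by = cell]
    ch <- calls[context == "CH", .(ch_meth_pct = 100 * mean(meth)), by = cell]
  } else cg <- ch <- NULL
  out[, `:=`(unique_cg_sites = 0L, cg_meth_pct = NA_real_,
             ch_meth_pct = NA_real_)]
  if (!is.null(cg) && nrow(cg)) {
    i <- match(cg$cell, cells)
    out$unique_cg_sites[i] <- cg$unique_cg_sites
    out$cg_meth_pct[i] <- cg$cg_meth_pct
  }
  if (!is.null(ch) && nrow(ch))
    out$ch_meth_pct[match(ch$cell, cells)] <- ch$ch_meth_pct
  out[, cg_per_raw_read := ifelse(raw_reads > 0,
                                  unique_cg_sites / raw_reads, 0)]
  out[]
}
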