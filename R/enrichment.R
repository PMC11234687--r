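#' Build a merged probe set
#'
#' Reads (or accepts) capture-probe intervals, merges overlapping and
#' bookended intervals (a shared endpoint joins them), clips intervals to
#' chromosome bounds with a warning, and records the panel and genome
#' sizes used by fold-enrichment arithmetic.
#'
#' @param probes BED path or \code{GRanges}.
#' @param chromSizes named vector of chromosome lengths (bp). The genome
#'   size denominator includes all bases of the listed chromosomes.
#' @return A \code{GRanges} with attributes-like metadata: metadata fields
#'   \code{totalBp} and \code{genomeBp} (also retrievable with
#'   \code{probeTotalBp}/\code{probeGenomeBp}).
#' @export
#' @examples
#' ps <- buildProbeSet(GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(101, 151, 401), c(200, 300, 500))),
#'   c(chr1 = 1000))
#' probeTotalBp(ps)  # 300
buildProbeSet <- function(probes, chromSizes) {
  if (is.character(probes)) probes <- readBed(probes)
  if (!length(probes)) stop("empty probe set")
  if (is.null(names(chromSizes))) stop("chromSizes must be named")
  beyond <- end(probes) > chromSizes[as.character(seqnames(probes))] |
    start(probes) < 1L
  if (any(beyond, na.rm = TRUE)) {
    warning(sum(beyond, na.rm = TRUE), " probe interval(s) clipped to ",
            "chromosome bounds")
  }
  si <- Seqinfo(seqnames = names(chromSizes),
                seqlengths = as.integer(chromSizes))
  GenomeInfoDb::seqlevels(probes) <- names(chromSizes)
  GenomeInfoDb::seqinfo(probes) <- si
  probes <- GenomicRanges::trim(probes)
  merged <- reduce(sort(probes))
  S4Vectors::metadata(merged) <- list(totalBp = sum(width(merged)),
                                      genomeBp = sum(as.numeric(chromSizes)))
  merged
}

#' @rdname buildProbeSet
#' @param ps probe set from \code{buildProbeSet}.
#' @export
probeTotalBp <- function(ps) {
  tb <- S4Vectors::metadata(ps)$totalBp
  if (is.null(tb)) sum(width(ps)) else tb
}

#' @rdname buildProbeSet
#' @export
probeGenomeBp <- function(ps) {
  gb <- S4Vectors::metadata(ps)$genomeBp
  if (is.null(gb)) sum(as.numeric(GenomeInfoDb::seqlengths(ps))) else gb
}

# fragment-level ranges (one per read pair / single-end read) from mates
.fragmentRanges <- function(aln) {
  if (!length(aln))
    return(data.table(readId = character(), cell = character(),
                      chrom = character(), fs = integer(), fe = integer(),
                      strand = character(), track = character()))
  m <- mcols(aln)
  dt <- data.table(readId = m$readId, cell = m$cell,
                   chrom = as.character(seqnames(aln)),
                   fs = m$fragStart, fe = m$fragEnd,
                   strand = as.character(strand(aln)), track = m$track)
  dt[!duplicated(readId)]
}

#' Per-cell and dataset on-target fractions
#'
#' A read pair counts on-target when its fragment overlaps any merged
#' probe interval by at least \code{minOverlap} bp. Reads on chromosomes
#' absent from the probe set count off-target.
#'
#' @param aln alignment \code{GRanges} (pre- or post-dedup).
#' @param probes merged probe \code{GRanges} (see
#'   \code{\link{buildProbeSet}}).
#' @param minOverlap minimum overlap in bp (default 1).
#' @return List: \code{fraction} (dataset level), \code{perCell}
#'   (\code{data.table}: cell, on, total, fraction), \code{nOnTarget},
#'   \code{nTotal}.
#' @export
onTargetFraction <- function(aln, probes, minOverlap = 1) {
  fr <- .fragmentRanges(aln)
  if (!nrow(fr)) return(list(fraction = NaN, perCell = data.table(),
                             nOnTarget = 0L, nTotal = 0L))
  gr <- GRanges(fr$chrom, IRanges(fr$fs, fr$fe))
  suppressWarnings(
    ov <- overlapsAny(gr, probes, minoverlap = minOverlap))
  fr[, on := ov]
  perCell <- fr[, .(on = sum(on), total = .N), by = cell]
  perCell[, fraction := on / total]
  list(fraction = sum(fr$on) / nrow(fr), perCell = perCell[],
       nOnTarget = sum(fr$on), nTotal = nrow(fr))
}

#' Fold enrichment over the panel's genome fraction
#'
#' \code{fold = fraction / (panel bp / genome bp)}. The transform is
#' monotone, so the median per-cell fold equals the fold of the median
#' per-cell fraction.
#'
#' @param fraction on-target fraction(s), in \[0,1\].
#' @param probes merged probe set, or \code{NULL} when \code{totalBp} and
#'   \code{genomeBp} are given directly.
#' @param totalBp,genomeBp panel and genome sizes in bp.
#' @return Fold enrichment, same length as \code{fraction}.
#' @export
#' @examples
#' # printed worked example: 29.4% on target against a 123,043,166-bp panel
#' foldEnrichment(0.294, totalBp = 123043166,
#'                genomeBp = sum(hg38MainChromSizes()))
foldEnrichment <- function(fraction, probes = NULL, totalBp = NULL,
                           genomeBp = NULL) {
  if (!is.null(probes)) {
    totalBp <- probeTotalBp(probes)
    genomeBp <- probeGenomeBp(probes)
  }
  if (is.null(totalBp) || is.null(genomeBp) || totalBp <= 0)
    stop("zero-size probe set")
  fraction / (totalBp / genomeBp)
}

#' Shadow coverage: on-target accounting with padded probes
#'
#' Probe intervals are expanded by \code{pad} bp on each side, re-merged
#' and clipped at chromosome bounds before recomputing the on-target
#' fraction; captures the halo of fragments partially pulled down by a
#' probe.
#'
#' @inheritParams onTargetFraction
#' @param pad bp added to each side (default 200).
#' @return As \code{\link{onTargetFraction}}, plus \code{paddedProbes}.
#' @export
shadowCoverage <- function(aln, probes, pad = 200, minOverlap = 1) {
  padded <- suppressWarnings(GenomicRanges::trim(probes + pad))
  padded <- reduce(padded)
  S4Vectors::metadata(padded) <- S4Vectors::metadata(probes)
  res <- onTargetFraction(aln, padded, minOverlap)
  res$paddedProbes <- padded
  res
}

#' Strand and conversion-track balance
#'
#' Fractions of Watson/Crick fragments and of C-to-T/G-to-A conversion
#' tracks, overall and stratified by target status, with exact binomial
#' tests against 50:50.
#'
#' @inheritParams onTargetFraction
#' @return \code{data.table}: stratum (all/on/off), nWatson, nCrick,
#'   watsonFraction, nCT, nGA, ctFraction, pStrand (binomial test).
#' @export
strandTrackBalance <- function(aln, probes) {
  fr <- .fragmentRanges(aln)
  gr <- GRanges(fr$chrom, IRanges(fr$fs, fr$fe))
  fr[, on := overlapsAny(gr, probes)]
  one <- function(d, label) {
    nW <- sum(d$strand == "+"); nC <- sum(d$strand == "-")
    nCT <- sum(d$track == "CT"); nGA <- sum(d$track == "GA")
    p <- if (nW + nC > 0) stats::binom.test(nW, nW + nC)$p.value else NA_real_
    data.table(stratum = label, nWatson = nW, nCrick = nC,
               watsonFraction = if (nW + nC > 0) nW / (nW + nC) else NaN,
               nCT = nCT, nGA = nGA,
               ctFraction = if (nCT + nGA > 0) nCT / (nCT + nGA) else NaN,
               pStrand = p)
  }
  rbindlist(list(one(fr, "all"), one(fr[on == TRUE], "on_target"),
                 one(fr[on == FALSE], "off_target")))
}

#' GC content of non-overlapping genome bins
#'
#' @param genome reference (\code{SimGenome}, \code{DNAStringSet}, path).
#' @param binSize bin width in bp (default 2000).
#' @return \code{GRanges} of bins with metadata column \code{gc}.
#' @export
gcBins <- function(genome, binSize = 2000) {
  seqs <- .asGenomeSeq(genome)
  si <- .genomeSeqinfo(seqs)
  bins <- tileGenome(GenomeInfoDb::seqlengths(si), tilewidth = binSize,
                     cut.last.tile.in.chrom = TRUE)
  gc <- numeric(length(bins))
  for (ci in names(seqs)) {
    sel <- which(as.character(seqnames(bins)) == ci)
    vv <- Biostrings::Views(seqs[[ci]], IRanges(start(bins)[sel],
                                                end(bins)[sel]))
    f <- Biostrings::letterFrequency(vv, c("G", "C", "A", "T"))
    gc[sel] <- rowSums(f[, 1:2, drop = FALSE]) /
      pmax(rowSums(f), 1)
  }
  mcols(bins)$gc <- gc
  bins
}

# aggregate a call table to per-site methylated fractions and coverage
.siteAggregate <- function(calls, context = "CG") {
  sub <- calls[which(calls$context == context)]
  sub[, .(meth = sum(meth), cov = .N), by = .(chrom, pos, strand)]
}

#' Site-level methylation correlation between two callsets
#'
#' Aggregates both call tables to per-CG-site methylation fractions,
#' restricts to sites with coverage at least \code{minCov} in both, and
#' reports the Pearson correlation for all shared sites, on-/off-target
#' strata, and sites falling in the top and bottom GC-content quartiles of
#' \code{gcWindow}-bp bins. Strata with fewer than two sites are reported
#' as \code{NA}.
#'
#' @param callsA,callsB call tables from \code{\link{extractCalls}}.
#' @param probes merged probe \code{GRanges}.
#' @param genome reference, for GC bins.
#' @param minCov minimum coverage per site in each callset (default 5).
#' @param gcWindow GC bin width (default 2000).
#' @return \code{data.table}: stratum, nSites, r.
#' @export
siteCorrelation <- function(callsA, callsB, probes, genome, minCov = 5,
                            gcWindow = 2000) {
  a <- .siteAggregate(callsA)
  b <- .siteAggregate(callsB)
  shared <- merge(a[cov >= minCov], b[cov >= minCov],
                  by = c("chrom", "pos", "strand"), suffixes = c(".a", ".b"))
  if (!nrow(shared))
    return(data.table(stratum = "all", nSites = 0L, r = NA_real_))
  shared[, `:=`(fa = meth.a / cov.a, fb = meth.b / cov.b)]
  gr <- GRanges(shared$chrom, IRanges(shared$pos, shared$pos))
  shared[, on := overlapsAny(gr, probes)]
  bins <- gcBins(genome, gcWindow)
  hit <- findOverlaps(gr, bins, select = "first")
  shared[, gc := mcols(bins)$gc[hit]]
  qs <- stats::quantile(mcols(bins)$gc, c(0.25, 0.75))
  strata <- list(all = rep(TRUE, nrow(shared)),
                 on_target = shared$on,
                 off_target = !shared$on,
                 top25_gc = !is.na(shared$gc) & shared$gc >= qs[2],
                 bottom25_gc = !is.na(shared$gc) & shared$gc <= qs[1])
  rbindlist(lapply(names(strata), function(nm) {
    sel <- strata[[nm]]
    r <- if (sum(sel) >= 2) {
      suppressWarnings(cor(shared$fa[sel], shared$fb[sel]))
    } else NA_real_
    data.table(stratum = nm, nSites = sum(sel), r = r)
  }))
}

#' Capture enrichment report
#'
#' Combines pre- and post-dedup on-target accounting, fold enrichment,
#' shadow coverage and strand/track balance into one report.
#'
#' @param alnPre pre-dedup alignment \code{GRanges}.
#' @param alnPost post-dedup alignment \code{GRanges}.
#' @param probes merged probe set with size metadata.
#' @param pad shadow padding (bp).
#' @return List of the component results plus headline numbers.
#' @export
enrichmentReport <- function(alnPre, alnPost, probes, pad = 200) {
  pre <- onTargetFraction(alnPre, probes)
  post <- onTargetFraction(alnPost, probes)
  shadow <- shadowCoverage(alnPost, probes, pad = pad)
  bal <- strandTrackBalance(alnPost, probes)
  list(pre = pre, post = post, shadow = shadow, balance = bal,
       pctOnTargetPre = 100 * pre$fraction,
       pctOnTargetPost = 100 * post$fraction,
       foldPre = foldEnrichment(pre$fraction, probes),
       foldPost = foldEnrichment(post$fraction, probes),
       pctShadow = 100 * shadow$fraction)
}
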