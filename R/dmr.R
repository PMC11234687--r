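#' Aggregate counts of all clusters except the focal one
#'
#' One-vs-rest testing uses the pooled coverage of every non-focal
#' cluster, rather than uniting per-cluster tracks, so that a single
#' low-coverage cluster cannot knock windows out of every comparison.
#'
#' @param agg cluster-aggregated \code{\link{MethWindowMatrix}}.
#' @param focal focal cluster name (column of \code{agg}).
#' @return List of numeric vectors: \code{methFocal}, \code{unmethFocal},
#'   \code{methRest}, \code{unmethRest}, one entry per window.
#' @export
buildRestAggregate <- function(agg, focal) {
  if (ncol(agg) < 2) stop("at least two clusters are required")
  if (!focal %in% colnames(agg)) stop("unknown focal cluster: ", focal)
  m <- SummarizedExperiment::assay(agg, "meth")
  tt <- SummarizedExperiment::assay(agg, "total")
  f <- which(colnames(agg) == focal)
  mf <- as.numeric(m[, f])
  tf <- as.numeric(tt[, f])
  mr <- as.numeric(Matrix::rowSums(m[, -f, drop = FALSE]))
  tr <- as.numeric(Matrix::rowSums(tt[, -f, drop = FALSE]))
  list(methFocal = mf, unmethFocal = tf - mf,
       methRest = mr, unmethRest = tr - mr)
}

# vectorized two-sided Fisher exact p for 2x2 tables given as count vectors
.fisherVec <- function(mf, uf, mr, ur) {
  n <- length(mf)
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    # two-sided by summing all tables with probability <= observed
    m <- mf[i] + mr[i]          # total methylated (white balls)
    nn <- uf[i] + ur[i]         # total unmethylated
    kk <- mf[i] + uf[i]         # focal draws
    x <- mf[i]
    support <- max(0, kk - nn):min(kk, m)
    dens <- dhyper(support, m, nn, kk)
    pObs <- dhyper(x, m, nn, kk)
    p[i] <- sum(dens[dens <= pObs * (1 + 1e-7)])
  }
  pmin(p, 1)
}

#' Test one window: focal vs rest
#'
#' Two-sided Fisher's exact test on the 2x2 methylated/unmethylated table,
#' plus the methylation difference in percentage points (focal minus
#' rest). Windows where either group's total coverage is below
#' \code{minCov} are untested (\code{NA}).
#'
#' @param methFocal,unmethFocal,methRest,unmethRest count vectors (or
#'   scalars).
#' @param minCov minimum total calls per group (default 10).
#' @return \code{data.table}: \code{p}, \code{methDiff}, \code{tested}.
#' @export
#' @examples
#' testWindow(0, 20, 20, 0)  # p = 2 / choose(40, 20), diff = -100
testWindow <- function(methFocal, unmethFocal, methRest, unmethRest,
                       minCov = 10) {
  mf <- as.numeric(methFocal); uf <- as.numeric(unmethFocal)
  mr <- as.numeric(methRest); ur <- as.numeric(unmethRest)
  stopifnot(all(c(mf, uf, mr, ur) >= 0))
  tf <- mf + uf
  tr <- mr + ur
  tested <- tf >= minCov & tr >= minCov
  p <- rep(NA_real_, length(mf))
  if (any(tested))
    p[tested] <- .fisherVec(mf[tested], uf[tested], mr[tested], ur[tested])
  methDiff <- ifelse(tested, 100 * mf / pmax(tf, 1) - 100 * mr / pmax(tr, 1),
                     NA_real_)
  data.table(p = p, methDiff = methDiff, tested = tested)
}

#' Call cluster-specific DMRs
#'
#' For every cluster: aggregate the rest, test every window with adequate
#' coverage, convert p-values to Benjamini-Hochberg q-values within that
#' focal cluster's test family, and flag windows passing
#' \code{q <= qMax} and \code{|methDiff| >= diffMin}. All passing windows
#' are retained, including overlapping ones and windows significant in
#' more than one cluster; per-cluster merged regions are additionally
#' reported.
#'
#' @param agg cluster-aggregated \code{\link{MethWindowMatrix}} (1500-bp /
#'   500-bp sliding windows in the standard workflow).
#' @param qMax q-value threshold (default 1e-4).
#' @param diffMin minimum absolute methylation difference in percentage
#'   points (default 25).
#' @param minCov minimum per-group coverage (default 10).
#' @return List: \code{windows} (\code{data.table}: cluster, chrom, start,
#'   end, counts, methPct of both groups, methDiff, p, q, pass) and
#'   \code{regions} (\code{GRanges} of per-cluster merged passing windows
#'   with \code{cluster} and \code{nWindows}).
#' @export
callDMRs <- function(agg, qMax = 1e-4, diffMin = 25, minCov = 10) {
  win <- SummarizedExperiment::rowRanges(agg)
  res <- vector("list", ncol(agg))
  for (ci in seq_len(ncol(agg))) {
    cl <- colnames(agg)[ci]
    rest <- buildRestAggregate(agg, cl)
    tst <- testWindow(rest$methFocal, rest$unmethFocal,
                      rest$methRest, rest$unmethRest, minCov = minCov)
    q <- rep(NA_real_, nrow(tst))
    q[tst$tested] <- p.adjust(tst$p[tst$tested], method = "BH")
    tf <- rest$methFocal + rest$unmethFocal
    tr <- rest$methRest + rest$unmethRest
    res[[ci]] <- data.table(
      cluster = cl, chrom = as.character(seqnames(win)),
      start = start(win), end = end(win),
      methFocal = rest$methFocal, totalFocal = tf,
      methRest = rest$methRest, totalRest = tr,
      methPctFocal = ifelse(tf > 0, 100 * rest$methFocal / tf, NA_real_),
      methPctRest = ifelse(tr > 0, 100 * rest$methRest / tr, NA_real_),
      methDiff = tst$methDiff, p = tst$p, q = q,
      tested = tst$tested)
  }
  dm <- rbindlist(res)
  dm[, pass := tested & !is.na(q) & q <= qMax & abs(methDiff) >= diffMin]
  regions <- GRanges()
  passing <- dm[pass == TRUE]
  if (nrow(passing)) {
    pieces <- lapply(split(passing, passing$cluster), function(s) {
      r <- reduce(GRanges(s$chrom, IRanges(s$start, s$end)))
      mcols(r)$cluster <- s$cluster[1]
      mcols(r)$nWindows <- countOverlaps(
        r, GRanges(s$chrom, IRanges(s$start, s$end)))
      r
    })
    regions <- sort(do.call(c, unname(pieces)))
  }
  list(windows = dm[], regions = regions)
}

#' Annotate DMR regions by overlap
#'
#' Labels each region with every annotation class it overlaps by at least
#' 1 bp; the primary label follows the precedence given by the order of
#' the annotation list; regions overlapping nothing are
#' \code{"intergenic"}.
#'
#' @param regions DMR \code{GRanges}.
#' @param annotations named list of \code{GRanges} in precedence order
#'   (e.g. promoter, enhancer, gene_body).
#' @return \code{regions} with added metadata: \code{annotation} (primary)
#'   and \code{annotationAll} (comma-separated hits).
#' @export
annotateDMRs <- function(regions, annotations) {
  if (is.null(annotations) || !length(annotations)) {
    warning("no annotation files provided; regions left unannotated")
    mcols(regions)$annotation <- NA_character_
    return(regions)
  }
  hits <- vapply(annotations, function(a) overlapsAny(regions, a),
                 logical(length(regions)))
  if (length(regions) == 1L) hits <- matrix(hits, nrow = 1L,
                                            dimnames = list(NULL,
                                                            names(annotations)))
  primary <- apply(hits, 1L, function(h) {
    w <- which(h)
    if (length(w)) names(annotations)[w[1]] else "intergenic"
  })
  all <- apply(hits, 1L, function(h) {
    w <- which(h)
    if (length(w)) paste(names(annotations)[w], collapse = ",") else
      "intergenic"
  })
  mcols(regions)$annotation <- primary
  mcols(regions)$annotationAll <- all
  regions
}

#' Export per-cluster sliding-window bedgraph tracks
#'
#' Each 1500-bp window sliding by 500 bp emits one record on its central
#' 500-bp third, so adjacent records do not overlap; values are the
#' cluster's window methylation percentage (windows without coverage are
#' skipped). BED-style 0-based half-open coordinates.
#'
#' @param agg cluster-aggregated \code{\link{MethWindowMatrix}} over
#'   sliding windows of size 1500, step 500 (anything else errors).
#' @param dir output directory; one \code{<cluster>.bedgraph} per cluster.
#' @return Invisibly, the written paths.
#' @export
exportBedgraph <- function(agg, dir) {
  if (!(identical(agg@windowKind, "sliding") && agg@windowSize == 1500 &&
        agg@windowStep == 500))
    stop("bedgraph export requires 1500-bp windows sliding by 500 bp")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  win <- SummarizedExperiment::rowRanges(agg)
  m <- SummarizedExperiment::assay(agg, "meth")
  tt <- SummarizedExperiment::assay(agg, "total")
  paths <- character(ncol(agg))
  for (ci in seq_len(ncol(agg))) {
    cov <- as.numeric(tt[, ci])
    keep <- cov > 0
    pct <- 100 * as.numeric(m[keep, ci]) / cov[keep]
    df <- data.frame(chrom = as.character(seqnames(win))[keep],
                     start = start(win)[keep] - 1L + 500L,
                     end = start(win)[keep] - 1L + 1000L,
                     value = round(pct, 2))
    paths[ci] <- file.path(dir, paste0(colnames(agg)[ci], ".bedgraph"))
    fwrite(df, paths[ci], sep = "\t", col.names = FALSE)
  }
  invisible(paths)
}

#' Overlap partition of several DMR region sets
#'
#' Merges the union of all regions into loci and labels each locus with
#' the subset of input sets overlapping it; the per-subset counts are
#' ready for Euler/Venn plotting.
#'
#' @param sets named list of \code{GRanges} (two or more; empty sets
#'   contribute nothing).
#' @return List: \code{loci} (\code{GRanges} with \code{label}) and
#'   \code{counts} (table of subset label -> locus count).
#' @export
compareDMRSets <- function(sets) {
  if (length(sets) < 2) stop("at least two DMR sets are required")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  nonEmpty <- sets[vapply(sets, length, integer(1)) > 0]
  if (!length(nonEmpty))
    return(list(loci = GRanges(), counts = table(character())))
  all <- do.call(c, lapply(unname(nonEmpty), function(g) {
    mcols(g) <- NULL
    GenomeInfoDb::seqinfo(g) <- Seqinfo(GenomeInfoDb::seqlevels(g))
    g
  }))
  loci <- reduce(sort(all))
  member <- vapply(sets, function(g)
    if (length(g)) overlapsAny(loci, g) else rep(FALSE, length(loci)),
    logical(length(loci)))
  if (length(loci) == 1L) member <- matrix(member, nrow = 1L,
                                           dimnames = list(NULL, names(sets)))
  label <- apply(member, 1L, function(h)
    paste(names(sets)[h], collapse = "&"))
  mcols(loci)$label <- label
  list(loci = loci, counts = table(label))
}
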