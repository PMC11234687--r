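#' Build a window set
#'
#' Tiling windows start at the chromosome origin and partition it exactly,
#' the last window truncated at the chromosome end. Sliding windows start
#' every \code{step} bp while the start lies inside the chromosome and are
#' truncated at the end (terminal truncated windows are kept). Target
#' windows are the merged probe intervals themselves.
#'
#' @param chromSizes named vector of chromosome lengths, or a probe
#'   \code{GRanges} when \code{kind = "target"}.
#' @param kind \code{"tiling"}, \code{"sliding"} or \code{"target"}.
#' @param size window size (bp).
#' @param step step for sliding windows (must be < size).
#' @return \code{GRanges} of windows, sorted, with the geometry stored in
#'   metadata (\code{kind}, \code{size}, \code{step}).
#' @export
#' @examples
#' w <- makeWindows(c(chr1 = 120000), "tiling", 50000)
#' BiocGenerics::width(w)  # 50000, 50000, 20000
makeWindows <- function(chromSizes, kind = c("tiling", "sliding", "target"),
                        size = NULL, step = NULL) {
  kind <- match.arg(kind)
  if (kind == "target") {
    stopifnot(is(chromSizes, "GRanges"))
    win <- sort(reduce(chromSizes))
    S4Vectors::metadata(win) <- c(S4Vectors::metadata(chromSizes),
                                  list(kind = "target", size = NA_real_,
                                       step = NA_real_))
    return(win)
  }
  stopifnot(!is.null(names(chromSizes)))
  if (is.null(size) || size <= 0) stop("size must be > 0")
  if (kind == "tiling") {
    step <- size
  } else {
    if (is.null(step) || step <= 0) stop("step must be > 0")
    if (step >= size) stop("sliding windows require step < size")
  }
  pieces <- lapply(names(chromSizes), function(ch) {
    L <- chromSizes[[ch]]
    starts <- seq.int(1L, L, by = step)
    data.frame(chrom = ch, start = starts, end = pmin(starts + size - 1, L))
  })
  df <- do.call(rbind, pieces)
  win <- GRanges(df$chrom, IRanges(df$start, df$end),
                 seqinfo = Seqinfo(names(chromSizes),
                                   as.integer(chromSizes)))
  S4Vectors::metadata(win) <- list(kind = kind, size = size,
                                   step = if (kind == "tiling") size else step)
  win
}

#' Windowed methylation count matrix
#'
#' Assigns every call of the requested context to every window containing
#' its position (sliding windows multiply-assign) and accumulates
#' methylated and total call counts per cell per window into a
#' \code{\link{MethWindowMatrix}}. Percentages and the coverage filter are
#' applied downstream by \code{\link{methPct}}, keeping missingness
#' explicit rather than encoded as zero.
#'
#' @param calls call table from \code{\link{extractCalls}}.
#' @param windows window \code{GRanges} from \code{\link{makeWindows}}.
#' @param context \code{"CG"} or \code{"CH"}.
#' @param cells optional full cell universe (columns); defaults to the
#'   cells present in \code{calls}.
#' @return A \code{\link{MethWindowMatrix}}.
#' @export
meth2mtx <- function(calls, windows, context = c("CG", "CH"), cells = NULL) {
  context <- match.arg(context)
  wantCtx <- which(calls$context == context)
  sub <- calls[wantCtx]
  if (!nrow(sub) && is.null(cells))
    stop("no calls of context ", context)
  if (is.null(cells)) cells <- sort(unique(sub$cell))
  gr <- GRanges(sub$chrom, IRanges(sub$pos, sub$pos))
  ov <- findOverlaps(gr, windows)
  ci <- match(sub$cell[queryHits(ov)], cells)
  wi <- subjectHits(ov)
  keep <- !is.na(ci)
  meth <- Matrix::sparseMatrix(i = wi[keep], j = ci[keep],
                               x = as.numeric(sub$meth[queryHits(ov)][keep]),
                               dims = c(length(windows), length(cells)))
  total <- Matrix::sparseMatrix(i = wi[keep], j = ci[keep],
                                x = rep(1, sum(keep)),
                                dims = c(length(windows), length(cells)))
  md <- S4Vectors::metadata(windows)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(meth = meth, total = total),
    rowRanges = windows,
    colData = DataFrame(cell = cells, row.names = cells))
  new("MethWindowMatrix", se,
      windowKind = if (is.null(md$kind)) "target" else md$kind,
      windowSize = if (is.null(md$size)) NA_real_ else as.numeric(md$size),
      windowStep = if (is.null(md$step)) NA_real_ else as.numeric(md$step),
      context = context)
}

#' Methylation percentage matrix with explicit missingness
#'
#' @param x a \code{\link{MethWindowMatrix}}.
#' @param minCalls windows with fewer total calls for a column are
#'   \code{NA} (default 1).
#' @return Dense numeric matrix (windows x columns), percentages in
#'   \[0,100\] or \code{NA}.
#' @export
methPct <- function(x, minCalls = 1) {
  m <- as.matrix(SummarizedExperiment::assay(x, "meth"))
  tt <- as.matrix(SummarizedExperiment::assay(x, "total"))
  out <- 100 * m / tt
  out[tt < minCalls] <- NA_real_
  out
}

#' Aggregate window counts across clusters
#'
#' Sums methylated and total calls of all cells carrying the same cluster
#' label; unlabeled cells are excluded and counted. Integer call counts
#' are conserved: the cluster-level totals sum to the cell-level totals of
#' labeled cells.
#'
#' @param x a \code{\link{MethWindowMatrix}} (cells as columns).
#' @param labels named vector (cell -> cluster) or vector aligned with
#'   columns.
#' @return A \code{\link{MethWindowMatrix}} with clusters as columns;
#'   number of excluded cells in \code{metadata(x)$nUnlabeled}.
#' @export
aggregateByCluster <- function(x, labels) {
  cells <- colnames(x)
  if (!is.null(names(labels))) labels <- labels[cells]
  if (length(labels) != ncol(x))
    stop("labels must cover the matrix columns")
  lab <- as.character(labels)
  keep <- !is.na(lab)
  nUnlabeled <- sum(!keep)
  lab <- lab[keep]
  clusters <- sort(unique(lab))
  design <- Matrix::sparseMatrix(i = seq_along(lab),
                                 j = match(lab, clusters),
                                 x = 1,
                                 dims = c(length(lab), length(clusters)))
  m <- SummarizedExperiment::assay(x, "meth")[, keep, drop = FALSE] %*% design
  tt <- SummarizedExperiment::assay(x, "total")[, keep, drop = FALSE] %*% design
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(meth = methods::as(m, "CsparseMatrix"),
                  total = methods::as(tt, "CsparseMatrix")),
    rowRanges = SummarizedExperiment::rowRanges(x),
    colData = DataFrame(cell = clusters, row.names = clusters))
  out <- new("MethWindowMatrix", se, windowKind = x@windowKind,
             windowSize = x@windowSize, windowStep = x@windowStep,
             context = x@context)
  S4Vectors::metadata(out)$nUnlabeled <- nUnlabeled
  out
}

#' Per-cluster coverage statistics
#'
#' For each cluster: the percentage of reference CG sites (both strands
#' counted separately) covered by at least one call, and the percentage of
#' windows whose aggregate call count reaches \code{minCov}.
#'
#' @param agg cluster-aggregated \code{\link{MethWindowMatrix}}.
#' @param calls the call table used to build it (site-level resolution).
#' @param labels cell -> cluster labels (as in
#'   \code{\link{aggregateByCluster}}).
#' @param contextTable reference context table (for the CG site universe).
#' @param minCov window coverage threshold (default 10).
#' @return \code{data.table}: cluster, pctCgSitesCovered, pctWindowsCovered.
#' @export
clusterCoverageStats <- function(agg, calls, labels, contextTable,
                                 minCov = 10) {
  tt <- SummarizedExperiment::assay(agg, "total")
  pctWin <- 100 * Matrix::colSums(tt >= minCov) / nrow(tt)
  nSitesTotal <- nrow(contextTable[context == "CG"])
  cg <- calls[calls$context == "CG"]
  lab <- labels
  if (!is.null(names(lab))) {
    cl <- as.character(lab[cg$cell])
  } else stop("labels must be a named cell -> cluster vector")
  cg <- cg[!is.na(cl)]
  cl <- cl[!is.na(cl)]
  cg[, cluster := cl]
  siteCov <- cg[, .(nSites = nrow(unique(.SD[, .(chrom, pos, strand)]))),
                by = cluster]
  out <- data.table(cluster = colnames(agg), pctWindowsCovered = pctWin)
  out[, pctCgSitesCovered :=
        100 * siteCov$nSites[match(cluster, siteCov$cluster)] / nSitesTotal]
  out[is.na(pctCgSitesCovered), pctCgSitesCovered := 0]
  out[]
}

#' Write a MethWindowMatrix as MTX plus row/column annotations
#'
#' @param x a \code{\link{MethWindowMatrix}}.
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
writeWindowMatrix <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pm <- file.path(dir, "meth.mtx")
  pt <- file.path(dir, "total.mtx")
  Matrix::writeMM(SummarizedExperiment::assay(x, "meth"), pm)
  Matrix::writeMM(SummarizedExperiment::assay(x, "total"), pt)
  writeBed(SummarizedExperiment::rowRanges(x), file.path(dir, "windows.bed"))
  writeLines(colnames(x), file.path(dir, "columns.txt"))
  invisible(c(pm, pt))
}
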