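#' Reduce a window matrix by truncated SVD
#'
#' Builds the cells x windows methylation-percentage matrix, imputes
#' missing entries to the per-window mean, centres each window, and takes
#' a truncated SVD keeping the first \code{d} components (cell scores =
#' left singular vectors scaled by the singular values). Windows with no
#' observations anywhere are dropped. Deterministic for a fixed seed.
#'
#' @param x a \code{\link{MethWindowMatrix}} or a plain windows x cells
#'   percentage matrix with \code{NA} for missing.
#' @param d number of components (default 50); clipped with a warning when
#'   it exceeds the matrix rank.
#' @param minCalls coverage filter passed to \code{\link{methPct}}.
#' @param dropFirst drop the first component (some methylome pipelines
#'   discard a coverage-correlated leading component; default FALSE).
#' @param seed RNG seed for the iterative solver.
#' @return cells x d score matrix; rownames are cells. The per-component
#'   singular values are in \code{attr(, "d")}.
#' @export
reduceDims <- function(x, d = 50, minCalls = 1, dropFirst = FALSE,
                       seed = 1L) {
  pct <- if (is(x, "MethWindowMatrix")) methPct(x, minCalls) else x
  m <- t(pct)  # cells x windows
  mu <- colMeans(m, na.rm = TRUE)
  seen <- !is.na(mu)
  m <- m[, seen, drop = FALSE]
  mu <- mu[seen]
  na <- is.na(m)
  if (any(na)) m[na] <- mu[((which(na) - 1L) %/% nrow(m)) + 1L]
  m <- sweep(m, 2L, mu)
  maxd <- min(dim(m)) - 1L
  want <- d + as.integer(dropFirst)
  if (want > maxd) {
    warning("d clipped from ", d, " to ", maxd - as.integer(dropFirst))
    want <- maxd
  }
  sv <- withSeed(deriveSeed(seed, "svd"), {
    if (want >= min(dim(m)) - 1L || min(dim(m)) < 10L) {
      s <- svd(m, nu = want, nv = 0)
      list(u = s$u[, seq_len(want), drop = FALSE], d = s$d[seq_len(want)])
    } else {
      s <- irlba::irlba(m, nv = want)
      list(u = s$u, d = s$d)
    }
  })
  keep <- seq_len(ncol(sv$u))
  if (dropFirst) keep <- keep[-1]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("SV", seq_len(ncol(scores)))
  attr(scores, "d") <- sv$d[keep]
  scores
}

#' Merge two reduced matrices
#'
#' Concatenates two score blocks (typically 25 + 25 dimensions from a
#' target-window CG matrix and a large-tile CH matrix) after scaling each
#' block to unit total variance so neither signal dominates. Cell sets
#' must match; cell order follows the first block.
#'
#' @param a,b score matrices from \code{\link{reduceDims}}.
#' @return Combined score matrix with \code{ncol(a) + ncol(b)} columns.
#' @export
mergeReductions <- function(a, b) {
  ca <- rownames(a); cb <- rownames(b)
  if (is.null(ca) || is.null(cb)) stop("score matrices must carry cell names")
  if (!setequal(ca, cb)) {
    miss <- c(setdiff(ca, cb), setdiff(cb, ca))
    stop("cell sets differ: ", paste(head(miss, 10), collapse = ", "),
         if (length(miss) > 10) " ...")
  }
  b <- b[ca, , drop = FALSE]
  scaleBlock <- function(m) {
    v <- sum(apply(m, 2L, var))
    if (v > 0) m / sqrt(v) else m
  }
  out <- cbind(scaleBlock(a), scaleBlock(b))
  colnames(out) <- paste0("SV", seq_len(ncol(out)))
  out
}

# shared-nearest-neighbor graph with Jaccard edge weights over a k-NN graph
.snnGraph <- function(scores, k) {
  n <- nrow(scores)
  if (k >= n) stop("k must be smaller than the number of cells")
  d <- as.matrix(stats::dist(scores))
  nn <- t(apply(d, 1L, function(r) order(r)[2:(k + 1L)]))
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                              j = as.vector(t(nn)), x = 1,
                              dims = c(n, n))
  # include self for Jaccard so singleton neighborhoods behave
  adj <- adj + Matrix::Diagonal(n)
  shared <- Matrix::tcrossprod(adj)
  deg <- Matrix::rowSums(adj)
  sm <- methods::as(shared, "TsparseMatrix")
  i <- sm@i + 1L; j <- sm@j + 1L
  jac <- sm@x / (deg[i] + deg[j] - sm@x)
  keep <- i < j & jac > 0
  igraph::graph_from_data_frame(
    data.frame(from = i[keep], to = j[keep], weight = jac[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
}

#' Graph-based clustering of reduced cell profiles
#'
#' Builds a k-nearest-neighbor graph on the reduced scores (Euclidean
#' distance), weights edges by shared-neighbor Jaccard similarity, and
#' partitions it with Louvain community detection. Deterministic for a
#' fixed seed; the parameters used are recorded as attributes.
#'
#' @param scores cells x d matrix from \code{\link{reduceDims}}.
#' @param k neighbors (default 20).
#' @param resolution Louvain resolution (default 1).
#' @param seed RNG seed.
#' @return Named factor of cluster labels (cell -> cluster), with
#'   \code{k}, \code{resolution} and \code{seed} attributes.
#' @export
clusterCells <- function(scores, k = 20, resolution = 1, seed = 1L) {
  g <- .snnGraph(scores, k)
  cl <- withSeed(deriveSeed(seed, "louvain"),
                 igraph::cluster_louvain(g, resolution = resolution))
  lab <- factor(igraph::membership(cl))
  names(lab) <- rownames(scores)
  attr(lab, "k") <- k
  attr(lab, "resolution") <- resolution
  attr(lab, "seed") <- seed
  lab
}

#' 2-D UMAP embedding of reduced profiles
#'
#' Standard-library contract (uwot); deterministic for a fixed seed and
#' single-threaded optimization. The neighbor count is clipped for very
#' small inputs.
#'
#' @param scores cells x d matrix.
#' @param seed RNG seed.
#' @param nNeighbors UMAP neighborhood size (default 15).
#' @return cells x 2 coordinate matrix.
#' @export
embedUMAP <- function(scores, seed = 1L, nNeighbors = 15) {
  nNeighbors <- min(nNeighbors, nrow(scores) - 1L)
  emb <- withSeed(deriveSeed(seed, "umap"),
                  uwot::umap(scores, n_neighbors = max(2L, nNeighbors),
                             n_threads = 1, n_sgd_threads = 0,
                             init = if (nrow(scores) < 20) "random" else
                               "spectral",
                             verbose = FALSE))
  rownames(emb) <- rownames(scores)
  colnames(emb) <- c("UMAP1", "UMAP2")
  emb
}

# adjusted Rand index from the contingency table
.ariFromTable <- function(tab) {
  n <- sum(tab)
  sumComb <- function(x) sum(choose(x, 2))
  a <- sumComb(rowSums(tab))
  b <- sumComb(colSums(tab))
  idx <- sumComb(as.vector(tab))
  expect <- a * b / choose(n, 2)
  maxidx <- (a + b) / 2
  if (maxidx == expect) return(1)
  (idx - expect) / (maxidx - expect)
}

#' Compare two cluster labelings
#'
#' Computed on the intersection of the labeled cell sets: contingency
#' table and adjusted Rand index (chance-corrected agreement; invariant to
#' label permutation).
#'
#' @param l1,l2 named label vectors/factors (cell -> cluster).
#' @return List: \code{table}, \code{ari}, \code{nShared}.
#' @export
compareLabelings <- function(l1, l2) {
  if (is.null(names(l1)) || is.null(names(l2)))
    stop("labelings must be named by cell")
  shared <- intersect(names(l1), names(l2))
  if (!length(shared)) stop("empty intersection of cell sets")
  tab <- table(as.character(l1[shared]), as.character(l2[shared]))
  list(table = tab, ari = .ariFromTable(tab), nShared = length(shared))
}
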