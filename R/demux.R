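#' Read a FASTQ file
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet} that splits the
#' header line into read id (names) and comment (metadata column
#' \code{comment}, where instrument-style demultiplexed index reads such as
#' \code{1:N:0:ACGT+TTTT} live).
#'
#' @param path FASTQ(.gz) path.
#' @return \code{DNAStringSet} with names = read ids and a \code{comment}
#'   metadata column.
#' @export
readFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  hdr <- names(x)
  sp <- regexpr(" ", hdr, fixed = TRUE)
  id <- ifelse(sp > 0, substr(hdr, 1L, sp - 1L), hdr)
  cm <- ifelse(sp > 0, substr(hdr, sp + 1L, nchar(hdr)), "")
  names(x) <- id
  mcols(x)$comment <- cm
  x
}

#' Write a FASTQ file
#'
#' @param x \code{DNAStringSet}; names become read ids.
#' @param path output path; \code{.gz} suffix triggers compression.
#' @param comment optional per-read header comment.
#' @param qual optional \code{BStringSet} of qualities; constant Q40
#'   otherwise.
#' @return Invisibly, \code{path}.
#' @export
writeFastq <- function(x, path, comment = NULL, qual = NULL) {
  ids <- names(x)
  if (!is.null(comment)) ids <- paste(ids, comment)
  y <- x
  names(y) <- ids
  if (is.null(qual))
    qual <- Biostrings::BStringSet(vapply(Biostrings::width(y), function(w)
      strrep("I", w), character(1)))
  Biostrings::writeXStringSet(y, path, format = "fastq", qualities = qual,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Match observed barcodes against a whitelist
#'
#' Returns, for each observed barcode, the unique whitelist entry with
#' minimal Hamming distance at most \code{maxDist}; \code{ambiguous} when
#' two or more entries tie at the minimum and \code{nomatch} when the
#' minimum exceeds \code{maxDist}. Ambiguous reads are conservatively
#' discarded downstream. An exact-match fast path is used first; it is
#' equivalent to the full scan because whitelist entries are unique.
#'
#' @param observed character vector of observed barcode sequences.
#' @param whitelist character vector of expected barcodes (equal length,
#'   unique).
#' @param maxDist maximum Hamming distance accepted (default 2, the
#'   conventional tolerance for index correction).
#' @return \code{data.frame} with columns \code{entry} (corrected sequence
#'   or \code{NA}), \code{index}, \code{dist}, \code{status}.
#' @export
#' @examples
#' matchBarcode(c("ACGTACGA", "AAAAAAAA"), c("ACGTACGT", "TTTTTTTT"))
matchBarcode <- function(observed, whitelist, maxDist = 2) {
  len <- nchar(whitelist[1])
  if (any(nchar(whitelist) != len) || anyDuplicated(whitelist))
    stop("whitelist entries must be unique and of equal length")
  if (any(nchar(observed) != len))
    stop("input error: observed barcode length differs from whitelist")
  n <- length(observed)
  best <- rep.int(len + 1L, n)
  bestIdx <- rep.int(NA_integer_, n)
  ties <- integer(n)
  exact <- match(observed, whitelist)
  todo <- which(is.na(exact))
  if (length(todo)) {
    obsMat <- .charMatrix(observed[todo], len)
    wlMat <- .charMatrix(whitelist, len)
    bs <- best[todo]
    bi <- bestIdx[todo]
    ts <- ties[todo]
    for (j in seq_along(whitelist)) {
      d <- .hammingToEntry(obsMat, wlMat[j, ])
      eq <- d == bs
      ts[eq] <- ts[eq] + 1L
      lt <- d < bs
      bs[lt] <- d[lt]
      bi[lt] <- j
      ts[lt] <- 1L
    }
    best[todo] <- bs
    bestIdx[todo] <- bi
    ties[todo] <- ts
  }
  hit <- which(!is.na(exact))
  best[hit] <- 0L
  bestIdx[hit] <- exact[hit]
  ties[hit] <- 1L
  status <- rep("match", n)
  status[best > maxDist] <- "nomatch"
  status[best <= maxDist & ties > 1L] <- "ambiguous"
  ok <- status == "match"
  data.frame(entry = ifelse(ok, whitelist[bestIdx], NA_character_),
             index = ifelse(ok, bestIdx, NA_integer_),
             dist = ifelse(best > len, NA_integer_, best),
             status = status, stringsAsFactors = FALSE)
}

#' Restructure read 2
#'
#' The first 8 bases of read 2 are the tagmentation barcode; bases 9-29
#' carry the transposase mosaic-end recognition sequence and are removed;
#' the remainder is genomic. Reads shorter than 30 bases are dropped and
#' counted.
#'
#' @param read2 \code{DNAStringSet} of raw read-2 sequences.
#' @return List with \code{barcode} (character), \code{genomic}
#'   (\code{DNAStringSet}), \code{keep} (logical index into the input) and
#'   \code{nDropped}.
#' @export
restructureRead2 <- function(read2) {
  w <- Biostrings::width(read2)
  keep <- w >= 30L
  kept <- read2[keep]
  list(barcode = as.character(Biostrings::subseq(kept, 1L, 8L)),
       genomic = Biostrings::subseq(kept, 30L),
       keep = keep, nDropped = sum(!keep))
}

#' Demultiplex a read-pair stream by three barcodes
#'
#' Assigns each read pair to a cell when and only when all three indices
#' match their whitelists uniquely within \code{maxDist}. The two PCR
#' indices are taken from the header comment (\code{...:I1+I2}) or,
#' alternatively, from separate index-read sets; the tagmentation index is
#' the first 8 bp of read 2, which is then restructured. Cell ids are
#' built from the corrected whitelist sequences, never from the observed
#' ones.
#'
#' @param read1,read2 \code{DNAStringSet} pairs (read from
#'   \code{\link{readFastq}} or a \code{\link{SimReads}} object via
#'   \code{demultiplexSim}).
#' @param comment header comments carrying \code{index1+index2}; ignored
#'   when \code{index1}/\code{index2} are given.
#' @param whitelists list with \code{index1}, \code{index2}, \code{index3}.
#' @param maxDist Hamming tolerance per index.
#' @param index1,index2 optional \code{DNAStringSet}/character of separate
#'   index reads (same order as \code{read1}).
#' @return List: \code{assignments} (data.table readId/cell/status),
#'   \code{read1}, \code{read2genomic} (assigned reads only, named by
#'   read id), \code{cells} (per-read cell ids, assigned only) and
#'   \code{stats} (per-slot match/ambiguous/nomatch counts plus totals).
#' @export
demultiplex <- function(read1, read2, comment = NULL, whitelists,
                        maxDist = 2, index1 = NULL, index2 = NULL) {
  stopifnot(length(read1) == length(read2))
  n <- length(read1)
  if (is.null(index1) || is.null(index2)) {
    if (is.null(comment)) comment <- mcols(read1)$comment
    if (is.null(comment)) stop("no index source: provide comment or index reads")
    idx <- sub("^.*:", "", comment)
    parts <- strsplit(idx, "+", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("malformed index field in header comment at record ",
                       which(bad)[1])
    i1obs <- vapply(parts, `[`, character(1), 1L)
    i2obs <- vapply(parts, `[`, character(1), 2L)
  } else {
    i1obs <- as.character(index1)
    i2obs <- as.character(index2)
  }
  rs <- restructureRead2(read2)
  keep <- rs$keep
  m1 <- matchBarcode(i1obs[keep], whitelists$index1, maxDist)
  m2 <- matchBarcode(i2obs[keep], whitelists$index2, maxDist)
  m3 <- matchBarcode(rs$barcode, whitelists$index3, maxDist)
  assigned <- m1$status == "match" & m2$status == "match" & m3$status == "match"
  cell <- ifelse(assigned, paste0(m1$entry, m2$entry, m3$entry), NA_character_)
  ids <- names(read1)[keep]
  status <- ifelse(assigned, "assigned",
                   ifelse(m1$status == "ambiguous" | m2$status == "ambiguous" |
                            m3$status == "ambiguous", "ambiguous", "nomatch"))
  slotStats <- function(m) table(factor(m$status,
                                        c("match", "ambiguous", "nomatch")))
  stats <- list(index1 = slotStats(m1), index2 = slotStats(m2),
                index3 = slotStats(m3),
                total = n, tooShort = rs$nDropped, assigned = sum(assigned))
  r1k <- read1[keep][assigned]
  r2k <- rs$genomic[assigned]
  names(r1k) <- names(r2k) <- ids[assigned]
  list(assignments = data.table(readId = ids, cell = cell, status = status),
       read1 = r1k, read2genomic = r2k, cells = cell[assigned],
       stats = stats)
}

#' @rdname demultiplex
#' @param sim a \code{\link{SimReads}} object.
#' @param ... passed to \code{demultiplex}.
#' @export
demultiplexSim <- function(sim, maxDist = 2, ...) {
  demultiplex(sim@read1, sim@read2, comment = sim@headerComment,
              whitelists = sim@truth@whitelists, maxDist = maxDist, ...)
}

#' Downsample read pairs
#'
#' Uniform sampling without replacement, pairs kept intact, deterministic
#' for a fixed seed.
#'
#' @param read1,read2 paired \code{DNAStringSet}s.
#' @param n number of pairs to keep (must not exceed the total).
#' @param seed RNG seed.
#' @return List with the sampled \code{read1}, \code{read2} and the
#'   selected indices \code{idx}.
#' @export
downsampleReads <- function(read1, read2, n, seed = 1L) {
  stopifnot(length(read1) == length(read2))
  if (n > length(read1)) stop("n exceeds the number of read pairs")
  idx <- withSeed(deriveSeed(seed, "downsample"),
                  sort(sample.int(length(read1), n)))
  list(read1 = read1[idx], read2 = read2[idx], idx = idx)
}
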