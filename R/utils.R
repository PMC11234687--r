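#' @import methods
#' @importFrom stats rbinom rpois rnbinom runif rlnorm cor fisher.test p.adjust
#'   setNames complete.cases var phyper dhyper
#' @importFrom utils head tail write.table read.table packageVersion
#' @importFrom data.table data.table as.data.table setkey setkeyv setorder := .N .SD
#'   fread fwrite rbindlist setnames copy setattr
NULL

# evaluate `expr` under a private RNG state seeded with `seed`; the caller's
# RNG stream is untouched
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# deterministic sub-seed derivation (keeps results < 2^31 and independent-ish
# across stage labels)
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L) + 1L
}

#' Sizes of the hg38 main-series chromosomes
#'
#' Named vector of chromosome lengths (bp) for the human GRCh38/hg38
#' main-series chromosomes (chr1-22, X, Y), totalling 3,088,269,832 bp.
#' Used as the genome denominator in fold-enrichment worked examples.
#'
#' @return Named integer-valued numeric vector of chromosome sizes.
#' @export
#' @examples
#' sum(hg38MainChromSizes())
hg38MainChromSizes <- function() {
  c(chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
    chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
    chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
    chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
    chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
    chr21 = 46709983, chr22 = 50818468, chrX = 156040895, chrY = 57227415)
}

# Hamming distances between a character matrix of barcodes (rows) and one
# whitelist entry given as a character vector of bases
.hammingToEntry <- function(obsMat, entryChars) {
  d <- integer(nrow(obsMat))
  for (j in seq_along(entryChars)) d <- d + (obsMat[, j] != entryChars[j])
  d
}

# split fixed-length strings into an n x L character matrix
.charMatrix <- function(x, len = NULL) {
  if (is.null(len)) len <- nchar(x[1])
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         ncol = len, byrow = TRUE)
}

# collapse an n x L character matrix back to strings
.collapseRows <- function(m) {
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

.revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.stopifnotScalar <- function(x, name) {
  if (length(x) != 1 || is.na(x)) stop("'", name, "' must be a non-NA scalar")
}
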