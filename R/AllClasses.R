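#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' Simulation configuration
#'
#' Parameters of a synthetic capture-enriched single-cell bisulfite
#' experiment. Defaults describe the study conditions emulated at desk
#' scale: a 2 x 1 Mbp genome, four cell types of 50 cells, 40 planted
#' 1500-bp DMRs with a methylation-fraction difference of 0.5 against a
#' 0.8 baseline, a probe panel covering 4\% of the genome with 10x
#' capture oversampling, ~10\% PCR duplication, 99\% bisulfite conversion
#' and 100-bp paired reads.
#'
#' @slot nChromosomes number of chromosomes.
#' @slot chromLength chromosome length (bp).
#' @slot cpgRate per-position probability of planting a CpG dinucleotide.
#' @slot nCellTypes,cellsPerType cell-type structure.
#' @slot nDMRs,dmrLength,dmrDelta planted DMR count, length (bp) and
#'   methylation-fraction difference in \[0,1\].
#' @slot baselineMeth CpG methylation fraction outside DMRs.
#' @slot chMeth methylation fraction at non-CpG cytosines.
#' @slot targetFraction fraction of the genome covered by capture probes.
#' @slot probeLength length of one probe interval (bp).
#' @slot dmrOnTargetFrac fraction of DMRs placed inside probe intervals.
#' @slot captureWeight on-target fragment oversampling multiplier (>= 1).
#' @slot dupRate expected PCR duplicates per unique fragment (>= 0).
#' @slot conversionEfficiency probability an unmethylated C reads as T.
#' @slot errorRate per-base sequencing error probability.
#' @slot readsPerCell mean raw read pairs per cell.
#' @slot readDispersion negative-binomial size for per-cell read counts.
#' @slot readLength read length (bp); the usable genomic part of read 2 is
#'   \code{readLength - 29}.
#' @slot insertMean,insertSd log-normal insert-size parameters (bp scale).
#' @slot seed integer RNG seed; fixed seed gives byte-identical output.
#' @export
setClass("SimConfig", slots = c(
  nChromosomes = "integer", chromLength = "numeric", cpgRate = "numeric",
  nCellTypes = "integer", cellsPerType = "integer",
  nDMRs = "integer", dmrLength = "integer", dmrDelta = "numeric",
  baselineMeth = "numeric", chMeth = "numeric",
  targetFraction = "numeric", probeLength = "integer",
  dmrOnTargetFrac = "numeric", captureWeight = "numeric", dupRate = "numeric",
  conversionEfficiency = "numeric", errorRate = "numeric",
  readsPerCell = "numeric", readDispersion = "numeric",
  readLength = "integer", insertMean = "numeric", insertSd = "numeric",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  inUnit <- function(x) x >= 0 && x <= 1
  if (object@nChromosomes < 1) msg <- c(msg, "nChromosomes must be >= 1")
  if (object@chromLength < 1000) msg <- c(msg, "chromLength must be >= 1000")
  for (s in c("cpgRate", "dmrDelta", "baselineMeth", "chMeth",
              "dmrOnTargetFrac")) {
    if (!inUnit(slot(object, s))) msg <- c(msg, paste0(s, " must be in [0,1]"))
  }
  if (object@targetFraction <= 0 || object@targetFraction >= 1)
    msg <- c(msg, "targetFraction must be in (0,1)")
  if (object@conversionEfficiency <= 0 || object@conversionEfficiency > 1)
    msg <- c(msg, "conversionEfficiency must be in (0,1]")
  if (object@errorRate < 0 || object@errorRate > 0.5)
    msg <- c(msg, "errorRate must be in [0,0.5]")
  if (object@captureWeight < 1) msg <- c(msg, "captureWeight must be >= 1")
  if (object@dupRate < 0) msg <- c(msg, "dupRate must be >= 0")
  if (object@readLength < 30)
    msg <- c(msg, "readLength must be >= 30 (read 2 loses 29 bases)")
  if (as.numeric(object@nDMRs) * object@dmrLength >=
      as.numeric(object@nChromosomes) * object@chromLength)
    msg <- c(msg, "planted DMRs exceed total genome length")
  if (object@probeLength >= object@chromLength)
    msg <- c(msg, "probeLength must be smaller than chromLength")
  if (length(msg)) msg else TRUE
})

#' @param nChromosomes,chromLength,cpgRate,nCellTypes,cellsPerType,nDMRs,dmrLength,dmrDelta,baselineMeth,chMeth,targetFraction,probeLength,dmrOnTargetFrac,captureWeight,dupRate,conversionEfficiency,errorRate,readsPerCell,readDispersion,readLength,insertMean,insertSd,seed
#'   see the slot documentation.
#' @return A validated \code{SimConfig} object.
#' @rdname SimConfig-class
#' @export
#' @examples
#' SimConfig(nChromosomes = 1, chromLength = 5e4, readsPerCell = 50)
SimConfig <- function(nChromosomes = 2L, chromLength = 1e6, cpgRate = 0.02,
                      nCellTypes = 4L, cellsPerType = 50L,
                      nDMRs = 40L, dmrLength = 1500L, dmrDelta = 0.5,
                      baselineMeth = 0.8, chMeth = 0.01,
                      targetFraction = 0.04, probeLength = 500L,
                      dmrOnTargetFrac = 0.8, captureWeight = 10,
                      dupRate = 0.1, conversionEfficiency = 0.99,
                      errorRate = 0.001, readsPerCell = 1000,
                      readDispersion = 10, readLength = 100L,
                      insertMean = log(250), insertSd = 0.25, seed = 1L) {
  new("SimConfig",
      nChromosomes = as.integer(nChromosomes), chromLength = chromLength,
      cpgRate = cpgRate, nCellTypes = as.integer(nCellTypes),
      cellsPerType = as.integer(cellsPerType), nDMRs = as.integer(nDMRs),
      dmrLength = as.integer(dmrLength), dmrDelta = dmrDelta,
      baselineMeth = baselineMeth, chMeth = chMeth,
      targetFraction = targetFraction, probeLength = as.integer(probeLength),
      dmrOnTargetFrac = dmrOnTargetFrac, captureWeight = captureWeight,
      dupRate = dupRate, conversionEfficiency = conversionEfficiency,
      errorRate = errorRate, readsPerCell = readsPerCell,
      readDispersion = readDispersion, readLength = as.integer(readLength),
      insertMean = insertMean, insertSd = insertSd, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nChromosomes, "x",
      format(object@chromLength, big.mark = ","), "bp;",
      object@nCellTypes, "cell types x", object@cellsPerType, "cells;",
      object@nDMRs, "DMRs (delta", object@dmrDelta, ");",
      "target", object@targetFraction, "w", object@captureWeight, "\n")
})

#' Synthetic reference genome
#'
#' Reference sequences with the planted CpG dinucleotide positions and the
#' merged capture-probe panel. All coordinates are 0-based half-open.
#'
#' @slot seq \code{DNAStringSet} of chromosome sequences.
#' @slot cpgSites \code{GRanges} of CpG dinucleotides (width 2, 1-based
#'   start at the Watson C).
#' @slot probes \code{GRanges} of merged, non-overlapping probe intervals.
#' @export
setClass("SimGenome", slots = c(seq = "DNAStringSet", cpgSites = "GRanges",
                                probes = "GRanges"))

setMethod("show", "SimGenome", function(object) {
  cat("SimGenome:", length(object@seq), "chromosome(s),",
      format(sum(Biostrings::width(object@seq)), big.mark = ","), "bp;",
      length(object@cpgSites), "CpGs;",
      length(object@probes), "probe intervals (",
      format(sum(BiocGenerics::width(object@probes)), big.mark = ","),
      "bp )\n")
})

#' Accessors for simulated objects
#'
#' @param x a \code{SimGenome}, \code{SimMethylomes} or \code{SimTruth}.
#' @return \code{refSeqs}: the \code{DNAStringSet} of chromosome sequences;
#'   \code{cpgSites}/\code{probeSet}/\code{dmrTruth}: \code{GRanges};
#'   \code{cellTable}: a \code{data.frame} mapping cell barcode to type.
#' @name sim-accessors
NULL

#' @rdname sim-accessors
#' @export
refSeqs <- function(x) x@seq
#' @rdname sim-accessors
#' @export
cpgSites <- function(x) x@cpgSites
#' @rdname sim-accessors
#' @export
probeSet <- function(x) x@probes

#' Planted per-cell-type methylomes
#'
#' @slot prob matrix of methylation probabilities, cell types x CpG sites
#'   (columns parallel to \code{cpgSites(genome)}).
#' @slot dmrs \code{GRanges} of planted DMRs with metadata columns
#'   \code{type} (the affected cell type), \code{methAffected} and
#'   \code{methOthers} (the methylation fractions inside the DMR) and
#'   \code{onTarget}.
#' @export
setClass("SimMethylomes", slots = c(prob = "matrix", dmrs = "GRanges"))

setMethod("show", "SimMethylomes", function(object) {
  cat("SimMethylomes:", nrow(object@prob), "cell types x",
      ncol(object@prob), "CpGs;", length(object@dmrs), "planted DMRs\n")
})

#' @rdname sim-accessors
#' @export
dmrTruth <- function(x) x@dmrs

#' Simulation ground truth
#'
#' @slot cellTable data.frame: \code{cell} (corrected barcode
#'   concatenation), \code{type}, and the three whitelist entries used.
#' @slot dmrs planted DMR \code{GRanges} (see \code{SimMethylomes}).
#' @slot probes merged probe panel \code{GRanges}.
#' @slot expectedOnTargetFraction closed-form w t / (w t + 1 - t).
#' @slot duplicateMap data.frame: \code{readId} -> \code{fragId}, plus the
#'   fragment's true coordinates (1-based inclusive), strand and capture
#'   status.
#' @slot whitelists list of the three barcode whitelists.
#' @slot nSkipped fragments skipped because the insert was shorter than the
#'   read length.
#' @export
setClass("SimTruth", slots = c(
  cellTable = "data.frame", dmrs = "GRanges", probes = "GRanges",
  expectedOnTargetFraction = "numeric", duplicateMap = "data.frame",
  whitelists = "list", nSkipped = "integer"))

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@cellTable), "cells;",
      nrow(object@duplicateMap), "read pairs;",
      "expected on-target", round(object@expectedOnTargetFraction, 4), "\n")
})

#' @rdname sim-accessors
#' @export
cellTable <- function(x) x@cellTable
#' @rdname sim-accessors
#' @export
duplicateMap <- function(x) x@duplicateMap

#' Simulated paired reads
#'
#' In-memory paired FASTQ records following the combinatorial-index read
#' structure: read 1 is genomic; read 2 carries the 8-bp tagmentation
#' barcode, a 21-bp mosaic-end spacer, then genomic sequence. The two PCR
#' indices ride in the header comment (\code{1:N:0:index1+index2}).
#'
#' @slot read1,read2 \code{DNAStringSet}, names are read ids.
#' @slot headerComment character vector of header comments.
#' @slot truth the \code{SimTruth}.
#' @export
setClass("SimReads", slots = c(read1 = "DNAStringSet", read2 = "DNAStringSet",
                               headerComment = "character", truth = "SimTruth"))

setMethod("show", "SimReads", function(object) {
  cat("SimReads:", length(object@read1), "read pairs from",
      nrow(object@truth@cellTable), "cells\n")
})

#' @rdname sim-accessors
#' @param x object carrying simulation truth.
#' @export
simTruth <- function(x) x@truth

#' Windowed methylation matrix
#'
#' A \code{RangedSummarizedExperiment} with windows as rows and cells (or
#' clusters) as columns, carrying two assays: \code{meth} (methylated call
#' counts) and \code{total} (all calls), both sparse. Methylation
#' percentages are derived on demand via \code{\link{methPct}} so that the
#' coverage filter stays explicit.
#'
#' @slot windowKind one of "tiling", "sliding", "target".
#' @slot windowSize,windowStep window geometry (bp); step is \code{NA} for
#'   target windows.
#' @slot context "CG" or "CH".
#' @export
setClass("MethWindowMatrix", contains = "RangedSummarizedExperiment",
         slots = c(windowKind = "character", windowSize = "numeric",
                   windowStep = "numeric", context = "character"))

setValidity("MethWindowMatrix", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("meth", "total") %in% a))
    return("assays 'meth' and 'total' are required")
  m <- SummarizedExperiment::assay(object, "meth")
  tt <- SummarizedExperiment::assay(object, "total")
  if (any(m@x < 0) || any(tt@x < 0)) return("counts must be non-negative")
  if (any(m@x > 0) && max(m - tt) > 0) return("meth cannot exceed total")
  TRUE
})

setMethod("show", "MethWindowMatrix", function(object) {
  cat("MethWindowMatrix (", object@context, "):", nrow(object), object@windowKind,
      "windows x", ncol(object), "columns\n")
  cov <- Matrix::colSums(SummarizedExperiment::assay(object, "total"))
  cat("  median calls per column:", stats::median(cov), "\n")
})
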