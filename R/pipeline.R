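.KNOWN_CONFIG <- list(
  global = c("seed", "outDir", "logLevel"),
  simulate = c("nChromosomes", "chromLength", "cpgRate", "nCellTypes",
               "cellsPerType", "nDMRs", "dmrLength", "dmrDelta",
               "baselineMeth", "chMeth", "targetFraction", "probeLength",
               "dmrOnTargetFrac", "captureWeight", "dupRate",
               "conversionEfficiency", "errorRate", "readsPerCell",
               "readDispersion", "readLength", "insertMean", "insertSd"),
  demux = c("maxDist"),
  align = c("maxMismatch", "swapMates", "maxInsert"),
  rmdup = c("key"),
  extract = character(),
  qc = character(),
  enrich = c("pad", "minOverlap"),
  matrix = c("windowKind", "windowSize", "windowStep", "context"),
  cluster = c("d", "k", "resolution", "minCalls", "dropFirst"),
  dmr = c("qMax", "diffMin", "minCov", "windowSize", "windowStep"))

.validateConfig <- function(config) {
  bad <- setdiff(names(config), names(.KNOWN_CONFIG))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (blk in names(config)) {
    extra <- setdiff(names(config[[blk]]), .KNOWN_CONFIG[[blk]])
    if (length(extra))
      stop("unknown key(s) in config block '", blk, "': ",
           paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}

.stageFile <- function(outDir, stage) file.path(outDir, "state",
                                                paste0(stage, ".rds"))

.loadStage <- function(outDir, stage) {
  f <- .stageFile(outDir, stage)
  if (!file.exists(f))
    stop("missing upstream output for stage '", stage,
         "': run that stage first")
  readRDS(f)
}

#' Run the processing pipeline
#'
#' Orchestrates the stages (simulate, demux, align, rmdup, extract, qc,
#' enrich, matrix, cluster, dmr) over a validated configuration. Stage
#' outputs are checkpointed under \code{outDir/state} and reused on
#' resume, so re-running a suffix of the stage list reproduces a fresh
#' run exactly (all randomness is keyed off the global seed). A
#' provenance manifest (package version, parameters, stage timings) is
#' written to \code{outDir/manifest.json}, and the configuration is
#' serialized verbatim alongside it.
#'
#' @param config nested list of per-stage parameter blocks (or a YAML file
#'   path); unknown keys are rejected before any stage runs.
#' @param outDir output directory.
#' @param stages ordered subset of stages to run.
#' @return Invisibly, a list with the final stage outputs.
#' @export
runPipeline <- function(config = list(), outDir,
                        stages = c("simulate", "demux", "align", "rmdup",
                                   "extract", "qc", "enrich", "matrix",
                                   "cluster", "dmr")) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  .validateConfig(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(file.path(outDir, "state"), showWarnings = FALSE,
             recursive = TRUE)
  seed <- config$global$seed %||% 1L
  cfg <- function(blk) config[[blk]] %||% list()
  manifest <- list(package = "scMethCap",
                   version = as.character(packageVersion("scMethCap")),
                   seed = seed, config = config,
                   started = format(Sys.time()), stages = list())
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  save <- function(stage, value) {
    saveRDS(value, .stageFile(outDir, stage))
    manifest$stages[[stage]] <<- list(done = format(Sys.time()))
    value
  }
  out <- list()

  for (stage in stages) {
    message("[", format(Sys.time(), "%H:%M:%S"), "] stage: ", stage)
    out[[stage]] <- switch(stage,
      simulate = {
        sc <- do.call(SimConfig, c(cfg("simulate"), list(seed = seed)))
        save("simulate", simulateExperiment(sc))
      },
      demux = {
        sim <- out$simulate %||% .loadStage(outDir, "simulate")
        p <- cfg("demux")
        save("demux", demultiplexSim(sim$reads,
                                     maxDist = p$maxDist %||% 2))
      },
      align = {
        sim <- out$simulate %||% .loadStage(outDir, "simulate")
        dx <- out$demux %||% .loadStage(outDir, "demux")
        p <- cfg("align")
        save("align", alignPairsToy(dx$read1, dx$read2genomic, dx$cells,
                                    sim$genome,
                                    maxMismatch = p$maxMismatch %||% 2,
                                    swapMates = p$swapMates %||% TRUE,
                                    maxInsert = p$maxInsert %||% 2000))
      },
      rmdup = {
        al <- out$align %||% .loadStage(outDir, "align")
        p <- cfg("rmdup")
        save("rmdup", rmdupPE(al$alignments, key = p$key %||% "fragment"))
      },
      extract = {
        sim <- out$simulate %||% .loadStage(outDir, "simulate")
        rd <- out$rmdup %||% .loadStage(outDir, "rmdup")
        ex <- extractCalls(rd$alignments, sim$genome)
        writeCallFiles(ex$calls, file.path(outDir, "calls"))
        save("extract", ex)
      },
      qc = {
        al <- out$align %||% .loadStage(outDir, "align")
        rd <- out$rmdup %||% .loadStage(outDir, "rmdup")
        ex <- out$extract %||% .loadStage(outDir, "extract")
        qc <- cellQC(ex$calls, al$alignments, rd$alignments)
        fwrite(qc, file.path(outDir, "cell_qc.tsv"), sep = "\t")
        save("qc", qc)
      },
      enrich = {
        sim <- out$simulate %||% .loadStage(outDir, "simulate")
        al <- out$align %||% .loadStage(outDir, "align")
        rd <- out$rmdup %||% .loadStage(outDir, "rmdup")
        p <- cfg("enrich")
        sizes <- setNames(GenomeInfoDb::seqlengths(
          .genomeSeqinfo(sim$genome@seq)), names(sim$genome@seq))
        probes <- buildProbeSet(sim$genome@probes, sizes)
        er <- enrichmentReport(al$alignments, rd$alignments, probes,
                                pad = p$pad %||% 200)
        jsonlite::write_json(
          er[c("pctOnTargetPre", "pctOnTargetPost", "foldPre", "foldPost",
                "pctShadow")],
          file.path(outDir, "enrichment.json"), auto_unbox = TRUE)
        save("enrich", er)
      },
      matrix = {
        sim <- out$simulate %||% .loadStage(outDir, "simulate")
        ex <- out$extract %||% .loadStage(outDir, "extract")
        p <- cfg("matrix")
        kind <- p$windowKind %||% "target"
        win <- if (kind == "target") {
          makeWindows(sim$genome@probes, "target")
        } else {
          sizes <- setNames(Biostrings::width(sim$genome@seq),
                            names(sim$genome@seq))
          makeWindows(sizes, kind, size = p$windowSize %||% 50000,
                      step = p$windowStep)
        }
        save("matrix", meth2mtx(ex$calls, win,
                                context = p$context %||% "CG"))
      },
      cluster = {
        wm <- out$matrix %||% .loadStage(outDir, "matrix")
        p <- cfg("cluster")
        scores <- reduceDims(wm, d = p$d %||% 50,
                             minCalls = p$minCalls %||% 1,
                             dropFirst = p$dropFirst %||% FALSE, seed = seed)
        labels <- clusterCells(scores, k = p$k %||% 20,
                               resolution = p$resolution %||% 1, seed = seed)
        emb <- embedUMAP(scores, seed = seed)
        fwrite(data.table(cell = names(labels), cluster = as.character(labels),
                          UMAP1 = emb[, 1], UMAP2 = emb[, 2]),
               file.path(outDir, "clusters.tsv"), sep = "\t")
        save("cluster", list(scores = scores, labels = labels,
                             embedding = emb))
      },
      dmr = {
        sim <- out$simulate %||% .loadStage(outDir, "simulate")
        ex <- out$extract %||% .loadStage(outDir, "extract")
        cl <- out$cluster %||% .loadStage(outDir, "cluster")
        p <- cfg("dmr")
        sizes <- setNames(Biostrings::width(sim$genome@seq),
                          names(sim$genome@seq))
        win <- makeWindows(sizes, "sliding", size = p$windowSize %||% 1500,
                           step = p$windowStep %||% 500)
        wm <- meth2mtx(ex$calls, win, context = "CG")
        agg <- aggregateByCluster(wm, cl$labels)
        dm <- callDMRs(agg, qMax = p$qMax %||% 1e-4,
                       diffMin = p$diffMin %||% 25,
                       minCov = p$minCov %||% 10)
        fwrite(dm$windows[pass == TRUE],
               file.path(outDir, "dmr_windows.tsv"), sep = "\t")
        if (length(dm$regions))
          writeBed(dm$regions, file.path(outDir, "dmr_regions.bed"))
        exportBedgraph(agg, file.path(outDir, "bedgraph"))
        save("dmr", dm)
      })
  }
  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
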