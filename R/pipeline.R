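#' Run the whole pipeline with one call
#'
#' Orchestrates read preprocessing, single-pass pseudo-genome alignment
#' with coordinate restoration, PCR-duplicate removal, per-CpG methylation
#' calling, spike-in conversion-rate estimation, QC profiling and HTML
#' report rendering.  Each stage writes its artifact plus a
#' \code{.stage_<name>.done} marker; with \code{resume = TRUE} completed
#' stages are skipped.  All randomness flows from \code{seed}, and outputs
#' are byte-identical regardless of \code{threads} (chunks merge in input
#' order).
#'
#' @param r1,r2 FASTQ path(s) (vectors are treated as lanes and
#'   concatenated); \code{r2 = NULL} for single-end data.
#' @param fasta Reference FASTA (used to build the index when
#'   \code{indexDir} is NULL or empty).
#' @param indexDir Pseudo-genome index directory (built by
#'   \code{\link{writeGenomeIndex}}); built on the fly from \code{fasta}
#'   when absent.
#' @param mode \code{"three_letter"} or \code{"four_letter"}.
#' @param chem \code{"bisulfite"} or \code{"taps"} (mandatory; the two
#'   chemistries have inverted calling semantics).
#' @param outDir Output directory.
#' @param tss Optional BED6 of transcript start sites for the meta-profile.
#' @param spikeInNames Chromosome names treated as spike-in controls.
#' @param trimCfg,alignCfg Stage configurations
#'   (\code{\link{trimConfig}}, \code{\link{alignConfig}}).
#' @param minQual,minMapq Calling filters.
#' @param threads Worker count for the alignment stage.
#' @param seed Integer seed for all randomized behavior.
#' @param resume Skip stages whose marker and artifacts already exist.
#' @param timestamp Run timestamp string embedded in report metadata
#'   (injected, not sampled, so reruns are reproducible).
#' @return Invisibly, a list with the principal artifacts' paths, the
#'   \linkS4class{QCBundle} and the per-stage statistics.
#' @export
runPipeline <- function(r1, r2 = NULL, fasta = NULL, indexDir = NULL,
                        mode = c("three_letter", "four_letter"),
                        chem = c("bisulfite", "taps"),
                        outDir, tss = NULL, spikeInNames = "lambda",
                        trimCfg = trimConfig(), alignCfg = alignConfig(),
                        minQual = 20L, minMapq = 20L, threads = 1L,
                        seed = 1L, resume = FALSE,
                        timestamp = "1970-01-01T00:00:00Z") {
  if (missing(chem)) stop("chem must be given ('bisulfite' or 'taps')")
  if (missing(mode)) stop("mode must be given ('three_letter' or 'four_letter')")
  mode <- match.arg(mode)
  chem <- match.arg(chem)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  alignCfg$seed <- as.integer(seed)

  marker <- function(stage) file.path(outDir, sprintf(".stage_%s.done", stage))
  done <- function(stage) resume && file.exists(marker(stage))
  finish <- function(stage) writeLines(timestamp, marker(stage))
  log <- function(...) message(sprintf("[metharc] %s", sprintf(...)))
  timings <- list()
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    v
  }

  cfgEcho <- list(mode = mode, chem = chem, seed = seed, threads = threads,
                  r1 = r1, r2 = r2, fasta = fasta, indexDir = indexDir,
                  tss = tss, spike_ins = spikeInNames,
                  min_qual = minQual, min_mapq = minMapq,
                  trim = trimCfg, align = alignCfg,
                  version = as.character(utils::packageVersion("metharc")),
                  timestamp = timestamp)
  jsonlite::write_json(cfgEcho, file.path(outDir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  # ---- stage: index --------------------------------------------------------
  if (is.null(indexDir)) indexDir <- file.path(outDir, "index")
  if (!file.exists(file.path(indexDir, "manifest.json"))) {
    if (is.null(fasta))
      stop("no index found and no fasta given to build one")
    log("building %s pseudo-genome index", mode)
    ref <- loadFasta(fasta, spikeIns = spikeInNames)
    pg <- buildPseudoGenome(ref, mode)
    idxGr <- buildCpGIndex(ref)
    writeGenomeIndex(pg, idxGr, ref, indexDir)
  }
  ix <- readGenomeIndex(indexDir, mode = mode)
  ref <- ix$ref; pg <- ix$pg; idxGr <- ix$idx

  # ---- stage: trim ---------------------------------------------------------
  trimRds <- file.path(outDir, "trimmed.rds")
  if (done("trim") && file.exists(trimRds)) {
    log("resume: skipping trim")
    trimmed <- readRDS(trimRds)
  } else {
    log("trimming reads")
    trimmed <- timed("trim", {
      raw1 <- readFastqFiles(r1)
      raw2 <- if (!is.null(r2)) readFastqFiles(r2)
      trimReadPairs(raw1, raw2, trimCfg)
    })
    writeFastq(trimmed$r1, file.path(outDir, "trimmed_R1.fq.gz"))
    if (!trimmed$single_end)
      writeFastq(trimmed$r2, file.path(outDir, "trimmed_R2.fq.gz"))
    saveRDS(trimmed, trimRds)
    finish("trim")
  }

  # ---- stage: align --------------------------------------------------------
  alnRds <- file.path(outDir, "alignments.rds")
  samPath <- file.path(outDir, "alignments.sam")
  if (done("align") && file.exists(alnRds)) {
    log("resume: skipping align")
    aln <- readRDS(alnRds)
  } else {
    log("aligning %d read (pair)s", length(trimmed$r1$seq))
    aln <- timed("align", {
      pa <- builtinAlign(trimmed, pg, alignCfg, threads = threads)
      restoreAlignments(pa, trimmed, pg, ref)
    })
    writeSamFile(aln, ref, samPath, bam = TRUE,
                 programLine = paste0("@PG\tID:metharc\tPN:metharc\tVN:",
                                      utils::packageVersion("metharc")))
    saveRDS(aln, alnRds)
    finish("align")
  }
  nReadsRaw <- trimmed$stats$total_pairs * (if (is.null(r2)) 1L else 2L)

  # ---- stage: methcall -----------------------------------------------------
  callRds <- file.path(outDir, "methcall.rds")
  if (done("methcall") && file.exists(callRds)) {
    log("resume: skipping methcall")
    mc <- readRDS(callRds)
  } else {
    log("removing duplicates and calling methylation (%s)", chem)
    mc <- timed("methcall", {
      dd <- dedupAlignments(aln, minMapq = minMapq)
      calls <- callCpGs(dd$alignments, ref, idxGr, chem,
                        minQual = minQual, minMapq = minMapq)
      conv <- withCallingHandlers(
        conversionRate(dd$alignments, ref, chem, minQual, minMapq),
        warning = function(w) invokeRestart("muffleWarning"))
      mb <- mBias(dd$alignments, ref, idxGr, chem, minQual, minMapq)
      lv <- perChromosomeLevels(calls, ref)
      sz <- sizeDistribution(dd$alignments)
      list(dedup = dd$stats, calls = calls, conv = conv, mbias = mb,
           levels = lv, sizes = sz)
    })
    writeCpGCalls(mc$calls[is_spike_in == FALSE],
                  file.path(outDir, "cpg_calls.tsv"))
    writeCpGCalls(mc$calls[is_spike_in == FALSE],
                  file.path(outDir, "cpg_calls.bedgraph"),
                  format = "bedgraph")
    saveRDS(mc, callRds)
    finish("methcall")
  }

  # ---- stage: report -------------------------------------------------------
  reportPath <- file.path(outDir, "report", "report.html")
  if (!(done("report") && file.exists(reportPath))) {
    log("rendering report")
    tssTab <- if (!is.null(tss)) readTssBed(tss)
    profile <- if (is.null(tssTab)) list(skipped = TRUE)
      else tssProfile(mc$calls[is_spike_in == FALSE], tssTab)
    bundle <- QCBundle(
      # resource settings (threads, paths) stay out of the bundle so that
      # reports from identical analyses are byte-identical
      run = list(mode = mode, chemistry = chem, seed = seed,
                 timestamp = timestamp,
                 version = as.character(utils::packageVersion("metharc"))),
      trim = trimmed$stats,
      alignment = list(n_reads = nReadsRaw,
                       n_mapped = nrow(aln),
                       dedup = mc$dedup),
      conversion = mc$conv,
      methylation = list(overall = attr(mc$levels, "overall"),
                         per_chromosome = mc$levels),
      mbias = mc$mbias,
      sizes = mc$sizes,
      tss = profile)
    statsOut <- qcStats(bundle)
    statsOut$mbias <- as.data.frame(statsOut$mbias)
    statsOut$methylation$per_chromosome <-
      as.list(statsOut$methylation$per_chromosome)
    jsonlite::write_json(
      statsOut[c("run", "alignment", "conversion", "methylation")],
      file.path(outDir, "stats.json"), auto_unbox = TRUE, pretty = TRUE,
      force = TRUE, digits = NA)
    timed("report", renderReport(bundle, file.path(outDir, "report")))
    saveRDS(bundle, file.path(outDir, "bundle.rds"))
    finish("report")
  } else {
    log("resume: skipping report")
    bundle <- readRDS(file.path(outDir, "bundle.rds"))
  }

  if (length(timings))
    log("stage timings (s): %s",
        paste(names(timings), unlist(timings), sep = "=", collapse = ", "))
  invisible(list(outDir = outDir, sam = samPath,
                 cpg_calls = file.path(outDir, "cpg_calls.tsv"),
                 report = reportPath, bundle = bundle,
                 alignments = aln, methcall = mc, timings = timings))
}
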