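## Orchestration: filter -> index -> map -> peaks -> classify, per
## contig, plus all report artifacts. Contigs are independent work
## units; the per-contig stage can run on several cores with
## bit-identical output.

#' Run the whole termini-detection workflow
#'
#' Reads contigs and reads, maps read starts, calls start-enriched
#' peaks per contig, classifies each contig's packaging mechanism and
#' writes the report artifacts (`report.csv`, `termini_rotated.fasta`,
#' per-contig coverage TSVs, `run.log`).
#'
#' @param fasta contig FASTA path, or a [Biostrings::DNAStringSet].
#' @param r1 FASTQ path (R1), or a character vector of read sequences.
#' @param r2 optional mate FASTQ path (or sequence vector).
#' @param outDir output directory, created if needed; `NULL` suppresses
#'   all file output (results are only returned).
#' @param seedLen mapping seed length (`--seed-len`, default 20).
#' @param minContigLen minimum contig length (`--limit`, default 500).
#' @param cores worker count for the per-contig stage (`--core`); output
#'   is identical for any value.
#' @param alpha,tauMin,minCov,mergeWindow see [callPeaks()].
#' @param maxOverhang,maxDtr,dtrRatioMin see [classifyPackaging()].
#' @param minMeanCov optional mean-coverage floor: contigs below it are
#'   reported as LOW_COVERAGE without testing (default 0 = off; ~10x is
#'   a reasonable choice to harden results).
#' @param chunkSize reads per mapping chunk.
#' @param plots also write per-contig PNG coverage plots.
#' @param verbose log progress via [message()].
#' @return invisibly, a list with `predictions`, `peakSets`, `profiles`,
#'   `contigs`, `summary` (per-mechanism counts), `log` (character) and
#'   `paths`.
#' @export
runPipeline <- function(fasta, r1, r2 = NULL, outDir = NULL,
                        seedLen = 20L, minContigLen = 500L, cores = 1L,
                        alpha = 0.01, tauMin = 0.1, minCov = 10L,
                        mergeWindow = 20L, maxOverhang = 20L,
                        maxDtr = 10000L, dtrRatioMin = 1.4,
                        minMeanCov = 0, chunkSize = 200000L,
                        plots = FALSE, verbose = TRUE) {
  logLines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    logLines <<- c(logLines, msg)
    if (verbose) message(msg)
  }

  contigs <- if (is.character(fasta) && length(fasta) == 1L)
    readContigs(fasta) else fasta
  if (!is(contigs, "DNAStringSet")) stop("fasta must be a path or DNAStringSet")
  note("contigs read: %d", length(contigs))
  nBefore <- length(contigs)
  contigs <- suppressWarnings(filterContigs(contigs, minContigLen))
  note("contigs below %d bp skipped: %d", minContigLen, nBefore - length(contigs))
  if (length(contigs) == 0L)
    stop("no contigs of length >= ", minContigLen, " bp to analyze")

  index <- buildSeedIndex(contigs, k = seedLen)
  fromFiles <- is.character(r1) && length(r1) == 1L && file.exists(r1)
  if (fromFiles) {
    streamer <- streamReads(r1, r2, chunkSize = chunkSize)
    profiles <- accumulateProfiles(index, streamer, chunkSize = chunkSize)
    note("read pairs parsed: %d", streamer$totalReads())
  } else {
    profiles <- accumulateProfiles(index, r1, mates = r2,
                                   chunkSize = chunkSize)
  }
  for (p in profiles) {
    note("contig %s: %d reads used, %d ambiguous skipped, mean coverage %.1fx",
         p@contigId, p@nReadsUsed, p@nAmbiguousSkipped, meanCoverage(p))
  }

  analyseOne <- function(p) {
    if (minMeanCov > 0 && meanCoverage(p) < minMeanCov) {
      ps <- new("PeakSet", contigId = p@contigId, primaryFwd = NULL,
                primaryRev = NULL, secondary = list(),
                meanCov = meanCoverage(p), lowCoverage = TRUE)
      pred <- .TerminiPrediction(
        p@contigId, "LOW_COVERAGE",
        warnings = sprintf("mean coverage %.1fx below floor %.1fx; not tested",
                           meanCoverage(p), minMeanCov))
      return(list(peaks = ps, pred = pred))
    }
    ps <- callPeaks(p, alpha = alpha, tauMin = tauMin, minCov = minCov,
                    mergeWindow = mergeWindow, seedLen = seedLen)
    pred <- classifyPackaging(ps, p, maxOverhang = maxOverhang,
                              maxDtr = maxDtr, dtrRatioMin = dtrRatioMin,
                              guard = mergeWindow)
    list(peaks = ps, pred = pred)
  }
  res <- if (cores > 1L) {
    parallel::mclapply(profiles, analyseOne, mc.cores = cores)
  } else {
    lapply(profiles, analyseOne)
  }
  peakSets <- lapply(res, `[[`, "peaks")
  predictions <- lapply(res, `[[`, "pred")

  classes <- vapply(predictions, mechanism, character(1))
  summary <- table(factor(classes, levels = MECHANISM_CODES))
  for (cl in names(summary)[summary > 0])
    note("class %s: %d contig(s)", mechanismLabel(cl), summary[[cl]])

  paths <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      csv = file.path(outDir, "report.csv"),
      fasta = file.path(outDir, "termini_rotated.fasta"),
      coverageDir = file.path(outDir, "coverage"),
      log = file.path(outDir, "run.log"))
    writeCsvReport(predictions, peakSets, profiles, paths$csv)
    writeReorganizedFasta(contigs, predictions, paths$fasta)
    writeCoverageTables(profiles, peakSets, paths$coverageDir, plots = plots)
    writeLines(logLines, paths$log)
    note("artifacts written under %s", outDir)
  }

  invisible(list(predictions = predictions, peakSets = peakSets,
                 profiles = profiles, contigs = contigs,
                 summary = summary, log = logLines, paths = paths))
}
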