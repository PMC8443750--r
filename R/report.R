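## User-facing artifacts: CSV prediction table, termini-rotated FASTA,
## per-contig coverage tables and optional plots. All positions in these
## files are 1-based inclusive; absent values are rendered as "-".

.REPORT_COLUMNS <- c(
  "contig_id", "length", "n_reads_used", "mean_coverage", "mechanism",
  "term_fwd", "term_rev", "overhang_len", "repeat_len", "pac_strand",
  "peak_fwd_spc", "peak_fwd_cov", "peak_fwd_tau", "peak_fwd_qval",
  "peak_rev_spc", "peak_rev_cov", "peak_rev_tau", "peak_rev_qval",
  "elevation_ratio", "n_secondary_peaks", "warnings")

.fmtNum <- function(x, digits) {
  if (length(x) != 1L || is.na(x)) return("-")
  if (is.infinite(x)) return("Inf")
  formatC(x, digits = digits, format = "g")
}

#' Write the per-contig prediction CSV
#'
#' One row per analyzed contig with the mechanism call, termini (1-based),
#' the primary peak statistics per strand and the secondary peak count.
#'
#' @param predictions list of [TerminiPrediction-class].
#' @param peakSets list of [PeakSet-class] (same order).
#' @param profiles list of [CoverageProfiles-class] (same order).
#' @param path output CSV path.
#' @return invisibly, the written `data.frame` (all character columns,
#'   `"-"` for absent values).
#' @export
writeCsvReport <- function(predictions, peakSets, profiles, path) {
  stopifnot(length(predictions) == length(peakSets),
            length(predictions) == length(profiles))
  rows <- lapply(seq_along(predictions), function(i) {
    pred <- predictions[[i]]
    ps <- peakSets[[i]]
    pro <- profiles[[i]]
    pk <- function(p, what) {
      if (is.null(p)) return("-")
      switch(what,
             spc = as.character(p@spc), cov = as.character(p@cov),
             tau = .fmtNum(p@tau, 4L), qval = .fmtNum(p@qval, 4L))
    }
    c(contig_id = pred@contigId,
      length = as.character(length(pro@spcFwd)),
      n_reads_used = as.character(pro@nReadsUsed),
      mean_coverage = .fmtNum(meanCoverage(pro), 6L),
      mechanism = mechanismLabel(pred@mechanism),
      term_fwd = .fmtNA(pred@termFwd),
      term_rev = .fmtNA(pred@termRev),
      overhang_len = .fmtNA(pred@overhangLen),
      repeat_len = .fmtNA(pred@repeatLen),
      pac_strand = .fmtNA(pred@pacStrand),
      peak_fwd_spc = pk(ps@primaryFwd, "spc"),
      peak_fwd_cov = pk(ps@primaryFwd, "cov"),
      peak_fwd_tau = pk(ps@primaryFwd, "tau"),
      peak_fwd_qval = pk(ps@primaryFwd, "qval"),
      peak_rev_spc = pk(ps@primaryRev, "spc"),
      peak_rev_cov = pk(ps@primaryRev, "cov"),
      peak_rev_tau = pk(ps@primaryRev, "tau"),
      peak_rev_qval = pk(ps@primaryRev, "qval"),
      elevation_ratio = .fmtNum(pred@elevationRatio, 4L),
      n_secondary_peaks = as.character(length(ps@secondary)),
      warnings = paste(pred@warnings, collapse = "; "))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  colnames(df) <- .REPORT_COLUMNS
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(df)
}

#' Write contigs reorganised to start at their predicted termini
#'
#' Only contigs with a successful prediction (cos, DTR or headful pac)
#' are rewritten: each is rotated so its left terminus (`term_fwd` for
#' cos/DTR, the pac peak for headful) becomes position 1. The header is
#' annotated with the mechanism and the original 1-based offset, so
#' rotating the output back by `original_offset - 1` reproduces the
#' input.
#'
#' @param contigs [Biostrings::DNAStringSet] of the analyzed contigs.
#' @param predictions list of [TerminiPrediction-class].
#' @param path output FASTA path.
#' @return invisibly, the ids written.
#' @export
writeReorganizedFasta <- function(contigs, predictions, path) {
  keep <- vapply(predictions, function(p)
    p@mechanism %in% c("COS_5P", "COS_3P", "DTR", "HEADFUL_PAC"), logical(1))
  preds <- predictions[keep]
  if (!length(preds)) {
    writeLines(character(0), path)
    return(invisible(character(0)))
  }
  seqs <- character(length(preds))
  heads <- character(length(preds))
  for (i in seq_along(preds)) {
    p <- preds[[i]]
    left1 <- if (p@mechanism == "HEADFUL_PAC") {
      if (is.na(p@termFwd)) p@termRev else p@termFwd
    } else p@termFwd
    seqs[i] <- rotateToStart(as.character(contigs[[p@contigId]]), left1 - 1L)
    heads[i] <- sprintf("%s mechanism=%s original_offset=%d", p@contigId,
                        gsub(" ", "_", mechanismLabel(p@mechanism)), left1)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- heads
  Biostrings::writeXStringSet(out, path)
  invisible(vapply(preds, contigId, character(1)))
}

#' Write per-contig coverage/SPC tables (and optional plots)
#'
#' One TSV per contig with columns `position` (1-based), `cov_fwd`,
#' `cov_rev`, `spc_fwd`, `spc_rev` and `flag` marking primary/secondary
#' peak rows; optionally a PNG coverage plot per contig.
#'
#' @param profiles list of [CoverageProfiles-class].
#' @param peakSets matching list of [PeakSet-class].
#' @param outDir output directory (created if needed).
#' @param plots also render a PNG per contig (default `FALSE`).
#' @return invisibly, the TSV paths.
#' @export
writeCoverageTables <- function(profiles, peakSets, outDir, plots = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(profiles))
  for (i in seq_along(profiles)) {
    pro <- profiles[[i]]
    ps <- peakSets[[i]]
    L <- length(pro@spcFwd)
    flag <- character(L)
    mark <- function(p, what) {
      if (!is.null(p)) flag[p@pos + 1L] <<- what
    }
    for (s in ps@secondary) mark(s, "secondary")
    mark(ps@primaryFwd, "primary")
    mark(ps@primaryRev, "primary")
    dt <- data.table(position = seq_len(L), cov_fwd = pro@covFwd,
                     cov_rev = pro@covRev, spc_fwd = pro@spcFwd,
                     spc_rev = pro@spcRev, flag = flag)
    paths[i] <- file.path(outDir, paste0(pro@contigId, "_coverage.tsv"))
    fwrite(dt, paths[i], sep = "\t")
    if (plots) {
      png(file.path(outDir, paste0(pro@contigId, "_coverage.png")),
          width = 1200, height = 500)
      plotCoverage(pro, ps)
      dev.off()
    }
  }
  invisible(paths)
}

#' Plot total coverage and SPC with peak annotations
#'
#' @param profiles a [CoverageProfiles-class].
#' @param peaks optional [PeakSet-class] to annotate.
#' @param ... passed to [plot()].
#' @return invisibly, `NULL`.
#' @export
plotCoverage <- function(profiles, peaks = NULL, ...) {
  L <- length(profiles@spcFwd)
  total <- profiles@covFwd + profiles@covRev
  plot(seq_len(L), total, type = "l", col = "grey40",
       xlab = "position (bp)", ylab = "count",
       main = paste0(profiles@contigId, ": coverage and read starts"), ...)
  lines(seq_len(L), profiles@spcFwd, col = "firebrick")
  lines(seq_len(L), -profiles@spcRev, col = "steelblue")
  abline(h = 0, col = "grey80")
  if (!is.null(peaks)) {
    ann <- function(p, pch) {
      if (!is.null(p))
        points(p@pos + 1L, if (p@strand == "fwd") p@spc else -p@spc,
               pch = pch, col = "black", cex = 1.2)
    }
    ann(peaks@primaryFwd, 17)
    ann(peaks@primaryRev, 17)
    for (s in peaks@secondary) ann(s, 2)
  }
  legend("topright", c("total coverage", "SPC fwd", "SPC rev (neg)"),
         col = c("grey40", "firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(NULL)
}
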