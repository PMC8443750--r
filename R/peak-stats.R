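## Start-enrichment statistics. Null: conditional on a position being
## covered by `cov` reads, each covering read starts at that exact
## position with probability 1/meanReadLen (a read start is uniform along
## its own span under random fragmentation), so the SPC is
## Binomial(cov, 1/meanReadLen) and termini show up in the upper tail.
## This normalises the start counts against the whole-sequence coverage.

#' Upper-tail p-value for start-position enrichment
#'
#' `P(X >= spc)` with `X ~ Binomial(cov, 1/meanReadLen)`; vectorised over
#' `spc`/`cov`. Uncovered positions return 1.
#'
#' @param spc observed read starts at the position (one strand).
#' @param cov reads covering the position on that strand.
#' @param meanReadLen mean mapped read length (bp), > 1.
#' @return numeric p-values in `[0, 1]`.
#' @export
startEnrichmentPvalue <- function(spc, cov, meanReadLen) {
  if (length(meanReadLen) != 1L || is.na(meanReadLen) || meanReadLen <= 1)
    stop("meanReadLen must be a single value > 1")
  spc <- as.integer(spc)
  cov <- as.integer(cov)
  if (any(spc < 0L)) stop("spc must be non-negative")
  if (any(spc > cov))
    stop("spc > cov at some position: upstream invariant breach")
  out <- rep(1, length(spc))
  nz <- cov > 0L
  out[nz] <- stats::pbinom(spc[nz] - 1L, cov[nz], 1 / meanReadLen,
                           lower.tail = FALSE)
  out
}

#' Call start-enriched peaks on one contig
#'
#' Positions with per-strand coverage `>= minCov` are tested on both
#' strands under the binomial null; Benjamini-Hochberg correction is
#' applied across all tested positions of the contig (both strands
#' pooled — each contig is an independent genome hypothesis). Candidates
#' (`qval <= alpha` and `tau >= tauMin`) within `mergeWindow` bp on the
#' same strand are clustered and represented by their maximal-SPC
#' position (ties: smaller coordinate). The best representative per
#' strand (smallest q, then larger SPC, then smaller position) is the
#' primary peak; all other representatives are secondary.
#'
#' @param profiles a [CoverageProfiles-class].
#' @param alpha FDR level (default 0.01).
#' @param tauMin minimum start ratio SPC/coverage (default 0.1); guards
#'   against vanishing-effect significance at extreme coverage.
#' @param minCov per-strand coverage floor for testing a position
#'   (default 10; below ~10x calls are not trusted).
#' @param mergeWindow clustering window in bp (default 20).
#' @param seedLen seed length used in mapping, for the edge flag.
#' @return a [PeakSet-class].
#' @export
callPeaks <- function(profiles, alpha = 0.01, tauMin = 0.1, minCov = 10L,
                      mergeWindow = 20L, seedLen = 20L) {
  stopifnot(is(profiles, "CoverageProfiles"))
  L <- length(profiles@spcFwd)
  meanCov <- mean(profiles@covFwd + profiles@covRev)
  lowCov <- meanCov < minCov
  empty <- new("PeakSet", contigId = profiles@contigId, primaryFwd = NULL,
               primaryRev = NULL, secondary = list(), meanCov = meanCov,
               lowCoverage = lowCov)
  mrl <- profiles@meanReadLen
  if (is.na(mrl) || mrl <= 1) return(empty)

  idxF <- which(profiles@covFwd >= minCov)
  idxR <- which(profiles@covRev >= minCov)
  if (length(idxF) + length(idxR) == 0L) return(empty)
  tests <- data.table(
    strand = rep(c("fwd", "rev"), c(length(idxF), length(idxR))),
    pos = c(idxF, idxR) - 1L,
    spc = c(profiles@spcFwd[idxF], profiles@spcRev[idxR]),
    cov = c(profiles@covFwd[idxF], profiles@covRev[idxR]))
  tests[, pval := startEnrichmentPvalue(spc, cov, mrl)]
  tests[, qval := stats::p.adjust(pval, method = "BH")]
  tests[, tau := spc / cov]
  cand <- tests[qval <= alpha & tau >= tauMin]
  if (nrow(cand) == 0L) return(empty)

  # cluster candidates per strand: chain positions within mergeWindow
  repList <- list()
  for (str in c("fwd", "rev")) {
    s <- cand[strand == str][order(pos)]
    if (nrow(s) == 0L) next
    s[, cluster := cumsum(c(1L, as.integer(diff(s$pos) > mergeWindow)))]
    r <- s[, .SD[order(-spc, pos)[1L]], by = cluster]
    r[, cluster := NULL]
    repList[[str]] <- r
  }
  reps <- rbindlist(repList)

  mkPeak <- function(row) {
    new("PeakCall", strand = row$strand, pos = as.integer(row$pos),
        spc = as.integer(row$spc), cov = as.integer(row$cov),
        tau = row$tau, pval = row$pval, qval = row$qval,
        atEdge = row$pos < seedLen || row$pos >= L - seedLen)
  }
  pickPrimary <- function(str) {
    s <- reps[strand == str]
    if (nrow(s) == 0L) return(NULL)
    mkPeak(as.list(s[order(qval, -spc, pos)][1L]))
  }
  pf <- pickPrimary("fwd")
  pr <- pickPrimary("rev")
  prim <- data.table(
    strand = c(if (!is.null(pf)) "fwd", if (!is.null(pr)) "rev"),
    pos = c(if (!is.null(pf)) pf@pos, if (!is.null(pr)) pr@pos))
  sec <- reps[!prim, on = c("strand", "pos")][order(qval, -spc, pos)]
  secondary <- lapply(seq_len(nrow(sec)), function(i) mkPeak(as.list(sec[i])))

  new("PeakSet", contigId = profiles@contigId, primaryFwd = pf,
      primaryRev = pr, secondary = secondary, meanCov = meanCov,
      lowCoverage = lowCov)
}
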