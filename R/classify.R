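## Packaging-mechanism classification from per-strand peak geometry.
## Linear packaged DNA with staggered terminase nicks: top-strand cut at
## a, bottom-strand cut at b, a < b (delta = b - a > 0) leaves protruding
## 5' ends (5' cos); delta < 0 leaves 3' overhangs. Two far-apart peaks
## over a doubly covered interval are a collapsed direct terminal repeat;
## a lone peak is a headful pac site; silence at good coverage is random
## headful packaging (T4-like).

#' Coverage elevation of an interval relative to its flanks
#'
#' Mean total coverage (both strands) over `[a, b]` divided by the mean
#' over the rest of the contig, excluding a guard band of `guard` bp
#' around `a` and `b`. A collapsed DTR is covered twice per molecule, so
#' the ratio is ~2 at the repeat. Returns `Inf` when the flank coverage
#' is zero.
#'
#' @param profiles a [CoverageProfiles-class].
#' @param a,b 0-based positions with `a < b` (inclusive interval).
#' @param guard guard band width in bp (default 20).
#' @return a single numeric ratio.
#' @export
coverageElevationRatio <- function(profiles, a, b, guard = 20L) {
  a <- as.integer(a); b <- as.integer(b)
  L <- length(profiles@covFwd)
  if (a >= b) stop("need a < b; got a=", a, ", b=", b)
  if (a < 0L || b >= L) stop("interval out of contig bounds")
  total <- profiles@covFwd + profiles@covRev
  inside <- mean(total[(a + 1L):(b + 1L)])
  flank <- total[-(max(1L, a - guard + 1L):min(L, b + guard + 1L))]
  if (length(flank) == 0L || mean(flank) == 0) return(Inf)
  inside / mean(flank)
}

## Elevation of the circular arc from a forward around the origin to b
## (b < a in linear coordinates): rotate the coverage so a maps to 0.
.wrappedElevation <- function(profiles, a, b, guard = 20L) {
  total <- profiles@covFwd + profiles@covRev
  L <- length(total)
  rot <- c(total[(a + 1L):L], total[seq_len(a)])
  span <- ((b - a) %% L)  # 0-based end of the arc in rotated coords
  inside <- mean(rot[seq_len(span + 1L)])
  flank <- rot[-(seq_len(min(L, span + guard + 1L)))]
  flank <- flank[seq_len(max(0L, length(flank) - guard))]
  if (length(flank) == 0L || mean(flank) == 0) return(Inf)
  inside / mean(flank)
}

#' Classify the packaging mechanism of one contig
#'
#' Decision rules, in order: (1) low coverage with no peaks ->
#' `LOW_COVERAGE` (warned); (2) no peak -> `NO_SIGNAL` (headful without a
#' detectable pac site); (3) a peak on exactly one strand ->
#' `HEADFUL_PAC`; (4) peaks on both strands with `delta = posRev -
#' posFwd`: `0 < delta <= maxOverhang` -> `COS_5P` with overhang `delta`;
#' the mirrored case -> `COS_3P`; `delta == 0` -> `AMBIGUOUS` (blunt or
#' unresolved cos polarity); `maxOverhang < delta <= maxDtr` with
#' coverage elevation `>= dtrRatioMin` over the interval -> `DTR`;
#' otherwise the complementary arc is evaluated under a circular
#' interpretation (circularly permuted contigs), and failing that the
#' contig is `AMBIGUOUS`. Total: every input yields a prediction.
#'
#' @param peaks a [PeakSet-class].
#' @param profiles the matching [CoverageProfiles-class].
#' @param maxOverhang largest cos overhang in bp (default 20).
#' @param maxDtr largest direct terminal repeat in bp (default 10000).
#' @param dtrRatioMin minimum coverage elevation for a DTR call (default
#'   1.4; the ideal doubly covered repeat gives 2.0, noise and partial
#'   assembler collapse push it down).
#' @param guard guard band (bp) around the interval when measuring
#'   elevation (default 20).
#' @return a [TerminiPrediction-class].
#' @export
classifyPackaging <- function(peaks, profiles, maxOverhang = 20L,
                              maxDtr = 10000L, dtrRatioMin = 1.4,
                              guard = 20L) {
  stopifnot(is(peaks, "PeakSet"), is(profiles, "CoverageProfiles"),
            peaks@contigId == profiles@contigId)
  id <- peaks@contigId
  pf <- peaks@primaryFwd
  pr <- peaks@primaryRev
  L <- length(profiles@covFwd)
  warn <- character(0)
  if (peaks@lowCoverage)
    warn <- c(warn, sprintf("very low mean coverage (%.1fx); inspect manually",
                            peaks@meanCov))

  if (is.null(pf) && is.null(pr)) {
    if (peaks@lowCoverage) {
      return(.TerminiPrediction(id, "LOW_COVERAGE", warnings = warn))
    }
    return(.TerminiPrediction(id, "NO_SIGNAL", warnings = warn))
  }
  if (is.null(pf) || is.null(pr)) {
    p <- if (is.null(pr)) pf else pr
    return(.TerminiPrediction(
      id, "HEADFUL_PAC",
      termFwd = if (p@strand == "fwd") p@pos + 1L else NA_integer_,
      termRev = if (p@strand == "rev") p@pos + 1L else NA_integer_,
      pacStrand = p@strand,
      warnings = c(warn, if (p@atEdge) "pac peak at contig edge")))
  }

  a <- pf@pos
  b <- pr@pos
  edgeWarn <- c(if (pf@atEdge) "forward peak at contig edge",
                if (pr@atEdge) "reverse peak at contig edge")
  tryDelta <- function(delta, elevation) {
    # elevation: function() lazily computing the interval elevation ratio
    if (delta > 0L && delta <= maxOverhang) {
      return(.TerminiPrediction(id, "COS_5P", termFwd = a + 1L,
                                termRev = b + 1L, overhangLen = delta,
                                warnings = c(warn, edgeWarn)))
    }
    if (delta < 0L && -delta <= maxOverhang) {
      return(.TerminiPrediction(id, "COS_3P", termFwd = a + 1L,
                                termRev = b + 1L, overhangLen = -delta,
                                warnings = c(warn, edgeWarn)))
    }
    if (delta == 0L) {
      return(.TerminiPrediction(
        id, "AMBIGUOUS", termFwd = a + 1L, termRev = b + 1L,
        warnings = c(warn, edgeWarn, "blunt or unresolved cos polarity")))
    }
    if (delta > maxOverhang && delta <= maxDtr) {
      ratio <- elevation()
      if (ratio >= dtrRatioMin) {
        return(.TerminiPrediction(id, "DTR", termFwd = a + 1L,
                                  termRev = b + 1L, repeatLen = delta,
                                  elevationRatio = ratio,
                                  warnings = c(warn, edgeWarn)))
      }
      return(.TerminiPrediction(
        id, "AMBIGUOUS", termFwd = a + 1L, termRev = b + 1L,
        elevationRatio = ratio,
        warnings = c(warn, edgeWarn,
                     "two unpaired peaks without repeat-level coverage elevation")))
    }
    NULL
  }

  res <- tryDelta(b - a, function() coverageElevationRatio(profiles, a, b, guard))
  if (!is.null(res)) return(res)

  # circular interpretation: the assembler origin may fall between the
  # two termini; measure delta around the circle instead.
  deltaCirc <- (b - a) %% L
  for (d in c(deltaCirc, deltaCirc - L)) {
    res <- tryDelta(d, function() .wrappedElevation(profiles, a, b, guard))
    if (!is.null(res)) {
      res@warnings <- c(res@warnings, "circular interpretation used")
      validObject(res)
      return(res)
    }
  }
  .TerminiPrediction(
    id, "AMBIGUOUS", termFwd = a + 1L, termRev = b + 1L,
    warnings = c(warn, edgeWarn, "peak separation fits no mechanism"))
}
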