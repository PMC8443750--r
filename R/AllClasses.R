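setOldClass(c("data.table", "data.frame"))

## Internal mechanism codes and the user-facing vocabulary used in reports.
MECHANISM_CODES <- c("COS_5P", "COS_3P", "DTR", "HEADFUL_PAC",
                     "HEADFUL_RANDOM", "NO_SIGNAL", "AMBIGUOUS",
                     "LOW_COVERAGE")

MECHANISM_LABELS <- c(
  COS_5P         = "5' cos",
  COS_3P         = "3' cos",
  DTR            = "DTR (short)",
  HEADFUL_PAC    = "headful (pac)",
  HEADFUL_RANDOM = "-",
  NO_SIGNAL      = "-",
  AMBIGUOUS      = "ambiguous",
  LOW_COVERAGE   = "low coverage"
)

#' Human-readable packaging mechanism label
#'
#' Maps an internal mechanism code (e.g. `"COS_5P"`) to the vocabulary used
#' in reports (`"5' cos"`, `"3' cos"`, `"DTR (short)"`, `"headful (pac)"`,
#' `"-"` for no signal).
#'
#' @param code character vector of mechanism codes.
#' @return character vector of labels.
#' @export
mechanismLabel <- function(code) {
  unname(MECHANISM_LABELS[match(code, names(MECHANISM_LABELS))])
}

# ---------------------------------------------------------------------------
# SeedIndex

#' @title SeedIndex: exact k-mer lookup table over contig forward strands
#'
#' @description Maps every N-free k-mer of every contig to its (contig,
#' 0-based position) occurrences. Built by [buildSeedIndex()]; consumed by
#' [accumulateProfiles()].
#'
#' @slot k integer seed length.
#' @slot table a `data.table` with columns `kmer`, `cid` (index into
#'   `names(contigLengths)`) and `pos0`, keyed by `kmer`.
#' @slot contigLengths named integer vector of contig lengths (bp).
#' @exportClass SeedIndex
setClass("SeedIndex",
  representation(k = "integer", table = "data.table",
                 contigLengths = "integer"))

setValidity("SeedIndex", function(object) {
  if (length(object@k) != 1L || object@k < 8L)
    return("k must be a single integer >= 8")
  if (is.null(names(object@contigLengths)) ||
      anyDuplicated(names(object@contigLengths)))
    return("contigLengths must be uniquely named")
  TRUE
})

setMethod("show", "SeedIndex", function(object) {
  cat(sprintf("SeedIndex: k=%d, %d contigs, %s seed positions\n",
              object@k, length(object@contigLengths),
              format(nrow(object@table), big.mark = ",")))
})

# ---------------------------------------------------------------------------
# CoverageProfiles

#' @title CoverageProfiles: per-contig SPC and coverage arrays
#'
#' @description For one contig, the per-position starting-position coverage
#' (SPC) and read coverage on each strand. `spcFwd[i]` counts reads whose
#' 5' base maps at 0-based position `i` on the forward strand; `covFwd[i]`
#' counts forward reads covering `i`; likewise for the reverse strand,
#' where a read's 5' base is its rightmost contig coordinate.
#'
#' @slot contigId character scalar.
#' @slot spcFwd,spcRev,covFwd,covRev integer vectors of length L.
#' @slot nReadsUsed integer, reads with exactly one candidate start here.
#' @slot nAmbiguousSkipped integer, reads discarded as multi-mapping
#'   within this contig.
#' @slot meanReadLen numeric, mean length (bp) of the used reads.
#' @exportClass CoverageProfiles
setClass("CoverageProfiles",
  representation(contigId = "character",
                 spcFwd = "integer", spcRev = "integer",
                 covFwd = "integer", covRev = "integer",
                 nReadsUsed = "integer", nAmbiguousSkipped = "integer",
                 meanReadLen = "numeric"))

setValidity("CoverageProfiles", function(object) {
  L <- length(object@spcFwd)
  if (length(object@spcRev) != L || length(object@covFwd) != L ||
      length(object@covRev) != L)
    return("all four arrays must have equal length")
  if (L < 1L) return("arrays must be non-empty")
  if (min(object@spcFwd, object@spcRev, object@covFwd, object@covRev) < 0L)
    return("counts must be non-negative")
  if (any(object@spcFwd > object@covFwd) || any(object@spcRev > object@covRev))
    return("SPC cannot exceed coverage at any position")
  if (sum(object@spcFwd) + sum(object@spcRev) != object@nReadsUsed)
    return("sum(spcFwd) + sum(spcRev) must equal nReadsUsed")
  TRUE
})

#' Construct a CoverageProfiles object
#'
#' @param contigId contig identifier.
#' @param spcFwd,spcRev,covFwd,covRev integer vectors, one entry per
#'   contig position.
#' @param nAmbiguousSkipped reads discarded as ambiguous within the contig.
#' @param meanReadLen mean length of the used reads (bp).
#' @return a [CoverageProfiles-class] object; `nReadsUsed` is derived as
#'   `sum(spcFwd) + sum(spcRev)` (each used read starts exactly once).
#' @export
CoverageProfiles <- function(contigId, spcFwd, spcRev, covFwd, covRev,
                             nAmbiguousSkipped = 0L, meanReadLen = NA_real_) {
  new("CoverageProfiles", contigId = as.character(contigId),
      spcFwd = as.integer(spcFwd), spcRev = as.integer(spcRev),
      covFwd = as.integer(covFwd), covRev = as.integer(covRev),
      nReadsUsed = as.integer(sum(spcFwd) + sum(spcRev)),
      nAmbiguousSkipped = as.integer(nAmbiguousSkipped),
      meanReadLen = as.numeric(meanReadLen))
}

setMethod("show", "CoverageProfiles", function(object) {
  cat(sprintf(
    "CoverageProfiles for '%s': L=%d, reads used=%d (ambiguous skipped=%d)\n",
    object@contigId, length(object@spcFwd), object@nReadsUsed,
    object@nAmbiguousSkipped))
  cat(sprintf("  mean coverage %.1fx, mean read length %.1f bp\n",
              mean(object@covFwd + object@covRev), object@meanReadLen))
})

# ---------------------------------------------------------------------------
# PeakCall / PeakSet

#' @title PeakCall: one significantly start-enriched position
#'
#' @description A contig position whose SPC is significantly above the
#' binomial null on one strand. `tau` is the coverage-normalised start
#' ratio SPC/coverage.
#'
#' @slot strand `"fwd"` or `"rev"`.
#' @slot pos integer 0-based contig position of the read 5' base.
#' @slot spc,cov integer counts at that position/strand.
#' @slot tau,pval,qval numerics in \[0, 1\].
#' @slot atEdge logical, position within one seed length of a contig end.
#' @exportClass PeakCall
setClass("PeakCall",
  representation(strand = "character", pos = "integer", spc = "integer",
                 cov = "integer", tau = "numeric", pval = "numeric",
                 qval = "numeric", atEdge = "logical"))

setValidity("PeakCall", function(object) {
  if (!object@strand %in% c("fwd", "rev")) return("strand must be fwd/rev")
  if (object@tau < 0 || object@tau > 1) return("tau must be in [0,1]")
  if (object@pval < 0 || object@pval > 1) return("pval must be in [0,1]")
  if (object@qval < 0 || object@qval > 1) return("qval must be in [0,1]")
  if (object@spc > object@cov) return("spc cannot exceed cov")
  TRUE
})

setClassUnion("PeakCallOrNULL", c("PeakCall", "NULL"))

setMethod("show", "PeakCall", function(object) {
  cat(sprintf(
    "PeakCall %s:%d (1-based %d)  spc=%d cov=%d tau=%.3f q=%.3g%s\n",
    object@strand, object@pos, object@pos + 1L, object@spc, object@cov,
    object@tau, object@qval, if (object@atEdge) " [edge]" else ""))
})

#' @title PeakSet: the called peaks of one contig
#'
#' @description Result of [callPeaks()]: the best surviving peak per
#' strand (candidate termini) plus all remaining significant cluster
#' representatives (candidate secondary terminase cutting sites).
#'
#' @slot contigId character scalar.
#' @slot primaryFwd,primaryRev a [PeakCall-class] or `NULL`.
#' @slot secondary list of [PeakCall-class].
#' @slot meanCov numeric mean total coverage of the contig.
#' @slot lowCoverage logical, `meanCov` below the testing floor.
#' @exportClass PeakSet
setClass("PeakSet",
  representation(contigId = "character",
                 primaryFwd = "PeakCallOrNULL", primaryRev = "PeakCallOrNULL",
                 secondary = "list", meanCov = "numeric",
                 lowCoverage = "logical"))

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet for '%s' (mean coverage %.1fx%s)\n", object@contigId,
              object@meanCov, if (object@lowCoverage) ", LOW" else ""))
  for (nm in c("primaryFwd", "primaryRev")) {
    p <- slot(object, nm)
    cat("  ", nm, ": ", sep = "")
    if (is.null(p)) cat("-\n") else show(p)
  }
  cat(sprintf("  secondary peaks: %d\n", length(object@secondary)))
})

# ---------------------------------------------------------------------------
# TerminiPrediction

#' @title TerminiPrediction: packaging mechanism call for one contig
#'
#' @description Output of [classifyPackaging()]. Termini are 1-based
#' contig coordinates; absent fields are `NA`.
#'
#' @slot contigId character scalar.
#' @slot mechanism one of `r paste(MECHANISM_CODES, collapse=", ")`.
#' @slot termFwd,termRev integer 1-based positions or `NA`.
#' @slot overhangLen integer bp (cos only) or `NA`.
#' @slot repeatLen integer bp (DTR only) or `NA`.
#' @slot elevationRatio numeric DTR coverage evidence or `NA`.
#' @slot pacStrand `"fwd"`, `"rev"` or `NA` (headful pac only).
#' @slot warnings character vector.
#' @exportClass TerminiPrediction
setClass("TerminiPrediction",
  representation(contigId = "character", mechanism = "character",
                 termFwd = "integer", termRev = "integer",
                 overhangLen = "integer", repeatLen = "integer",
                 elevationRatio = "numeric", pacStrand = "character",
                 warnings = "character"))

setValidity("TerminiPrediction", function(object) {
  m <- object@mechanism
  if (!m %in% MECHANISM_CODES) return("unknown mechanism code")
  if (m %in% c("COS_5P", "COS_3P") &&
      (is.na(object@termFwd) || is.na(object@termRev) ||
       is.na(object@overhangLen) || object@overhangLen < 1L))
    return("cos prediction requires both termini and a positive overhang")
  if (m == "DTR" && (is.na(object@repeatLen) || object@repeatLen < 1L))
    return("DTR prediction requires a positive repeat length")
  if (m == "HEADFUL_PAC" &&
      sum(!is.na(c(object@termFwd, object@termRev))) != 1L)
    return("headful pac prediction requires exactly one terminus")
  if (m == "NO_SIGNAL" && any(!is.na(c(object@termFwd, object@termRev))))
    return("NO_SIGNAL must carry no termini")
  TRUE
})

.TerminiPrediction <- function(contigId, mechanism, termFwd = NA_integer_,
                               termRev = NA_integer_,
                               overhangLen = NA_integer_,
                               repeatLen = NA_integer_,
                               elevationRatio = NA_real_,
                               pacStrand = NA_character_,
                               warnings = character(0)) {
  new("TerminiPrediction", contigId = as.character(contigId),
      mechanism = mechanism, termFwd = as.integer(termFwd),
      termRev = as.integer(termRev), overhangLen = as.integer(overhangLen),
      repeatLen = as.integer(repeatLen),
      elevationRatio = as.numeric(elevationRatio),
      pacStrand = as.character(pacStrand), warnings = warnings)
}

setMethod("show", "TerminiPrediction", function(object) {
  cat(sprintf("TerminiPrediction '%s': %s\n", object@contigId,
              mechanismLabel(object@mechanism)))
  cat(sprintf("  term_fwd=%s term_rev=%s overhang=%s repeat=%s pac_strand=%s\n",
              .fmtNA(object@termFwd), .fmtNA(object@termRev),
              .fmtNA(object@overhangLen), .fmtNA(object@repeatLen),
              .fmtNA(object@pacStrand)))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

# ---------------------------------------------------------------------------
# VirionSpec

#' @title VirionSpec: parameters of one simulated phage
#'
#' @description Describes a phage genome and how virion DNA molecules are
#' produced from it: fixed cos cuts with a 5' or 3' overhang, direct
#' terminal repeats, processive headful packaging from a pac site, or
#' headful packaging from random positions (no detectable terminus).
#'
#' @slot name unique phage/contig name.
#' @slot genomeLen genome length (bp).
#' @slot gc GC content in (0, 1).
#' @slot mechanism one of COS_5P, COS_3P, DTR, HEADFUL_PAC, HEADFUL_RANDOM.
#' @slot cutPos 0-based top-strand cut (cos), repeat start (DTR) or pac
#'   site (headful).
#' @slot overhangLen cos overhang length, 1-20 bp.
#' @slot repeatLen DTR length, >= 30 bp.
#' @slot headfulFactor headful size as multiple of genome length (> 1).
#' @slot seriesLen headfuls packaged per concatemer series.
#' @slot headfulJitterSd sd (bp) of the imprecision of non-pac headful
#'   boundaries; only the series-initiating pac cut is exact.
#' @slot nReadPairs read pairs to draw for this phage.
#' @slot seed RNG seed for this phage's genome and reads.
#' @exportClass VirionSpec
setClass("VirionSpec",
  representation(name = "character", genomeLen = "integer", gc = "numeric",
                 mechanism = "character", cutPos = "integer",
                 overhangLen = "integer", repeatLen = "integer",
                 headfulFactor = "numeric", seriesLen = "integer",
                 headfulJitterSd = "numeric", nReadPairs = "integer",
                 seed = "integer"))

setValidity("VirionSpec", function(object) {
  m <- object@mechanism
  if (!m %in% c("COS_5P", "COS_3P", "DTR", "HEADFUL_PAC", "HEADFUL_RANDOM"))
    return("unknown simulated mechanism")
  if (object@genomeLen < 1000L) return("genomeLen must be >= 1000")
  if (object@gc <= 0 || object@gc >= 1) return("gc must be in (0,1)")
  if (object@cutPos < 0L || object@cutPos >= object@genomeLen)
    return("cutPos must be in [0, genomeLen)")
  if (m %in% c("COS_5P", "COS_3P") &&
      (object@overhangLen < 1L || object@overhangLen > 20L))
    return("cos overhangLen must be in [1, 20]")
  if (m == "DTR" && object@repeatLen < 30L)
    return("DTR repeatLen must be >= 30")
  if (m %in% c("HEADFUL_PAC", "HEADFUL_RANDOM") && object@headfulFactor <= 1)
    return("headfulFactor must be > 1")
  TRUE
})

#' Construct a VirionSpec
#'
#' @param name unique phage name (becomes the reference contig id).
#' @param genomeLen genome length in bp (>= 1000).
#' @param mechanism `"COS_5P"`, `"COS_3P"`, `"DTR"`, `"HEADFUL_PAC"` or
#'   `"HEADFUL_RANDOM"`.
#' @param gc GC content, default 0.5.
#' @param cutPos 0-based cut/pac/repeat-start coordinate; default mid-genome.
#' @param overhangLen cos overhang (1-20 bp).
#' @param repeatLen DTR length (>= 30 bp).
#' @param headfulFactor headful length as a multiple of the genome, default
#'   1.03 (~3% terminal redundancy).
#' @param seriesLen headfuls per packaging series, default 4.
#' @param headfulJitterSd sd in bp of non-pac headful boundary imprecision;
#'   default 1% of the genome length.
#' @param nReadPairs read pairs to simulate for this phage.
#' @param seed integer RNG seed.
#' @return a [VirionSpec-class] object.
#' @export
VirionSpec <- function(name, genomeLen, mechanism, gc = 0.5,
                       cutPos = genomeLen %/% 2L, overhangLen = NA,
                       repeatLen = NA, headfulFactor = 1.03, seriesLen = 4L,
                       headfulJitterSd = 0.01 * genomeLen,
                       nReadPairs = 10000L, seed = 1L) {
  new("VirionSpec", name = as.character(name),
      genomeLen = as.integer(genomeLen), gc = as.numeric(gc),
      mechanism = mechanism, cutPos = as.integer(cutPos),
      overhangLen = as.integer(overhangLen), repeatLen = as.integer(repeatLen),
      headfulFactor = as.numeric(headfulFactor),
      seriesLen = as.integer(seriesLen),
      headfulJitterSd = as.numeric(headfulJitterSd),
      nReadPairs = as.integer(nReadPairs), seed = as.integer(seed))
}

setMethod("show", "VirionSpec", function(object) {
  cat(sprintf("VirionSpec '%s': %s, %d bp, gc=%.2f, cut=%d, %d pairs\n",
              object@name, object@mechanism, object@genomeLen, object@gc,
              object@cutPos, object@nReadPairs))
})
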