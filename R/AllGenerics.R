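#' @title Accessors for phageTermini result objects
#' @description Standard accessors so slots never need to be touched
#'   directly: `contigId()`, `mechanism()`, `termini()`, `nReadsUsed()`,
#'   `meanCoverage()`, `isLowCoverage()`, `peakCalls()`.
#' @param x a [CoverageProfiles-class], [PeakSet-class] or
#'   [TerminiPrediction-class] object.
#' @return `contigId`, `mechanism`: character scalars. `termini`: named
#'   integer vector `c(fwd=, rev=)` of 1-based positions (`NA` when
#'   absent). `nReadsUsed`: integer. `meanCoverage`: numeric.
#'   `isLowCoverage`: logical. `peakCalls`: `data.frame` with one row per
#'   called peak (columns `role`, `strand`, `pos` 1-based, `spc`, `cov`,
#'   `tau`, `pval`, `qval`, `at_edge`).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("contigId", function(x) standardGeneric("contigId"))
#' @rdname accessors
#' @export
setGeneric("mechanism", function(x) standardGeneric("mechanism"))
#' @rdname accessors
#' @export
setGeneric("termini", function(x) standardGeneric("termini"))
#' @rdname accessors
#' @export
setGeneric("nReadsUsed", function(x) standardGeneric("nReadsUsed"))
#' @rdname accessors
#' @export
setGeneric("meanCoverage", function(x) standardGeneric("meanCoverage"))
#' @rdname accessors
#' @export
setGeneric("isLowCoverage", function(x) standardGeneric("isLowCoverage"))
#' @rdname accessors
#' @export
setGeneric("peakCalls", function(x) standardGeneric("peakCalls"))

#' @rdname accessors
setMethod("contigId", "CoverageProfiles", function(x) x@contigId)
#' @rdname accessors
setMethod("contigId", "PeakSet", function(x) x@contigId)
#' @rdname accessors
setMethod("contigId", "TerminiPrediction", function(x) x@contigId)

#' @rdname accessors
setMethod("mechanism", "TerminiPrediction", function(x) x@mechanism)

#' @rdname accessors
setMethod("termini", "TerminiPrediction",
          function(x) c(fwd = x@termFwd, rev = x@termRev))

#' @rdname accessors
setMethod("nReadsUsed", "CoverageProfiles", function(x) x@nReadsUsed)

#' @rdname accessors
setMethod("meanCoverage", "CoverageProfiles",
          function(x) mean(x@covFwd + x@covRev))
#' @rdname accessors
setMethod("meanCoverage", "PeakSet", function(x) x@meanCov)

#' @rdname accessors
setMethod("isLowCoverage", "PeakSet", function(x) x@lowCoverage)

#' @rdname accessors
setMethod("peakCalls", "PeakSet", function(x) {
  calls <- c(
    if (!is.null(x@primaryFwd)) list(c(role = "primary", .peakRow(x@primaryFwd))),
    if (!is.null(x@primaryRev)) list(c(role = "primary", .peakRow(x@primaryRev))),
    lapply(x@secondary, function(p) c(role = "secondary", .peakRow(p)))
  )
  if (!length(calls)) {
    return(data.frame(role = character(0), strand = character(0),
                      pos = integer(0), spc = integer(0), cov = integer(0),
                      tau = numeric(0), pval = numeric(0), qval = numeric(0),
                      at_edge = logical(0)))
  }
  df <- as.data.frame(do.call(rbind, calls), stringsAsFactors = FALSE)
  for (col in c("pos", "spc", "cov")) df[[col]] <- as.integer(df[[col]])
  for (col in c("tau", "pval", "qval")) df[[col]] <- as.numeric(df[[col]])
  df$at_edge <- as.logical(df$at_edge)
  df
})

.peakRow <- function(p) {
  c(strand = p@strand, pos = p@pos + 1L, spc = p@spc, cov = p@cov,
    tau = p@tau, pval = p@pval, qval = p@qval, at_edge = p@atEdge)
}
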