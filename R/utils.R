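## Small shared helpers; all internal except rotateToStart.

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.fmtNA <- function(x) if (length(x) != 1L || is.na(x)) "-" else as.character(x)

#' Rotate a sequence to a new start position
#'
#' Returns `substr(seq, newStart+1, L)` followed by
#' `substr(seq, 1, newStart)`: the circular permutation of `seq` that
#' begins at 0-based position `newStart`. Used to rewrite contigs so that
#' a predicted terminus becomes position 1.
#'
#' @param seq a single nucleotide string.
#' @param newStart 0-based position in `[0, nchar(seq))`.
#' @return the rotated string (same length, same base composition).
#' @examples
#' rotateToStart("ACGTAC", 2)  # "GTACAC"
#' @export
rotateToStart <- function(seq, newStart) {
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  newStart <- as.integer(newStart)
  if (is.na(newStart) || newStart < 0L || newStart >= L)
    stop("newStart must be in [0, ", L, "); got ", newStart)
  if (newStart == 0L) return(seq)
  paste0(substr(seq, newStart + 1L, L), substr(seq, 1L, newStart))
}

## Derive a stream of sub-seeds from one run seed, all < 2^31.
.subSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}
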