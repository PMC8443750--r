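## FASTA/FASTQ input, contig filtering. Whole-file FASTA goes through
## Biostrings; FASTQ is streamed in chunks over a gzfile() connection so
## memory stays constant in file size (gzfile transparently reads plain
## files, which detects gzip by content rather than extension).

#' Read assembled contigs from a (multi-)FASTA file
#'
#' Ids are the header up to the first whitespace (matching assembler node
#' names); the full header is kept in `mcols(x)$header`. Sequences are
#' uppercased; IUPAC ambiguity codes other than A/C/G/T/N are collapsed
#' to N (they can never seed-match); any non-IUPAC character is an error
#' reporting its position.
#'
#' @param path FASTA file, plain or gzipped.
#' @return a [Biostrings::DNAStringSet] named by contig id.
#' @export
readContigs <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no contigs in ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  if (any(ids == "")) stop("empty FASTA header in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate contig id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(x))
  bad <- regexpr("[^ACGTNRYSWKMBDHVU-]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-IUPAC character '%s' in contig '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  if (any(nchar(seqs) == 0L)) stop("zero-length contig: ",
                                   ids[which(nchar(seqs) == 0L)[1L]])
  # collapse ambiguity codes (and gaps/U) to N; keep only A,C,G,T,N
  seqs <- chartr("RYSWKMBDHVU-", "NNNNNNNNNNNN", seqs)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$header <- headers
  out
}

#' Write contigs to FASTA
#'
#' @param contigs a [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeContigs <- function(contigs, path) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(contigs, path)
  invisible(path)
}

#' Drop contigs below a minimum length
#'
#' Retains exactly the contigs with `length >= minLen` (inclusive
#' boundary), preserving order. The removed count is messaged; a warning
#' is raised if nothing survives.
#'
#' @param contigs a [Biostrings::DNAStringSet].
#' @param minLen minimum contig length in bp (default 500).
#' @return the filtered `DNAStringSet`.
#' @export
filterContigs <- function(contigs, minLen = 500L) {
  stopifnot(minLen >= 1L)
  keep <- Biostrings::width(contigs) >= minLen
  if (any(!keep)) {
    message(sum(!keep), " contig(s) below ", minLen, " bp removed: ",
            paste(head(names(contigs)[!keep], 10L), collapse = ", "))
  }
  out <- contigs[keep]
  if (length(out) == 0L)
    warning("no contigs of length >= ", minLen, " bp remain")
  out
}

#' Stream reads from FASTQ file(s) in constant memory
#'
#' Returns a streamer over single or paired FASTQ (plain or gzipped;
#' detected by content). Each call to `$nextChunk()` yields up to
#' `chunkSize` records as `list(id, seq, mateSeq)` (`mateSeq` `NULL` in
#' single-end mode), or `NULL` at exhaustion; `$totalReads()` reports the
#' record count so far; `$close()` releases the connections. Qualities
#' are parsed but ignored. Truncated records and mate-desynchronised
#' pairs are errors.
#'
#' @param r1 FASTQ path (R1 in paired mode).
#' @param r2 optional mate FASTQ path.
#' @param chunkSize records per chunk (default 100000).
#' @return an object of class `"ReadStreamer"` (a list of closures).
#' @export
streamReads <- function(r1, r2 = NULL, chunkSize = 100000L) {
  if (!file.exists(r1)) stop("FASTQ file not found: ", r1)
  if (!is.null(r2) && !file.exists(r2)) stop("FASTQ file not found: ", r2)
  con1 <- gzfile(r1, "rt")
  con2 <- if (!is.null(r2)) gzfile(r2, "rt") else NULL
  total <- 0L
  open <- TRUE
  closeAll <- function() {
    if (open) {
      close(con1)
      if (!is.null(con2)) close(con2)
      open <<- FALSE
    }
  }
  parse <- function(lines, path, offset) {
    nl <- length(lines)
    if (nl %% 4L != 0L) {
      closeAll()
      stop("truncated FASTQ record near record ", offset + nl %/% 4L + 1L,
           " in ", path)
    }
    if (nl == 0L) return(NULL)
    ids <- lines[seq(1L, nl, by = 4L)]
    plus <- lines[seq(3L, nl, by = 4L)]
    if (!all(startsWith(ids, "@")) || !all(startsWith(plus, "+"))) {
      closeAll()
      stop("malformed FASTQ record near record ",
           offset + which(!startsWith(ids, "@") | !startsWith(plus, "+"))[1L],
           " in ", path)
    }
    list(id = sub("\\s.*$", "", substring(ids, 2L)),
         seq = toupper(lines[seq(2L, nl, by = 4L)]))
  }
  nextChunk <- function() {
    if (!open) return(NULL)
    l1 <- readLines(con1, n = 4L * chunkSize)
    p1 <- parse(l1, r1, total)
    if (!is.null(con2)) {
      l2 <- readLines(con2, n = 4L * chunkSize)
      p2 <- parse(l2, r2, total)
      n1 <- if (is.null(p1)) 0L else length(p1$seq)
      n2 <- if (is.null(p2)) 0L else length(p2$seq)
      if (n1 != n2) {
        closeAll()
        stop("paired FASTQ files have unequal record counts (desync after ",
             total + min(n1, n2), " records)")
      }
      if (is.null(p1)) { closeAll(); return(NULL) }
      total <<- total + n1
      return(list(id = p1$id, seq = p1$seq, mateSeq = p2$seq))
    }
    if (is.null(p1)) { closeAll(); return(NULL) }
    total <<- total + length(p1$seq)
    list(id = p1$id, seq = p1$seq, mateSeq = NULL)
  }
  structure(list(nextChunk = nextChunk,
                 totalReads = function() total,
                 close = closeAll),
            class = "ReadStreamer")
}

#' Read an entire FASTQ file into memory
#'
#' Convenience wrapper over [streamReads()] for small files.
#'
#' @inheritParams streamReads
#' @return list with `id`, `seq` and (paired mode) `mateSeq` character
#'   vectors.
#' @export
readFastq <- function(r1, r2 = NULL) {
  st <- streamReads(r1, r2, chunkSize = 1000000L)
  out <- list(id = character(0), seq = character(0),
              mateSeq = if (is.null(r2)) NULL else character(0))
  while (!is.null(ch <- st$nextChunk())) {
    out$id <- c(out$id, ch$id)
    out$seq <- c(out$seq, ch$seq)
    if (!is.null(r2)) out$mateSeq <- c(out$mateSeq, ch$mateSeq)
  }
  out
}
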