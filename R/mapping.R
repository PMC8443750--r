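## Exact k-mer seed mapping. The terminus signal lives in a read's first
## base, so each read is anchored by a perfect match of its first k bases
## (default 20): one forward or reverse-complement occurrence per contig
## places the read; more than one within a contig discards it for that
## contig (within-contig repeats must not fabricate SPC peaks).

#' Build an exact k-mer seed index over contig forward strands
#'
#' Every k-mer of every contig forward strand is stored once per
#' occurrence; windows containing N are excluded so ambiguity can never
#' create a match. Contigs shorter than `k` are indexed with zero entries
#' (with a warning).
#'
#' @param contigs a [Biostrings::DNAStringSet] or named character vector.
#' @param k seed length in bp, >= 8 (default 20: the first 20-mer of each
#'   read is the mapping anchor).
#' @return a [SeedIndex-class] object.
#' @export
buildSeedIndex <- function(contigs, k = 20L) {
  k <- as.integer(k)
  if (k < 8L) stop("seed length k must be >= 8")
  ids <- names(contigs)
  seqs <- as.character(contigs)
  if (length(seqs) == 0L) stop("no contigs to index")
  if (is.null(ids) || anyDuplicated(ids)) stop("contigs must be uniquely named")
  lens <- nchar(seqs)
  parts <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    L <- lens[i]
    if (L < k) {
      warning("contig '", ids[i], "' (", L, " bp) is shorter than the seed (",
              k, " bp); it receives no index entries")
      next
    }
    nw <- L - k + 1L
    kmers <- substring(seqs[i], seq_len(nw), seq_len(nw) + k - 1L)
    ok <- !grepl("N", kmers, fixed = TRUE)
    if (!any(ok)) next
    parts[[i]] <- data.table(kmer = kmers[ok], cid = i,
                             pos0 = which(ok) - 1L)
  }
  tab <- rbindlist(parts)
  if (nrow(tab) == 0L)
    tab <- data.table(kmer = character(0), cid = integer(0), pos0 = integer(0))
  setkey(tab, kmer)
  new("SeedIndex", k = k, table = tab,
      contigLengths = structure(as.integer(lens), names = ids))
}

## Map one chunk of read sequences against the index. Returns a data.table
## of uniquely placed starts (cid, rc, start, len) plus per-contig
## ambiguous-read counts, or NULL if nothing in the chunk is usable.
.mapChunk <- function(index, seqs) {
  k <- index@k
  lens <- nchar(seqs)
  usable <- which(lens >= k)
  res <- list(nUsable = length(usable), hits = NULL, amb = NULL)
  if (length(usable) == 0L) return(res)
  seeds <- substr(seqs[usable], 1L, k)
  q <- data.table(
    kmer = c(seeds, .revcomp(seeds)),
    rid = rep.int(seq_along(usable), 2L),
    rc = rep(c(FALSE, TRUE), each = length(usable)))
  hits <- index@table[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(res)
  hits[, start := ifelse(rc, pos0 + k - 1L, pos0)]
  hits[, len := lens[usable][rid]]
  hits[, n := .N, by = .(rid, cid)]
  res$amb <- hits[n > 1L, .(namb = uniqueN(rid)), by = cid]
  res$hits <- hits[n == 1L, .(cid, rc, start, len)]
  res
}

#' Accumulate SPC and coverage profiles from reads
#'
#' For each read (mates are independent reads), the first `k` bases form
#' the seed. A forward occurrence at contig position `p` is a candidate
#' start `(fwd, p)`; an occurrence of the seed's reverse complement at
#' `q` is a candidate start `(rev, q + k - 1)` — the contig coordinate of
#' the read's 5' base. Per contig, a read with exactly one candidate
#' start increments the SPC array there and the coverage over the read's
#' span (clipped at contig bounds); reads with several candidates within
#' one contig are skipped for that contig and counted as ambiguous. A
#' read may contribute to several different contigs.
#'
#' @param index a [SeedIndex-class].
#' @param reads read sequences: a character vector, a
#'   [Biostrings::DNAStringSet], or a `"ReadStreamer"` from
#'   [streamReads()].
#' @param mates optional mate sequences (character vector /
#'   `DNAStringSet`); ignored when `reads` is a streamer (the streamer
#'   carries its own mates).
#' @param chunkSize reads per processing chunk for vector input.
#' @return named list of [CoverageProfiles-class], one per contig in the
#'   index.
#' @export
accumulateProfiles <- function(index, reads, mates = NULL,
                               chunkSize = 200000L) {
  if (nrow(index@table) == 0L) stop("empty seed index")
  lens <- index@contigLengths
  nc <- length(lens)
  spcF <- lapply(lens, integer)
  spcR <- lapply(lens, integer)
  covdF <- lapply(lens + 1L, numeric)
  covdR <- lapply(lens + 1L, numeric)
  nAmb <- integer(nc)
  lenSum <- numeric(nc)
  nUsed <- integer(nc)
  totalUsable <- 0L

  feed <- function(seqs) {
    res <- .mapChunk(index, seqs)
    totalUsable <<- totalUsable + res$nUsable
    if (!is.null(res$amb) && nrow(res$amb)) {
      nAmb[res$amb$cid] <<- nAmb[res$amb$cid] + res$amb$namb
    }
    h <- res$hits
    if (is.null(h) || nrow(h) == 0L) return(invisible())
    for (ci in unique(h$cid)) {
      L <- lens[ci]
      hf <- h[cid == ci & rc == FALSE]
      hr <- h[cid == ci & rc == TRUE]
      if (nrow(hf)) {
        spcF[[ci]] <<- spcF[[ci]] + tabulate(hf$start + 1L, L)
        covdF[[ci]] <<- covdF[[ci]] +
          tabulate(hf$start + 1L, L + 1L) -
          tabulate(pmin(hf$start + hf$len, L) + 1L, L + 1L)
      }
      if (nrow(hr)) {
        spcR[[ci]] <<- spcR[[ci]] + tabulate(hr$start + 1L, L)
        covdR[[ci]] <<- covdR[[ci]] +
          tabulate(pmax(0L, hr$start - hr$len + 1L) + 1L, L + 1L) -
          tabulate(hr$start + 2L, L + 1L)
      }
      nUsed[ci] <<- nUsed[ci] + nrow(hf) + nrow(hr)
      lenSum[ci] <<- lenSum[ci] + sum(hf$len) + sum(hr$len)
    }
    invisible()
  }

  if (inherits(reads, "ReadStreamer")) {
    while (!is.null(ch <- reads$nextChunk())) {
      feed(ch$seq)
      if (!is.null(ch$mateSeq)) feed(ch$mateSeq)
    }
  } else {
    seqs <- toupper(as.character(reads))
    if (!is.null(mates)) seqs <- c(seqs, toupper(as.character(mates)))
    nseq <- length(seqs)
    for (beg in seq(1L, max(nseq, 1L), by = chunkSize)) {
      if (beg > nseq) break
      feed(seqs[beg:min(beg + chunkSize - 1L, nseq)])
    }
  }
  if (totalUsable == 0L)
    stop("no usable reads: all reads are shorter than the seed length (",
         index@k, " bp)")

  out <- vector("list", nc)
  names(out) <- names(lens)
  for (ci in seq_len(nc)) {
    L <- lens[ci]
    out[[ci]] <- CoverageProfiles(
      contigId = names(lens)[ci],
      spcFwd = spcF[[ci]], spcRev = spcR[[ci]],
      covFwd = as.integer(cumsum(covdF[[ci]])[seq_len(L)]),
      covRev = as.integer(cumsum(covdR[[ci]])[seq_len(L)]),
      nAmbiguousSkipped = nAmb[ci],
      meanReadLen = if (nUsed[ci] > 0L) lenSum[ci] / nUsed[ci] else NA_real_)
  }
  out
}
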