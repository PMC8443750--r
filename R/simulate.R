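## Virion DNA simulator: genomes, mechanism-specific packaged molecules,
## random-fragmentation shearing and paired-end reads, plus the ground
## truth the pipeline should recover. All functions are deterministic
## given their seed.

#' Simulate a random genome sequence
#'
#' i.i.d. bases with `P(G) + P(C) = gc`, deterministic for a fixed seed.
#'
#' @param length genome length in bp (>= 1000).
#' @param gc GC content in (0, 1).
#' @param seed integer RNG seed.
#' @return a single nucleotide string.
#' @export
simulateGenome <- function(length, gc = 0.5, seed = 1L) {
  stopifnot(length >= 1000L, gc > 0, gc < 1)
  set.seed(as.integer(seed))
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate packaged virion molecules and their ground truth
#'
#' Produces the linear DNA molecules found in capsids under the
#' mechanism of `spec`, as strings over the circular genome:
#' \describe{
#'   \item{COS_5P / COS_3P}{every molecule spans the circle from the
#'     top-strand cut to the far truth terminus inclusive (length
#'     `genomeLen + overhang + 1` for 5' cos, `genomeLen - overhang + 1`
#'     for 3' cos); overhangs are modelled at coordinate level, the
#'     contract shared with [classifyPackaging()]'s delta convention.}
#'   \item{DTR}{rotation starting at `cutPos`, length `genomeLen +
#'     repeatLen` (first `repeatLen` bases duplicated at the 3' end);
#'     the reference contig stays collapsed, as assemblers produce.}
#'   \item{HEADFUL_PAC}{series of `seriesLen` headfuls per concatemer;
#'     only the series-initiating cut is exactly at the pac site,
#'     subsequent headful boundaries carry Gaussian imprecision
#'     (`headfulJitterSd`). Headful length is
#'     `round(headfulFactor * genomeLen)`.}
#'   \item{HEADFUL_RANDOM}{headful-length molecules starting uniformly
#'     on the circle: no shared terminus, the T4-like negative class.}
#' }
#'
#' @param genome genome string (must match `spec@genomeLen`).
#' @param spec a [VirionSpec-class].
#' @param nMolecules number of molecules to emit.
#' @param seed integer RNG seed.
#' @return list with `molecules` (character vector) and `truth`
#'   (one-row `data.frame`: name, mechanism, term_fwd, term_rev,
#'   overhang_len, repeat_len; 1-based coordinates on the reference
#'   contig, NA when absent).
#' @export
makeVirionMolecules <- function(genome, spec, nMolecules, seed = 1L) {
  stopifnot(is(spec, "VirionSpec"))
  if (nchar(genome) != spec@genomeLen)
    stop("genome length does not match spec (", nchar(genome), " vs ",
         spec@genomeLen, ")")
  set.seed(as.integer(seed))
  L <- spec@genomeLen
  cut <- spec@cutPos
  circ <- function(start0, len) {
    # substring of the circular genome, 0-based start, any len <= 2L
    r <- rotateToStart(genome, start0 %% L)
    if (len <= L) substr(r, 1L, len) else paste0(r, substr(r, 1L, len - L))
  }
  truth <- data.frame(name = spec@name, mechanism = spec@mechanism,
                      term_fwd = NA_integer_, term_rev = NA_integer_,
                      overhang_len = NA_integer_, repeat_len = NA_integer_,
                      stringsAsFactors = FALSE)
  mech <- spec@mechanism
  if (mech %in% c("COS_5P", "COS_3P")) {
    o <- spec@overhangLen
    endPos <- if (mech == "COS_5P") (cut + o) %% L else (cut - o) %% L
    len <- if (mech == "COS_5P") L + o + 1L else L - o + 1L
    mol <- circ(cut, len)
    molecules <- rep(mol, nMolecules)
    truth$term_fwd <- cut + 1L
    truth$term_rev <- endPos + 1L
    truth$overhang_len <- o
  } else if (mech == "DTR") {
    r <- spec@repeatLen
    mol <- circ(cut, L + r)
    molecules <- rep(mol, nMolecules)
    truth$term_fwd <- cut + 1L
    truth$term_rev <- ((cut + r - 1L) %% L) + 1L
    truth$repeat_len <- r
  } else if (mech == "HEADFUL_PAC") {
    h <- round(spec@headfulFactor * L)
    molecules <- character(nMolecules)
    pos <- cut
    j <- 0L
    for (i in seq_len(nMolecules)) {
      if (j == 0L) pos <- cut  # series restarts exactly at pac
      hj <- max(L %/% 2L, round(h + stats::rnorm(1L, 0, spec@headfulJitterSd)))
      molecules[i] <- circ(pos, hj)
      pos <- (pos + hj) %% L
      j <- (j + 1L) %% spec@seriesLen
    }
    truth$term_fwd <- cut + 1L
  } else {  # HEADFUL_RANDOM
    h <- round(spec@headfulFactor * L)
    starts <- sample.int(L, nMolecules, replace = TRUE) - 1L
    molecules <- vapply(starts, function(s) circ(s, h), character(1))
    truth$mechanism <- "NO_SIGNAL"  # expected call: no detectable terminus
  }
  list(molecules = molecules, truth = truth)
}

#' Shear molecules and emit paired-end reads
#'
#' Emulates random fragmentation followed by paired-end sequencing:
#' every molecule is cut into successive fragments with lengths drawn
#' from Normal(`fragMu`, `fragSd`) truncated below at `readLen` (the
#' terminal fragments end exactly at the molecule ends — this is what
#' creates the terminus signal: one fragment in about
#' `moleculeLength/fragMu` starts at the left end). `nReadPairs`
#' fragments are then sampled from the pool (without replacement when
#' possible) — sampling fragments is implicitly length-weighted across
#' molecules. R1 is the first `readLen` bases of the fragment, R2 the
#' reverse complement of its last `readLen` bases; substitution errors
#' are i.i.d. at `errorRate`.
#'
#' @param molecules character vector of molecule strings.
#' @param nReadPairs number of read pairs to emit.
#' @param fragMu,fragSd fragment length mean/sd in bp (default 400/100).
#' @param readLen read length in bp (default 75).
#' @param errorRate per-base substitution probability (default 0).
#' @param seed integer RNG seed.
#' @return list with character vectors `r1`, `r2` and `id`.
#' @export
shearAndSequence <- function(molecules, nReadPairs, fragMu = 400,
                             fragSd = 100, readLen = 75L, errorRate = 0,
                             seed = 1L) {
  stopifnot(length(molecules) > 0L, readLen <= fragMu)
  set.seed(as.integer(seed))
  readLen <- as.integer(readLen)
  fragMol <- list()
  fragStart <- list()
  fragEnd <- list()
  for (i in seq_along(molecules)) {
    M <- nchar(molecules[i])
    if (M < 2L * readLen) next
    nGuess <- ceiling(M / max(readLen, fragMu - 4 * fragSd)) + 4L
    lens <- pmax(readLen, round(stats::rnorm(nGuess, fragMu, fragSd)))
    while (sum(lens) < M)
      lens <- c(lens, pmax(readLen, round(stats::rnorm(nGuess, fragMu, fragSd))))
    ends <- cumsum(lens)
    ends <- c(ends[ends < M], M)
    starts <- c(0, ends[-length(ends)])
    if (length(ends) > 1L && ends[length(ends)] - starts[length(starts)] < readLen) {
      # merge a too-short terminal remainder into the previous fragment
      starts <- starts[-length(starts)]
      ends <- ends[-(length(ends) - 1L)]
    }
    fragMol[[length(fragMol) + 1L]] <- rep.int(i, length(starts))
    fragStart[[length(fragStart) + 1L]] <- starts
    fragEnd[[length(fragEnd) + 1L]] <- ends
  }
  if (!length(fragMol)) stop("no molecule long enough to sequence")
  fm <- unlist(fragMol); fs <- unlist(fragStart); fe <- unlist(fragEnd)
  npool <- length(fm)
  pick <- if (nReadPairs <= npool) sample.int(npool, nReadPairs)
          else sample.int(npool, nReadPairs, replace = TRUE)
  fm <- fm[pick]; fs <- fs[pick]; fe <- fe[pick]
  r1 <- substr(molecules[fm], fs + 1L, fs + readLen)
  r2 <- .revcomp(substr(molecules[fm], fe - readLen + 1L, fe))
  if (errorRate > 0) {
    r1 <- .mutate(r1, errorRate)
    r2 <- .mutate(r2, errorRate)
  }
  list(r1 = r1, r2 = r2,
       id = sprintf("frag_%06d", seq_along(r1)))
}

.mutate <- function(seqs, rate) {
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  vapply(strsplit(seqs, "", fixed = TRUE), function(b) {
    hit <- which(stats::runif(length(b)) < rate & b %in% names(alt))
    for (i in hit) {
      j <- sample.int(3L, 1L)
      b[i] <- substr(alt[[b[i]]], j, j)
    }
    paste(b, collapse = "")
  }, character(1))
}

#' Build a pooled mock virome with known truth
#'
#' Simulates each phage of `specs` (genome, packaged molecules, sheared
#' paired-end reads), pools all reads into one R1/R2 pair shuffled under
#' the run seed, and returns the reference contigs (one per phage) plus
#' a truth table. With `outPrefix`, also writes `<prefix>_R1.fastq`,
#' `<prefix>_R2.fastq`, `<prefix>_contigs.fasta` and
#' `<prefix>_truth.tsv`.
#'
#' @param specs list of [VirionSpec-class] with unique names.
#' @param outPrefix optional path prefix for on-disk artifacts.
#' @param fragMu,fragSd,readLen,errorRate passed to [shearAndSequence()].
#' @param seed run seed controlling pooling order (per-phage randomness
#'   comes from each spec's own seed).
#' @return list with `contigs` ([Biostrings::DNAStringSet]), `r1`, `r2`
#'   (character vectors), `truth` (`data.frame`) and, when written,
#'   `paths`.
#' @export
buildMockVirome <- function(specs, outPrefix = NULL, fragMu = 400,
                            fragSd = 100, readLen = 75L, errorRate = 0,
                            seed = 1L) {
  nms <- vapply(specs, function(s) s@name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate phage names: ", paste(unique(nms[duplicated(nms)]),
                                          collapse = ", "))
  genomes <- character(length(specs))
  allR1 <- list(); allR2 <- list(); truths <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sub <- .subSeeds(sp@seed, 3L)
    genomes[i] <- simulateGenome(sp@genomeLen, sp@gc, sub[1])
    nMol <- max(20L, ceiling(sp@nReadPairs * fragMu / sp@genomeLen))
    vm <- makeVirionMolecules(genomes[i], sp, nMol, sub[2])
    rd <- shearAndSequence(vm$molecules, sp@nReadPairs, fragMu, fragSd,
                           readLen, errorRate, sub[3])
    allR1[[i]] <- rd$r1
    allR2[[i]] <- rd$r2
    truths[[i]] <- vm$truth
  }
  r1 <- unlist(allR1); r2 <- unlist(allR2)
  set.seed(as.integer(seed))
  ord <- sample.int(length(r1))
  r1 <- r1[ord]; r2 <- r2[ord]
  contigs <- Biostrings::DNAStringSet(genomes)
  names(contigs) <- nms
  truth <- do.call(rbind, truths)
  out <- list(contigs = contigs, r1 = r1, r2 = r2, truth = truth)
  if (!is.null(outPrefix)) {
    paths <- list(fasta = paste0(outPrefix, "_contigs.fasta"),
                  r1 = paste0(outPrefix, "_R1.fastq"),
                  r2 = paste0(outPrefix, "_R2.fastq"),
                  truth = paste0(outPrefix, "_truth.tsv"))
    writeContigs(contigs, paths$fasta)
    ids <- sprintf("pair_%07d", seq_along(r1))
    .writeFastq(r1, paste0(ids, "/1"), paths$r1)
    .writeFastq(r2, paste0(ids, "/2"), paths$r2)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Reference five-phage mock virome specifications
#'
#' The validation panel mirrors the classical reference set: a 5' cos
#' phage (Lambda-like, 12 nt overhang), a 3' cos phage (HK97-like, 10 nt
#' overhang), a short-DTR phage (T7-like, 160 bp repeat), a headful
#' phage with a pac site (P1-like, series of 4 headfuls at 1.03x genome
#' length) and a headful phage without a fixed start (T4-like, the
#' expected no-signal class). Genomes are 40 kb; 2e4 pairs each of 2x75
#' bp give ~75x coverage.
#'
#' @param nReadPairs read pairs per phage (default 20000).
#' @param genomeLen genome length per phage (default 40000).
#' @param seed run seed; per-phage seeds are derived from it.
#' @return list of five [VirionSpec-class] objects.
#' @export
mockFivePhageSpecs <- function(nReadPairs = 20000L, genomeLen = 40000L,
                               seed = 1L) {
  sub <- .subSeeds(seed, 5L)
  list(
    VirionSpec("lambda_like", genomeLen, "COS_5P", gc = 0.50,
               cutPos = as.integer(round(genomeLen * 0.33)),
               overhangLen = 12L, nReadPairs = nReadPairs, seed = sub[1]),
    VirionSpec("hk97_like", genomeLen, "COS_3P", gc = 0.50,
               cutPos = as.integer(round(genomeLen * 0.42)),
               overhangLen = 10L, nReadPairs = nReadPairs, seed = sub[2]),
    VirionSpec("t7_like", genomeLen, "DTR", gc = 0.48,
               cutPos = as.integer(round(genomeLen * 0.52)),
               repeatLen = 160L, nReadPairs = nReadPairs, seed = sub[3]),
    VirionSpec("p1_like", genomeLen, "HEADFUL_PAC", gc = 0.47,
               cutPos = as.integer(round(genomeLen * 0.25)),
               headfulFactor = 1.03, seriesLen = 4L,
               nReadPairs = nReadPairs, seed = sub[4]),
    VirionSpec("t4_like", genomeLen, "HEADFUL_RANDOM", gc = 0.35,
               cutPos = as.integer(round(genomeLen * 0.6)),
               headfulFactor = 1.03, nReadPairs = nReadPairs, seed = sub[5])
  )
}

## Constant-quality FASTQ writer ('I' = Q40); qualities are carried but
## never used downstream.
.writeFastq <- function(seqs, ids, path) {
  qual <- strrep("I", nchar(seqs))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
  invisible(path)
}
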