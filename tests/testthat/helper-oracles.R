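# Independent oracles and small fixture builders used across the suite.

rcOracle <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force mapper: scans every read against every contig position and
# strand by direct substring comparison; applies the same
# unique-candidate-per-contig rule. Slow, simple, independent.
naiveProfiles <- function(contigs, reads, k) {
  out <- list()
  for (id in names(contigs)) {
    seq <- contigs[[id]]
    L <- nchar(seq)
    nw <- L - k + 1L
    wins <- substring(seq, seq_len(nw), seq_len(nw) + k - 1L)
    winOk <- !grepl("N", wins, fixed = TRUE)
    spcF <- spcR <- covF <- covR <- integer(L)
    nUsed <- 0L; nAmb <- 0L; lenSum <- 0
    for (r in reads) {
      ln <- nchar(r)
      if (ln < k) next
      seed <- substr(r, 1L, k)
      fh <- which(winOk & wins == seed)              # 1-based window start
      rh <- which(winOk & wins == rcOracle(seed))
      starts <- c(fh - 1L, rh - 1L + k - 1L)         # 0-based read 5' coords
      strands <- rep(c(1L, 2L), c(length(fh), length(rh)))
      if (length(starts) == 0L) next
      if (length(starts) > 1L) { nAmb <- nAmb + 1L; next }
      st <- starts[1L]
      if (strands[1L] == 1L) {
        spcF[st + 1L] <- spcF[st + 1L] + 1L
        rng <- (st + 1L):min(st + ln, L)
        covF[rng] <- covF[rng] + 1L
      } else {
        spcR[st + 1L] <- spcR[st + 1L] + 1L
        rng <- max(1L, st - ln + 2L):(st + 1L)
        covR[rng] <- covR[rng] + 1L
      }
      nUsed <- nUsed + 1L
      lenSum <- lenSum + ln
    }
    out[[id]] <- list(spcFwd = spcF, spcRev = spcR, covFwd = covF,
                      covRev = covR, nReadsUsed = nUsed,
                      nAmbiguousSkipped = nAmb,
                      meanReadLen = if (nUsed) lenSum / nUsed else NA_real_)
  }
  out
}

# Exact binomial upper tail by direct pmf summation.
binomTailOracle <- function(spc, cov, p) {
  if (spc == 0L) return(1)
  if (spc > cov) stop("spc > cov")
  sum(dbinom(spc:cov, cov, p))
}

# Simulate one phage and map its own reads back onto its genome.
simPhage <- function(mechanism, genomeLen = 20000L, nPairs = 4000L,
                     seed = 1L, overhangLen = NA, repeatLen = NA,
                     cutPos = round(genomeLen * 0.35), gc = 0.5,
                     name = "sim") {
  sp <- VirionSpec(name, genomeLen, mechanism, gc = gc,
                   cutPos = as.integer(cutPos), overhangLen = overhangLen,
                   repeatLen = repeatLen, nReadPairs = as.integer(nPairs),
                   seed = as.integer(seed))
  mock <- buildMockVirome(list(sp), seed = seed)
  idx <- buildSeedIndex(mock$contigs, 20L)
  pro <- accumulateProfiles(idx, mock$r1, mock$r2)[[1]]
  list(spec = sp, contigs = mock$contigs, r1 = mock$r1, r2 = mock$r2,
       profiles = pro, truth = mock$truth)
}

# Hand-built flat-coverage profile with chosen SPC spikes, for peak and
# classifier unit tests. spikes: data.frame(strand, pos1, spc).
flatProfiles <- function(L, cov = 50L, spikes = NULL, meanReadLen = 50,
                         contigId = "toy", covBoost = NULL) {
  covF <- rep(as.integer(cov), L)
  covR <- rep(as.integer(cov), L)
  if (!is.null(covBoost)) {   # list(from1, to1, mult)
    rng <- covBoost$from1:covBoost$to1
    covF[rng] <- as.integer(covF[rng] * covBoost$mult)
    covR[rng] <- as.integer(covR[rng] * covBoost$mult)
  }
  spcF <- integer(L); spcR <- integer(L)
  if (!is.null(spikes)) {
    for (i in seq_len(nrow(spikes))) {
      if (spikes$strand[i] == "fwd") spcF[spikes$pos1[i]] <- spikes$spc[i]
      else spcR[spikes$pos1[i]] <- spikes$spc[i]
    }
  }
  CoverageProfiles(contigId, spcF, spcR, pmax(covF, spcF), pmax(covR, spcR),
                   meanReadLen = meanReadLen)
}
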