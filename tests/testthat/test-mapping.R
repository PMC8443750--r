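test_that("seed index enumerates every N-free k-mer occurrence", {
  idx <- buildSeedIndex(c(c1 = "ACGTACGT"), k = 8L)  # k >= 8 floor
  expect_equal(nrow(idx@table), 1L)

  # enumeration on a k=8 example with a repeated k-mer
  s <- paste0("ACGTACGT", "ACGTACGT")  # "ACGTACGT" occurs at 0 and 8
  idx <- buildSeedIndex(c(c1 = s), k = 8L)
  expect_equal(nrow(idx@table), nchar(s) - 8L + 1L)
  expect_equal(sort(idx@table[kmer == "ACGTACGT", pos0]), c(0L, 4L, 8L))

  # windows containing N are excluded
  idxN <- buildSeedIndex(c(c1 = "ACGTACGTNACGTACG"), k = 8L)
  expect_false(any(grepl("N", idxN@table$kmer)))
  expect_equal(nrow(idxN@table), 1L)  # only window 0 avoids the N

  # a k-mer shared by two contigs lists both placements
  idx2 <- buildSeedIndex(c(a = "AACCGGTTAA", b = "TTAACCGGTT"), k = 8L)
  expect_equal(nrow(idx2@table[kmer == "AACCGGTT"]), 2L)
  expect_setequal(idx2@table[kmer == "AACCGGTT", cid], c(1L, 2L))

  # contig shorter than k: zero entries plus a warning
  expect_warning(idx3 <- buildSeedIndex(c(a = "ACGTACGTAC", b = "ACGT"), k = 8L),
                 "shorter than the seed")
  expect_equal(unname(idx3@contigLengths), c(10L, 4L))
  expect_false(any(idx3@table$cid == 2L))
})

test_that("within-contig ambiguous reads are skipped and counted", {
  # seed of the read occurs twice in the contig
  contig <- c(c1 = paste0("ACGTACGTAC", "ACGTACGTAC"))
  idx <- buildSeedIndex(contig, k = 8L)
  pro <- accumulateProfiles(idx, c("ACGTACGTACGT"))[[1]]
  expect_equal(pro@nReadsUsed, 0L)
  expect_equal(pro@nAmbiguousSkipped, 1L)
  expect_true(all(pro@spcFwd == 0L) && all(pro@spcRev == 0L))
})

test_that("unique forward and reverse starts land where the oracle says", {
  set.seed(77)
  g <- randomSeq(60L)
  idx <- buildSeedIndex(c(c1 = g), k = 8L)
  # forward read taken from 1-based 21..40: SPC at 21, coverage 21..40
  pro <- accumulateProfiles(idx, substr(g, 21L, 40L))[[1]]
  expect_equal(which(pro@spcFwd == 1L), 21L)
  expect_equal(which(pro@covFwd == 1L), 21:40)
  expect_equal(sum(pro@spcRev), 0L)
  # reverse read: revcomp of 1-based 31..50; its 5' base maps at 50 on
  # the reverse strand and coverage extends leftwards over 31..50
  pro2 <- accumulateProfiles(idx, rcOracle(substr(g, 31L, 50L)))[[1]]
  expect_equal(sum(pro2@spcFwd), 0L)
  expect_equal(which(pro2@spcRev == 1L), 50L)
  expect_equal(which(pro2@covRev == 1L), 31:50)
  # a read matching nowhere contributes nothing; an all-short input errors
  pro3 <- accumulateProfiles(idx, paste(rep("T", 30L), collapse = ""))[[1]]
  expect_equal(pro3@nReadsUsed + pro3@nAmbiguousSkipped, 0L)
  expect_error(accumulateProfiles(idx, c("ACG", "T")), "no usable reads")
})

test_that("profiles equal the brute-force all-positions oracle", {
  set.seed(202)
  k <- 12L
  nContig <- 20L
  contigs <- setNames(
    vapply(sample(300:2000, nContig, replace = TRUE), randomSeq, character(1)),
    paste0("ctg", seq_len(nContig)))
  # reads: substrings of contigs (both strands), some random, some short
  reads <- character(0)
  for (i in 1:400) {
    ci <- sample.int(nContig, 1L)
    L <- nchar(contigs[ci])
    ln <- sample(20:80, 1L)
    st <- sample.int(L - ln + 1L, 1L)
    r <- substr(contigs[ci], st, st + ln - 1L)
    if (runif(1) < 0.5) r <- rcOracle(r)
    reads <- c(reads, r)
  }
  reads <- c(reads, vapply(rep(40L, 50L), randomSeq, character(1)),
             vapply(rep(5L, 10L), randomSeq, character(1)))
  reads <- sample(reads)

  idx <- buildSeedIndex(contigs, k = k)
  got <- accumulateProfiles(idx, reads)
  want <- naiveProfiles(contigs, reads, k = k)
  for (id in names(contigs)) {
    expect_equal(got[[id]]@spcFwd, want[[id]]$spcFwd, label = id)
    expect_equal(got[[id]]@spcRev, want[[id]]$spcRev)
    expect_equal(got[[id]]@covFwd, want[[id]]$covFwd)
    expect_equal(got[[id]]@covRev, want[[id]]$covRev)
    expect_equal(got[[id]]@nReadsUsed, want[[id]]$nReadsUsed)
    expect_equal(got[[id]]@nAmbiguousSkipped, want[[id]]$nAmbiguousSkipped)
    expect_equal(got[[id]]@meanReadLen, want[[id]]$meanReadLen)
    # SPC conservation (also enforced by the class validity)
    expect_equal(sum(got[[id]]@spcFwd) + sum(got[[id]]@spcRev),
                 got[[id]]@nReadsUsed)
  }
})

test_that("mapping is invariant to read order and chunk size", {
  set.seed(9)
  contigs <- c(g = randomSeq(3000L))
  reads <- vapply(1:300, function(i) {
    st <- sample.int(2900L, 1L)
    r <- substr(contigs[[1]], st, st + 59L)
    if (i %% 2L) rcOracle(r) else r
  }, character(1))
  idx <- buildSeedIndex(contigs, 20L)
  a <- accumulateProfiles(idx, reads)[[1]]
  b <- accumulateProfiles(idx, rev(reads))[[1]]
  d <- accumulateProfiles(idx, reads, chunkSize = 17L)[[1]]
  for (s in c("spcFwd", "spcRev", "covFwd", "covRev", "nReadsUsed")) {
    expect_identical(slot(a, s), slot(b, s))
    expect_identical(slot(a, s), slot(d, s))
  }
})

test_that("reverse-complementing the contig swaps strands and mirrors coords", {
  set.seed(31)
  g <- randomSeq(2500L)
  reads <- vapply(1:250, function(i) {
    st <- sample.int(2400L, 1L)
    r <- substr(g, st, st + 69L)
    if (i %% 3L == 0L) rcOracle(r) else r
  }, character(1))
  fwd <- accumulateProfiles(buildSeedIndex(c(x = g), 20L), reads)[[1]]
  rev <- accumulateProfiles(buildSeedIndex(c(x = rcOracle(g)), 20L), reads)[[1]]
  expect_identical(rev@spcFwd, rev(fwd@spcRev))
  expect_identical(rev@spcRev, rev(fwd@spcFwd))
  expect_identical(rev@covFwd, rev(fwd@covRev))
  expect_identical(rev@covRev, rev(fwd@covFwd))
})
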