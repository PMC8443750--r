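# Build a PeakSet by hand around a flat-coverage profile.
mkPeak <- function(strand, pos0, spc = 50L, cov = 60L) {
  new("PeakCall", strand = strand, pos = as.integer(pos0), spc = spc,
      cov = cov, tau = spc / cov, pval = 1e-30, qval = 1e-28,
      atEdge = FALSE)
}
mkPeakSet <- function(id, fwd = NULL, rev = NULL, secondary = list(),
                      meanCov = 30, lowCoverage = FALSE) {
  new("PeakSet", contigId = id, primaryFwd = fwd, primaryRev = rev,
      secondary = secondary, meanCov = meanCov, lowCoverage = lowCoverage)
}

test_that("coverage elevation ratio behaves on flat and stepped coverage", {
  pro <- flatProfiles(5000L, cov = 15L, contigId = "toy")  # 30x total
  expect_equal(coverageElevationRatio(pro, 1000L, 1200L), 1.0)
  pro2 <- flatProfiles(5000L, cov = 15L, contigId = "toy",
                       covBoost = list(from1 = 1001L, to1 = 1201L, mult = 2))
  expect_equal(coverageElevationRatio(pro2, 1000L, 1200L), 2.0)
  expect_error(coverageElevationRatio(pro, 1200L, 1000L), "a < b")
})

test_that("decision rules map peak geometry to the mechanism classes", {
  pro <- flatProfiles(40000L, cov = 15L, contigId = "c")

  # 4a: fwd 1000, rev 1012 -> 5' cos, overhang 12
  p <- classifyPackaging(mkPeakSet("c", mkPeak("fwd", 999L), mkPeak("rev", 1011L)), pro)
  expect_equal(mechanism(p), "COS_5P")
  expect_equal(p@overhangLen, 12L)
  expect_equal(unname(termini(p)), c(1000L, 1012L))

  # 4b: fwd 1010, rev 1000 -> 3' cos, overhang 10
  p <- classifyPackaging(mkPeakSet("c", mkPeak("fwd", 1009L), mkPeak("rev", 999L)), pro)
  expect_equal(mechanism(p), "COS_3P")
  expect_equal(p@overhangLen, 10L)

  # 4c: identical positions -> ambiguous polarity
  p <- classifyPackaging(mkPeakSet("c", mkPeak("fwd", 999L), mkPeak("rev", 999L)), pro)
  expect_equal(mechanism(p), "AMBIGUOUS")
  expect_match(paste(p@warnings, collapse = " "), "blunt")

  # 3: single fwd peak -> headful pac on fwd
  p <- classifyPackaging(mkPeakSet("c", fwd = mkPeak("fwd", 4999L)), pro)
  expect_equal(mechanism(p), "HEADFUL_PAC")
  expect_equal(p@pacStrand, "fwd")
  expect_equal(unname(termini(p)), c(5000L, NA_integer_))

  # 2: no peaks at decent coverage -> no signal (T4-like)
  p <- classifyPackaging(mkPeakSet("c"), pro)
  expect_equal(mechanism(p), "NO_SIGNAL")

  # 1: no peaks and very low coverage -> low-coverage warning class
  proLow <- flatProfiles(40000L, cov = 2L, contigId = "c")
  p <- classifyPackaging(mkPeakSet("c", meanCov = 4, lowCoverage = TRUE), proLow)
  expect_equal(mechanism(p), "LOW_COVERAGE")
  expect_match(paste(p@warnings, collapse = " "), "low mean coverage")
})

test_that("distant peak pairs need coverage elevation to call a DTR", {
  # doubly covered interval between the peaks -> DTR
  proDtr <- flatProfiles(40000L, cov = 15L, contigId = "c",
                         covBoost = list(from1 = 1000L, to1 = 1160L, mult = 2))
  p <- classifyPackaging(mkPeakSet("c", mkPeak("fwd", 999L), mkPeak("rev", 1159L)),
                         proDtr)
  expect_equal(mechanism(p), "DTR")
  expect_equal(p@repeatLen, 160L)
  expect_gt(p@elevationRatio, 1.8)
  # same geometry without elevation -> ambiguous, both peaks reported
  proFlat <- flatProfiles(40000L, cov = 15L, contigId = "c")
  p2 <- classifyPackaging(mkPeakSet("c", mkPeak("fwd", 999L), mkPeak("rev", 1159L)),
                          proFlat)
  expect_equal(mechanism(p2), "AMBIGUOUS")
  expect_equal(unname(termini(p2)), c(1000L, 1160L))
})

test_that("circularly permuted termini are recovered via the wrap-around arc", {
  # origin falls between the cos cuts: fwd peak near the right end, rev
  # peak near the left end, circular delta = (4 - (L-3)) mod L = 7
  L <- 40000L
  pro <- flatProfiles(L, cov = 15L, contigId = "c")
  p <- classifyPackaging(mkPeakSet("c", mkPeak("fwd", L - 3L),
                                   mkPeak("rev", 4L)), pro)
  expect_equal(mechanism(p), "COS_5P")
  expect_equal(p@overhangLen, 7L)
  expect_match(paste(p@warnings, collapse = " "), "circular")

  # wrapped DTR: repeat spans the origin with doubled coverage
  covF <- rep(15L, L); covF[c(1:100, (L - 59L):L)] <- 30L
  proW <- CoverageProfiles("c", integer(L), integer(L), covF, rep(15L, L),
                           meanReadLen = 75)
  pW <- classifyPackaging(mkPeakSet("c", mkPeak("fwd", L - 60L),
                                    mkPeak("rev", 99L)), proW)
  expect_equal(mechanism(pW), "DTR")
  expect_equal(pW@repeatLen, 159L)  # circular distance between the peaks
})

test_that("classification is total over random peak configurations", {
  set.seed(55)
  pro <- flatProfiles(5000L, cov = 15L, contigId = "c")
  for (i in 1:60) {
    fwd <- if (runif(1) < 0.7) mkPeak("fwd", sample.int(5000L, 1L) - 1L)
    rev <- if (runif(1) < 0.7) mkPeak("rev", sample.int(5000L, 1L) - 1L)
    p <- classifyPackaging(mkPeakSet("c", fwd, rev), pro,
                           maxDtr = 2000L)
    expect_true(validObject(p, complete = TRUE))
    expect_length(mechanism(p), 1L)
  }
})

test_that("each mechanism is recovered across seeded simulations at ~30x", {
  set.seed(1234)
  perMech <- 20L
  mechs <- c("COS_5P", "COS_3P", "DTR", "HEADFUL_PAC")
  ok <- 0L; total <- 0L
  for (mech in mechs) {
    seeds <- sample.int(1e7L, perMech)
    for (sd in seeds) {
      sim <- simPhage(mech, genomeLen = 12000L, nPairs = 2400L, seed = sd,
                      overhangLen = if (mech == "COS_5P") 12L
                                    else if (mech == "COS_3P") 10L else NA,
                      repeatLen = if (mech == "DTR") 120L else NA)
      pred <- classifyPackaging(callPeaks(sim$profiles), sim$profiles)
      total <- total + 1L
      if (mechanism(pred) == mech) {
        ok <- ok + 1L
        if (mech %in% c("COS_5P", "COS_3P")) {
          # overhang recovered exactly in every correct classification
          expect_equal(pred@overhangLen, sim$truth$overhang_len)
          expect_equal(pred@termFwd, sim$truth$term_fwd)
        }
      }
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("cos polarity survives reverse complementation of the contig", {
  sim <- simPhage("COS_5P", genomeLen = 15000L, nPairs = 3000L,
                  overhangLen = 12L, cutPos = 6000L, seed = 17L)
  callAndClassify <- function(contig) {
    pro <- accumulateProfiles(buildSeedIndex(contig, 20L), sim$r1, sim$r2)[[1]]
    classifyPackaging(callPeaks(pro), pro)
  }
  fwd <- callAndClassify(sim$contigs)
  rcContig <- Biostrings::reverseComplement(sim$contigs)
  names(rcContig) <- names(sim$contigs)
  rev <- callAndClassify(rcContig)
  L <- 15000L
  expect_equal(mechanism(fwd), "COS_5P")
  expect_equal(mechanism(rev), "COS_5P")  # 5' overhangs stay 5'
  expect_equal(rev@overhangLen, fwd@overhangLen)
  # termini mirror: fwd terminus of one is the mirrored rev terminus
  expect_equal(rev@termFwd, L + 1L - fwd@termRev)
  expect_equal(rev@termRev, L + 1L - fwd@termFwd)
})
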