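test_that("FASTA parsing uppercases, truncates ids at whitespace, keeps order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1 NODE description", "acgt", ">c2", "NN", "NN"), f)
  x <- readContigs(f)
  expect_equal(names(x), c("c1", "c2"))
  expect_equal(as.character(x[["c1"]]), "ACGT")
  expect_equal(as.character(x[["c2"]]), "NNNN")  # wrapped lines joined
  expect_equal(S4Vectors::mcols(x)$header[1], "c1 NODE description")
})

test_that("FASTA error paths: empty, duplicate id, non-IUPAC character", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(readContigs(f), "no contigs")

  writeLines(c(">a", "AC", ">a", "GT"), f)
  expect_error(readContigs(f), "duplicate contig id.*a")

  writeLines(c(">a", "ACXGT"), f)
  expect_error(readContigs(f), "non-IUPAC.*position 3")
})

test_that("ambiguity codes are accepted and collapsed to N", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACRYGT"), f)
  expect_equal(as.character(readContigs(f)[[1]]), "ACNNGT")
})

test_that("FASTA round-trip preserves ids and sequences", {
  f <- withr::local_tempfile(fileext = ".fasta")
  set.seed(5)
  seqs <- setNames(vapply(c(10L, 333L, 71L), randomSeq, character(1)),
                   c("n1", "n2", "n3"))
  writeContigs(seqs, f)
  back <- readContigs(f)
  expect_equal(names(back), names(seqs))
  expect_equal(as.character(back), unname(seqs), ignore_attr = TRUE)
})

test_that("gzipped FASTA and FASTQ yield identical records to plain files", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  fagz <- withr::local_tempfile(fileext = ".fasta.gz")
  lines <- c(">a", "ACGTACGT", ">b", "TTTTGGGG")
  writeLines(lines, fa)
  con <- gzfile(fagz, "wt"); writeLines(lines, con); close(con)
  expect_identical(as.character(readContigs(fa)), as.character(readContigs(fagz)))

  fq <- withr::local_tempfile(fileext = ".fastq")
  fqgz <- withr::local_tempfile(fileext = ".fastq.gz")
  rec <- c("@r1", "acgt", "+", "IIII", "@r2", "GGCC", "+", "IIII")
  writeLines(rec, fq)
  con <- gzfile(fqgz, "wt"); writeLines(rec, con); close(con)
  expect_identical(readFastq(fq), readFastq(fqgz))
  expect_equal(readFastq(fq)$seq, c("ACGT", "GGCC"))
})

test_that("FASTQ streaming: chunking is transparent and counts are exact", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  set.seed(7)
  seqs <- vapply(rep(30L, 25L), randomSeq, character(1))
  writeLines(paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n",
                    strrep("I", 30L)), fq)
  st <- streamReads(fq, chunkSize = 7L)
  got <- character(0)
  while (!is.null(ch <- st$nextChunk())) got <- c(got, ch$seq)
  expect_equal(got, seqs)
  expect_equal(st$totalReads(), 25L)
})

test_that("FASTQ error paths: truncation and mate desynchronisation", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), fq)
  st <- streamReads(fq)
  expect_error(st$nextChunk(), "truncated FASTQ record near record 2")

  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@a/1", "ACGT", "+", "IIII", "@b/1", "GGGG", "+", "IIII"), r1)
  writeLines(c("@a/2", "TTTT", "+", "IIII"), r2)
  st <- streamReads(r1, r2)
  expect_error(st$nextChunk(), "unequal record counts")
})

test_that("contig length filter keeps the inclusive boundary and order", {
  set.seed(1)
  x <- Biostrings::DNAStringSet(vapply(c(400L, 500L, 600L), randomSeq,
                                       character(1)))
  names(x) <- c("a", "b", "c")
  expect_message(kept <- filterContigs(x, 500L), "1 contig")
  expect_equal(names(kept), c("b", "c"))
  expect_equal(Biostrings::width(kept), c(500L, 600L))
  # min_len = 1 is the identity
  expect_equal(names(filterContigs(x, 1L)), names(x))
  # everything short -> empty set plus warning
  expect_warning(none <- filterContigs(x, 10000L), "no contigs")
  expect_length(none, 0L)
})

test_that("rotateToStart rotates, preserves composition, and inverts", {
  expect_equal(rotateToStart("ACGTAC", 2L), "GTACAC")
  expect_equal(rotateToStart("ACGTAC", 0L), "ACGTAC")
  expect_error(rotateToStart("ACGT", 4L), "newStart")
  expect_error(rotateToStart("ACGT", -1L), "newStart")
  set.seed(42)
  for (i in 1:20) {
    s <- randomSeq(sample(5:200, 1L))
    p <- sample.int(nchar(s), 1L) - 1L
    r <- rotateToStart(s, p)
    expect_equal(nchar(r), nchar(s))
    expect_equal(sort(strsplit(r, "")[[1]]), sort(strsplit(s, "")[[1]]))
    # composition of rotations is the identity
    expect_equal(rotateToStart(r, (nchar(s) - p) %% nchar(s)), s)
  }
})
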