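test_that("quality characters decode as code point minus offset", {
  p <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), p)
  fq <- read_fastq(p, offset = 33)
  expect_equal(fq$id, "r1")
  expect_equal(fq$seq, "ACGT")
  expect_equal(fq$qual[[1]], c(40L, 40L, 40L, 40L))

  writeLines(c("@r1", "ACGT", "+", "!!!!"), p)
  expect_equal(read_fastq(p, offset = 33)$qual[[1]], rep(0L, 4))

  writeLines(c("@r2", "ACGT", "+", "hhhh"), p)
  expect_equal(read_fastq(p, offset = 64)$qual[[1]], rep(40L, 4))
})

test_that("parse/serialize round trip is byte-identical", {
  set.seed(11)
  reads <- make_reads(lapply(1:50, function(i) {
    sample(0:93, sample(1:150, 1), replace = TRUE)
  }))
  reads$seq <- vapply(nchar(reads$seq), function(L) {
    paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE), collapse = "")
  }, "")
  p1 <- write_tmp_fastq(reads, "a.fastq")
  fq <- read_fastq(p1)
  p2 <- file.path(dirname(p1), "b.fastq")
  write_fastq(fq, p2)
  expect_identical(readLines(p2), readLines(p1))
  expect_identical(fq$qual, reads$qual)
})

test_that("gzip input is transparently decompressed", {
  reads <- make_reads(list(c(30L, 31L, 32L)))
  d <- withr::local_tempdir()
  gz <- file.path(d, "r.fastq.gz")
  write_fastq(reads, gz)
  fq <- read_fastq(gz, offset = 33)
  expect_equal(fq$qual[[1]], c(30L, 31L, 32L))
})

test_that("malformed records are fatal and name the record ordinal", {
  p <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+"), p)
  expect_error(read_fastq(p, offset = 33), "multiple of 4")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2", "ACGT", "+", "IIII"), p)
  expect_error(read_fastq(p, offset = 33), "record 2.*@")
  writeLines(c("@r1", "ACGT", "x", "IIII"), p)
  expect_error(read_fastq(p, offset = 33), "record 1.*\\+")
  writeLines(c("@r1", "ACGT", "+", "III"), p)
  expect_error(read_fastq(p, offset = 33), "record 1.*length")
})

test_that("encoding detection follows the code-point rules", {
  p <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "II#I"), p)  # '#' = 35 < 59
  expect_equal(detect_quality_encoding(p), 33L)
  writeLines(c("@r1", "ACGT", "+", "fghf"), p)  # 102-104, all >= 64, > 74
  expect_equal(detect_quality_encoding(p), 64L)
  writeLines(c("@r1", "ACGT", "+", "@ABC"), p)  # 64-67: ambiguous
  expect_warning(off <- detect_quality_encoding(p), "ambiguous")
  expect_equal(off, 33L)
  writeLines(character(0), p)
  expect_error(detect_quality_encoding(p), "empty")
})

test_that("auto-detected Phred+64 input decodes to the same scores as +33", {
  reads <- make_reads(list(c(20L, 30L, 40L), c(2L, 15L, 41L)))
  d <- withr::local_tempdir()
  p64 <- file.path(d, "p64.fastq")
  lines <- character(8)
  lines[c(1, 5)] <- paste0("@", reads$id)
  lines[c(2, 6)] <- reads$seq
  lines[c(3, 7)] <- "+"
  lines[c(4, 8)] <- vapply(reads$qual, function(q) intToUtf8(q + 64L), "")
  writeLines(lines, p64)
  fq <- read_fastq(p64)  # auto-detect
  expect_identical(fq$qual, reads$qual)
})

test_that("pair reading is positional and rejects unequal files", {
  r1 <- make_reads(list(c(30L, 30L), c(31L, 31L), c(32L, 32L)))
  r2 <- make_reads(list(c(20L, 20L), c(21L, 21L), c(22L, 22L)))
  d <- withr::local_tempdir()
  p1 <- file.path(d, "r1.fastq")
  p2 <- file.path(d, "r2.fastq")
  write_fastq(r1, p1)
  write_fastq(r2, p2)
  pr <- read_fastq_pair(p1, p2, offset = 33)
  expect_equal(length(pr$r1), 3L)
  expect_equal(pr$r1$mate, 1L)
  expect_equal(pr$r2$mate, 2L)
  expect_equal(pr$r2$qual[[3]], c(22L, 22L))

  write_fastq(r2[1:2], p2)
  expect_error(read_fastq_pair(p1, p2, offset = 33), "unequal")

  write_fastq(r1[0], p1)
  write_fastq(r2[0], p2)
  pr0 <- read_fastq_pair(p1, p2, offset = 33)
  expect_equal(length(pr0$r1), 0L)
})

test_that("record validation enforces the container invariants", {
  expect_error(fastq("r1", "ACGT", list(c(30L, 30L))), "length")
  expect_error(fastq("r1", "", list(integer(0))), "empty")
  expect_error(fastq("r1", "AC", list(c(94L, 10L))), "\\[0, 93\\]")
  expect_error(fastq("r1", "AC", list(c(-1L, 10L))), "\\[0, 93\\]")
})
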