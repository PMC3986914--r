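test_that("RTSS catalogs parse with midpoint anchors and survive round-trips", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t1100\tr1\t0\t+",
               "chr1\t1000\t1001\tr2\t0\t-"), f)
  cat <- read_rtss_catalog(f)
  expect_equal(cat$anchor, c(1050L, 1000L))
  expect_equal(cat$strand, c("+", "-"))

  f2 <- withr::local_tempfile(fileext = ".bed")
  write_rtss_catalog(cat, f2)
  expect_equal(read_rtss_catalog(f2), cat)
})

test_that("catalog parsing rejects malformed input with line numbers", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1\t100\tr1\t0\t+", "chr1\t5\t50"), f)
  expect_error(read_rtss_catalog(f), "line 2")

  writeLines(c("chr1\t1\t100\tr1\t0\t+", "chr1\t5\t50\tr1\t0\t-"), f)
  expect_error(read_rtss_catalog(f), "duplicate")

  writeLines(c("chr1\t100\t100\tr1\t0\t+"), f)
  expect_error(read_rtss_catalog(f), "half-open")

  writeLines(character(0), f)
  expect_warning(cat0 <- read_rtss_catalog(f), "empty")
  expect_equal(nrow(cat0), 0L)
})

test_that("peak files keep all unmerged intervals and ignore extra columns", {
  f <- withr::local_tempfile(fileext = ".broadPeak")
  writeLines(c("chr1\t500\t900\tp1\t800\t.\t4.5\t-1\t-1",
               "chr1\t100\t300\tp2\t900\t.\t5.0\t-1\t-1",
               "chr1\t200\t400\tp3\t700\t.\t3.0\t-1\t-1"), f)
  peaks <- read_peaks(f)
  expect_equal(nrow(peaks), 3L)            # overlapping peaks both retained
  expect_equal(peaks$start, c(100L, 200L, 500L))  # sorted within chromosome
  expect_named(peaks, c("chrom", "start", "end"))

  writeLines("chr1\t300\t200\tp1", f)
  expect_error(read_peaks(f), "start >= end")
})

test_that("bedGraph and wiggle signal tracks have identical query semantics", {
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t10\t2.5", "chr1\t10\t20\t1.0"), bg)
  track <- read_signal(bg)
  # value 2.5 at bp 0..9, 1.0 at bp 10..19: bins [0,10) and [10,20)
  expect_equal(signal_profile(track, anchor = 10, chrom = "chr1",
                              bin_bp = 10, flank = 10),
               c(25, 10))
  # query fully outside the covered region -> zeros
  expect_equal(signal_profile(track, anchor = 5000, chrom = "chr1",
                              bin_bp = 100, flank = 300), rep(0, 6))

  # fixedStep (1-based) equivalent of the same data
  wig <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=1 step=10 span=10",
               "2.5", "1.0"), wig)
  expect_equal(as.data.frame(read_signal(wig)), as.data.frame(track))

  # variableStep form
  wig2 <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("variableStep chrom=chr1 span=10", "1\t2.5", "11\t1.0"), wig2)
  expect_equal(as.data.frame(read_signal(wig2)), as.data.frame(track))
})

test_that("overlapping signal intervals are rejected", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t10\t1", "chr1\t5\t15\t2"), f)
  expect_error(read_signal(f), "overlapping")
})

test_that("expression matrices and tag files round-trip", {
  m <- matrix(c(0L, 5L, 2L, 7L), nrow = 2,
              dimnames = list(c("r1", "r2"), c("s1", "s2")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, f)
  expect_equal(read_expression_matrix(f), m)

  reads <- read_starts(c("chr1", "chr2"), c(100L, 7L), c("+", "-"), mark = "X")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_tag_file(reads, f2)
  back <- read_tag_file(f2, mark = "X")
  expect_equal(back$pos, reads$pos)
  expect_equal(back$strand, reads$strand)
})

test_that("parsed intervals obey the half-open invariant on random lines", {
  set.seed(11)
  for (i in 1:25) {
    s <- sample.int(1e6, 1L)
    w <- sample.int(500, 1L)
    f <- withr::local_tempfile()
    writeLines(sprintf("chr%d\t%d\t%d\tx\t0\t%s",
                       sample.int(3, 1L), s, s + w,
                       sample(c("+", "-"), 1L)), f)
    cat <- read_rtss_catalog(f)
    expect_true(cat$start < cat$end)
    expect_true(cat$anchor >= cat$start && cat$anchor < cat$end)
  }
})

test_that("BAM ingestion reduces alignments to 5' tag records", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    paste("a1", 0, "chr1", 101, 60, "10M", "*", 0, 0,
          "ACGTACGTAC", "**********", sep = "\t"),
    paste("a2", 16, "chr1", 201, 60, "10M", "*", 0, 0,
          "ACGTACGTAC", "**********", sep = "\t")
  ), sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  tags <- read_tags_bam(bam, mark = "test")
  # + read: 0-based leftmost; - read: 0-based last aligned base
  expect_equal(tags$pos, c(100L, 209L))
  expect_equal(tags$strand, c("+", "-"))
})
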