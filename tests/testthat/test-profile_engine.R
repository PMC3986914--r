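test_that("read-start shifting is strand-aware and clipped at zero", {
  r <- read_starts(c("chr1", "chr1", "chr1"), c(500L, 500L, 50L),
                   c("+", "-", "-"))
  s <- shift_read_starts(r, 100L)
  expect_equal(s$pos, c(600L, 400L, 0L))
  expect_error(shift_read_starts(r, -1L), ">= 0")
})

test_that("binning follows the half-open bin-edge and orientation rules", {
  # a position exactly at the anchor falls in the first downstream bin (31)
  p <- bin_profile(1000L, anchor = 1000L, strand = "+")
  expect_length(p, 60L)
  expect_equal(which(p == 1), 31L)
  expect_equal(sum(p), 1)

  # all positions outside the window -> zero vector
  expect_equal(sum(bin_profile(c(1L, 99999L), anchor = 50000L)), 0)

  # minus-strand profile is the reversal of the plus-strand profile
  pos <- c(47100L, 48000L, 50100L, 52950L)
  plus <- bin_profile(pos, 50000L, "+")
  minus <- bin_profile(pos, 50000L, "-")
  expect_equal(minus, rev(plus))
})

test_that("binning totals match a naive per-read loop on random inputs", {
  set.seed(7)
  for (i in 1:50) {
    anchor <- sample.int(100000, 1L) + 10000L
    pos <- sample.int(200000, 80L)
    strand <- sample(c("+", "-"), 1L)
    prof <- bin_profile(pos, anchor, strand)
    # independent oracle: loop over reads
    naive <- rep(0, 60)
    for (p in pos) {
      if (p >= anchor - 3000 && p < anchor + 3000) {
        b <- (p - anchor + 3000) %/% 100 + 1
        naive[b] <- naive[b] + 1
      }
    }
    if (strand == "-") naive <- rev(naive)
    expect_equal(prof, naive)
  }
})

test_that("profiles are translation-equivariant and orientation-involutive", {
  set.seed(8)
  pos <- sample.int(50000, 60L) + 20000L
  anchor <- 45000L
  for (strand in c("+", "-")) {
    base <- bin_profile(pos, anchor, strand)
    shifted <- bin_profile(pos + 1234L, anchor + 1234L, strand)
    expect_equal(shifted, base)
    # flipping strand twice returns the original
    expect_equal(rev(rev(base)), base)
    expect_equal(bin_profile(pos, anchor, strand),
                 rev(bin_profile(pos, anchor, setdiff(c("+", "-"), strand))))
  }
})

test_that("low-signal filtering keeps profiles at the 100-read boundary", {
  m <- rbind(a = c(rep(1, 50), rep(1, 10)),          # 60 reads
             b = rep(2, 60),                          # 120 reads
             c = c(rep(0, 59), 100))                  # exactly 100
  kept <- filter_low_signal(m, min_reads = 100)
  expect_setequal(rownames(kept), c("b", "c"))
  expect_equal(nrow(filter_low_signal(m[0, , drop = FALSE])), 0L)
})

test_that("Gaussian smoothing maps 60 bins to 48 and preserves mass and level", {
  expect_length(smooth_profile(rnorm(60)^2), 48L)
  expect_error(smooth_profile(rnorm(59)), "length 60")

  # constant profile stays constant (kernel is normalised)
  expect_equal(smooth_profile(rep(3.7, 60)), rep(3.7, 48))

  # mass of an interior delta is preserved after trimming (support inside)
  delta <- rep(0, 60); delta[30] <- 1
  expect_equal(sum(smooth_profile(delta)), 1)

  # matrix input smooths row-wise
  m <- rbind(r1 = delta, r2 = rep(1, 60))
  sm <- smooth_profile(m)
  expect_equal(dim(sm), c(2L, 48L))
  expect_equal(unname(sm["r2", ]), rep(1, 48))
})

test_that("profile averaging is the element-wise mean with member counting", {
  a <- c(rep(0, 9), 1, rep(0, 50))
  b <- c(rep(0, 19), 1, rep(0, 40))
  expect_equal(average_profiles(rbind(a, a))$values, a)
  avg <- average_profiles(rbind(a, b))
  expect_equal(avg$values[c(10, 20)], c(0.5, 0.5))
  expect_equal(avg$n_members, 2L)
  expect_equal(average_profiles(rbind(a))$values, a)
  expect_error(average_profiles(list(a, b[1:30])), "mixed lengths")
})

test_that("signal-track binning sums per-bp values with the same geometry", {
  uni <- signal_track(data.frame(chrom = "chr1", start = 0L, end = 200000L,
                                 value = 1))
  expect_equal(signal_profile(uni, 50000L, "chr1", "+"), rep(100, 60))
  zero <- signal_track(data.frame(chrom = "chr1", start = 0L, end = 10L,
                                  value = 0))
  expect_equal(signal_profile(zero, 50000L, "chr1", "+"), rep(0, 60))

  # cross-operation oracle: an indicator track of read starts matches
  # bin_profile on the same (unshifted) positions
  set.seed(12)
  pos <- unique(sample.int(20000, 100L) + 40000L)
  track <- signal_track(data.frame(chrom = "chr1", start = pos,
                                   end = pos + 1L, value = 1))
  for (strand in c("+", "-")) {
    expect_equal(signal_profile(track, 50000L, "chr1", strand),
                 bin_profile(pos, 50000L, strand))
  }
})
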