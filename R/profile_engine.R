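#' Shift mapped-read 5' starts toward the fragment centre
#'
#' ChIP-seq reads tag fragment ends; with an average fragment length around
#' 200 bp, shifting plus-strand starts by `+shift` and minus-strand starts by
#' `-shift` (default 100 bp) re-centres the signal on the bound site. Shifted
#' positions are clipped at 0.
#'
#' @param reads a `read_starts` data.frame.
#' @param shift non-negative shift in bp (default 100).
#' @return a `read_starts` with shifted positions.
#' @export
shift_read_starts <- function(reads, shift = 100L) {
  if (shift < 0L) stop("shift must be >= 0")
  pos <- ifelse(reads$strand == "+", reads$pos + shift, reads$pos - shift)
  read_starts(reads$chrom, pmax(pos, 0L), reads$strand,
              mark = attr(reads, "mark"))
}

#' Bin read positions around an anchor into an oriented profile
#'
#' Counts positions in `bin_bp` intervals over the window
#' `[anchor - flank, anchor + flank)` (half-open bins; a position exactly at
#' the anchor falls in the first downstream bin). For minus-strand RTSSs the
#' vector is reversed so index 1..n runs upstream to downstream in transcript
#' orientation.
#'
#' @param positions integer vector of (already shifted) read positions on the
#'   RTSS's chromosome.
#' @param anchor anchor coordinate in bp.
#' @param strand RTSS strand, `+` or `-`.
#' @param bin_bp bin width in bp (default 100).
#' @param flank half-window in bp (default 3000); must be divisible by `bin_bp`.
#' @return numeric vector of `2 * flank / bin_bp` bin counts (60 by default).
#' @export
bin_profile <- function(positions, anchor, strand = "+", bin_bp = 100L,
                        flank = 3000L) {
  if (flank %% bin_bp != 0L) stop("flank must be divisible by bin_bp")
  nbins <- as.integer(2L * flank / bin_bp)
  off <- positions - (anchor - flank)
  off <- off[off >= 0L & off < 2L * flank]
  v <- tabulate(off %/% bin_bp + 1L, nbins = nbins)
  if (strand == "-") v <- rev(v)
  as.numeric(v)
}

#' Build the raw profile matrix for a catalog and one mark
#'
#' Applies the read-start shift, then bins reads around every RTSS anchor with
#' [bin_profile()]. Rows are RTSSs (named by id), columns are oriented bins.
#'
#' @param reads a `read_starts` data.frame for one mark (replicates pooled).
#' @param catalog an `rtss_catalog`.
#' @param shift read-start shift in bp (default 100; 0 disables).
#' @param bin_bp,flank binning geometry, see [bin_profile()].
#' @return numeric matrix, `nrow(catalog)` x `2 * flank / bin_bp`.
#' @export
profile_matrix <- function(reads, catalog, shift = 100L, bin_bp = 100L,
                           flank = 3000L) {
  if (shift > 0L) reads <- shift_read_starts(reads, shift)
  nbins <- as.integer(2L * flank / bin_bp)
  out <- matrix(0, nrow = nrow(catalog), ncol = nbins,
                dimnames = list(catalog$id, NULL))
  by_chrom <- split(reads$pos, reads$chrom)
  by_chrom <- lapply(by_chrom, sort)
  for (i in seq_len(nrow(catalog))) {
    pos <- by_chrom[[catalog$chrom[i]]]
    if (is.null(pos)) next
    a <- catalog$anchor[i]
    lo <- findInterval(a - flank - 0.5, pos) + 1L
    hi <- findInterval(a + flank - 0.5, pos)
    if (hi < lo) next
    out[i, ] <- bin_profile(pos[lo:hi], a, catalog$strand[i],
                            bin_bp = bin_bp, flank = flank)
  }
  out
}

#' Drop RTSS profiles with too little signal
#'
#' @param profiles raw profile matrix (rows RTSSs).
#' @param min_reads minimum total reads per profile (default 100); profiles
#'   with fewer than `min_reads` reads are removed.
#' @return the retained rows of `profiles`.
#' @export
filter_low_signal <- function(profiles, min_reads = 100) {
  profiles[rowSums(profiles) >= min_reads, , drop = FALSE]
}

# normalized 7-bin Gaussian kernel used for profile smoothing
gauss_kernel7 <- function(sigma = 1.5) {
  x <- -3:3
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

#' Smooth a raw 60-bin profile to 48 bins
#'
#' Convolution with a normalised 7-bin Gaussian kernel (sigma 1.5 bins,
#' truncated and renormalised), then 6 bins trimmed from each end, reducing the
#' measuring points from 60 to 48. All retained points have full kernel
#' support, so a constant profile stays constant.
#'
#' @param profile numeric vector of length 60 (or a matrix with 60 columns,
#'   smoothed row-wise).
#' @param sigma kernel standard deviation in bins (default 1.5).
#' @param trim bins removed from each end (default 6).
#' @return numeric vector of length 48 (or matrix with 48 columns).
#' @export
smooth_profile <- function(profile, sigma = 1.5, trim = 6L) {
  w <- gauss_kernel7(sigma)
  if (is.matrix(profile)) {
    if (ncol(profile) != 60L) stop("profile matrix must have 60 columns")
    out <- t(apply(profile, 1L, smooth_profile, sigma = sigma, trim = trim))
    rownames(out) <- rownames(profile)
    return(out)
  }
  if (length(profile) != 60L) stop("raw profile must have length 60")
  s <- stats::filter(profile, w, sides = 2)
  as.numeric(s[(trim + 1L):(length(profile) - trim)])
}

#' Average a set of equal-length profiles
#'
#' @param profiles numeric matrix (rows are member profiles) or list of
#'   equal-length vectors.
#' @return list with `values` (element-wise mean) and `n_members`.
#' @export
average_profiles <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    if (length(unique(lengths(profiles))) > 1L) {
      stop("profiles have mixed lengths")
    }
    profiles <- do.call(rbind, profiles)
  }
  if (nrow(profiles) < 1L) stop("average requires at least one profile")
  list(values = colMeans(profiles), n_members = nrow(profiles))
}

#' Bin a base-resolution signal track around an anchor
#'
#' Per-bin sum of per-bp signal over `[anchor - flank, anchor + flank)`, with
#' the same bin-edge and orientation rules as [bin_profile()]. Uncovered bases
#' contribute 0.
#'
#' @param track a `signal_track`.
#' @param anchor anchor coordinate in bp.
#' @param chrom chromosome of the anchor.
#' @param strand RTSS strand.
#' @param bin_bp,flank binning geometry.
#' @return numeric vector of `2 * flank / bin_bp` per-bin sums.
#' @export
signal_profile <- function(track, anchor, chrom, strand = "+", bin_bp = 100L,
                           flank = 3000L) {
  if (flank %% bin_bp != 0L) stop("flank must be divisible by bin_bp")
  nbins <- as.integer(2L * flank / bin_bp)
  v <- numeric(nbins)
  tr <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(tr)) {
    win_start <- anchor - flank
    bins <- IRanges::IRanges(start = win_start + (seq_len(nbins) - 1L) * bin_bp + 1L,
                             width = bin_bp)
    segs <- IRanges::IRanges(start = tr$start + 1L, end = tr$end)
    hits <- IRanges::findOverlaps(bins, segs)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      ov <- pmin(IRanges::end(bins)[qh], IRanges::end(segs)[sh]) -
        pmax(IRanges::start(bins)[qh], IRanges::start(segs)[sh]) + 1L
      contrib <- ov * tr$value[sh]
      acc <- rowsum(contrib, qh)
      v[as.integer(rownames(acc))] <- acc[, 1L]
    }
  }
  if (strand == "-") v <- rev(v)
  v
}

#' Build a signal-track profile matrix for a catalog
#'
#' @param track a `signal_track`.
#' @param catalog an `rtss_catalog`.
#' @param bin_bp,flank binning geometry.
#' @return numeric matrix, rows RTSSs (named by id).
#' @export
signal_profile_matrix <- function(track, catalog, bin_bp = 100L, flank = 3000L) {
  nbins <- as.integer(2L * flank / bin_bp)
  out <- matrix(0, nrow = nrow(catalog), ncol = nbins,
                dimnames = list(catalog$id, NULL))
  for (i in seq_len(nrow(catalog))) {
    out[i, ] <- signal_profile(track, catalog$anchor[i], catalog$chrom[i],
                               catalog$strand[i], bin_bp = bin_bp, flank = flank)
  }
  out
}
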