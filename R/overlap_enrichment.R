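#' Count RTSSs overlapping enrichment peaks
#'
#' An RTSS counts as overlapping when its interval, extended by `extension` bp
#' on each end (clipped at 0), intersects any peak. Half-open convention: an
#' exactly abutting peak does not overlap.
#'
#' @param rtss_set an `rtss_catalog` (or subset).
#' @param peaks peak data.frame (`chrom`, `start`, `end`).
#' @param extension extension in bp on each end (default 500).
#' @return list with `n_overlapping`, `fraction` and logical `hits` per RTSS.
#' @export
count_overlaps <- function(rtss_set, peaks, extension = 500L) {
  if (extension < 0L) stop("extension must be >= 0")
  n <- nrow(rtss_set)
  if (n == 0L) return(list(n_overlapping = 0L, fraction = NaN, hits = logical(0)))
  if (NROW(peaks) == 0L) {
    return(list(n_overlapping = 0L, fraction = 0,
                hits = setNames(rep(FALSE, n), rtss_set$id)))
  }
  ext <- data.frame(chrom = rtss_set$chrom,
                    start = pmax(rtss_set$start - extension, 0L),
                    end = rtss_set$end + extension)
  hits <- IRanges::overlapsAny(intervals_to_granges(ext),
                               intervals_to_granges(peaks),
                               ignore.strand = TRUE)
  list(n_overlapping = sum(hits), fraction = mean(hits),
       hits = setNames(hits, rtss_set$id))
}

#' Monte-Carlo permutation p-value for peak overlap
#'
#' Null model: each RTSS interval is uniformly repositioned within its own
#' chromosome (interval length and per-chromosome counts preserved). The
#' statistic is the number of overlapping RTSSs; the add-one estimator
#' `p = (1 + #\{perm >= observed\}) / (1 + n_perm)` gives a one-sided
#' enrichment p-value (`tail = "depletion"` flips the comparison).
#'
#' @param rtss_set an `rtss_catalog` (or subset).
#' @param peaks peak data.frame.
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @param extension overlap extension in bp (default 500).
#' @param n_perm number of permutations (default 100).
#' @param seed optional integer seed.
#' @param tail `"enrichment"` (default) or `"depletion"`.
#' @return list with `p_value`, `observed`, `perm_stats`.
#' @export
overlap_pvalue <- function(rtss_set, peaks, chrom_sizes, extension = 500L,
                           n_perm = 100L, seed = NULL,
                           tail = c("enrichment", "depletion")) {
  tail <- match.arg(tail)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  widths <- rtss_set$end - rtss_set$start
  csize <- chrom_sizes[rtss_set$chrom]
  if (any(is.na(csize))) stop("chromosome missing from chrom_sizes")
  if (any(widths > csize)) stop("RTSS interval longer than its chromosome")
  if (!is.null(seed)) set.seed(seed)

  observed <- count_overlaps(rtss_set, peaks, extension)$n_overlapping

  n <- nrow(rtss_set)
  # all permutations in one batch: uniform starts in [0, L - w]
  starts <- floor(runif(n * n_perm) * rep(csize - widths + 1L, n_perm))
  perm <- data.frame(chrom = rep(rtss_set$chrom, n_perm),
                     start = pmax(starts - extension, 0),
                     end = starts + rep(widths, n_perm) + extension)
  hits <- IRanges::overlapsAny(intervals_to_granges(perm),
                               intervals_to_granges(peaks),
                               ignore.strand = TRUE)
  perm_stats <- as.vector(rowsum(as.integer(hits),
                                 rep(seq_len(n_perm), each = n)))
  extreme <- if (tail == "enrichment") sum(perm_stats >= observed)
             else sum(perm_stats <= observed)
  list(p_value = (1 + extreme) / (1 + n_perm), observed = observed,
       perm_stats = perm_stats)
}

#' Overlap statistics per mark and RTSS class
#'
#' Convenience wrapper producing one [count_overlaps()] +
#' [overlap_pvalue()] row per (mark, class) combination.
#'
#' @param catalog an `rtss_catalog`.
#' @param classes named expression-class vector from [classify_expression()].
#' @param peak_sets named list of peak data.frames, one per mark.
#' @param chrom_sizes named chromosome lengths.
#' @param extension,n_perm,seed see [overlap_pvalue()].
#' @return data.frame with columns mark, rtss_class, n_rtss, n_overlapping,
#'   fraction, p_value.
#' @export
overlap_stats <- function(catalog, classes, peak_sets, chrom_sizes,
                          extension = 500L, n_perm = 100L, seed = NULL) {
  rows <- list()
  for (mark in names(peak_sets)) {
    for (cls in c("expressed", "repressed")) {
      sub <- catalog[classes[catalog$id] == cls, , drop = FALSE]
      if (!nrow(sub)) next
      ov <- count_overlaps(sub, peak_sets[[mark]], extension)
      pv <- overlap_pvalue(sub, peak_sets[[mark]], chrom_sizes,
                           extension = extension, n_perm = n_perm,
                           seed = if (is.null(seed)) NULL
                                  else derive_stage_seed(seed, paste(mark, cls)))
      rows[[length(rows) + 1L]] <- data.frame(
        mark = mark, rtss_class = cls, n_rtss = nrow(sub),
        n_overlapping = ov$n_overlapping, fraction = ov$fraction,
        p_value = pv$p_value
      )
    }
  }
  do.call(rbind, rows)
}
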