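#' Default chromatin-mark panel roles
#'
#' The twelve-mark ENCODE-style panel plus Pol II: ten marks traditionally
#' regarded as transcription-activating, two repressive marks, and Pol II kept
#' separate from the active pool.
#'
#' @return list with `active`, `repressive` and `polII` character vectors.
#' @export
default_mark_panel <- function() {
  list(
    active = c("DNaseHS", "H2AZ", "H3K4me1", "H3K4me2", "H3K4me3",
               "H3K27ac", "H3K9ac", "H3K36me3", "H3K79me2", "H4K20me1"),
    repressive = c("H3K27me3", "H3K9me3"),
    polII = "PolII"
  )
}

#' Selection thresholds for poised-RTSS detection
#'
#' @param pooled_min_reads minimum total pooled active-mark signal (strict >,
#'   default 1000).
#' @param min_corr_repressed minimum correlation to the average repressed
#'   profile (strict >, default 0.5).
#' @param max_p dependent-correlation p-value bound (inclusive, default 0.05).
#' @param per_mark_min_reads per-mark signal threshold for the per-mark
#'   procedure (strict >, default 100).
#' @param min_marks_passing marks that must pass in the per-mark procedure
#'   (default 3).
#' @param peak_extension bp extension used for the peak-overlap criterion
#'   (default 500).
#' @return a `poised_criteria` list.
#' @export
poised_criteria <- function(pooled_min_reads = 1000, min_corr_repressed = 0.5,
                            max_p = 0.05, per_mark_min_reads = 100,
                            min_marks_passing = 3L, peak_extension = 500L) {
  stopifnot(pooled_min_reads > 0, per_mark_min_reads > 0,
            max_p > 0, max_p < 1)
  structure(list(pooled_min_reads = pooled_min_reads,
                 min_corr_repressed = min_corr_repressed, max_p = max_p,
                 per_mark_min_reads = per_mark_min_reads,
                 min_marks_passing = min_marks_passing,
                 peak_extension = peak_extension),
            class = "poised_criteria")
}

#' Pool raw active-mark profiles around one RTSS
#'
#' Element-wise sum of the raw per-mark profiles over the active panel
#' (a missing mark contributes zeros).
#'
#' @param rtss_id RTSS id.
#' @param raw_profiles named list of raw profile matrices (one per mark, rows
#'   named by RTSS id).
#' @param active_marks character vector of active-mark names.
#' @return list with `profile` (pooled vector) and `total`.
#' @export
pool_active_profiles <- function(rtss_id, raw_profiles, active_marks) {
  stopifnot(length(active_marks) >= 1L)
  nbins <- ncol(raw_profiles[[1L]])
  pooled <- numeric(nbins)
  for (mark in active_marks) {
    m <- raw_profiles[[mark]]
    if (!is.null(m) && rtss_id %in% rownames(m)) pooled <- pooled + m[rtss_id, ]
  }
  list(profile = pooled, total = sum(pooled))
}

# pooled profiles for many ids at once (rows = ids)
pool_active_matrix <- function(ids, raw_profiles, active_marks) {
  nbins <- ncol(raw_profiles[[1L]])
  pooled <- matrix(0, nrow = length(ids), ncol = nbins,
                   dimnames = list(ids, NULL))
  for (mark in active_marks) {
    m <- raw_profiles[[mark]]
    if (is.null(m)) next
    present <- intersect(ids, rownames(m))
    pooled[present, ] <- pooled[present, ] + m[present, , drop = FALSE]
  }
  pooled
}

#' Test for comparing two dependent correlations sharing a variable
#'
#' Steiger's test in Williams' t form for `H0: rho_jk = rho_jh` against the
#' one-sided alternative `rho_jk > rho_jh`, where both correlations share
#' variable j (here the RTSS profile, correlated with the average repressed
#' and average expressed profiles k and h). With `rbar = (r_jk + r_jh)/2` and
#' `|R| = 1 - r_jk^2 - r_jh^2 - r_kh^2 + 2 r_jk r_jh r_kh`,
#' \deqn{t = (r_{jk} - r_{jh}) \sqrt{\frac{(n-1)(1+r_{kh})}
#'   {2\frac{n-1}{n-3}|R| + \bar r^2 (1-r_{kh})^3}}}
#' on `n - 3` degrees of freedom.
#'
#' @param r_jk correlation of the profile with the average repressed profile.
#' @param r_jh correlation of the profile with the average expressed profile.
#' @param r_kh correlation between the two average profiles.
#' @param n number of observations behind each correlation (profile bins).
#' @return list with `statistic`, `df` and one-sided `p_value`.
#' @export
dependent_corr_test <- function(r_jk, r_jh, r_kh, n) {
  if (n < 4L) stop("n must be >= 4")
  if (any(abs(c(r_jk, r_jh, r_kh)) > 1)) stop("correlations must be in [-1, 1]")
  detR <- 1 - r_jk^2 - r_jh^2 - r_kh^2 + 2 * r_jk * r_jh * r_kh
  detR <- max(detR, 0)
  rbar <- (r_jk + r_jh) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r_kh)^3
  tstat <- if (denom <= 0) {
    if (r_jk == r_jh) 0 else sign(r_jk - r_jh) * Inf
  } else {
    (r_jk - r_jh) * sqrt((n - 1) * (1 + r_kh) / denom)
  }
  list(statistic = tstat, df = n - 3L,
       p_value = stats::pt(tstat, df = n - 3L, lower.tail = FALSE))
}

# shared core: apply criteria (i)-(iv) to a set of candidate profiles
# given raw pooled matrix rows and reference average profiles
apply_poised_criteria <- function(pooled_raw, avg_repressed_raw,
                                  avg_expressed_raw, peak_hit, criteria,
                                  min_reads) {
  ids <- rownames(pooled_raw)
  smoothed <- smooth_profile(pooled_raw)
  avg_rep_s <- smooth_profile(avg_repressed_raw)
  avg_exp_s <- smooth_profile(avg_expressed_raw)
  r_kh <- safe_cor(avg_rep_s, avg_exp_s)
  nbins <- length(avg_rep_s)

  totals <- rowSums(pooled_raw)
  r_rep <- apply(smoothed, 1L, safe_cor, b = avg_rep_s)
  r_exp <- apply(smoothed, 1L, safe_cor, b = avg_exp_s)
  p <- vapply(seq_along(ids), function(i) {
    dependent_corr_test(r_rep[i], r_exp[i], r_kh, nbins)$p_value
  }, numeric(1))

  data.frame(
    rtss_id = ids,
    peak_overlap = peak_hit[ids],
    pooled_total = totals,
    r_repressed = r_rep,
    r_expressed = r_exp,
    p_value = p,
    pass_signal = totals > min_reads,
    pass_corr = r_rep > criteria$min_corr_repressed,
    pass_test = p <= criteria$max_p,
    row.names = NULL
  )
}

#' Select poised RTSSs by the pooled-profile procedure
#'
#' Candidates are repressed RTSSs overlapping at least one significant
#' enrichment peak (any mark, with the configured extension). A candidate is
#' selected when, on its pooled active-mark profile, (i) the peak overlap
#' holds, (ii) the total pooled signal exceeds `pooled_min_reads` (strict),
#' (iii) the correlation to the average pooled repressed profile exceeds
#' `min_corr_repressed` (strict), and (iv) that correlation is significantly
#' larger than the correlation to the average pooled expressed profile
#' (dependent-correlations test, `p <= max_p`). Reference averages are the
#' mean pooled profiles of peak-overlapping repressed and expressed RTSSs of
#' the same dataset; correlations are computed on smoothed profiles.
#'
#' @param repressed_ids,expressed_ids character vectors of RTSS ids.
#' @param raw_profiles named list of raw (60-bin) profile matrices per mark.
#' @param catalog an `rtss_catalog` covering the ids.
#' @param peak_sets named list of peak data.frames per mark.
#' @param active_marks active-mark names to pool.
#' @param criteria a [poised_criteria()] list.
#' @return a `poised_result`: list with `selected` ids and a `diagnostics`
#'   data.frame for all candidates.
#' @export
select_poised_pooled <- function(repressed_ids, expressed_ids, raw_profiles,
                                 catalog, peak_sets, active_marks,
                                 criteria = poised_criteria()) {
  peak_hit <- any_peak_overlap(catalog, peak_sets, criteria$peak_extension)
  cand <- repressed_ids[peak_hit[repressed_ids]]
  ref_exp <- expressed_ids[peak_hit[expressed_ids]]
  if (!length(cand)) {
    return(structure(list(selected = character(0),
                          diagnostics = data.frame()),
                     class = "poised_result"))
  }
  if (!length(ref_exp)) stop("no peak-overlapping expressed RTSSs for reference")

  pooled_rep <- pool_active_matrix(cand, raw_profiles, active_marks)
  pooled_exp <- pool_active_matrix(ref_exp, raw_profiles, active_marks)
  diag <- apply_poised_criteria(pooled_rep, colMeans(pooled_rep),
                                colMeans(pooled_exp), peak_hit, criteria,
                                criteria$pooled_min_reads)
  selected <- diag$rtss_id[diag$peak_overlap & diag$pass_signal &
                             diag$pass_corr & diag$pass_test]
  structure(list(selected = selected, diagnostics = diag,
                 procedure = "pooled"),
            class = "poised_result")
}

# logical: RTSS (extended) overlaps a peak of any mark
any_peak_overlap <- function(catalog, peak_sets, extension) {
  hit <- setNames(rep(FALSE, nrow(catalog)), catalog$id)
  for (peaks in peak_sets) {
    hit <- hit | count_overlaps(catalog, peaks, extension)$hits
  }
  hit
}

#' Select poised RTSSs by the per-mark procedure
#'
#' The pooled criteria applied to each active mark individually, with the
#' signal threshold lowered to `per_mark_min_reads`; an RTSS is selected when
#' it passes all criteria in at least `min_marks_passing` active marks. Peak
#' overlap is evaluated per mark.
#'
#' @inheritParams select_poised_pooled
#' @return a `poised_result` with per-mark pass counts in `diagnostics`.
#' @export
select_poised_per_mark <- function(repressed_ids, expressed_ids, raw_profiles,
                                   catalog, peak_sets, active_marks,
                                   criteria = poised_criteria()) {
  cat_by_id <- catalog[match(repressed_ids, catalog$id), , drop = FALSE]
  class(cat_by_id) <- c("rtss_catalog", "data.frame")
  n_pass <- setNames(integer(length(repressed_ids)), repressed_ids)
  per_mark <- list()
  for (mark in active_marks) {
    m <- raw_profiles[[mark]]
    peaks <- peak_sets[[mark]]
    if (is.null(m) || is.null(peaks)) next
    hit <- count_overlaps(cat_by_id, peaks, criteria$peak_extension)$hits
    exp_cat <- catalog[match(expressed_ids, catalog$id), , drop = FALSE]
    class(exp_cat) <- c("rtss_catalog", "data.frame")
    exp_hit <- count_overlaps(exp_cat, peaks, criteria$peak_extension)$hits
    cand <- repressed_ids[hit]
    ref_exp <- expressed_ids[exp_hit]
    if (!length(cand) || !length(ref_exp)) next
    raw_cand <- m[intersect(cand, rownames(m)), , drop = FALSE]
    if (!nrow(raw_cand)) next
    raw_ref <- m[intersect(ref_exp, rownames(m)), , drop = FALSE]
    diag <- apply_poised_criteria(raw_cand, colMeans(raw_cand),
                                  colMeans(raw_ref), hit, criteria,
                                  criteria$per_mark_min_reads)
    pass <- diag$rtss_id[diag$peak_overlap & diag$pass_signal &
                           diag$pass_corr & diag$pass_test]
    n_pass[pass] <- n_pass[pass] + 1L
    per_mark[[mark]] <- diag
  }
  selected <- names(n_pass)[n_pass >= criteria$min_marks_passing]
  structure(list(selected = selected,
                 diagnostics = data.frame(rtss_id = names(n_pass),
                                          n_marks_passing = as.integer(n_pass),
                                          row.names = NULL),
                 per_mark = per_mark, procedure = "per_mark"),
            class = "poised_result")
}

#' @export
print.poised_result <- function(x, ...) {
  cat("Poised-RTSS selection (", x$procedure, " procedure)\n", sep = "")
  cat("  candidates:", nrow(x$diagnostics), "| selected:",
      length(x$selected), "\n")
  invisible(x)
}

#' Compare two selected RTSS sets
#'
#' @param a,b character id vectors.
#' @return list with `frac_a` (`|a n b| / |a|`), `frac_b`, `jaccard`,
#'   `n_intersect`.
#' @export
compare_selections <- function(a, b) {
  i <- length(intersect(a, b))
  u <- length(union(a, b))
  list(frac_a = if (length(a)) i / length(a) else 0,
       frac_b = if (length(b)) i / length(b) else 0,
       jaccard = if (u) i / u else 0,
       n_intersect = i)
}

#' Average profiles of expressed / poised / repressed groups for one mark
#'
#' @param groups named list of disjoint RTSS id vectors (e.g. `expressed`,
#'   `poised`, `repressed`).
#' @param profile_mat profile matrix for the mark of interest (rows named).
#' @return named list of [average_profiles()] results.
#' @export
profile_comparison_report <- function(groups, profile_mat) {
  ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(ids)) stop("groups must be disjoint")
  lapply(groups, function(g) {
    if (!length(g)) stop("empty group")
    average_profiles(profile_mat[intersect(g, rownames(profile_mat)), ,
                                 drop = FALSE])
  })
}
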