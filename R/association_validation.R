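#' Mean pairwise expression correlation in windows around gene TSSs
#'
#' For each anchor TSS and half-width W, collects the member RTSSs whose
#' anchors lie within `[TSS - W, TSS + W]`, computes Pearson correlations
#' between their (transformed) expression vectors for all within-anchor pairs,
#' and reports the grand mean over pairs pooled across anchors. Default
#' half-widths follow the 0.05/0.2/0.5/1/5/10/50/150 kbp ladder.
#'
#' @param expr expression matrix (RTSS rownames, sample columns).
#' @param catalog an `rtss_catalog` giving RTSS anchors.
#' @param anchors data.frame with `chrom` and `tss` columns (gene TSS list).
#' @param rtss_subset optional character vector restricting membership
#'   (default: all RTSSs in `expr`).
#' @param half_widths numeric vector of half-window sizes in bp.
#' @param transform expression transform passed to [transform_expression()].
#' @return data.frame with `window_half_width`, `n_pairs`, `mean_pairwise_r`
#'   (NA when no pairs).
#' @export
window_intra_correlation <- function(expr, catalog, anchors,
                                     rtss_subset = NULL,
                                     half_widths = c(50, 200, 500, 1000, 5000,
                                                     10000, 50000, 150000),
                                     transform = "log_cpm") {
  stopifnot(all(half_widths > 0), !is.unsorted(half_widths))
  if (is.null(rtss_subset)) rtss_subset <- rownames(expr)
  members <- catalog[catalog$id %in% rtss_subset, , drop = FALSE]
  tx <- transform_expression(expr, transform)
  out <- lapply(half_widths, function(W) {
    pair_r <- numeric(0)
    for (a in seq_len(nrow(anchors))) {
      ids <- members$id[members$chrom == anchors$chrom[a] &
                          abs(members$anchor - anchors$tss[a]) <= W]
      if (length(ids) < 2L) next
      r <- suppressWarnings(cor(t(tx[ids, , drop = FALSE])))
      r[!is.finite(r)] <- 0
      pair_r <- c(pair_r, r[upper.tri(r)])
    }
    data.frame(window_half_width = W, n_pairs = length(pair_r),
               mean_pairwise_r = if (length(pair_r)) mean(pair_r) else NA_real_)
  })
  do.call(rbind, out)
}

#' Baseline: mean pairwise correlation among randomly drawn RTSSs
#'
#' All pairwise correlations among `n_sample` RTSSs drawn uniformly from the
#' global set.
#'
#' @param expr expression matrix.
#' @param n_sample number of RTSSs to draw (default 100).
#' @param seed optional integer seed.
#' @param transform expression transform.
#' @return list with `mean_r` and `n_pairs`.
#' @export
random_baseline_correlation <- function(expr, n_sample = 100L, seed = NULL,
                                        transform = "log_cpm") {
  if (nrow(expr) < n_sample) stop("catalog smaller than n_sample")
  if (!is.null(seed)) set.seed(seed)
  ids <- sample(rownames(expr), n_sample)
  tx <- transform_expression(expr[ids, , drop = FALSE], transform)
  r <- suppressWarnings(cor(t(tx)))
  r[!is.finite(r)] <- 0
  list(mean_r = mean(r[upper.tri(r)]), n_pairs = sum(upper.tri(r)))
}

#' Strand-aware promoter regions upstream of RTSSs
#'
#' The region `upstream_bp` immediately upstream of the RTSS:
#' `[start - upstream_bp, start)` for plus-strand, `[end, end + upstream_bp)`
#' for minus-strand RTSSs, clipped at chromosome bounds.
#'
#' @param catalog an `rtss_catalog` (or any data.frame with `chrom`, `start`,
#'   `end`, `strand` and `id`).
#' @param upstream_bp promoter length in bp (default 200).
#' @param chrom_sizes optional named chromosome lengths for right-clipping.
#' @return data.frame `id`, `chrom`, `start`, `end` (0-width rows dropped).
#' @export
promoter_regions <- function(catalog, upstream_bp = 200L, chrom_sizes = NULL) {
  if (upstream_bp <= 0L) stop("upstream_bp must be > 0")
  plus <- catalog$strand == "+"
  start <- ifelse(plus, pmax(catalog$start - upstream_bp, 0L), catalog$end)
  end <- ifelse(plus, catalog$start, catalog$end + upstream_bp)
  if (!is.null(chrom_sizes)) {
    end <- pmin(end, chrom_sizes[catalog$chrom])
  }
  out <- data.frame(id = catalog$id, chrom = catalog$chrom,
                    start = as.integer(start), end = as.integer(end))
  out[out$start < out$end, , drop = FALSE]
}

# per-promoter bp overlap with a set of intervals
promoter_overlap_bp <- function(promoters, track) {
  ov <- setNames(numeric(nrow(promoters)), promoters$id)
  if (!nrow(promoters) || !NROW(track)) return(ov)
  pg <- intervals_to_granges(promoters)
  tg <- IRanges::reduce(intervals_to_granges(track))
  hits <- GenomicRanges::findOverlaps(pg, tg, ignore.strand = TRUE)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    w <- pmin(GenomicRanges::end(pg)[qh], GenomicRanges::end(tg)[sh]) -
      pmax(GenomicRanges::start(pg)[qh], GenomicRanges::start(tg)[sh]) + 1L
    acc <- rowsum(w, qh)
    ov[as.integer(rownames(acc))] <- acc[, 1L]
  }
  ov
}

#' CpG-island enrichment of a promoter set
#'
#' Ratio of observed bp overlap with the CpG-island track to the overlap
#' expected from the background promoters' overlap fraction:
#' `expected = promoter_bp * (background overlap bp / background bp)`.
#'
#' @param promoters promoter data.frame from [promoter_regions()].
#' @param cpg_track CpG-island intervals (`chrom`, `start`, `end`).
#' @param background_promoters background promoter set (e.g. all promoters).
#' @return list with `observed_bp`, `expected_bp`, `ratio`.
#' @export
cpg_enrichment <- function(promoters, cpg_track, background_promoters) {
  if (!NROW(background_promoters)) stop("background promoter set is empty")
  obs <- sum(promoter_overlap_bp(promoters, cpg_track))
  bg_bp <- sum(background_promoters$end - background_promoters$start)
  bg_ov <- sum(promoter_overlap_bp(background_promoters, cpg_track))
  frac <- bg_ov / bg_bp
  expected <- sum(promoters$end - promoters$start) * frac
  if (expected == 0) stop("expected overlap is zero (background has no CpG overlap)")
  list(observed_bp = obs, expected_bp = expected, ratio = obs / expected)
}

#' Monte-Carlo case/control test for CpG-island overlap
#'
#' Statistic: case overlap fraction minus control overlap fraction, where a
#' set's overlap fraction is its total CpG bp overlap divided by its total
#' promoter bp. Case/control labels are permuted across the combined promoter
#' list preserving set sizes; one-sided add-one p-value for enrichment of the
#' case set.
#'
#' @param case_promoters,control_promoters promoter data.frames.
#' @param cpg_track CpG-island intervals.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @return list with `p_value`, `observed`, `perm_stats`.
#' @export
cpg_case_control_test <- function(case_promoters, control_promoters, cpg_track,
                                  n_perm = 1000L, seed = NULL) {
  if (!nrow(case_promoters) || !nrow(control_promoters)) {
    stop("case and control promoter sets must be nonempty")
  }
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  all_prom <- rbind(case_promoters, control_promoters)
  ov <- promoter_overlap_bp(all_prom, cpg_track)
  bp <- all_prom$end - all_prom$start
  n_case <- nrow(case_promoters)
  n <- nrow(all_prom)
  stat <- function(case_idx) {
    sum(ov[case_idx]) / sum(bp[case_idx]) -
      sum(ov[-case_idx]) / sum(bp[-case_idx])
  }
  observed <- stat(seq_len(n_case))
  perm_stats <- vapply(seq_len(n_perm),
                       function(i) stat(sample.int(n, n_case)), numeric(1))
  list(p_value = (1 + sum(perm_stats >= observed)) / (1 + n_perm),
       observed = observed, perm_stats = perm_stats)
}

#' PCA of a binary term-gene membership matrix
#'
#' Rows are clusters (samples), columns are genes (variables) with 0/1
#' membership in significant ontology terms. Columns are centred, not scaled.
#' Scores for the first two components are returned with a deterministic sign
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param m numeric 0/1 matrix with >= 2 rows and columns.
#' @return list with `scores` (rows x 2), `explained_variance` (length 2
#'   fractions).
#' @export
term_matrix_pca <- function(m) {
  if (nrow(m) < 2L || ncol(m) < 2L) stop("matrix must be at least 2 x 2")
  centered <- scale(m, center = TRUE, scale = FALSE)
  if (all(abs(centered) < 1e-12)) {
    return(list(scores = matrix(0, nrow(m), 2L,
                                dimnames = list(rownames(m), c("PC1", "PC2"))),
                explained_variance = c(0, 0)))
  }
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ncomp <- min(2L, ncol(p$rotation))
  scores <- matrix(0, nrow(m), 2L,
                   dimnames = list(rownames(m), c("PC1", "PC2")))
  ev <- c(0, 0)
  tot <- sum(p$sdev^2)
  for (c in seq_len(ncomp)) {
    load <- p$rotation[, c]
    s <- sign(load[which.max(abs(load))])
    if (s == 0) s <- 1
    scores[, c] <- p$x[, c] * s
    ev[c] <- p$sdev[c]^2 / tot
  }
  list(scores = scores, explained_variance = ev)
}

#' Filter an ontology term table by display rules
#'
#' Term tables exported from an external annotation service may carry
#' per-term statistics; when the columns are present, terms are kept only if
#' both p-values are <= `max_p` and the fold enrichment is >= `min_fold`, and
#' at most `top_n` terms per (cluster, category) are retained by binomial
#' p-value. Absent columns are not filtered on.
#'
#' @param terms data.frame with at least `cluster`, `term`, `gene` columns and
#'   optionally `category`, `binom_p`, `hyper_p`, `fold`.
#' @param max_p p-value cutoff (default 0.05).
#' @param min_fold fold-enrichment cutoff (default 2).
#' @param top_n terms retained per cluster/category (default 20).
#' @return the filtered data.frame.
#' @export
filter_term_table <- function(terms, max_p = 0.05, min_fold = 2, top_n = 20L) {
  keep <- rep(TRUE, nrow(terms))
  if ("binom_p" %in% names(terms)) keep <- keep & terms$binom_p <= max_p
  if ("hyper_p" %in% names(terms)) keep <- keep & terms$hyper_p <= max_p
  if ("fold" %in% names(terms)) keep <- keep & terms$fold >= min_fold
  terms <- terms[keep, , drop = FALSE]
  if ("binom_p" %in% names(terms)) {
    grp <- if ("category" %in% names(terms)) {
      paste(terms$cluster, terms$category)
    } else terms$cluster
    keep2 <- unlist(lapply(split(seq_len(nrow(terms)), grp), function(idx) {
      tt <- unique(terms$term[idx][order(terms$binom_p[idx])])
      idx[terms$term[idx] %in% head(tt, top_n)]
    }), use.names = FALSE)
    terms <- terms[sort(keep2), , drop = FALSE]
  }
  rownames(terms) <- NULL
  terms
}

#' Build the 0/1 cluster-by-gene matrix from a term table
#'
#' @param terms data.frame with `cluster` and `gene` columns (one row per
#'   term-gene association, typically after [filter_term_table()]).
#' @return binary matrix, rows clusters, columns genes.
#' @export
term_gene_matrix <- function(terms) {
  clusters <- sort(unique(terms$cluster))
  genes <- sort(unique(terms$gene))
  m <- matrix(0L, length(clusters), length(genes),
              dimnames = list(as.character(clusters), genes))
  m[cbind(match(terms$cluster, clusters), match(terms$gene, genes))] <- 1L
  m
}
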