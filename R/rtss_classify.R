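#' Classify RTSSs as expressed, repressed or intermediate
#'
#' In the focal sample, an RTSS with zero mapped CAGE tags is repressed; one
#' with at least `threshold` tags is expressed; anything in between is
#' intermediate and excluded from both downstream sets. Typical thresholds are
#' 5 tags, or 3 for a markedly shallower library; `scale_by_library` rescales
#' the threshold by library depth relative to 30e6 tags (rounded, minimum 1).
#'
#' @param expr expression matrix (RTSS rownames, sample colnames).
#' @param focal_sample column name of the focal sample.
#' @param threshold minimum tag count for "expressed" (default 5).
#' @param scale_by_library if TRUE, use
#'   `max(1, round(threshold * libsize / 30e6))`.
#' @return named character vector over RTSS ids with values
#'   `"expressed"`, `"repressed"`, `"intermediate"`.
#' @export
classify_expression <- function(expr, focal_sample, threshold = 5L,
                                scale_by_library = FALSE) {
  if (!focal_sample %in% colnames(expr)) {
    stop("focal sample not in expression matrix: ", focal_sample)
  }
  if (threshold < 1L) stop("threshold must be >= 1")
  if (scale_by_library) {
    threshold <- max(1L, round(threshold * sum(expr[, focal_sample]) / 30e6))
  }
  counts <- expr[, focal_sample]
  cls <- ifelse(counts == 0L, "repressed",
                ifelse(counts >= threshold, "expressed", "intermediate"))
  setNames(cls, rownames(expr))
}

#' Classify RTSSs by genomic location relative to gene annotations
#'
#' Exactly one class per RTSS under the precedence
#' annotated > proximal > intragenic > intergenic:
#' * annotated — the RTSS interval contains an annotated TSS base on the same
#'   strand;
#' * proximal — the RTSS anchor lies within `proximal_bp` of a same-strand
#'   annotated TSS (up- or downstream);
#' * intragenic — any overlap with any gene span, either strand;
#' * intergenic — none of the above.
#'
#' @param catalog an `rtss_catalog`.
#' @param genes gene annotation data.frame (see [gene_annotation()]).
#' @param proximal_bp proximity window in bp (default 150).
#' @return named character vector over RTSS ids.
#' @export
classify_location <- function(catalog, genes, proximal_bp = 150L) {
  n <- nrow(catalog)
  out <- setNames(rep("intergenic", n), catalog$id)
  if (n == 0L || nrow(genes) == 0L) return(out)

  tss_gr <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$tss + 1L, width = 1L),
                                   strand = genes$strand)
  rtss_gr <- catalog_to_granges(catalog, use_strand = TRUE)
  anchor_gr <- GenomicRanges::GRanges(catalog$chrom,
                                      IRanges::IRanges(catalog$anchor + 1L,
                                                       width = 1L),
                                      strand = catalog$strand)
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$txStart + 1L,
                                                     genes$txEnd))

  intragenic <- IRanges::overlapsAny(rtss_gr, gene_gr, ignore.strand = TRUE)
  prox_win <- GenomicRanges::resize(tss_gr, width = 2L * proximal_bp + 1L,
                                    fix = "center")
  proximal <- IRanges::overlapsAny(anchor_gr, prox_win, ignore.strand = FALSE)
  annotated <- IRanges::overlapsAny(rtss_gr, tss_gr, ignore.strand = FALSE)

  out[intragenic] <- "intragenic"
  out[proximal] <- "proximal"
  out[annotated] <- "annotated"
  out
}

#' Identify isolated RTSSs
#'
#' An RTSS is isolated when its edge-to-edge genomic distance to every other
#' RTSS (any strand, same chromosome) is at least `min_gap`; the bound is
#' inclusive, and the sole RTSS on a chromosome is isolated.
#'
#' @param catalog an `rtss_catalog`.
#' @param min_gap minimum distance in bp (default 2000).
#' @return character vector of isolated RTSS ids.
#' @export
find_isolated <- function(catalog, min_gap = 2000L) {
  if (nrow(catalog) == 0L) return(character(0))
  gr <- catalog_to_granges(catalog)
  hit <- GenomicRanges::distanceToNearest(gr, ignore.strand = TRUE)
  dist <- rep(Inf, nrow(catalog))
  dist[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  catalog$id[dist >= min_gap]
}

#' Remove RTSSs overlapping excludable (unmappable) regions
#'
#' Any base-pair overlap with any excludable interval removes the RTSS.
#'
#' @param catalog an `rtss_catalog`.
#' @param excludable data.frame of intervals (`chrom`, `start`, `end`).
#' @return the filtered catalog.
#' @export
filter_unmappable <- function(catalog, excludable) {
  if (nrow(catalog) == 0L || NROW(excludable) == 0L) return(catalog)
  hit <- IRanges::overlapsAny(catalog_to_granges(catalog),
                              intervals_to_granges(excludable),
                              ignore.strand = TRUE)
  out <- catalog[!hit, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rtss_catalog", "data.frame")
  out
}
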