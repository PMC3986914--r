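#' @import GenomicRanges
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors queryHits subjectHits width
#' @importFrom data.table fread fwrite data.table as.data.table :=
#' @importFrom stats cor pt rnbinom rnorm runif prcomp sd setNames
#' @importFrom utils head tail
NULL

# Pearson correlation with the convention that a constant vector has r = 0.
safe_cor <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 2L) stop("correlation requires length >= 2")
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

# Column-wise correlations between the rows of X (n x p) and rows of C (k x p),
# returning an n x k matrix; constant rows yield 0 rather than NA.
cor_rows <- function(X, C) {
  r <- suppressWarnings(cor(t(X), t(C)))
  r[!is.finite(r)] <- 0
  r
}

# 0-based half-open intervals -> GRanges (1-based closed internally)
intervals_to_granges <- function(df, use_strand = FALSE) {
  strand <- if (use_strand && "strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

catalog_to_granges <- function(catalog, use_strand = FALSE) {
  intervals_to_granges(catalog, use_strand = use_strand)
}

#' Transform an expression matrix for correlation analyses
#'
#' Tags-per-million normalisation per sample followed by `log(1 + x)`, or raw
#' counts unchanged. Correlation-based validation is run on the transformed
#' values by default; CAGE libraries differ in depth, so per-sample scaling
#' avoids library-size-driven correlation.
#'
#' @param counts numeric matrix, RTSSs in rows, samples in columns.
#' @param method `"log_cpm"` (default) or `"raw"`.
#' @return numeric matrix of the same dimensions.
#' @export
transform_expression <- function(counts, method = c("log_cpm", "raw")) {
  method <- match.arg(method)
  if (method == "raw") return(counts)
  libsize <- colSums(counts)
  libsize[libsize == 0] <- 1
  log1p(sweep(counts, 2, libsize, "/") * 1e6)
}

# deterministic, collision-resistant-enough stage seed derivation
#' Derive a per-stage random seed from a master seed
#'
#' Polynomial string hash of the stage name mixed with the master seed,
#' reduced modulo 2^31 - 1. Deterministic in both arguments.
#'
#' @param master_seed integer master seed.
#' @param stage_name character scalar naming the pipeline stage.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_stage_seed <- function(master_seed, stage_name) {
  stopifnot(is.character(stage_name), length(stage_name) == 1L)
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  for (code in utf8ToInt(stage_name)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}
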