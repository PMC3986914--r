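# Small deterministic builders used across test files.

tiny_catalog <- function(rows) {
  # rows: list of c(chrom, start, end, id, strand)
  df <- do.call(rbind.data.frame, lapply(rows, function(r) {
    data.frame(id = r[[4]], chrom = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), strand = r[[5]],
               stringsAsFactors = FALSE)
  }))
  rtss_catalog(df)
}

tiny_genes <- function(rows) {
  # rows: list of c(gene_id, chrom, strand, txStart, txEnd)
  gene_annotation(do.call(rbind.data.frame, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], chrom = r[[2]], strand = r[[3]],
               txStart = as.integer(r[[4]]), txEnd = as.integer(r[[5]]),
               stringsAsFactors = FALSE)
  })))
}

random_profiles <- function(n, p = 48, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(n * p), nrow = n)
  rownames(m) <- paste0("r", seq_len(n))
  m
}

# The shared default-scale analysis used by the planted-recovery and
# qualitative-profile tests; computed once per session.
.analysis_cache <- new.env(parent = emptyenv())

default_analysis <- function() {
  if (!exists("res", envir = .analysis_cache)) {
    sim <- simulate_dataset(seed = 1)
    ecls <- classify_expression(sim$expr, "s1")
    expressed <- sim$catalog$id[ecls == "expressed"]
    repressed <- sim$catalog$id[ecls == "repressed"]
    marks <- c(sim$panel$active, sim$panel$polII)
    raw <- lapply(sim$reads[marks], profile_matrix, catalog = sim$catalog)
    mark_data <- lapply(sim$panel$active, function(mark) {
      totals <- rowSums(raw[[mark]])
      keep <- intersect(expressed, names(totals)[totals >= 100])
      sm <- smooth_profile(raw[[mark]])
      sp <- kmeans_shapes(sm[keep, , drop = FALSE], k = 5, npass = 200,
                          seed = derive_stage_seed(1, mark), mark = mark)
      list(smoothed = sm, totals = totals, subprofiles = sp)
    })
    names(mark_data) <- sim$panel$active
    meta_mat <- build_meta_matrix(mark_data, expressed)
    mc <- metacluster(meta_mat, k = 10, npass = 1000,
                      seed = derive_stage_seed(1, "metacluster"))
    pooled <- select_poised_pooled(repressed, expressed, raw, sim$catalog,
                                   sim$peaks, sim$panel$active)
    per_mark <- select_poised_per_mark(repressed, expressed, raw, sim$catalog,
                                       sim$peaks, sim$panel$active)
    assign("res", list(sim = sim, expressed = expressed,
                       repressed = repressed, raw = raw,
                       mark_data = mark_data, metaclusters = mc,
                       poised_pooled = pooled, poised_per_mark = per_mark),
           envir = .analysis_cache)
  }
  get("res", envir = .analysis_cache)
}
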