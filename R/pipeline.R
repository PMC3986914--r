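#' Pipeline configuration with study-condition defaults
#'
#' Flat, typed configuration for [run_pipeline()]. Every analysis threshold
#' defaults to its reference value: expression threshold 5 tags, 500 bp
#' overlap extension, 2 kbp isolation gap, 100-read profile filter, level-1
#' k = 5 with 200 passes, level-2 k = 10 with 1000 passes, pooled poised
#' threshold 1000 (per-mark 100), correlation > 0.5, p <= 0.05, >= 3 marks,
#' the 0.05-150 kbp window ladder and 100/1000 permutations. Unknown keys are
#' rejected.
#'
#' @param ... overrides for any default listed above.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    threshold = 5L, focal_sample = NULL, proximal_bp = 150L,
    min_gap = 2000L, extension = 500L, n_perm_overlap = 100L,
    shift = 100L, bin_bp = 100L, flank = 3000L, min_reads = 100,
    kernel_sigma = 1.5, k1 = 5L, npass1 = 200L, k2 = 10L, npass2 = 1000L,
    pooled_min = 1000, corr_min = 0.5, p_max = 0.05, per_mark_min = 100,
    min_marks = 3L,
    windows = c(50, 200, 500, 1000, 5000, 10000, 50000, 150000),
    n_perm_cpg = 1000L, n_random_rtss = 100L, promoter_bp = 200L,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, overrides)
  class(cfg) <- "pipeline_config"
  cfg
}

# write a TSV with a provenance header
write_stage_tsv <- function(df, path, config, stage) {
  hdr <- c(
    paste0("# chromtss stage: ", stage),
    paste0("# seed: ", config$seed),
    paste0("# config: ",
           paste(names(unclass(config)), vapply(unclass(config), function(v)
             paste(format(v), collapse = ","), ""), sep = "=",
             collapse = "; "))
  )
  writeLines(hdr, path)
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       append = TRUE)
  )
  invisible(path)
}

#' Run the full analysis pipeline on a dataset
#'
#' Executes the stages in dependency order — classify, overlap, profiles,
#' cluster, metacluster, poised, validate — on either a `tss_simulation` or
#' an equivalently shaped list of loaded inputs, writing per-stage TSV outputs
#' with provenance headers into `outdir`. Reruns with the same data and
#' config are deterministic.
#'
#' @param data a `tss_simulation` (or list with `catalog`, `expr`, `reads`,
#'   `peaks`, `genome`, `panel`).
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing).
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(data, config = pipeline_config(), outdir) {
  if (missing(outdir)) stop("outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  catalog <- data$catalog
  expr <- data$expr
  panel <- data$panel
  marks <- c(panel$active, panel$polII)
  focal <- if (is.null(config$focal_sample)) colnames(expr)[1L]
           else config$focal_sample
  res <- list()

  # classify
  ecls <- classify_expression(expr, focal, threshold = config$threshold)
  lcls <- classify_location(catalog, data$genome$genes,
                            proximal_bp = config$proximal_bp)
  isolated <- find_isolated(catalog, min_gap = config$min_gap)
  res$classify <- data.frame(rtss_id = catalog$id,
                             expression_class = ecls[catalog$id],
                             location_class = lcls[catalog$id],
                             isolated = catalog$id %in% isolated)
  write_stage_tsv(res$classify, file.path(outdir, "classify.tsv"), config,
                  "classify")
  message("classify: ", sum(ecls == "expressed"), " expressed, ",
          sum(ecls == "repressed"), " repressed, ",
          sum(ecls == "intermediate"), " intermediate; ",
          length(isolated), " isolated")

  # overlap enrichment
  res$overlap <- overlap_stats(catalog, ecls, data$peaks,
                               data$genome$chrom_sizes,
                               extension = config$extension,
                               n_perm = config$n_perm_overlap,
                               seed = derive_stage_seed(config$seed, "overlap"))
  write_stage_tsv(res$overlap, file.path(outdir, "overlap.tsv"), config,
                  "overlap")

  # profiles
  expressed_ids <- catalog$id[ecls[catalog$id] == "expressed"]
  repressed_ids <- catalog$id[ecls[catalog$id] == "repressed"]
  raw <- lapply(data$reads[marks], profile_matrix, catalog = catalog,
                shift = config$shift, bin_bp = config$bin_bp,
                flank = config$flank)
  res$profiles <- raw
  smoothed <- lapply(raw, smooth_profile, sigma = config$kernel_sigma)
  for (mark in marks) {
    write_stage_tsv(data.frame(rtss_id = rownames(raw[[mark]]),
                               round(raw[[mark]], 4), check.names = FALSE),
                    file.path(outdir, paste0("profiles_", mark, ".tsv")),
                    config, "profiles")
  }
  message("profiles: ", length(marks), " marks x ", nrow(catalog), " RTSSs")

  # level-1 clustering per active mark
  mark_data <- list()
  for (mark in panel$active) {
    totals <- rowSums(raw[[mark]])
    keep <- intersect(expressed_ids,
                      rownames(raw[[mark]])[totals >= config$min_reads])
    sp <- kmeans_shapes(smoothed[[mark]][keep, , drop = FALSE], k = config$k1,
                        npass = config$npass1,
                        seed = derive_stage_seed(config$seed,
                                                 paste0("cluster_", mark)),
                        mark = mark)
    mark_data[[mark]] <- list(smoothed = smoothed[[mark]], totals = totals,
                              subprofiles = sp)
    write_stage_tsv(data.frame(subprofile = seq_len(config$k1),
                               round(sp$subprofiles, 5)),
                    file.path(outdir, paste0("subprofiles_", mark, ".tsv")),
                    config, "cluster")
  }
  res$mark_data <- mark_data

  # level-2 metaclustering
  meta_mat <- build_meta_matrix(mark_data, expressed_ids,
                                min_signal = config$min_reads)
  res$metacluster <- metacluster(meta_mat, k = config$k2,
                                 npass = config$npass2,
                                 seed = derive_stage_seed(config$seed,
                                                          "metacluster"))
  write_stage_tsv(data.frame(rtss_id = names(res$metacluster$assignments),
                             metacluster = res$metacluster$assignments),
                  file.path(outdir, "metaclusters.tsv"), config, "metacluster")
  message("metacluster: ", ncol(meta_mat), " features, sizes ",
          paste(res$metacluster$sizes, collapse = ","))

  # poised selection
  crit <- poised_criteria(pooled_min_reads = config$pooled_min,
                          min_corr_repressed = config$corr_min,
                          max_p = config$p_max,
                          per_mark_min_reads = config$per_mark_min,
                          min_marks_passing = config$min_marks,
                          peak_extension = config$extension)
  res$poised_pooled <- select_poised_pooled(repressed_ids, expressed_ids, raw,
                                            catalog, data$peaks, panel$active,
                                            criteria = crit)
  res$poised_per_mark <- select_poised_per_mark(repressed_ids, expressed_ids,
                                                raw, catalog, data$peaks,
                                                panel$active, criteria = crit)
  write_stage_tsv(data.frame(rtss_id = res$poised_pooled$selected),
                  file.path(outdir, "poised.tsv"), config, "poised")
  message("poised: pooled ", length(res$poised_pooled$selected),
          ", per-mark ", length(res$poised_per_mark$selected))

  # validation: window correlations vs metacluster subsets
  anchors <- data.frame(chrom = data$genome$genes$chrom,
                        tss = data$genome$genes$tss)
  res$validate_all <- window_intra_correlation(expr, catalog, anchors,
                                               half_widths = config$windows)
  biggest <- which.max(res$metacluster$sizes)
  members <- names(res$metacluster$assignments)[
    res$metacluster$assignments == biggest]
  res$validate_cluster <- window_intra_correlation(expr, catalog, anchors,
                                                   rtss_subset = members,
                                                   half_widths = config$windows)
  res$random_baseline <- random_baseline_correlation(
    expr, n_sample = min(config$n_random_rtss, nrow(expr)),
    seed = derive_stage_seed(config$seed, "baseline"))
  write_stage_tsv(rbind(cbind(group = "all", res$validate_all),
                        cbind(group = "cluster", res$validate_cluster)),
                  file.path(outdir, "window_correlation.tsv"), config,
                  "validate")
  invisible(res)
}
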