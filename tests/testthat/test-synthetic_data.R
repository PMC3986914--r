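test_that("shape templates are normalised and mutually consistent", {
  shapes <- builtin_shape_library()
  expect_gte(length(shapes), 5L)
  for (s in shapes) {
    expect_length(s$values, 60L)
    expect_true(all(s$values >= 0))
    expect_equal(sum(s$values), 1)
  }
  # ramps mirror each other; the dip template dips at the centre
  expect_equal(shapes$upstream_ramp$values, rev(shapes$downstream_ramp$values))
  dip <- shapes$dip$values
  expect_lt(mean(dip[30:31]), mean(dip[c(25:26, 35:36)]))
  nodip <- shapes$nodip$values
  expect_gt(mean(nodip[30:31]), mean(nodip[c(25:26, 35:36)]))
})

test_that("archetype matrices avoid the central-peak shape and stay distinct", {
  arch <- metacluster_archetypes(paste0("m", 1:6), 10)
  expect_equal(dim(arch), c(10L, 6L))
  expect_true(all(arch %in% c(1L, 3L, 4L)))
  H <- as.matrix(dist(arch, method = "manhattan"))  # 0 only on the diagonal
  expect_true(all(H[upper.tri(H)] > 0))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_gte(sum(arch[i, ] != arch[j, ]), 3L)
  }
})

test_that("genome generation is reproducible with non-overlapping genes", {
  g1 <- generate_genome(2, 6e6, 50, seed = 11)
  g2 <- generate_genome(2, 6e6, 50, seed = 11)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$genes), 50L)
  for (chrom in names(g1$chrom_sizes)) {
    gg <- g1$genes[g1$genes$chrom == chrom, ]
    if (nrow(gg) < 2) next
    gg <- gg[order(gg$txStart), ]
    expect_true(all(gg$txStart[-1] >= gg$txEnd[-nrow(gg)]))
  }
  empty <- generate_genome(1, 1e6, 0, seed = 1)
  expect_equal(nrow(empty$genes), 0L)
})

test_that("planted truth respects its structural invariants", {
  sim <- simulate_dataset(n_rtss = 400, S = 10, n_genes = 60,
                          chrom_length = 8e6, seed = 2)
  tr <- sim$truth
  # poised => repressed; metacluster label => expressed
  expect_true(all(tr$expression_class[tr$poised] == "repressed"))
  expect_true(all(tr$expression_class[!is.na(tr$metacluster)] == "expressed"))
  expect_true(all(is.na(tr$metacluster[tr$expression_class != "expressed"])))
  # planted proportions match the requested fractions within sampling error
  frac <- table(tr$expression_class)[rownames(default_class_fractions())] / 400
  expect_lt(max(abs(as.vector(frac) - rowSums(default_class_fractions()))),
            0.08)
  # poised bookkeeping: requested fraction of repressed
  expect_equal(sum(tr$poised),
               round(0.1 * sum(tr$expression_class == "repressed")))
})

test_that("the generator is byte-deterministic for a fixed seed", {
  s1 <- simulate_dataset(n_rtss = 150, S = 6, n_genes = 30,
                         chrom_length = 6e6, seed = 99)
  s2 <- simulate_dataset(n_rtss = 150, S = 6, n_genes = 30,
                         chrom_length = 6e6, seed = 99)
  expect_identical(s1$catalog, s2$catalog)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$reads, s2$reads)
  s3 <- simulate_dataset(n_rtss = 150, S = 6, n_genes = 30,
                         chrom_length = 6e6, seed = 100)
  expect_false(identical(s1$expr, s3$expr))
})

test_that("an all-repressed-intergenic world has zero focal counts", {
  cf <- default_class_fractions() * 0
  cf["repressed", "intergenic"] <- 1
  genome <- generate_genome(1, 6e6, 20, seed = 5)
  out <- generate_rtss_set(genome, n_rtss = 80, class_fractions = cf,
                           S = 5, seed = 5)
  expect_true(all(out$expr[, 1] == 0))
  expect_true(all(out$truth$location_class == "intergenic"))
  expect_error(generate_rtss_set(genome, 10, S = 1), "S must be")
})

test_that("zero neighbourhood correlation gives near-zero expression correlation", {
  genome <- generate_genome(1, 10e6, 40, seed = 6)
  out <- generate_rtss_set(genome, n_rtss = 150, S = 200,
                           neighborhood_sd = 0, cluster_sd = 0, seed = 6)
  r <- random_baseline_correlation(out$expr, n_sample = 100, seed = 1)
  expect_lt(abs(r$mean_r), 0.05)
})

test_that("noise-free reads reproduce the planted templates after profiling", {
  sim <- simulate_dataset(n_rtss = 200, S = 5, n_genes = 50,
                          chrom_length = 10e6, depth = 1000L,
                          poised_depth = 1000L, noise_rate = 0, seed = 13)
  shapes <- builtin_shape_library()
  mark <- sim$panel$active[1]
  raw <- profile_matrix(sim$reads[[mark]], sim$catalog)
  expr_idx <- which(sim$truth$expression_class == "expressed")
  tmpl <- sim$archetypes[sim$truth$metacluster[expr_idx], 1]
  for (tt in unique(tmpl)) {
    avg <- colMeans(raw[expr_idx[tmpl == tt], , drop = FALSE])
    tv <- shapes[[tt]]$values
    cosine <- sum(avg * tv) / sqrt(sum(avg^2) * sum(tv^2))
    expect_gt(cosine, 0.95)
  }
  # depth 0 leaves only background reads
  none <- simulate_dataset(n_rtss = 50, S = 5, n_genes = 20,
                           chrom_length = 6e6, depth = 0L, poised_depth = 0L,
                           polII_depth = 0L, polII_depth_poised = 0L,
                           noise_rate = 2, seed = 14)
  n_bg <- nrow(none$reads[[none$panel$active[1]]])
  expected_bg <- 2 * 2 * 6e3     # noise_rate * genome kbp
  expect_lt(abs(n_bg - expected_bg) / expected_bg, 0.1)
})

test_that("the nucleosome track encodes dip vs retained-nucleosome footprints", {
  sim <- simulate_dataset(n_rtss = 300, S = 5, n_genes = 60,
                          chrom_length = 8e6, seed = 21)
  nuc <- sim$nucleosome
  expect_s3_class(nuc, "signal_track")
  expr_ids <- sim$truth$rtss_id[sim$truth$expression_class == "expressed"]
  poised_ids <- sim$truth$rtss_id[sim$truth$poised]
  pm <- signal_profile_matrix(nuc, sim$catalog[sim$catalog$id %in% poised_ids, ])
  em <- signal_profile_matrix(nuc, sim$catalog[sim$catalog$id %in% expr_ids, ])
  pavg <- colMeans(pm); eavg <- colMeans(em)
  expect_gt(mean(pavg[30:31]), mean(pavg[c(25:26, 35:36)]))  # central peak
  expect_lt(mean(eavg[30:31]), mean(eavg[c(25:26, 35:36)]))  # central dip
})
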