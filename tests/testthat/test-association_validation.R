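test_that("window intra-correlation pools pairs across anchors", {
  cat <- tiny_catalog(list(c("chr1", 990, 1010, "a", "+"),
                           c("chr1", 1490, 1510, "b", "+"),
                           c("chr1", 90000, 90020, "c", "-")))
  expr <- rbind(a = c(1L, 5L, 9L, 2L), b = c(2L, 10L, 18L, 4L),
                c = c(9L, 1L, 0L, 7L))
  colnames(expr) <- paste0("s", 1:4)
  anchors <- data.frame(chrom = "chr1", tss = 1000L)
  rep <- window_intra_correlation(expr, cat, anchors,
                                  half_widths = c(100, 1000),
                                  transform = "raw")
  # 100 bp window holds only RTSS a -> no pairs
  expect_equal(rep$n_pairs, c(0L, 1L))
  expect_true(is.na(rep$mean_pairwise_r[1]))
  # a and b have proportional raw expression -> r = 1
  expect_equal(rep$mean_pairwise_r[2], 1)

  # the default window ladder
  dflt <- window_intra_correlation(expr, cat, anchors, transform = "raw")
  expect_equal(dflt$window_half_width,
               c(50, 200, 500, 1000, 5000, 10000, 50000, 150000))
})

test_that("random-baseline correlation is near zero for independent rows", {
  set.seed(17)
  expr <- matrix(rnbinom(300 * 200, mu = 20, size = 5), nrow = 300,
                 dimnames = list(paste0("r", 1:300), paste0("s", 1:200)))
  base <- random_baseline_correlation(expr, n_sample = 100, seed = 3)
  expect_equal(base$n_pairs, choose(100, 2))
  expect_lt(abs(base$mean_r), 0.05)
  expect_error(random_baseline_correlation(expr[1:50, ], n_sample = 100),
               "smaller")
  # identical rows correlate perfectly
  same <- matrix(rep(c(1L, 8L, 3L, 9L), each = 5), nrow = 5,
                 dimnames = list(paste0("r", 1:5), paste0("s", 1:4)))
  expect_equal(random_baseline_correlation(same, n_sample = 5,
                                           transform = "raw")$mean_r, 1)
})

test_that("promoters are the strand-aware 200 bp upstream regions", {
  cat <- tiny_catalog(list(c("chr1", 1000, 1100, "p", "+"),
                           c("chr1", 1000, 1100, "m", "-"),
                           c("chr1", 50, 120, "edge", "+")))
  prom <- promoter_regions(cat, upstream_bp = 200L)
  expect_equal(unlist(prom[prom$id == "p", c("start", "end")],
                      use.names = FALSE), c(800L, 1000L))
  expect_equal(unlist(prom[prom$id == "m", c("start", "end")],
                      use.names = FALSE), c(1100L, 1300L))
  expect_equal(prom[prom$id == "edge", "start"], 0L)  # clipped at chrom start
  expect_error(promoter_regions(cat, 0L), "> 0")
})

test_that("CpG enrichment is the observed / expected overlap ratio", {
  bg <- data.frame(id = paste0("b", 1:4), chrom = "chr1",
                   start = c(0L, 1000L, 2000L, 3000L),
                   end = c(200L, 1200L, 2200L, 3200L))
  cpg <- data.frame(chrom = "chr1", start = 0L, end = 1200L)
  # background overlap fraction: 400 / 800 = 0.5
  expect_equal(cpg_enrichment(bg, cpg, bg)$ratio, 1)   # set == background
  inside <- bg[1:2, ]                                  # fully inside islands
  expect_equal(cpg_enrichment(inside, cpg, bg)$ratio, 1 / 0.5)
  outside <- bg[3:4, ]
  expect_equal(cpg_enrichment(outside, cpg, bg)$ratio, 0)
  expect_error(cpg_enrichment(bg, cpg[0, ], bg), "zero")

  # union of disjoint sets lies between the sets' ratios (weighted mean)
  u <- cpg_enrichment(bg[1:3, ], cpg, bg)$ratio
  r1 <- cpg_enrichment(bg[1:2, ], cpg, bg)$ratio
  r2 <- cpg_enrichment(bg[3, , drop = FALSE], cpg, bg)$ratio
  expect_gte(u, min(r1, r2)); expect_lte(u, max(r1, r2))
})

test_that("the CpG case/control permutation test detects extreme separation", {
  case <- data.frame(id = paste0("c", 1:30), chrom = "chr1",
                     start = seq(0L, by = 1000L, length.out = 30),
                     end = seq(200L, by = 1000L, length.out = 30))
  control <- data.frame(id = paste0("k", 1:30), chrom = "chr1",
                        start = seq(100000L, by = 1000L, length.out = 30),
                        end = seq(100200L, by = 1000L, length.out = 30))
  cpg <- data.frame(chrom = "chr1", start = 0L, end = 50000L)
  res <- cpg_case_control_test(case, control, cpg, n_perm = 199L, seed = 1)
  expect_equal(res$p_value, 1 / 200)
  expect_error(cpg_case_control_test(case, control, cpg, n_perm = 0L),
               "n_perm")
  expect_error(cpg_case_control_test(case[0, ], control, cpg), "nonempty")
})

test_that("term-matrix PCA matches a small eigendecomposition oracle", {
  set.seed(23)
  m <- matrix(rbinom(16, 1, 0.5), nrow = 4,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:4)))
  res <- term_matrix_pca(m)
  # independent oracle: eigendecomposition of the covariance matrix
  cen <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(cen))
  oracle <- cen %*% eig$vectors[, 1:2]
  expect_equal(abs(unname(res$scores)), abs(unname(oracle)),
               tolerance = 1e-8)
  expect_equal(res$explained_variance,
               (eig$values / sum(eig$values))[1:2], tolerance = 1e-8)

  # deterministic sign and row-order invariance
  perm <- sample(4)
  res2 <- term_matrix_pca(m[perm, ])
  expect_equal(res2$scores[rownames(m), ], res$scores)

  # block-structured rows separate along PC1 with opposite signs
  blk <- rbind(a1 = c(1, 1, 1, 0, 0, 0), a2 = c(1, 1, 0, 0, 0, 0),
               b1 = c(0, 0, 0, 1, 1, 1), b2 = c(0, 0, 1, 1, 1, 0))
  sc <- term_matrix_pca(blk)$scores[, 1]
  expect_true(prod(sc[c("a1", "b1")]) < 0)
  expect_true(sign(sc[["a1"]]) == sign(sc[["a2"]]))

  # degenerate inputs
  expect_equal(term_matrix_pca(matrix(1, 3, 3))$explained_variance, c(0, 0))
  expect_error(term_matrix_pca(matrix(1, 1, 5)), "at least")
})

test_that("term tables filter on display rules and build 0/1 matrices", {
  terms <- data.frame(
    cluster = c(1, 1, 1, 2), term = c("t1", "t1", "t2", "t3"),
    gene = c("gA", "gB", "gC", "gA"),
    binom_p = c(0.01, 0.01, 0.2, 0.04),
    hyper_p = c(0.02, 0.02, 0.01, 0.04), fold = c(3, 3, 5, 2.5)
  )
  kept <- filter_term_table(terms)
  expect_setequal(kept$term, c("t1", "t3"))   # t2 fails the binomial cutoff
  m <- term_gene_matrix(kept)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["1", "gA"], 1L)
  expect_equal(m["2", "gB"], 0L)
})

test_that("co-clustered RTSSs out-correlate the window background", {
  res <- default_analysis()
  sim <- res$sim
  anchors <- data.frame(chrom = sim$genome$genes$chrom,
                        tss = sim$genome$genes$tss)
  mc <- res$metaclusters
  biggest <- which.max(mc$sizes)
  members <- names(mc$assignments)[mc$assignments == biggest]
  all_rep <- window_intra_correlation(sim$expr, sim$catalog, anchors,
                                      half_widths = c(5000, 10000, 50000))
  cl_rep <- window_intra_correlation(sim$expr, sim$catalog, anchors,
                                     rtss_subset = members,
                                     half_widths = c(5000, 10000, 50000))
  ok <- cl_rep$n_pairs >= 5
  expect_true(any(ok))
  expect_true(all(cl_rep$mean_pairwise_r[ok] > all_rep$mean_pairwise_r[ok]))
})
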