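test_that("median-of-ratios size factors match the formula", {
  set.seed(2)
  c1 <- matrix(rpois(40, 100), 20, 2,
               dimnames = list(sprintf("g%02d", 1:20), c("A", "B")))
  c1[, 2] <- 2 * c1[, 1]
  sf <- size_factors_median_ratio(c1)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  # single sample: factor 1
  expect_equal(unname(size_factors_median_ratio(c1[, 1, drop = FALSE])), 1)
  # random matrix against a direct one-line transcription
  m <- matrix(rpois(300, 50) + 1, 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("S%d", 1:6)))
  ref <- exp(rowMeans(log(m)))
  oracle <- apply(m / ref, 2, median)
  expect_equal(size_factors_median_ratio(m), oracle)
  # on duplicated profiles the factors recover the per-sample scalings,
  # normalised to unit geometric mean
  scales <- c(1, 2, 4)
  dup <- outer(c1[, 1], scales)
  colnames(dup) <- paste0("D", 1:3)
  sfd <- size_factors_median_ratio(dup)
  expect_equal(unname(sfd), scales / exp(mean(log(scales))))
  expect_error(size_factors_median_ratio(matrix(c(0, 1, 1, 0), 2, 2)),
               "nonzero")
})

test_that("NB likelihood-ratio test: degenerate, reordering, and antisymmetry", {
  counts <- rbind(constant = rep(50L, 8),
                  varying = c(10L, 20L, 15L, 12L, 80L, 90L, 85L, 88L),
                  zero = rep(0L, 8))
  colnames(counts) <- sprintf("S%d", 1:8)
  grp <- factor(rep(c("F", "E"), each = 4), levels = c("F", "E"))
  de <- nb_lrt_de(counts, size_factors = rep(1, 8), full = grp)
  const <- de[de$gene == "constant", ]
  expect_equal(const$stat, 0, tolerance = 1e-8)
  expect_equal(const$pvalue, 1, tolerance = 1e-6)
  expect_true(de$excluded[de$gene == "zero"])
  expect_true(is.na(de$stat[de$gene == "zero"]))
  expect_equal(unique(de$df), 1)
  # invariance to sample order
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  de_perm <- nb_lrt_de(counts[, perm], rep(1, 8), grp[perm])
  expect_equal(de_perm$stat, de$stat, tolerance = 1e-6)
  # group swap negates the fold change
  de_swap <- nb_lrt_de(counts, rep(1, 8), relevel(grp, "E"))
  expect_equal(de_swap$log2fc, -de$log2fc, tolerance = 1e-12)
})

test_that("implanted fold changes are recovered at the simulated sample sizes", {
  cfg <- simulation_config(seed = 1)
  sim <- simulate_methylation_cohort(cfg)
  ex <- simulate_expression_cohort(cfg, sim$truth$samples)
  lab <- sim$truth$samples
  tum <- lab$sample_id[lab$cluster %in% c("F", "E1", "E2")]
  grp <- factor(ifelse(lab$cluster[match(tum, lab$sample_id)] == "F", "F", "E"),
                levels = c("F", "E"))   # 12 F vs 24 E
  de <- nb_lrt_de(ex$counts[, tum], full = grp)
  tr <- ex$truth[match(de$gene, ex$truth$gene), ]
  # strong implanted genes (|log2FC| = 3) reach adjusted p < 0.001
  strong <- de[de$gene %in% cfg$starburst_genes, ]
  expect_true(all(strong$padj < 1e-3))
  expect_true(all(strong$log2fc > 2.5))
  # estimated fold changes track the implanted values
  big <- abs(tr$log2fc) >= 2 & !de$excluded
  expect_true(cor(de$log2fc[big], tr$log2fc[big]) > 0.98)
})

test_that("gene-set test: degenerate sets, implanted sets, and q ordering", {
  set.seed(3)
  mat <- matrix(rnorm(200 * 20), 200, 20,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("S%d", 1:20)))
  grp <- factor(rep(c("a", "b"), each = 10))
  # a set whose members do not differ at all between groups: p = 1
  mat[1:10, ] <- matrix(rep(rnorm(10), 20), 10, 20)
  sets <- list(flat = rownames(mat)[1:10],
               up = rownames(mat)[11:20],
               null = rownames(mat)[21:40],
               tiny = rownames(mat)[1])
  mat[sets$up, grp == "b"] <- mat[sets$up, grp == "b"] + 3
  expect_warning(res <- gene_set_test(mat, grp, sets), "tiny")
  expect_equal(res$pvalue[res$set == "flat"], 1)
  up <- res[res$set == "up", ]
  expect_equal(up$direction, "up")
  expect_true(up$qvalue < 0.001)
  expect_true(all(res$qvalue >= res$pvalue))
  expect_false("tiny" %in% res$set)
})

test_that("PCA on top-MAD genes: duplicates, variance ordering, separation", {
  cfg <- simulation_config(seed = 9, n_NL = 0)
  sim <- simulate_methylation_cohort(cfg)
  ex <- simulate_expression_cohort(cfg, sim$truth$samples)
  le <- log_normalize(ex$counts)
  # duplicated sample gets identical coordinates
  le2 <- cbind(le, dup = le[, 1])
  pc <- pca_top_mad(le2, 500)
  expect_equal(pc$scores["dup", ], pc$scores[1, ], tolerance = 1e-8)
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
  expect_equal(sum(pc$variance_explained), 1)
  # PC1 separates cluster F from E1/E2
  pc0 <- pca_top_mad(le, 500)
  lab <- sim$truth$samples
  grp <- ifelse(lab$cluster[match(rownames(pc0$scores), lab$sample_id)] == "F",
                "F", "E")
  f1 <- pc0$scores[grp == "F", 1]; e1 <- pc0$scores[grp == "E", 1]
  expect_true(max(min(f1) - max(e1), min(e1) - max(f1)) > 0)
  expect_error(pca_top_mad(le, 1e6), "exceeds")
})

test_that("signature scores are order-invariant means that rank the immature cluster", {
  cfg <- simulation_config(seed = 9)
  sim <- simulate_methylation_cohort(cfg)
  ex <- simulate_expression_cohort(cfg, sim$truth$samples)
  le <- log_normalize(ex$counts)
  one <- signature_score(le, "NQO1L")
  expect_equal(unname(one), unname(le["NQO1L", ]), ignore_attr = TRUE)
  sig <- c(cfg$starburst_genes, ex$truth$gene[ex$truth$is_de & ex$truth$log2fc > 1][1:20])
  s1 <- signature_score(le, sig)
  s2 <- signature_score(le, rev(sig))
  expect_equal(s1, s2)
  lab <- sim$truth$samples
  by_cluster <- tapply(s1[lab$sample_id[!is.na(lab$cluster)]],
                       lab$cluster[!is.na(lab$cluster)], mean)
  # the signature genes are implanted high in E1/E2
  expect_true(min(by_cluster[c("E1", "E2")]) > by_cluster["F"])
  missing_some <- signature_score(le, c("NQO1L", "NOT_A_GENE"))
  expect_equal(attr(missing_some, "n_missing"), 1)
  expect_error(signature_score(le, "NOT_A_GENE"), "none")
})
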