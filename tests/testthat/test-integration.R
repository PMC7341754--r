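test_that("promoter methylation difference is a flat average over the probe block", {
  ids <- c("cg1", "cg2", "cg3")
  man <- make_manifest(ids, genes = c("NQO1", "NQO1", "OTHER"))
  man$feature_category[3] <- "other"   # not promoter-associated: never used
  beta <- rbind(cg1 = c(0.2, 0.2, 0.6, 0.6),
                cg2 = c(0.3, 0.1, 0.7, 0.5),
                cg3 = c(0.9, 0.9, 0.9, 0.9))
  colnames(beta) <- sprintf("S%d", 1:4)
  grp <- factor(c("F", "F", "E", "E"), levels = c("F", "E"))
  res <- promoter_methylation_difference(beta, man, grp)
  nq <- res[res$gene == "NQO1", ]
  expect_equal(nq$n_probes, 2)
  # unweighted mean over the 2x2 block per group
  expect_equal(nq$mean_group1, mean(c(0.2, 0.2, 0.3, 0.1)))
  expect_equal(nq$mean_group2, mean(c(0.6, 0.6, 0.7, 0.5)))
  expect_equal(nq$delta_beta, 0.4)
  expect_false("OTHER" %in% res$gene)
  skipped <- promoter_methylation_difference(beta, man, grp, genes = c("NQO1", "GONE"))
  expect_equal(attr(skipped, "skipped"), "GONE")
  # identical group means give zero difference
  same <- promoter_methylation_difference(
    beta[, c(1, 2, 1, 2)], man, grp)
  expect_equal(same$delta_beta[same$gene == "NQO1"], 0)
})

test_that("starburst flags use inclusive thresholds and sign quadrants", {
  meth <- data.frame(gene = c("A", "B", "C", "D", "E"),
                     delta_beta = c(-0.30, -0.20, -0.25, 0.30, 0.10))
  de <- data.frame(gene = c("A", "B", "C", "D", "E", "F"),
                   log2fc = c(3.0, 5.0, 2.5, -2.6, 0.2, 9))
  res <- starburst(meth, de)
  row <- function(g) res[res$gene == g, ]
  expect_true(row("A")$flagged)
  expect_equal(row("A")$quadrant, "hypo_up")
  expect_false(row("B")$flagged)          # methylation below threshold
  expect_equal(row("B")$quadrant, "none")
  expect_true(row("C")$flagged)           # exactly at both thresholds
  expect_equal(row("C")$quadrant, "hypo_up")
  expect_true(row("D")$flagged)
  expect_equal(row("D")$quadrant, "hyper_down")
  expect_false(row("E")$flagged)
  expect_false("F" %in% res$gene)         # missing from the methylation table
  expect_equal(attr(res, "n_dropped"), 1)
})

test_that("flagged starburst genes equal the implanted set on synthetic cohorts", {
  # truth-table route: exact for any seed
  for (s in c(1, 8, 23, 57, 101)) {
    cfg <- simulation_config(seed = s)
    sim <- simulate_methylation_cohort(cfg)
    ex <- simulate_expression_cohort(cfg, sim$truth$samples)
    pr <- sim$truth$probes
    prom <- pr[pr$probe_id %in%
                 sim$manifest$probe_id[sim$manifest$feature_category %in%
                   c("Promoter_Associated", "Promoter_Associated_Cell_type_specific")], ]
    truth_meth <- aggregate(
      delta_beta ~ gene,
      data = data.frame(gene = prom$gene,
                        delta_beta = (prom$mean_E1 + prom$mean_E2) / 2 - prom$mean_F),
      FUN = mean)
    truth_de <- data.frame(gene = ex$truth$gene, log2fc = ex$truth$log2fc)
    res <- starburst(truth_meth, truth_de)
    expect_setequal(res$gene[res$flagged], cfg$starburst_genes)
  }
})

test_that("empirical starburst analysis recovers exactly the implanted genes", {
  cfg <- simulation_config(seed = 1)
  sim <- simulate_methylation_cohort(cfg)
  ex <- simulate_expression_cohort(cfg, sim$truth$samples)
  lab <- sim$truth$samples
  tum <- lab$sample_id[lab$cluster %in% c("F", "E1", "E2")]
  grp <- factor(ifelse(lab$cluster[match(tum, lab$sample_id)] == "F", "F", "E"),
                levels = c("F", "E"))
  meth <- promoter_methylation_difference(sim$beta[, tum], sim$manifest, grp)
  de <- nb_lrt_de(ex$counts[, tum], full = grp)
  res <- starburst(meth, de[, c("gene", "log2fc")])
  expect_setequal(res$gene[res$flagged], cfg$starburst_genes)
})

test_that("Spearman correlation: exact values, ties, and monotone invariance", {
  dec <- probe_expression_correlation(1:10, 10:1)
  expect_equal(dec$rho, -1)
  expect_equal(dec$pvalue, 0)
  # tie handling against brute-force average ranks on a 6-point fixture
  x <- c(0.1, 0.2, 0.2, 0.5, 0.7, 0.7)
  y <- c(5, 3, 4, 4, 1, 2)
  r <- probe_expression_correlation(x, y)
  rx <- c(1, 2.5, 2.5, 4, 5.5, 5.5)
  ry <- c(6, 3, 4.5, 4.5, 1, 2)
  expect_equal(r$rho, cor(rx, ry))
  tman <- r$rho * sqrt(4 / (1 - r$rho^2))
  expect_equal(r$pvalue, 2 * pt(-abs(tman), 4))
  # invariant under strictly monotone transforms
  r2 <- probe_expression_correlation(exp(x), y^3 - 100)
  expect_equal(r2$rho, r$rho)
  # constant vector: undefined, reported missing
  cst <- probe_expression_correlation(rep(0.5, 6), y)
  expect_true(is.na(cst$rho))
  expect_error(probe_expression_correlation(1:3, 3:1), "at least 4")
})

test_that("null probe-expression pairs have mean correlation near zero", {
  set.seed(12)
  rhos <- replicate(300, {
    probe_expression_correlation(runif(35), rnorm(35))$rho
  })
  expect_lt(abs(mean(rhos)), 0.02)
})

test_that("most negatively correlated probe of a gene is ranked first", {
  set.seed(5)
  ids <- c("cg_pos", "cg_neg", "cg_null")
  man <- make_manifest(ids, genes = c("NQO1", "NQO1", "NQO1"))
  expr <- rnorm(30)
  beta <- rbind(cg_pos = plogis(expr + rnorm(30, 0, 0.3)),
                cg_neg = plogis(-2 * expr + rnorm(30, 0, 0.2)),
                cg_null = runif(30))
  colnames(beta) <- sprintf("S%d", 1:30)
  ranked <- rank_probes_by_correlation(beta, man, "NQO1", expr)
  expect_equal(ranked$probe_id[1], "cg_neg")
  expect_true(ranked$rho[1] < -0.5)
  expect_error(rank_probes_by_correlation(beta, man, "TP53", expr), "no probes")
})

test_that("genotype correction scales FPKM by the activity-weighted allele fraction", {
  expect_equal(correct_nqo1_fpkm(100, nc = 0, nt = 50), 3.0)
  expect_equal(correct_nqo1_fpkm(100, nc = 50, nt = 0), 100.0)
  expect_equal(correct_nqo1_fpkm(100, nc = 25, nt = 25), 51.5)
  expect_error(correct_nqo1_fpkm(100, nc = 0, nt = 0), "unobserved")
  # the factor is monotone decreasing in the T-allele fraction, within [0.03, 1]
  nt <- 0:40
  fac <- correct_nqo1_fpkm(1, nc = 40 - nt, nt = nt)
  expect_true(all(diff(fac) < 0))
  expect_true(all(fac >= 0.03 & fac <= 1))
  expect_equal(fac[1], 1)
  expect_equal(fac[length(fac)], 0.03)
})
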