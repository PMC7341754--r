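test_that("probe selection applies eligibility rules and exact SD ranking", {
  set.seed(10)
  ids <- sprintf("cg%03d", 1:10)
  beta <- matrix(runif(10 * 6), 10, 6, dimnames = list(ids, sprintf("S%d", 1:6)))
  man <- make_manifest(ids)
  # full-sort oracle on all eligible probes
  sds <- apply(beta, 1, sd)
  oracle <- ids[order(-sds, ids)][1:3]
  expect_equal(select_variable_promoter_probes(beta, man, 3), oracle)

  # chrX, shelf/open-sea, and non-promoter probes are ineligible
  man2 <- man
  man2$chromosome[1] <- "chrX"
  man2$cgi_relation[2] <- "OpenSea"
  man2$feature_category[3] <- "other"
  sel <- select_variable_promoter_probes(beta, man2, 7)
  expect_false(any(ids[1:3] %in% sel))

  # a constant probe is never selected while a varying one is available
  beta[ids[5], ] <- 0.4
  sel2 <- select_variable_promoter_probes(beta, man, 9)
  expect_false(ids[5] %in% sel2)

  expect_error(select_variable_promoter_probes(beta, man2, 8), "eligible")
})

test_that("duplicated profiles give perfectly separated consensus", {
  dup <- duplicate_beta(m = 5)
  cc <- consensus_cluster(dup, k_range = 2:4, n_iter = 100, seed = 3)
  C <- cc$consensus[["2"]]
  expect_true(all(C >= 0 & C <= 1))
  expect_equal(C, t(C))
  expect_true(all(diag(C) == 1))
  within <- c(C[1:5, 1:5], C[6:10, 6:10])
  between <- C[1:5, 6:10]
  expect_true(all(within == 1))
  expect_true(all(between == 0))
  ck <- choose_k(cc)
  expect_equal(ck$k, 2)
  expect_false(ck$low_confidence)
  # doubling iterations barely moves the consensus entries
  cc2 <- consensus_cluster(dup, k_range = 2, n_iter = 200, seed = 3)
  expect_true(max(abs(cc2$consensus[["2"]] - C)) < 0.05)
})

test_that("consensus clustering recovers the implanted three-cluster structure", {
  cfg <- simulation_config(seed = 7)
  sim <- simulate_methylation_cohort(cfg)
  lab <- sim$truth$samples
  b <- sim$beta[, lab$sample_type == "biopsy"]
  probes <- select_variable_promoter_probes(b, sim$manifest, 3000)
  cc <- consensus_cluster(b[probes, ], k_range = 2:4, n_iter = 250, seed = 7)
  expect_equal(choose_k(cc)$k, 3)
  truth <- lab$cluster[match(colnames(b), lab$sample_id)]
  expect_equal(adjusted_rand_index(cc$assignments[["3"]], truth), 1.0)
})

test_that("two-step protocol recovers F/E1/E2 and drops non-biopsy samples", {
  cfg <- simulation_config(seed = 7, n_postchemo = 4)
  sim <- simulate_methylation_cohort(cfg)
  lab <- sim$truth$samples
  res <- two_step_cluster(sim$beta, sim$manifest, lab$sample_type, seed = 7)
  # postchemo and normal-liver samples are excluded before step 1
  expect_setequal(names(res$labels),
                  lab$sample_id[lab$sample_type == "biopsy"])
  truth <- lab$cluster[match(names(res$labels), lab$sample_id)]
  expect_equal(adjusted_rand_index(res$labels, truth), 1.0)
  # the naming convention puts F on the hypomethylated side
  expect_equal(unname(res$labels[truth == "F"][1]), "F")
  expect_length(res$probes_step1, 3000)
  expect_length(res$probes_step2, 1000)
})

test_that("agreement with an independent ARI implementation", {
  skip_if_not_installed("mclust")
  set.seed(42)
  for (i in 1:5) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, rep(1:5, 2)),
               mclust::adjustedRandIndex(1:10, rep(1:5, 2)))
})

test_that("differential methylation equals the pooled-variance t test", {
  beta <- rbind(
    flat = rep(0.4, 6),
    sig  = c(0.1, 0.2, 0.15, 0.7, 0.8, 0.75)
  )
  colnames(beta) <- sprintf("S%d", 1:6)
  groups <- factor(rep(c("F", "E"), each = 3), levels = c("F", "E"))
  res <- differential_methylation(beta, groups)
  flat <- res[res$probe_id == "flat", ]
  expect_equal(flat$delta_beta, 0)
  expect_equal(flat$pvalue, 1)
  # closed-form pooled t on the six numbers
  x <- c(0.1, 0.2, 0.15); y <- c(0.7, 0.8, 0.75)
  sp <- sqrt((2 * var(x) + 2 * var(y)) / 4)
  t_manual <- (mean(y) - mean(x)) / (sp * sqrt(2 / 3))
  sig <- res[res$probe_id == "sig", ]
  expect_equal(sig$t, t_manual)
  expect_equal(sig$delta_beta, 0.6)
  expect_equal(sig$pvalue, 2 * pt(-abs(t_manual), df = 4))
  # invariance to sample order; label swap flips the signs
  perm <- c(4, 1, 6, 2, 5, 3)
  res_perm <- differential_methylation(beta[, perm], groups[perm])
  expect_equal(res_perm$t, res$t)
  res_swap <- differential_methylation(beta, relevel(groups, "E"))
  expect_equal(res_swap[res_swap$probe_id == "sig", "t"], -t_manual)
  expect_equal(res_swap[res_swap$probe_id == "sig", "delta_beta"], -0.6)
})

test_that("Benjamini-Hochberg adjustment matches the step-up procedure by hand", {
  # step-up on (0.01, 0.02, 0.03, 0.04): all adjusted to 0.04
  set.seed(1)
  beta <- matrix(runif(4 * 8), 4, 8,
                 dimnames = list(sprintf("cg%d", 1:4), sprintf("S%d", 1:8)))
  res <- differential_methylation(beta, rep(c("a", "b"), each = 4))
  expect_equal(res$padj, p.adjust(res$pvalue, "BH"))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_true(all(res$padj >= res$pvalue))
  # top-probe helper splits by direction of delta beta
  hyper <- top_diffmeth_probes(res, 2, "hyper")
  expect_true(all(res$delta_beta[match(hyper, res$probe_id)] > 0))
})

test_that("zero within-group variance reports an infinite statistic, not a crash", {
  beta <- rbind(const_diff = c(0.2, 0.2, 0.2, 0.8, 0.8, 0.8))
  colnames(beta) <- sprintf("S%d", 1:6)
  res <- differential_methylation(beta, rep(c("a", "b"), each = 3))
  expect_true(is.infinite(res$t))
  expect_equal(res$pvalue, 0)
  expect_true(res$zero_variance)
})

test_that("region-set enrichment equals the hypergeometric tail", {
  # universe of 100 probes at positions 1..100 on chr1; the set covers 10
  ids <- sprintf("cg%03d", 1:100)
  man <- make_manifest(ids, position = 1:100)
  set_gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
  catalog <- list(demo = set_gr)
  # query of 20 containing 8 of the 10 covered probes
  query <- c(ids[1:8], ids[31:42])
  res <- region_set_enrichment(query, ids, man, catalog)
  expect_equal(res$overlap, 8)
  expect_equal(res$set_size, 10)
  oracle <- sum(dhyper(8:10, 10, 90, 20))
  expect_equal(res$pvalue, oracle, tolerance = 1e-12)
  # a set with no overlap and no expectation: p = 1
  far <- list(far = GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 10)))
  res0 <- region_set_enrichment(query, ids, man, far)
  expect_equal(res0$pvalue, 1)
  expect_equal(res0$overlap, 0)
  # query = universe: no enrichment possible
  resU <- region_set_enrichment(ids, ids, man, catalog)
  expect_equal(resU$pvalue, 1)
  expect_error(region_set_enrichment(c(ids[1], "cgXXX"), ids, man, catalog),
               "subset")
  expect_true(all(res$qvalue >= res$pvalue))
})
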