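test_that("primary filter matches the published criteria with reason codes", {
  expect_true(apply_primary_filter(make_call())$pass)
  cases <- list(
    list(make_call(depth = 99L), "P5_DEPTH"),
    list(make_call(consequence = "silent"), "P3_CONSEQUENCE"),
    list(make_call(consequence = "noncoding"), "P3_CONSEQUENCE"),
    list(make_call(strand_alt_fwd = 40L), "P4_STRAND"),   # all alt reads forward
    list(make_call(strand_alt_fwd = 0L), "P4_STRAND"),
    list(make_call(mapq = 19), "P1_MAPQ"),
    list(make_call(baseq = 14), "P2_BASEQ"),
    list(make_call(ref_reads = 4L), "P6_READS"),
    list(make_call(alt_reads = 4L, strand_alt_fwd = 2L), "P6_READS"),
    list(make_call(vaf = 0.049), "P7_VAF"),
    list(make_call(ebcall_p = 1e-19), "P8_EBCALL")
  )
  for (cs in cases) {
    out <- apply_primary_filter(cs[[1]])
    expect_false(out$pass)
    expect_match(out$reason_codes, cs[[2]])
  }
  # EBCall threshold is strict: 1e-21 < 1e-20 passes
  expect_true(apply_primary_filter(make_call(ebcall_p = 1e-21))$pass)
  # a call failing several rules reports every one
  multi <- apply_primary_filter(make_call(depth = 99L, mapq = 10))
  expect_match(multi$reason_codes, "P1_MAPQ")
  expect_match(multi$reason_codes, "P5_DEPTH")
})

test_that("germline exclusion fires only in the quoted CN contexts, with COSMIC rescue", {
  # VAF >= 0.35, copy-neutral, no LOH -> germline
  g2 <- classify_germline_somatic(make_call(vaf = 0.40))
  expect_equal(g2$label, "germline")
  expect_match(g2$germline_codes, "G2_VAF_NEUTRAL")
  # VAF >= 0.25 in CN-gain, no LOH -> germline
  g3 <- classify_germline_somatic(make_call(vaf = 0.30, cn_state = "gain"))
  expect_equal(g3$label, "germline")
  expect_match(g3$germline_codes, "G3_VAF_GAIN")
  # ten or more COSMIC solid-tumour mentions rescue to somatic
  g4 <- classify_germline_somatic(make_call(vaf = 0.40, cosmic_solid_mentions = 12L))
  expect_equal(g4$label, "somatic")
  expect_match(g4$germline_codes, "G4_COSMIC_RESCUE")
  # the exclusion rules require absence of LOH
  loh <- classify_germline_somatic(make_call(vaf = 0.40, loh = TRUE))
  expect_equal(loh$label, "somatic")
  # CN states other than neutral/gain are not named by any rule
  oth <- classify_germline_somatic(make_call(vaf = 0.60, cn_state = "other"))
  expect_equal(oth$label, "somatic")
  # SNP-database membership alone is decisive
  snp <- classify_germline_somatic(make_call(in_snp_db = TRUE))
  expect_equal(snp$label, "germline")
  expect_match(snp$germline_codes, "G1_SNP_DB")
})

test_that("TERT promoter path keeps low-depth calls inside the window", {
  expect_true(filter_tert_promoter(make_call(chrom = "chr5", pos = 1295200,
                                             ebcall_p = 1e-5)))
  expect_false(filter_tert_promoter(make_call(chrom = "chr5", pos = 1295000,
                                              ebcall_p = 1e-9)))
  expect_false(filter_tert_promoter(make_call(chrom = "chr5", pos = 1295200,
                                              ebcall_p = 1e-3)))
  # bypasses the primary depth rule within the full cascade
  tert <- make_call(chrom = "chr5", pos = 1295200, ebcall_p = 1e-5,
                    depth = 10L, ref_reads = 6L, alt_reads = 4L, vaf = 0.4,
                    strand_alt_fwd = 2L, consequence = "promoter")
  out <- filter_variants(tert)
  expect_equal(out$verdict, "somatic")
  expect_match(out$reason_codes, "TERT_WINDOW")
})

test_that("structural-variant filter applies support and context rules", {
  expect_true(filter_structural_variants(make_sv())$pass)
  expect_false(filter_structural_variants(make_sv(ref_pairs = 299L))$pass)
  expect_false(filter_structural_variants(make_sv(variant_pairs = 19L))$pass)
  expect_false(filter_structural_variants(make_sv(overhang_right = 149L))$pass)
  expect_false(filter_structural_variants(make_sv(on_mito_or_decoy = TRUE))$pass)
  intronic <- filter_structural_variants(
    make_sv(sv_type = "tandem_duplication", affects_coding_exon = FALSE))
  expect_false(intronic$pass)
  expect_match(intronic$reason_codes, "SV5_INTRONIC")
  # inversions are not subject to the intronic-removal rule
  expect_true(filter_structural_variants(
    make_sv(sv_type = "inversion", affects_coding_exon = FALSE))$pass)
  # boundary-inclusive pass
  expect_true(filter_structural_variants(
    make_sv(ref_pairs = 300L, variant_pairs = 20L,
            overhang_left = 150L, overhang_right = 150L))$pass)
})

test_that("germline truncating APC calls are picked up, missense left behind", {
  calls <- rbind(
    make_call(gene = "APC", truncating = TRUE, in_snp_db = TRUE),
    make_call(gene = "APC", truncating = FALSE, in_snp_db = TRUE),
    make_call(gene = "APC", truncating = TRUE),            # somatic: not picked up here
    make_call(gene = "CTNNB1", truncating = TRUE, in_snp_db = TRUE)
  )
  cls <- classify_germline_somatic(calls)
  picked <- include_germline_apc_truncating(cls)
  expect_equal(nrow(picked), 1)
  expect_equal(picked$label, "germline")
  expect_true(picked$truncating)
})

test_that("verdicts are per-call pure functions: permutation equivariance", {
  calls <- simulate_variant_cohort(simulation_config(seed = 5))
  out <- filter_variants(calls)
  set.seed(99)
  perm <- sample(nrow(calls))
  out_perm <- filter_variants(calls[perm, ])
  expect_equal(out_perm$verdict, out$verdict[perm])
  expect_equal(out_perm$reason_codes, out$reason_codes[perm])
})

test_that("filter verdicts agree with the independent rule transcription on any seed", {
  for (s in c(1, 17, 402)) {
    calls <- simulate_variant_cohort(simulation_config(seed = s))
    out <- filter_variants(calls)
    expect_equal(out$verdict, calls$expected_label)
    expect_equal(out$reason_codes, calls$expected_codes)
  }
})

test_that("predictive values follow the confusion-matrix identities", {
  verdict <- c(rep("somatic", 21), rep("germline", 173))
  truth <- c(rep(FALSE, 19), rep(TRUE, 2), rep(TRUE, 173))
  pv <- compute_ppv_npv(verdict, truth)
  expect_equal(pv$tp, 19); expect_equal(pv$fp, 2)
  expect_equal(pv$tn, 173); expect_equal(pv$fn, 0)
  expect_equal(pv$ppv, 19 / 21)
  expect_equal(pv$npv, 1)
  # undefined ratios are reported missing, not zero
  allg <- compute_ppv_npv(rep("germline", 5), c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_true(is.na(allg$ppv))
  expect_equal(allg$npv, 4 / 5)
  expect_error(compute_ppv_npv(verdict, rep(NA, 194)), "no evaluable")
})
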