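# hbmultiomics

An R package implementing a multiomics classification and target-discovery
workflow for hepatoblastoma-like tumour cohorts. Hepatoblastoma carries one
of the lowest mutation burdens of any cancer, so its striking clinical
heterogeneity is poorly explained by mutations alone; this workflow instead
discovers DNA-methylation subtypes and characterises them with expression,
integration and survival analyses. It is aimed at computational biologists
who want the published analysis chain as tested, reusable functions that can
be exercised end to end on synthetic, truth-labelled cohorts.

The workflow covers:

* **Variant filtering** — primary quality criteria (mapping quality ≥ 20,
  base quality ≥ 15, nonsilent exonic/splice-site, variant reads on both
  strands, depth ≥ 100, ref/var read support ≥ 5, VAF ≥ 0.05, EBCall
  p < 1e-20), copy-number-aware germline exclusion (VAF ≥ 0.35 copy-neutral
  / ≥ 0.25 CN-gained, both without LOH; SNP-database removal; re-inclusion
  at ≥ 10 COSMIC solid-tumour mentions), a TERT-promoter special path
  (chr5:1,295,105–1,295,353, EBCall p < 1e-4), structural-variant support
  rules, germline truncating APC pick-up, and PPV/NPV validation.
* **Methylation subtype discovery** — SD-ranked promoter-probe selection and
  two-step consensus clustering (top 3000 probes, Euclidean, k = 2 → F/E;
  then top 1000 within E, Pearson, k = 2 → E1/E2; 1000 iterations).
* **Differential methylation** — per-probe linear models (pooled-variance
  t), BH adjustment, and one-sided Fisher-exact region-set enrichment.
* **Differential expression** — median-of-ratios size factors and a
  negative-binomial likelihood-ratio test
  `2(ll_full − ll_reduced) ~ χ²(Δdf)` with gene-wise method-of-moments
  dispersion, plus mean-t gene-set testing, top-MAD PCA and signature
  scores.
* **Integration** — gene-level promoter Δβ (E − F) against log2 fold
  change with starburst flagging at |Δβ| ≥ 0.25 and |log2FC| ≥ 2.5,
  Spearman probe–expression correlation, and genotype-corrected NQO1
  expression: `corrected = raw × (Nc + 0.03·Nt)/(Nc + Nt)` from rs1800566
  allele read counts.
* **Survival** — OS/EFS endpoint derivation (remission failure as an event
  on day 0), Kaplan–Meier curves and log-rank tests.
* **Synthetic cohorts** — `simulation_config()` and four generators emit
  truth-labelled beta matrices, variant calls (with an independently
  transcribed expected verdict per call), NB counts with implanted fold
  changes, allele counts and survival times, so every stage is testable
  without any external data.

## Worked example

The `analysis/` scripts run the whole chain on one simulated cohort
(`Rscript analysis/01_simulate.R`, then `02`–`07` in order). Highlights of
what they print:

```
$ Rscript analysis/03_cluster_methylation.R
cluster sizes:
E1 E2  F
12 12 12
adjusted Rand index vs simulated truth: 1
```

The two-step clustering recovers the three implanted subtypes perfectly
(ARI = 1 against the generator's truth labels).

```
$ Rscript analysis/04_differential_methylation.R
region-set enrichment (ranked by q):
              set overlap query_size set_size universe_size odds_ratio       pvalue
1 binding_regions     150       2000      150          5000  488.06     6.31e-62
2 decoy_regions_1       0       2000        0          5000    1.50     1.00
```

All 150 binding-region probes land in the top-2000 hypermethylated list:
the implanted binding-region hypermethylation in E1/E2 is recovered as the
top-enriched set, with decoy sets at p = 1.

```
$ Rscript analysis/06_integrate.R
starburst-flagged genes (delta beta = E minus F):
   gene delta_beta   log2fc flagged quadrant
1 NQO1L -0.3893640 2.837120    TRUE  hypo_up
2 ODC1L -0.3993089 3.041343    TRUE  hypo_up
mean corrected/raw factor by genotype:
   CC    CT    TT
1.000 0.513 0.030
```

Exactly the two implanted NQO1-like/ODC1-like genes cross both starburst
thresholds, in the hypomethylated-and-overexpressed quadrant; the rs1800566
correction factor is 1 for C/C samples, ≈ 0.5 for heterozygotes and 0.03
for T/T samples, whose NQO1 enzyme retains only ~3 % activity.

```
$ Rscript analysis/07_survival.R
OS:  log-rank chi-square 12.28 on 2 df, p = 0.002159; events: 55/90
EFS: log-rank chi-square 16.48 on 2 df, p = 0.0002644; events: 56/90
```

With the configured cluster hazards, outcome differences between F and
E1/E2 are detected at 30 patients per cluster.

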