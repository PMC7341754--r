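#' Default run configuration
#'
#' Collects every tunable threshold of the workflow in one nested list, each
#' defaulting to the published value of the hepatoblastoma study the pipeline
#' re-implements. Stages read their parameters from this object so that a
#' single config can be passed around (and overridden) end to end.
#'
#' @details Sections:
#' \describe{
#'   \item{filter}{Primary variant-quality criteria: minimum mapping quality
#'     (20), base quality (15), read depth (100), reference and variant read
#'     support (5 each), variant allele frequency (0.05), and the EBCall
#'     error-probability ceiling (1e-20). Plus the germline-exclusion VAF
#'     cutoffs (0.35 in copy-neutral regions, 0.25 in CN-gained regions, both
#'     without LOH) and the COSMIC solid-tumour rescue count (10).}
#'   \item{tert}{The TERT-promoter special path: window chr5:1295105-1295353
#'     and EBCall p < 1e-4, bypassing the depth-based primary criteria.}
#'   \item{sv}{Structural-variant support thresholds: reference pairs >= 300,
#'     variant pairs >= 20, overhang >= 150 bp on both sides.}
#'   \item{clustering}{Two-step consensus-clustering protocol: top 3000
#'     SD-ranked promoter probes with Euclidean distance for step 1 (F vs E),
#'     top 1000 with Pearson distance for step 2 (E1 vs E2), 1000 iterations,
#'     80\% sample subsampling, average linkage.}
#'   \item{integration}{Starburst thresholds (|delta beta| >= 0.25,
#'     |log2 fold change| >= 2.5) and the residual NQO1 activity of the
#'     rs1800566 T allele (0.03).}
#'   \item{enrichment}{Number of top differentially methylated probes fed to
#'     region-set enrichment per direction (2000) and the reporting cut (50).}
#' }
#'
#' @param ... named overrides of any leaf value, e.g.
#'   `default_config(clustering = list(n_iter = 200))` (lists are merged
#'   recursively).
#' @return A nested list of parameters with class `"hb_config"`.
#' @export
default_config <- function(...) {
  cfg <- list(
    filter = list(
      min_mapq = 20,
      min_baseq = 15,
      min_depth = 100,
      min_reads = 5,
      min_vaf = 0.05,
      max_ebcall_p = 1e-20,
      vaf_neutral = 0.35,
      vaf_gain = 0.25,
      cosmic_rescue = 10
    ),
    tert = list(chrom = "chr5", start = 1295105, end = 1295353,
                max_ebcall_p = 1e-4),
    sv = list(min_ref_pairs = 300, min_variant_pairs = 20,
              min_overhang = 150),
    clustering = list(
      step1_n = 3000, step2_n = 1000,
      step1_distance = "euclidean", step2_distance = "pearson",
      n_iter = 1000, subsample = 0.8, linkage = "average",
      pac_limits = c(0.1, 0.9), pac_flag = 0.2
    ),
    integration = list(meth_threshold = 0.25, expr_threshold = 2.5,
                       t_allele_activity = 0.03),
    enrichment = list(top_n = 2000, report_n = 50)
  )
  cfg <- merge_config(cfg, list(...))
  class(cfg) <- c("hb_config", "list")
  cfg
}

# recursive merge used by both config constructors
merge_config <- function(base, override) {
  if (length(override) == 0L) return(base)
  bad <- setdiff(names(override), names(base))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Synthetic-cohort configuration
#'
#' Parameters of the truth-labelled synthetic cohorts used to exercise the
#' workflow. The defaults define the study conditions the generators emulate:
#' three tumour methylation clusters (F hypomethylated at the informative
#' promoter probes, E1/E2 hypermethylated, E1 and E2 separated on a second
#' probe block), normal-liver controls, negative-binomial expression with
#' implanted fold changes for designated NQO1-like and ODC1-like genes,
#' quality-annotated variant calls with controlled rule violations, and
#' cluster-dependent exponential survival.
#'
#' @param ... named overrides of any default (validated; unknown names error).
#' @return A list of class `"hb_sim_config"`.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    # cohort sizes (samples); 12 per tumour cluster = 36 tumours
    n_F = 12, n_E1 = 12, n_E2 = 12, n_NL = 10, n_postchemo = 0,
    # methylation array
    n_probes = 5000,
    n_informative_FE = 400,   # separate F from E1/E2
    n_informative_E12 = 200,  # separate E1 from E2
    n_binding = 150,          # gene-body probes inside binding-region intervals
    gap = 0.5,                # between-cluster beta-mean separation
    concentration_informative = 40,
    concentration_noise = 150,
    frac_chrx = 0.05, frac_noncore_cgi = 0.15,
    # expression
    n_genes = 2000, de_fraction = 0.15,
    log2fc_mean = 2, log2fc_sd = 0.5,
    dispersion = 0.1, libsize_range = c(0.5, 2),
    starburst_genes = c("NQO1L", "ODC1L"),
    starburst_log2fc = 3, starburst_delta_beta = -0.4,
    genotype_probs = c(CC = 0.6, CT = 0.3, TT = 0.1), allele_depth = 60,
    # variant cohort
    n_somatic = 40, n_germline = 160, n_artifact_per_rule = 3, n_tert = 2,
    snp_db_rate = 0.9, cosmic_rescue_rate = 0.02, germline_loh_rate = 0.03,
    germline_other_cn_rate = 0.1,
    # survival (hazards in events/day)
    hazard = c(F = 2.5e-4, E1 = 8e-4, E2 = 1.5e-3),
    censoring_rate = 0.3,
    p_remission_failure = c(F = 0, E1 = 0.05, E2 = 0.1),
    seed = 1L
  )
  cfg <- merge_config(cfg, list(...))
  stopifnot(
    cfg$de_fraction >= 0, cfg$de_fraction <= 1,
    cfg$dispersion > 0,
    cfg$censoring_rate >= 0, cfg$censoring_rate <= 1,
    cfg$n_informative_FE + cfg$n_informative_E12 + cfg$n_binding <= cfg$n_probes,
    all(cfg$genotype_probs >= 0), abs(sum(cfg$genotype_probs) - 1) < 1e-8,
    length(cfg$seed) == 1L, is.finite(cfg$seed)
  )
  class(cfg) <- c("hb_sim_config", "list")
  cfg
}
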