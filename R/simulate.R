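#' Simulate a cluster-structured methylation cohort
#'
#' Generates a beta matrix, a matching probe manifest and truth labels with
#' the structure the clustering protocol assumes: three tumour clusters
#' (F, E1, E2) plus optional normal-liver and post-chemotherapy samples.
#' Probe classes:
#' \itemize{
#'   \item informative F-vs-E promoter probes: cluster beta means separated
#'     by `gap` (F hypomethylated, E1/E2 hypermethylated; normal liver tracks
#'     the F side). Designated starburst genes get the opposite direction
#'     (promoter hypomethylation in E1/E2) with `starburst_delta_beta`.
#'   \item informative E1-vs-E2 promoter probes: E1 and E2 separated by
#'     `gap`, F intermediate — the signal the second clustering step finds.
#'   \item binding-region probes: gene-body probes placed inside simulated
#'     transcription-factor-binding intervals, hypermethylated in E1/E2
#'     (emulating HNF4A/CEBPA-binding-region hypermethylation); not eligible
#'     for the promoter-based probe selection.
#'   \item noise probes: one probe-specific mean shared by every cluster,
#'     with a slice placed on chrX or outside Island/Shore regions to
#'     exercise the eligibility rules.
#' }
#' Beta values are drawn from Beta distributions parameterised by (mean,
#' concentration). Identical config and seed give bit-identical output.
#'
#' @param config a [simulation_config()].
#' @return list: `beta` (probes x samples), `manifest` (`probe_manifest`),
#'   `truth` (list with `samples`, `probes`, `binding_regions`).
#' @export
simulate_methylation_cohort <- function(config = simulation_config()) {
  set.seed(config$seed)
  if (config$n_F < 1 || config$n_E1 < 1 || config$n_E2 < 1) {
    stop("every tumour cluster needs at least one sample")
  }
  samples <- data.frame(
    sample_id = sprintf("HBL%03d", seq_len(config$n_F + config$n_E1 +
                                             config$n_E2 + config$n_postchemo)),
    cluster = c(rep("F", config$n_F), rep("E1", config$n_E1),
                rep("E2", config$n_E2), rep(NA, config$n_postchemo)),
    sample_type = c(rep("biopsy", config$n_F + config$n_E1 + config$n_E2),
                    rep("postchemo", config$n_postchemo)),
    stringsAsFactors = FALSE
  )
  if (config$n_NL > 0) {
    samples <- rbind(samples, data.frame(
      sample_id = sprintf("NL%02d", seq_len(config$n_NL)),
      cluster = "NL", sample_type = "normal_liver", stringsAsFactors = FALSE))
  }
  ns <- nrow(samples)

  n_fe <- config$n_informative_FE
  n_e12 <- config$n_informative_E12
  n_bind <- config$n_binding
  n_noise <- config$n_probes - n_fe - n_e12 - n_bind
  probe_class <- c(rep("informative_FE", n_fe), rep("informative_E12", n_e12),
                   rep("binding", n_bind), rep("noise", n_noise))
  probe_id <- sprintf("cg%06d", seq_len(config$n_probes))

  # gene assignment: DE genes are, by convention, the first
  # ceil(de_fraction * n_genes) ids, so informative promoter probes are
  # linked to non-DE genes and designated starburst genes carry the only
  # implanted methylation+expression double hits
  genes_all <- sprintf("G%04d", seq_len(config$n_genes))
  n_de <- ceiling(config$de_fraction * config$n_genes)
  genes_nonde <- genes_all[setdiff(seq_len(config$n_genes), seq_len(n_de))]
  sb <- config$starburst_genes
  n_sb_probes <- 4L * length(sb)
  if (n_fe < n_sb_probes + 10) stop("n_informative_FE too small for the starburst genes")
  gene_link <- character(config$n_probes)
  is_sb_probe <- rep(FALSE, config$n_probes)
  gene_link[seq_len(n_sb_probes)] <- rep(sb, each = 4L)
  is_sb_probe[seq_len(n_sb_probes)] <- TRUE
  idx_fe_rest <- (n_sb_probes + 1):n_fe
  gene_link[idx_fe_rest] <- sample(genes_nonde, length(idx_fe_rest), replace = TRUE)
  idx_e12 <- n_fe + seq_len(n_e12)
  gene_link[idx_e12] <- sample(genes_nonde, n_e12, replace = TRUE)
  idx_bind <- n_fe + n_e12 + seq_len(n_bind)
  gene_link[idx_bind] <- sample(genes_all, n_bind, replace = TRUE)
  idx_noise <- (n_fe + n_e12 + n_bind + 1):config$n_probes
  gene_link[idx_noise] <- sample(genes_all, n_noise, replace = TRUE)

  # cluster-specific probe means
  lo <- 0.5 - config$gap / 2
  hi <- 0.5 + config$gap / 2
  mean_F <- mean_E1 <- mean_E2 <- mean_NL <- numeric(config$n_probes)
  fe <- probe_class == "informative_FE" & !is_sb_probe
  mean_F[fe] <- lo; mean_E1[fe] <- hi; mean_E2[fe] <- hi; mean_NL[fe] <- lo
  # starburst genes: promoter hypomethylated in E1/E2
  sb_hi <- 0.5 - config$starburst_delta_beta / 2  # delta_beta < 0 -> F side high
  sb_lo <- 0.5 + config$starburst_delta_beta / 2
  mean_F[is_sb_probe] <- sb_hi; mean_NL[is_sb_probe] <- sb_hi
  mean_E1[is_sb_probe] <- sb_lo; mean_E2[is_sb_probe] <- sb_lo
  e12 <- probe_class == "informative_E12"
  mean_F[e12] <- 0.5; mean_NL[e12] <- 0.5
  mean_E1[e12] <- lo; mean_E2[e12] <- hi
  bind <- probe_class == "binding"
  mean_F[bind] <- 0.3; mean_NL[bind] <- 0.25
  mean_E1[bind] <- 0.8; mean_E2[bind] <- 0.8
  noise <- probe_class == "noise"
  base <- stats::runif(sum(noise), 0.1, 0.9)
  mean_F[noise] <- base; mean_E1[noise] <- base
  mean_E2[noise] <- base; mean_NL[noise] <- base

  conc <- ifelse(probe_class == "noise", config$concentration_noise,
                 config$concentration_informative)
  cluster_of <- ifelse(is.na(samples$cluster), "postchemo", samples$cluster)
  mean_mat <- cbind(F = mean_F, E1 = mean_E1, E2 = mean_E2, NL = mean_NL,
                    postchemo = pmin(mean_E1 + 0.05, 0.99))
  beta <- matrix(0, config$n_probes, ns,
                 dimnames = list(probe_id, samples$sample_id))
  for (j in seq_len(ns)) {
    m <- mean_mat[, cluster_of[j]]
    beta[, j] <- stats::rbeta(config$n_probes, m * conc, (1 - m) * conc)
  }

  # manifest annotations: informative probes always eligible; a slice of the
  # noise probes is placed on chrX or in shelf/open-sea regions
  chrom <- sample(paste0("chr", 1:22), config$n_probes, replace = TRUE)
  cgi <- sample(c("Island", "N_Shore", "S_Shore"), config$n_probes,
                replace = TRUE, prob = c(0.6, 0.2, 0.2))
  featcat <- sample(c("Promoter_Associated", "Promoter_Associated_Cell_type_specific"),
                    config$n_probes, replace = TRUE, prob = c(0.8, 0.2))
  gene_region <- rep("promoter", config$n_probes)
  noise_idx <- which(noise)
  n_x <- round(config$frac_chrx * length(noise_idx))
  x_idx <- noise_idx[seq_len(n_x)]
  chrom[x_idx] <- "chrX"
  rest <- setdiff(noise_idx, x_idx)
  n_nc <- round(config$frac_noncore_cgi * length(noise_idx))
  nc_idx <- rest[seq_len(min(n_nc, length(rest)))]
  cgi[nc_idx] <- sample(c("S_Shelf", "N_Shelf", "OpenSea"), length(nc_idx),
                        replace = TRUE)
  featcat[idx_bind] <- "other"
  gene_region[idx_bind] <- "body"
  cgi[idx_bind] <- "OpenSea"

  # binding-region intervals on chr20: 5 probes per 2-kb interval
  n_iv <- ceiling(n_bind / 5)
  iv_start <- sort(sample.int(6e7, n_iv)) + (0:(n_iv - 1)) * 1e5
  binding_regions <- data.frame(chrom = "chr20", start = iv_start,
                                end = iv_start + 2000)
  position <- sample.int(2e8, config$n_probes, replace = TRUE)
  for (i in seq_len(n_bind)) {
    iv <- ((i - 1) %/% 5) + 1
    chrom[idx_bind[i]] <- "chr20"
    position[idx_bind[i]] <- binding_regions$start[iv] + 100 * ((i - 1) %% 5) + 50
  }

  manifest <- data.frame(probe_id = probe_id, chromosome = chrom,
                         position = position, feature_category = featcat,
                         cgi_relation = cgi, gene_region = gene_region,
                         stringsAsFactors = FALSE)
  manifest$gene_symbols <- I(as.list(gene_link))
  class(manifest) <- c("probe_manifest", "data.frame")

  truth_probes <- data.frame(probe_id = probe_id, class = probe_class,
                             informative = probe_class != "noise",
                             gene = gene_link, mean_F = mean_F,
                             mean_E1 = mean_E1, mean_E2 = mean_E2,
                             mean_NL = mean_NL,
                             in_binding_region = bind,
                             stringsAsFactors = FALSE)
  list(beta = beta, manifest = manifest,
       truth = list(samples = samples, probes = truth_probes,
                    binding_regions = binding_regions))
}

#' Simulate a truth-labelled variant-call cohort
#'
#' Emits a call table in the filter's input dialect with three truth classes:
#' somatic calls (VAF in \[0.05, 0.35), passing quality), germline calls
#' (VAF near 0.5 in copy-neutral regions, near 1/3 or 2/3 in CN-gained
#' regions, shifted towards 1 under LOH; mostly SNP-database-listed; a small
#' fraction with >= 10 COSMIC solid-tumour mentions), artifact calls (each
#' violating exactly one primary criterion), and TERT-promoter calls at
#' depth ~10 inside the special window. Every call also carries an expected
#' verdict computed by [expected_verdict()], an independent transcription of
#' the published filtering rules kept separate from the filter code so it can
#' serve as a true oracle.
#'
#' @param config a [simulation_config()].
#' @return `variant_table` with truth columns `truth_class`,
#'   `germline_confirmed`, `expected_label`.
#' @export
simulate_variant_cohort <- function(config = simulation_config()) {
  set.seed(config$seed)
  base_call <- function(n) {
    depth <- sample(120:600, n, replace = TRUE)
    data.frame(
      sample_id = sprintf("HBL%03d", sample.int(40, n, replace = TRUE)),
      chrom = sample(paste0("chr", 1:22), n, replace = TRUE),
      pos = sample.int(2e8, n, replace = TRUE),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      depth = depth,
      mapq = round(stats::runif(n, 25, 60), 1),
      baseq = round(stats::runif(n, 18, 40), 1),
      ebcall_p = 10^-stats::runif(n, 25, 80),
      consequence = sample(c("nonsilent_exonic", "splice_site"), n,
                           replace = TRUE, prob = c(0.8, 0.2)),
      gene = sample(c("CTNNB1", "APC", "DST", "PEG10", "PTPRO",
                      sprintf("G%04d", 1:50)), n, replace = TRUE),
      truncating = stats::runif(n) < 0.2,
      stringsAsFactors = FALSE
    )
  }
  finish_reads <- function(df, vaf) {
    alt <- pmax(5L, as.integer(ceiling(vaf * df$depth)))
    df$alt_reads <- alt
    df$ref_reads <- df$depth - alt
    df$vaf <- alt / df$depth
    df$strand_alt_fwd <- pmin(pmax(stats::rbinom(nrow(df), alt, 0.5), 1L), alt - 1L)
    df$strand_ref_fwd <- stats::rbinom(nrow(df), df$ref_reads, 0.5)
    df
  }

  # --- somatic ---
  ns <- config$n_somatic
  som <- base_call(ns)
  som$cn_state <- sample(c("neutral", "gain", "other"), ns, replace = TRUE,
                         prob = c(0.6, 0.25, 0.15))
  som$loh <- stats::runif(ns) < 0.2
  vaf <- stats::runif(ns, 0.05, 0.345)
  fix <- som$cn_state == "gain" & !som$loh & vaf >= 0.245
  vaf[fix] <- stats::runif(sum(fix), 0.05, 0.24)
  som <- finish_reads(som, vaf)
  som$in_snp_db <- FALSE
  som$cosmic_solid_mentions <- stats::rpois(ns, 0.3) +
    ifelse(stats::runif(ns) < 0.1, sample(10:40, ns, replace = TRUE), 0L)
  som$truth_class <- "somatic"
  som$germline_confirmed <- FALSE

  # --- germline ---
  ng <- config$n_germline
  ger <- base_call(ng)
  ger$cn_state <- sample(c("neutral", "gain", "other"), ng, replace = TRUE,
                         prob = c(1 - 0.2 - config$germline_other_cn_rate, 0.2,
                                  config$germline_other_cn_rate))
  ger$loh <- stats::runif(ng) < config$germline_loh_rate
  vaf <- numeric(ng)
  neu <- ger$cn_state == "neutral" & !ger$loh
  vaf[neu] <- pmin(pmax(stats::rnorm(sum(neu), 0.5, 0.02), 0.40), 0.60)
  gai <- ger$cn_state == "gain" & !ger$loh
  vaf[gai] <- sample(c(1 / 3, 2 / 3), sum(gai), replace = TRUE) +
    stats::rnorm(sum(gai), 0, 0.015)
  oth <- !neu & !gai
  vaf[oth] <- stats::runif(sum(oth), 0.55, 0.95)  # LOH / complex CN shift
  ger <- finish_reads(ger, pmin(vaf, 0.98))
  ger$in_snp_db <- stats::runif(ng) < config$snp_db_rate
  ger$cosmic_solid_mentions <-
    ifelse(stats::runif(ng) < config$cosmic_rescue_rate,
           sample(10:30, ng, replace = TRUE), stats::rpois(ng, 0.1))
  # a few canonical germline APC truncating + missense calls
  napc <- min(5L, ng)
  ger$gene[seq_len(napc)] <- "APC"
  ger$truncating[seq_len(napc)] <- c(TRUE, TRUE, TRUE, FALSE, FALSE)[seq_len(napc)]
  ger$in_snp_db[seq_len(napc)] <- TRUE
  ger$cosmic_solid_mentions[seq_len(napc)] <- 0L
  ger$truth_class <- "germline"
  ger$germline_confirmed <- TRUE

  # --- artifacts: one primary criterion broken per call ---
  na <- config$n_artifact_per_rule
  arts <- list()
  breakers <- list(
    function(d) { d$mapq <- 19; d },
    function(d) { d$baseq <- 14; d },
    function(d) { d$consequence <- "silent"; d },
    function(d) { d$strand_alt_fwd <- d$alt_reads; d },
    function(d) { d$depth <- 99L
                  d$alt_reads <- pmax(5L, as.integer(round(0.2 * 99)))
                  d$ref_reads <- d$depth - d$alt_reads
                  d$vaf <- d$alt_reads / d$depth
                  d$strand_alt_fwd <- pmax(1L, d$alt_reads %/% 2L); d },
    function(d) { d$ref_reads <- 4L
                  d$depth <- d$alt_reads + 4L
                  d$vaf <- d$alt_reads / d$depth; d },
    function(d) { d$depth <- 400L
                  d$alt_reads <- 12L; d$ref_reads <- 388L
                  d$vaf <- 0.03
                  d$strand_alt_fwd <- 6L; d },
    function(d) { d$ebcall_p <- 1e-19; d }
  )
  if (na > 0) {
    for (b in breakers) {
      d <- base_call(na)
      d$cn_state <- "other"; d$loh <- FALSE
      d <- finish_reads(d, stats::runif(na, 0.1, 0.2))
      d$in_snp_db <- FALSE
      d$cosmic_solid_mentions <- 0L
      d <- b(d)
      d$truth_class <- "artifact"
      d$germline_confirmed <- NA
      arts[[length(arts) + 1]] <- d
    }
  }
  art <- if (length(arts)) do.call(rbind, arts) else NULL

  # --- TERT promoter: low depth, inside the window ---
  nt <- config$n_tert
  tert <- NULL
  if (nt > 0) {
    tert <- base_call(nt)
    tert$chrom <- "chr5"
    tert$pos <- sample(1295105:1295353, nt, replace = TRUE)
    tert$depth <- sample(8:14, nt, replace = TRUE)
    tert$alt_reads <- pmax(2L, as.integer(round(tert$depth * 0.4)))
    tert$ref_reads <- tert$depth - tert$alt_reads
    tert$vaf <- tert$alt_reads / tert$depth
    tert$strand_alt_fwd <- pmax(1L, tert$alt_reads %/% 2L)
    tert$strand_ref_fwd <- tert$ref_reads %/% 2L
    tert$ebcall_p <- 10^-stats::runif(nt, 5, 9)
    tert$consequence <- "promoter"
    tert$gene <- "TERT"
    tert$cn_state <- "neutral"; tert$loh <- FALSE
    tert$in_snp_db <- FALSE; tert$cosmic_solid_mentions <- 0L
    tert$truth_class <- "somatic"
    tert$germline_confirmed <- FALSE
  }

  calls <- rbind(som, ger, art, tert)
  rownames(calls) <- NULL
  ev <- expected_verdict(calls)
  calls$expected_label <- ev$label
  calls$expected_codes <- ev$codes
  class(calls) <- c("variant_table", "data.frame")
  calls
}

#' Independent transcription of the filtering rules (oracle)
#'
#' A deliberately literal, per-call restatement of the published filter used
#' as a truth oracle for the vectorised implementation in
#' [filter_variants()]: the two are written independently and tests require
#' 100\% agreement on simulated cohorts.
#'
#' @param calls a `variant_table`.
#' @param config a [default_config()].
#' @return list of character vectors `label` and `codes`.
#' @export
expected_verdict <- function(calls, config = default_config()) {
  f <- config$filter; tw <- config$tert
  n <- nrow(calls)
  label <- character(n); codes <- character(n)
  for (i in seq_len(n)) {
    c_i <- calls[i, ]
    fails <- character(0)
    chk <- function(val, ok, code) {
      if (any(is.na(val))) paste0(code, "_MISSING")
      else if (!ok) code
      else NULL
    }
    fails <- c(fails, chk(c_i$mapq, isTRUE(c_i$mapq >= f$min_mapq), "P1_MAPQ"))
    fails <- c(fails, chk(c_i$baseq, isTRUE(c_i$baseq >= f$min_baseq), "P2_BASEQ"))
    fails <- c(fails, chk(c_i$consequence,
                          isTRUE(c_i$consequence %in% c("nonsilent_exonic", "splice_site")),
                          "P3_CONSEQUENCE"))
    strand_bad <- isTRUE(c_i$strand_alt_fwd == 0) ||
      isTRUE(c_i$strand_alt_fwd == c_i$alt_reads)
    fails <- c(fails, chk(c(c_i$strand_alt_fwd, c_i$alt_reads), !strand_bad,
                          "P4_STRAND"))
    fails <- c(fails, chk(c_i$depth, isTRUE(c_i$depth >= f$min_depth), "P5_DEPTH"))
    fails <- c(fails, chk(c(c_i$ref_reads, c_i$alt_reads),
                          isTRUE(c_i$ref_reads >= f$min_reads) &&
                            isTRUE(c_i$alt_reads >= f$min_reads), "P6_READS"))
    fails <- c(fails, chk(c_i$vaf, isTRUE(c_i$vaf >= f$min_vaf), "P7_VAF"))
    fails <- c(fails, chk(c_i$ebcall_p, isTRUE(c_i$ebcall_p < f$max_ebcall_p),
                          "P8_EBCALL"))
    if (length(fails) == 0) {
      is_germ <- FALSE; gcodes <- character(0)
      if (isTRUE(c_i$in_snp_db)) { is_germ <- TRUE; gcodes <- c(gcodes, "G1_SNP_DB") }
      if (isTRUE(c_i$vaf >= f$vaf_neutral) && isTRUE(c_i$cn_state == "neutral") &&
          !isTRUE(c_i$loh)) { is_germ <- TRUE; gcodes <- c(gcodes, "G2_VAF_NEUTRAL") }
      if (isTRUE(c_i$vaf >= f$vaf_gain) && isTRUE(c_i$cn_state == "gain") &&
          !isTRUE(c_i$loh)) { is_germ <- TRUE; gcodes <- c(gcodes, "G3_VAF_GAIN") }
      if (is_germ && isTRUE(c_i$cosmic_solid_mentions >= f$cosmic_rescue)) {
        is_germ <- FALSE; gcodes <- c(gcodes, "G4_COSMIC_RESCUE")
      }
      label[i] <- if (is_germ) "germline" else "somatic"
      codes[i] <- paste(gcodes, collapse = ";")
    } else {
      label[i] <- "rejected"
      codes[i] <- paste(fails, collapse = ";")
    }
    # TERT promoter path overrides
    if (isTRUE(c_i$chrom == tw$chrom) && isTRUE(c_i$pos >= tw$start) &&
        isTRUE(c_i$pos <= tw$end) && isTRUE(c_i$ebcall_p < tw$max_ebcall_p)) {
      label[i] <- "somatic"
      codes[i] <- if (codes[i] == "") "TERT_WINDOW"
                  else paste("TERT_WINDOW", codes[i], sep = ";")
    }
  }
  list(label = label, codes = codes)
}

#' Simulate an expression cohort matched to methylation truth labels
#'
#' Negative-binomial counts with gene-specific means, library-size factors
#' drawn log-uniformly, and implanted log2 fold changes between cluster F and
#' clusters E1/E2 for the DE gene block — including the designated NQO1-like
#' and ODC1-like genes upregulated in E1/E2. Also returns an FPKM table and
#' rs1800566 allele read counts drawn per simulated genotype (C/C, C/T, T/T).
#'
#' @param config a [simulation_config()].
#' @param labels the `truth$samples` data.frame from
#'   [simulate_methylation_cohort()] (columns `sample_id`, `cluster`).
#' @return list: `counts`, `fpkm`, `alleles` (sample, genotype, Nc, Nt),
#'   `truth` (gene-level truth with `is_de` and true `log2fc`),
#'   `size_factors_true`.
#' @export
simulate_expression_cohort <- function(config = simulation_config(), labels) {
  set.seed(config$seed + 1L)
  if (!all(c("sample_id", "cluster") %in% names(labels))) {
    stop("labels must carry sample_id and cluster columns")
  }
  labels <- labels[!is.na(labels$cluster), , drop = FALSE]
  ns <- nrow(labels)
  genes <- c(sprintf("G%04d", seq_len(config$n_genes)), config$starburst_genes)
  ngene <- length(genes)
  n_de <- ceiling(config$de_fraction * config$n_genes)
  is_de <- c(seq_len(config$n_genes) <= n_de,
             rep(TRUE, length(config$starburst_genes)))
  base_mean <- stats::rlnorm(ngene, meanlog = log(100), sdlog = 1)
  l2fc <- numeric(ngene)
  if (n_de > 0) {
    l2fc[seq_len(n_de)] <- sample(c(-1, 1), n_de, replace = TRUE) *
      pmax(stats::rnorm(n_de, config$log2fc_mean, config$log2fc_sd), 0.5)
  }
  l2fc[config$n_genes + seq_along(config$starburst_genes)] <- config$starburst_log2fc
  # a slice of genes separates normal liver from tumour cluster F
  nl_l2fc <- numeric(ngene)
  nl_idx <- sample.int(ngene, round(0.1 * ngene))
  nl_l2fc[nl_idx] <- sample(c(-1.5, 1.5), length(nl_idx), replace = TRUE)

  sf <- exp(stats::runif(ns, log(config$libsize_range[1]),
                         log(config$libsize_range[2])))
  names(sf) <- labels$sample_id
  in_e <- labels$cluster %in% c("E1", "E2")
  is_nl <- labels$cluster == "NL"
  mu <- outer(base_mean, rep(1, ns))
  mu[, in_e] <- mu[, in_e, drop = FALSE] * 2^l2fc
  mu[, is_nl] <- mu[, is_nl, drop = FALSE] * 2^nl_l2fc
  mu <- sweep(mu, 2L, sf, "*")
  counts <- matrix(stats::rnbinom(ngene * ns, mu = mu, size = 1 / config$dispersion),
                   ngene, ns, dimnames = list(genes, labels$sample_id))

  gene_length_kb <- stats::runif(ngene, 0.5, 10)
  lib_millions <- colSums(counts) / 1e6
  fpkm <- sweep(counts / gene_length_kb, 2L, lib_millions, "/")

  tumour <- labels$sample_id[!is_nl]
  geno <- sample(names(config$genotype_probs), length(tumour), replace = TRUE,
                 prob = config$genotype_probs)
  depth <- pmax(1L, stats::rpois(length(tumour), config$allele_depth))
  nc <- ifelse(geno == "CC", depth,
               ifelse(geno == "TT", 0L, stats::rbinom(length(tumour), depth, 0.5)))
  alleles <- data.frame(sample_id = tumour, genotype = geno,
                        Nc = as.integer(nc), Nt = as.integer(depth - nc),
                        stringsAsFactors = FALSE)
  truth <- data.frame(gene = genes, base_mean = base_mean, is_de = is_de,
                      log2fc = l2fc, nl_log2fc = nl_l2fc,
                      gene_length_kb = gene_length_kb, stringsAsFactors = FALSE)
  list(counts = counts, fpkm = fpkm, alleles = alleles, truth = truth,
       size_factors_true = sf)
}

#' Simulate cluster-dependent survival
#'
#' Exponential event times with a per-cluster hazard and independent
#' exponential censoring whose hazard is chosen so the expected censored
#' fraction equals `censoring_rate` (rate 1 censors everything at time 0,
#' rate 0 censors nothing). Under the EFS endpoint, a per-cluster fraction of
#' patients fails to achieve remission and is scored as an event on day 0.
#'
#' @param labels data.frame with `sample_id` and `cluster` (NL rows ignored).
#' @param config a [simulation_config()].
#' @param endpoint `"OS"` or `"EFS"`.
#' @return data.frame of survival records: `sample_id`, `endpoint`, `time`
#'   (days), `event`, `group`.
#' @export
simulate_survival <- function(labels, config = simulation_config(),
                              endpoint = c("OS", "EFS")) {
  endpoint <- match.arg(endpoint)
  set.seed(config$seed + 2L)
  labels <- labels[!is.na(labels$cluster) & labels$cluster %in% names(config$hazard), ]
  if (any(config$hazard < 0)) stop("hazards must be non-negative")
  n <- nrow(labels)
  hz <- config$hazard[labels$cluster]
  t_event <- stats::rexp(n, rate = hz)
  cr <- config$censoring_rate
  if (cr >= 1) {
    t_cens <- rep(0, n)
  } else if (cr <= 0) {
    t_cens <- rep(Inf, n)
  } else {
    t_cens <- stats::rexp(n, rate = hz * cr / (1 - cr))
  }
  time <- pmin(t_event, t_cens)
  event <- t_event <= t_cens
  if (endpoint == "EFS") {
    pr <- config$p_remission_failure[labels$cluster]
    rf <- stats::runif(n) < pr
    time[rf] <- 0
    event[rf] <- TRUE
  }
  data.frame(sample_id = labels$sample_id, endpoint = endpoint,
             time = time, event = event, group = labels$cluster,
             stringsAsFactors = FALSE)
}
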