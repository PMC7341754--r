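#' Select the most variable promoter-associated probes
#'
#' Eligibility follows the clustering protocol: probes annotated
#' `Promoter_Associated` or `Promoter_Associated_Cell_type_specific`,
#' designed in `Island`, `N_Shore` or `S_Shore` regions, on autosomes.
#' Eligible probes are ranked by the sample standard deviation of their beta
#' values (denominator n-1) and the top `n` are returned; ties are broken by
#' probe id in lexicographic order so the selection is reproducible.
#'
#' @param beta probes x samples beta matrix.
#' @param manifest a `probe_manifest`.
#' @param n number of probes to select.
#' @return character vector of `n` probe ids, ordered by decreasing SD.
#' @export
select_variable_promoter_probes <- function(beta, manifest, n) {
  elig <- eligible_probes(manifest)
  elig <- intersect(elig, rownames(beta))
  if (n > length(elig)) {
    stop(sprintf("requested %d probes but only %d are eligible (promoter-associated, Island/N_Shore/S_Shore, autosomal)",
                 n, length(elig)))
  }
  sub <- beta[elig, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  ord <- order(-sds, rownames(sub))
  rownames(sub)[ord][seq_len(n)]
}

eligible_probes <- function(manifest) {
  autosome <- manifest$chromosome %in% paste0("chr", 1:22)
  promoter <- manifest$feature_category %in%
    c("Promoter_Associated", "Promoter_Associated_Cell_type_specific")
  cgi <- manifest$cgi_relation %in% c("Island", "N_Shore", "S_Shore")
  manifest$probe_id[autosome & promoter & cgi]
}

#' Consensus clustering by sample subsampling
#'
#' Resampling-based clustering stability: at each of `n_iter` iterations a
#' fraction of the samples is drawn without replacement, the subsample is
#' clustered by agglomerative clustering (Euclidean distance or 1 - Pearson
#' correlation; average linkage) and cut at each `k`; the consensus index of a
#' sample pair is the number of times it co-clustered divided by the number of
#' times it was co-subsampled. Because probes are never subsampled, the full
#' pairwise sample distance matrix is computed once and subset per iteration,
#' which is exactly equivalent to recomputing it per subsample.
#'
#' Final assignments at each `k` come from agglomerative clustering of
#' `1 - consensus`. Cumulative distribution functions of the consensus
#' entries and relative delta-areas summarise stability across `k`.
#'
#' @param beta probes x samples matrix (already restricted to the selected
#'   probe space).
#' @param k_range integer vector of cluster numbers, within `[2, n_samples-1]`.
#' @param n_iter number of subsampling iterations (study value: 1000).
#' @param distance `"euclidean"` or `"pearson"`.
#' @param subsample fraction of samples drawn per iteration.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @param seed optional integer seed for the subsampling stream.
#' @return object of class `"consensus_result"`: per-k consensus matrices,
#'   CDF table, delta-areas, per-k assignments, and the parameters used.
#' @export
consensus_cluster <- function(beta, k_range = 2:5, n_iter = 1000,
                              distance = c("euclidean", "pearson"),
                              subsample = 0.8, linkage = "average",
                              seed = NULL) {
  distance <- match.arg(distance)
  n <- ncol(beta)
  if (n < 2) stop("consensus clustering needs at least 2 samples")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1)) {
    stop("k_range must lie within [2, n_samples - 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  D <- sample_distance(beta, distance)
  m <- max(2L, floor(subsample * n))
  ids <- colnames(beta)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))

  co_sampled <- matrix(0, n, n)
  co_clustered <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_clustered) <- as.character(k_range)
  for (it in seq_len(n_iter)) {
    idx <- sort(sample.int(n, m))
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
    h <- stats::hclust(stats::as.dist(D[idx, idx]), method = linkage)
    for (k in k_range) {
      if (k >= m) next
      ct <- stats::cutree(h, k = k)
      same <- outer(ct, ct, "==")
      kk <- as.character(k)
      co_clustered[[kk]][idx, idx] <- co_clustered[[kk]][idx, idx] + same
    }
  }
  off <- upper.tri(co_sampled)
  if (any(co_sampled[off] == 0)) {
    stop("some sample pairs were never co-subsampled; increase n_iter")
  }
  consensus <- lapply(co_clustered, function(M) {
    C <- M / pmax(co_sampled, 1)
    diag(C) <- 1
    dimnames(C) <- list(ids, ids)
    C
  })
  assignments <- lapply(k_range, function(k) {
    C <- consensus[[as.character(k)]]
    h <- stats::hclust(stats::as.dist(1 - C), method = linkage)
    ct <- stats::cutree(h, k = k)
    names(ct) <- ids
    ct
  })
  names(assignments) <- as.character(k_range)
  cdf <- consensus_cdf(consensus)
  areas <- vapply(consensus, cdf_area, numeric(1))
  delta <- relative_delta_area(areas, k_range)
  structure(list(consensus = consensus, assignments = assignments,
                 cdf = cdf, area = areas, delta_area = delta,
                 k_range = k_range,
                 params = list(n_iter = n_iter, subsample = subsample,
                               distance = distance, linkage = linkage,
                               seed = seed)),
            class = "consensus_result")
}

sample_distance <- function(beta, distance) {
  if (distance == "euclidean") {
    as.matrix(stats::dist(t(beta), method = "euclidean"))
  } else {
    1 - stats::cor(beta, method = "pearson")
  }
}

consensus_cdf <- function(consensus, grid = seq(0, 1, by = 0.01)) {
  do.call(rbind, lapply(names(consensus), function(k) {
    x <- consensus[[k]][upper.tri(consensus[[k]])]
    data.frame(k = as.integer(k), consensus_index = grid,
               cdf = stats::ecdf(x)(grid))
  }))
}

cdf_area <- function(C, grid = seq(0, 1, by = 0.01)) {
  x <- C[upper.tri(C)]
  cdf <- stats::ecdf(x)(grid)
  sum(diff(grid) * cdf[-length(cdf)])
}

relative_delta_area <- function(areas, k_range) {
  delta <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    delta[i] <- if (i == 1) areas[i] else (areas[i] - areas[i - 1]) / areas[i - 1]
  }
  names(delta) <- as.character(k_range)
  delta
}

#' Choose the number of clusters from consensus CDFs
#'
#' Returns the `k` maximising the relative delta-area of the consensus CDF,
#' mirroring the visual elbow read off CDF plots. Confidence in the chosen k
#' is judged by the proportion of ambiguous consensus entries (PAC) of its
#' consensus matrix: structureless data leave most entries between the PAC
#' limits, and the choice is flagged low-confidence when the PAC exceeds
#' `pac_flag`. An `override` always wins (the study chose k visually).
#'
#' @param result a `"consensus_result"`.
#' @param override optional manually chosen k.
#' @param pac_flag PAC above which the chosen k is flagged low-confidence.
#' @param pac_limits consensus-index interval counted as ambiguous.
#' @return list with `k`, logical `low_confidence`, and `pac`.
#' @export
choose_k <- function(result, override = NULL, pac_flag = 0.2,
                     pac_limits = c(0.1, 0.9)) {
  stopifnot(inherits(result, "consensus_result"))
  if (is.null(override)) {
    if (length(result$k_range) < 2) stop("choose_k needs at least 2 candidate k")
    best <- result$k_range[which.max(result$delta_area)]
  } else {
    best <- as.integer(override)
  }
  pac <- pac_score(result$consensus[[as.character(best)]], pac_limits)
  list(k = best, low_confidence = pac > pac_flag, pac = pac)
}

#' Two-step methylation clustering: F versus E, then E1 versus E2
#'
#' Reproduces the published protocol on biopsy samples only. Step 1 selects
#' the top 3000 eligible promoter probes by SD and runs consensus clustering
#' with Euclidean distance at k = 2; the cluster with the lower mean beta over
#' the selected probes is labelled F (fetal-like, hypomethylated), the other
#' E. Step 2 recomputes probe SDs within the E samples, selects the top 1000
#' probes, and clusters the E samples with Pearson-correlation distance at
#' k = 2 into E1 and E2 (E1 = lower mean beta over the step-2 probes, a
#' deterministic naming convention). Cluster-stability confidence is measured
#' by the proportion of ambiguous consensus entries (PAC).
#'
#' @param beta probes x samples beta matrix (all samples; non-biopsy samples
#'   are dropped internally).
#' @param manifest a `probe_manifest`.
#' @param sample_type character vector aligned with `colnames(beta)`;
#'   only `"biopsy"` samples are clustered.
#' @param config a [default_config()] object (section `clustering`).
#' @param seed integer seed for the subsampling streams.
#' @return list with `labels` (named character vector in `{F, E1, E2}` or
#'   `{F, E}` when step 2 is skipped), the step-1/step-2
#'   `consensus_result`s, the probe sets used, and confidence flags.
#' @export
two_step_cluster <- function(beta, manifest, sample_type,
                             config = default_config(), seed = 1L) {
  cc <- config$clustering
  stopifnot(length(sample_type) == ncol(beta))
  biopsy <- sample_type == "biopsy"
  if (sum(biopsy) < 4) stop("need at least 4 biopsy samples")
  b <- beta[, biopsy, drop = FALSE]

  probes1 <- select_variable_promoter_probes(b, manifest, cc$step1_n)
  step1 <- consensus_cluster(b[probes1, , drop = FALSE], k_range = 2,
                             n_iter = cc$n_iter, distance = cc$step1_distance,
                             subsample = cc$subsample, linkage = cc$linkage,
                             seed = seed)
  a1 <- step1$assignments[["2"]]
  mean_by <- tapply(colMeans(b[probes1, , drop = FALSE]), a1, mean)
  f_cluster <- as.integer(names(mean_by)[which.min(mean_by)])
  labels <- ifelse(a1 == f_cluster, "F", "E")
  names(labels) <- names(a1)
  step1_pac <- pac_score(step1$consensus[["2"]], cc$pac_limits)
  flags <- list(step1_low_confidence = step1_pac > cc$pac_flag,
                step2_skipped = FALSE)

  e_ids <- names(labels)[labels == "E"]
  step2 <- NULL; probes2 <- NULL
  if (length(e_ids) < 4) {
    flags$step2_skipped <- TRUE
  } else {
    be <- b[, e_ids, drop = FALSE]
    probes2 <- select_variable_promoter_probes(be, manifest, cc$step2_n)
    step2 <- consensus_cluster(be[probes2, , drop = FALSE], k_range = 2,
                               n_iter = cc$n_iter, distance = cc$step2_distance,
                               subsample = cc$subsample, linkage = cc$linkage,
                               seed = seed + 1L)
    a2 <- step2$assignments[["2"]]
    if (min(table(a2)) < 2) stop("step-2 cluster size < 2; E-side structure too weak")
    m2 <- tapply(colMeans(be[probes2, , drop = FALSE]), a2, mean)
    e1_cluster <- as.integer(names(m2)[which.min(m2)])
    labels[e_ids] <- ifelse(a2[e_ids] == e1_cluster, "E1", "E2")
  }
  list(labels = labels, step1 = step1, step2 = step2,
       probes_step1 = probes1, probes_step2 = probes2, flags = flags)
}

# proportion of ambiguous consensus entries, a standard stability score
pac_score <- function(C, limits = c(0.1, 0.9)) {
  x <- C[upper.tri(C)]
  mean(x > limits[1] & x < limits[2])
}

#' Per-probe differential methylation between two groups
#'
#' Fits a two-group linear model per probe on the beta values (equivalent to
#' a pooled-variance two-sample t test), reports the group-mean difference
#' `delta_beta = mean(group2) - mean(group1)`, and adjusts p values across
#' probes by Benjamini-Hochberg. Probes with zero pooled variance report an
#' infinite statistic with p -> 0 (flagged) when the means differ, or p = 1
#' when the groups are identical.
#'
#' @param beta probes x samples matrix.
#' @param groups two-level factor (or coercible) aligned with samples; the
#'   first level is group1, the second group2.
#' @return data.frame of class `"diffmeth_result"` sorted by adjusted p:
#'   `probe_id`, `delta_beta`, `t`, `df`, `pvalue`, `padj`, `zero_variance`.
#' @export
differential_methylation <- function(beta, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("differential_methylation needs exactly two groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  st <- row_t_stats(beta, groups)
  padj <- stats::p.adjust(st$pvalue, method = "BH")
  out <- data.frame(probe_id = rownames(beta), delta_beta = st$delta,
                    t = st$t, df = st$df, pvalue = st$pvalue, padj = padj,
                    zero_variance = st$zero_variance,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$padj, out$pvalue, out$probe_id), ]
  rownames(out) <- NULL
  class(out) <- c("diffmeth_result", "data.frame")
  out
}

# vectorised pooled-variance two-sample t statistics for each matrix row;
# delta = mean(level2) - mean(level1)
row_t_stats <- function(mat, groups) {
  l <- levels(groups)
  i1 <- groups == l[1]; i2 <- groups == l[2]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  v1 <- rowSums((mat[, i1, drop = FALSE] - m1)^2)
  v2 <- rowSums((mat[, i2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (v1 + v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  delta <- m2 - m1
  zero_var <- se == 0
  t <- ifelse(zero_var, ifelse(delta == 0, 0, sign(delta) * Inf), delta / se)
  p <- ifelse(zero_var & delta == 0, 1, 2 * stats::pt(-abs(t), df))
  list(delta = delta, t = t, df = df, pvalue = p,
       zero_variance = zero_var & delta != 0)
}

#' Top differentially methylated probes by direction
#'
#' Reporting helper for the "top 2000" convention: the `n` lowest-adjusted-p
#' probes among those hypermethylated (`delta_beta > 0`) or hypomethylated
#' (`delta_beta < 0`) in group2.
#'
#' @param result a `"diffmeth_result"`.
#' @param n number of probes.
#' @param direction `"hyper"` or `"hypo"` (relative to group2).
#' @return character vector of probe ids.
#' @export
top_diffmeth_probes <- function(result, n = 2000,
                                direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  sub <- if (direction == "hyper") result[result$delta_beta > 0, ]
         else result[result$delta_beta < 0, ]
  utils::head(sub$probe_id, n)
}

#' Region-set enrichment of a probe list (one-sided Fisher exact)
#'
#' For each named interval set, probes are located by their manifest
#' positions and counted inside/outside the set for the query and for the
#' rest of the universe; the one-sided Fisher exact p value (enrichment
#' direction, i.e. the hypergeometric upper tail) is computed from the 2x2
#' table, the odds ratio uses a Haldane 0.5 correction when any cell is
#' zero, and q values are Benjamini-Hochberg across sets. The universe is the
#' probe set that survived upstream QC, not the genome.
#'
#' @param query_probes character vector, must be a subset of the universe.
#' @param universe_probes character vector of all tested probes.
#' @param manifest a `probe_manifest` with `position` filled in.
#' @param catalog a `region_catalog` from [read_region_sets()] (or any named
#'   list of `GRanges`).
#' @return data.frame of class `"enrichment_result"` ranked by q:
#'   `set`, `overlap`, `query_size`, `set_size`, `universe_size`,
#'   `odds_ratio`, `pvalue`, `qvalue`.
#' @export
region_set_enrichment <- function(query_probes, universe_probes, manifest,
                                  catalog) {
  if (!all(query_probes %in% universe_probes)) {
    stop("query probes must be a subset of the universe")
  }
  idx <- match(universe_probes, manifest$probe_id)
  if (anyNA(idx)) stop("universe probes missing from the manifest")
  gr <- GenomicRanges::GRanges(
    seqnames = manifest$chromosome[idx],
    ranges = IRanges::IRanges(start = manifest$position[idx], width = 1L)
  )
  N <- length(universe_probes)
  nq <- length(query_probes)
  in_query <- universe_probes %in% query_probes
  rows <- lapply(names(catalog), function(nm) {
    # sets on chromosomes absent from the universe are a legitimate
    # zero-overlap case, not worth a seqlevel warning
    hit <- suppressWarnings(GenomicRanges::countOverlaps(gr, catalog[[nm]]) > 0)
    K <- sum(hit)
    a <- sum(hit & in_query)
    p <- fisher_enrichment_p(a, K, nq, N)
    b <- nq - a; cc <- K - a; d <- N - nq - cc
    or <- if (any(c(a, b, cc, d) == 0)) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else (a * d) / (b * cc)
    data.frame(set = nm, overlap = a, query_size = nq, set_size = K,
               universe_size = N, odds_ratio = or, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$qvalue, out$pvalue, out$set), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

# one-sided Fisher exact p for enrichment: P(X >= a), X ~ Hypergeom(N, K, n)
fisher_enrichment_p <- function(a, K, n, N) {
  stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
}

#' Top enriched region sets
#'
#' Reporting helper: the `n` sets with the smallest FDR q values
#' (study convention: top 50).
#'
#' @param result an `"enrichment_result"`.
#' @param n number of sets to report.
#' @return the first `n` rows of the ranked table.
#' @export
top_enrichment <- function(result, n = 50) utils::head(result, n)
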