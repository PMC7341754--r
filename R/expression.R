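#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors from the median-of-ratios formula: the
#' reference is the per-gene geometric mean over samples (genes with any zero
#' count are excluded), and each sample's factor is the median over genes of
#' its count divided by the reference.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @return named numeric vector of positive factors, one per sample.
#' @export
size_factors_median_ratio <- function(counts) {
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) stop("no gene has nonzero counts in all samples")
  ref <- exp(rowMeans(log(counts[keep, , drop = FALSE])))
  sf <- apply(counts[keep, , drop = FALSE] / ref, 2L, stats::median)
  names(sf) <- colnames(counts)
  sf
}

#' Log-normalised expression
#'
#' `log2(count / size_factor + 1)`, the transform used for MAD ranking, PCA,
#' gene-set testing and signature scoring.
#'
#' @param counts genes x samples matrix.
#' @param size_factors per-sample factors; computed by
#'   [size_factors_median_ratio()] when omitted.
#' @return matrix of log2-normalised values.
#' @export
log_normalize <- function(counts, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(counts)
  log2(sweep(counts, 2L, size_factors, "/") + 1)
}

# per-gene method-of-moments NB dispersion on normalised counts, floored;
# no cross-gene shrinkage (documented simplification)
estimate_dispersion_mom <- function(counts, size_factors, floor = 1e-8) {
  y <- sweep(counts, 2L, size_factors, "/")
  mu <- rowMeans(y)
  v <- apply(y, 1L, stats::var)
  alpha <- (v - mu) / mu^2
  alpha[!is.finite(alpha)] <- floor
  pmax(alpha, floor)
}

#' Negative-binomial likelihood-ratio differential expression
#'
#' Per gene, a negative-binomial GLM (log link, log size factors as offset)
#' is fitted under a full and a nested reduced design with the gene-wise
#' method-of-moments dispersion held fixed across both fits; the test
#' statistic is twice the log-likelihood difference (the change in deviance),
#' compared against a chi-square with df equal to the difference in model
#' dimensions, and p values are Benjamini-Hochberg adjusted across genes.
#' For a two-group full design, `log2fc` is the log2 ratio of normalised
#' group means (pseudocount 0.5), group2 over group1. All-zero genes are
#' excluded with a flag.
#'
#' @param counts genes x samples integer matrix.
#' @param size_factors per-sample factors (computed if omitted).
#' @param full factor giving the full-design groups (2 or more levels).
#' @param reduced factor for the reduced design, or `NULL` for
#'   intercept-only; must be nested in `full`.
#' @return data.frame of class `"de_result"`: `gene`, `base_mean`, `log2fc`,
#'   `dispersion`, `stat`, `df`, `pvalue`, `padj`, `excluded`.
#' @export
nb_lrt_de <- function(counts, size_factors = NULL, full, reduced = NULL) {
  full <- droplevels(as.factor(full))
  stopifnot(length(full) == ncol(counts))
  if (any(table(full) < 2)) stop("each full-design group needs at least 2 samples")
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(counts)
  Xf <- stats::model.matrix(~full)
  Xr <- if (is.null(reduced)) stats::model.matrix(~1, data.frame(row.names = seq_along(full)))
        else stats::model.matrix(~droplevels(as.factor(reduced)))
  df_test <- ncol(Xf) - ncol(Xr)
  if (df_test < 1) stop("the full design must nest and extend the reduced design")
  off <- log(size_factors)
  alpha <- estimate_dispersion_mom(counts, size_factors)

  ngene <- nrow(counts)
  stat <- rep(NA_real_, ngene)
  excluded <- rowSums(counts) == 0
  for (g in seq_len(ngene)) {
    if (excluded[g]) next
    y <- counts[g, ]
    fam <- MASS::negative.binomial(theta = 1 / alpha[g], link = "log")
    dev_f <- nb_deviance(Xf, y, fam, off)
    dev_r <- nb_deviance(Xr, y, fam, off)
    stat[g] <- max(0, dev_r - dev_f)
  }
  p <- stats::pchisq(stat, df = df_test, lower.tail = FALSE)
  y_norm <- sweep(counts, 2L, size_factors, "/")
  base_mean <- rowMeans(y_norm)
  log2fc <- rep(NA_real_, ngene)
  if (nlevels(full) == 2) {
    l <- levels(full)
    m1 <- rowMeans(y_norm[, full == l[1], drop = FALSE])
    m2 <- rowMeans(y_norm[, full == l[2], drop = FALSE])
    log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  }
  out <- data.frame(gene = rownames(counts), base_mean = base_mean,
                    log2fc = log2fc, dispersion = alpha, stat = stat,
                    df = df_test, pvalue = p,
                    padj = stats::p.adjust(p, method = "BH"),
                    excluded = excluded,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}

nb_deviance <- function(X, y, fam, off) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam, offset = off,
                   control = stats::glm.control(maxit = 50))
  )
  fit$deviance
}

#' Gene-set testing on group-difference t statistics
#'
#' Per gene, a pooled-variance two-sample t statistic between the groups is
#' computed on log-normalised expression; per set, the mean member statistic
#' is tested against zero with a one-sample t test on the member values
#' (df = set size - 1). Two one-sided tests give the direction; the reported
#' p is twice the smaller one-sided tail (capped at 1) and q values are
#' Benjamini-Hochberg across sets. Sets with fewer than two measured members
#' are skipped with a warning.
#'
#' @param log_expr genes x samples log-normalised matrix.
#' @param groups two-level factor aligned with samples.
#' @param gene_sets named list of character vectors.
#' @return data.frame of class `"geneset_result"` ranked by q: `set`,
#'   `size`, `mean_t`, `stat`, `pvalue`, `p_up`, `p_down`, `direction`,
#'   `qvalue`.
#' @export
gene_set_test <- function(log_expr, groups, gene_sets) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("gene_set_test needs exactly two groups")
  st <- row_t_stats(log_expr, groups)
  t_gene <- st$t
  names(t_gene) <- rownames(log_expr)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], rownames(log_expr))
    m <- length(members)
    if (m < 2) {
      warning("gene set '", nm, "' has fewer than 2 measured members; skipped")
      return(NULL)
    }
    tv <- t_gene[members]
    tv <- tv[is.finite(tv)]
    m <- length(tv)
    if (m < 2) return(NULL)
    tbar <- mean(tv)
    se <- stats::sd(tv) / sqrt(m)
    stat <- if (se == 0) ifelse(tbar == 0, 0, sign(tbar) * Inf) else tbar / se
    p_up <- stats::pt(stat, df = m - 1, lower.tail = FALSE)
    p_down <- stats::pt(stat, df = m - 1, lower.tail = TRUE)
    data.frame(set = nm, size = m, mean_t = tbar, stat = stat,
               pvalue = min(1, 2 * min(p_up, p_down)),
               p_up = p_up, p_down = p_down,
               direction = ifelse(tbar >= 0, "up", "down"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no testable gene sets")
  out <- do.call(rbind, rows)
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$qvalue, out$pvalue, out$set), ]
  rownames(out) <- NULL
  class(out) <- c("geneset_result", "data.frame")
  out
}

#' Significant gene sets at an FDR cut
#'
#' @param result a `"geneset_result"`.
#' @param q FDR threshold (study convention: 0.001).
#' @return the rows with `qvalue < q`.
#' @export
significant_gene_sets <- function(result, q = 0.001) result[result$qvalue < q, ]

#' PCA on the most variable genes by MAD
#'
#' Genes are ranked by the median absolute deviation of their log-transformed
#' expression; the top `n_genes` are mean-centred per gene and sample
#' coordinates are obtained by singular value decomposition.
#'
#' @param log_expr genes x samples log-normalised matrix.
#' @param n_genes number of top-MAD genes (study value: 10000).
#' @return list with `scores` (samples x components), `variance_explained`
#'   (non-increasing, sums to 1), and `genes` used.
#' @export
pca_top_mad <- function(log_expr, n_genes = 10000) {
  if (n_genes > nrow(log_expr)) stop("n_genes exceeds the number of measured genes")
  mads <- apply(log_expr, 1L, stats::mad)
  ord <- order(-mads, rownames(log_expr))
  genes <- rownames(log_expr)[ord][seq_len(n_genes)]
  X <- t(log_expr[genes, , drop = FALSE])
  X <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- colnames(log_expr)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  ve <- sv$d^2 / sum(sv$d^2)
  list(scores = scores, variance_explained = ve, genes = genes)
}

#' Mean-expression signature score
#'
#' Per-sample mean of log-normalised expression over a gene list (used for
#' the immature-fetal-liver 250-gene signature). Listed genes absent from
#' the matrix are dropped and their number reported.
#'
#' @param log_expr genes x samples log-normalised matrix.
#' @param gene_list character vector of signature genes.
#' @return named numeric vector of per-sample scores; attribute
#'   `n_missing` counts dropped genes.
#' @export
signature_score <- function(log_expr, gene_list) {
  found <- intersect(unique(gene_list), rownames(log_expr))
  if (!length(found)) stop("none of the listed genes are measured")
  score <- colMeans(log_expr[found, , drop = FALSE])
  attr(score, "n_missing") <- length(unique(gene_list)) - length(found)
  score
}
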