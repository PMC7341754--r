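#' Gene-level promoter methylation difference
#'
#' For every gene with at least one qualifying promoter probe (annotated
#' `Promoter_Associated` or `Promoter_Associated_Cell_type_specific` and
#' linked to the gene in the manifest), the mean beta value over the
#' probe x sample block is computed per group and the difference
#' `delta_beta = mean(group2) - mean(group1)` is reported. Averaging is
#' unweighted across probes and samples. With the F-side as group1 and the
#' E-side as group2, genes hypomethylated in E1/E2 (such as NQO1) have
#' negative `delta_beta`.
#'
#' @param beta probes x samples beta matrix.
#' @param manifest a `probe_manifest` with `gene_symbols`.
#' @param groups two-level factor aligned with samples (level1 = F-side,
#'   level2 = E-side).
#' @param genes optional character vector restricting the genes summarised;
#'   defaults to every gene with a qualifying probe.
#' @return data.frame: `gene`, `n_probes`, `mean_group1`, `mean_group2`,
#'   `delta_beta`; attribute `skipped` lists requested genes without
#'   qualifying probes.
#' @export
promoter_methylation_difference <- function(beta, manifest, groups,
                                            genes = NULL) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("needs exactly two groups")
  promoter <- manifest$feature_category %in%
    c("Promoter_Associated", "Promoter_Associated_Cell_type_specific")
  man <- manifest[promoter & manifest$probe_id %in% rownames(beta), , drop = FALSE]
  map <- data.frame(
    probe_id = rep(man$probe_id, lengths(man$gene_symbols)),
    gene = unlist(man$gene_symbols),
    stringsAsFactors = FALSE
  )
  if (is.null(genes)) genes <- sort(unique(map$gene))
  l <- levels(groups)
  i1 <- groups == l[1]; i2 <- groups == l[2]
  probes_by_gene <- split(map$probe_id, map$gene)
  have <- genes %in% names(probes_by_gene)
  rows <- lapply(genes[have], function(g) {
    p <- probes_by_gene[[g]]
    block1 <- beta[p, i1, drop = FALSE]
    block2 <- beta[p, i2, drop = FALSE]
    m1 <- mean(block1); m2 <- mean(block2)
    data.frame(gene = g, n_probes = length(p), mean_group1 = m1,
               mean_group2 = m2, delta_beta = m2 - m1,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), n_probes = integer(0),
               mean_group1 = numeric(0), mean_group2 = numeric(0),
               delta_beta = numeric(0))
  attr(out, "skipped") <- genes[!have]
  out
}

#' Starburst classification of methylation-expression pairs
#'
#' Joins the gene-level promoter methylation differences with expression
#' log2 fold changes and flags genes where both `|delta_beta| >= 0.25` and
#' `|log2fc| >= 2.5` (inclusive, as printed). The quadrant combines the two
#' signs: `hypo_up` (the NQO1-like quadrant: promoter hypomethylation with
#' overexpression in E1/E2), `hyper_down`, `hypo_down`, `hyper_up`; genes
#' below either threshold get `none`. Genes missing from either table are
#' dropped and counted.
#'
#' @param meth_table data.frame with `gene` and `delta_beta` (E-side minus
#'   F-side; see [promoter_methylation_difference()]).
#' @param de_table data.frame with `gene` and `log2fc` (E-side over F-side).
#' @param meth_threshold absolute methylation-difference cutoff.
#' @param expr_threshold absolute log2-fold-change cutoff.
#' @return data.frame of class `"starburst_result"`: `gene`, `delta_beta`,
#'   `log2fc`, `flagged`, `quadrant`; attribute `n_dropped` counts genes
#'   present in only one input.
#' @export
starburst <- function(meth_table, de_table, meth_threshold = 0.25,
                      expr_threshold = 2.5) {
  joined <- merge(meth_table[, c("gene", "delta_beta")],
                  de_table[, c("gene", "log2fc")], by = "gene")
  joined <- joined[stats::complete.cases(joined), ]
  n_dropped <- length(union(meth_table$gene, de_table$gene)) - nrow(joined)
  flagged <- abs(joined$delta_beta) >= meth_threshold &
    abs(joined$log2fc) >= expr_threshold
  quadrant <- ifelse(!flagged, "none",
    paste0(ifelse(joined$delta_beta < 0, "hypo", "hyper"),
           "_",
           ifelse(joined$log2fc > 0, "up", "down")))
  out <- data.frame(gene = joined$gene, delta_beta = joined$delta_beta,
                    log2fc = joined$log2fc, flagged = flagged,
                    quadrant = quadrant, stringsAsFactors = FALSE)
  out <- out[order(-as.integer(out$flagged), out$gene), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("starburst_result", "data.frame")
  out
}

#' Spearman correlation between a probe's methylation and a gene's expression
#'
#' Rank correlation with average ranks on ties and a two-sided p value from
#' the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of
#' freedom. A constant vector leaves rho undefined (reported as `NA`).
#'
#' @param beta_row numeric vector of beta values across samples.
#' @param expr_row numeric vector of expression values, same samples.
#' @return list with `rho`, `pvalue`, `n`.
#' @export
probe_expression_correlation <- function(beta_row, expr_row) {
  keep <- !is.na(beta_row) & !is.na(expr_row)
  x <- beta_row[keep]; y <- expr_row[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, pvalue = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, pvalue = p, n = n)
}

#' Rank a gene's probes by methylation-expression correlation
#'
#' Computes the Spearman correlation of every probe linked to `gene` in the
#' manifest against the gene's expression and returns the probes sorted most
#' negative first — the convention used to single out the probe nearest the
#' NQO1 antioxidant response element (cg26598152 in the study).
#'
#' @param beta probes x samples beta matrix.
#' @param manifest a `probe_manifest`.
#' @param gene gene symbol.
#' @param expr_row the gene's expression across the same samples.
#' @return data.frame: `probe_id`, `rho`, `pvalue`, sorted by `rho`.
#' @export
rank_probes_by_correlation <- function(beta, manifest, gene, expr_row) {
  linked <- manifest$probe_id[vapply(manifest$gene_symbols,
                                     function(gs) gene %in% gs, logical(1))]
  linked <- intersect(linked, rownames(beta))
  if (!length(linked)) stop("no probes linked to gene ", gene)
  rows <- lapply(linked, function(p) {
    r <- probe_expression_correlation(beta[p, ], expr_row)
    data.frame(probe_id = p, rho = r$rho, pvalue = r$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$rho), ]
}

#' Genotype-corrected NQO1 expression
#'
#' The NQO1 C609T polymorphism (rs1800566) leaves the T allele with only a
#' few percent of wild-type enzymatic activity, so raw FPKM overstates the
#' functional NQO1 level in T-carrying samples. The corrected value scales
#' raw FPKM by the activity-weighted allele fraction at rs1800566 in the
#' RNA-seq reads:
#' \deqn{corrected = raw \times \frac{Nc + 0.03\,Nt}{Nc + Nt}}
#' where `Nc` and `Nt` are read counts carrying the C and T allele. The
#' factor is bounded in \[0.03, 1\]: 1 for C/C samples, 0.03 when every read
#' carries T.
#'
#' @param raw_fpkm non-negative expression value(s).
#' @param nc,nt C- and T-allele read counts (vectorised; `nc + nt` must be
#'   positive — an unobserved genotype is an error, not a silent pass).
#' @param t_activity residual activity of the T allele (default 0.03).
#' @return corrected FPKM value(s).
#' @export
correct_nqo1_fpkm <- function(raw_fpkm, nc, nt, t_activity = 0.03) {
  stopifnot(all(raw_fpkm >= 0), all(nc >= 0), all(nt >= 0))
  if (any(nc + nt == 0)) stop("Nc + Nt must be positive: genotype unobserved")
  raw_fpkm * (nc + t_activity * nt) / (nc + nt)
}
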