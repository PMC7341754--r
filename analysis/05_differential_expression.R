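#!/usr/bin/env Rscript
# Expression analysis of the simulated cohort: median-of-ratios size
# factors, negative-binomial likelihood-ratio differential expression
# (F versus E1/E2 and the four-group tumour/normal-liver contrast),
# gene-set testing on implanted and random sets, PCA on the most variable
# genes by MAD, and an immature-signature score.

suppressMessages(library(hbmultiomics))

counts <- read_matrix("results/cohort/counts.tsv", "counts")
samples <- read.delim("results/cohort/samples.tsv")
labels <- read.delim("results/methylation_clusters.tsv")
truth <- read.delim("results/cohort/truth_genes.tsv")

tum <- labels$sample_id
grp <- factor(ifelse(labels$cluster == "F", "F", "E"), levels = c("F", "E"))
sf <- size_factors_median_ratio(counts[, tum])

de <- nb_lrt_de(counts[, tum], sf, full = grp)
write.table(de[order(de$padj), ], "results/de_F_vs_E.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("F vs E1/E2: genes at padj < 0.001:", sum(de$padj < 0.001, na.rm = TRUE), "\n")
hits <- de$gene[!is.na(de$padj) & de$padj < 0.001 & abs(de$log2fc) > 1]
cat("recall of implanted DE genes among those hits:",
    round(mean(truth$gene[truth$is_de] %in% hits), 3), "\n")

# four-group LRT (three tumour clusters + normal liver) against intercept
all_ids <- samples$sample_id
cl <- ifelse(is.na(samples$cluster), "postchemo", samples$cluster)
keep <- cl %in% c("F", "E1", "E2", "NL")
de4 <- nb_lrt_de(counts[, all_ids[keep]], full = factor(cl[keep]))
cat("four-group LRT: genes at padj < 0.001:",
    sum(de4$padj < 0.001, na.rm = TRUE), "\n")

le <- log_normalize(counts[, tum], sf)
sets <- list(
  implanted_up = truth$gene[truth$is_de & truth$log2fc > 1][1:30],
  implanted_down = truth$gene[truth$is_de & truth$log2fc < -1][1:30],
  random = sample(truth$gene[!truth$is_de], 30)
)
gs <- gene_set_test(le, grp, sets)
write.table(gs, "results/gene_sets.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
print(gs[, c("set", "size", "mean_t", "pvalue", "qvalue", "direction")])

pc <- pca_top_mad(log_normalize(counts), min(1000, nrow(counts)))
write.table(data.frame(sample_id = rownames(pc$scores),
                       round(pc$scores[, 1:4], 3)),
            "results/pca_scores.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat("PC1/PC2 variance explained:",
    round(100 * pc$variance_explained[1:2], 1), "%\n")

sig <- signature_score(le, truth$gene[truth$is_de & truth$log2fc > 2])
by_cl <- tapply(sig[labels$sample_id], labels$cluster, mean)
cat("mean immature-signature score by cluster:\n"); print(round(by_cl, 3))
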