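#!/usr/bin/env Rscript
# Methylation-expression integration between cluster F and clusters E1/E2:
# gene-level promoter methylation differences, the starburst classification
# (|delta beta| >= 0.25 and |log2FC| >= 2.5), the most negatively
# expression-correlated probe of the top starburst hit, and genotype-
# corrected NQO1-like expression from the rs1800566 allele counts.

suppressMessages(library(hbmultiomics))

beta <- read_matrix("results/cohort/beta.tsv", "beta")
manifest <- read_probe_manifest("results/cohort/probe_manifest.tsv")
labels <- read.delim("results/methylation_clusters.tsv")
counts <- read_matrix("results/cohort/counts.tsv", "counts")
fpkm <- read_matrix("results/cohort/fpkm.tsv", "fpkm")
alleles <- read.delim("results/cohort/rs1800566_alleles.tsv")

tum <- labels$sample_id
grp <- factor(ifelse(labels$cluster == "F", "F", "E"), levels = c("F", "E"))

meth <- promoter_methylation_difference(beta[, tum], manifest, grp)
de <- nb_lrt_de(counts[, tum], full = grp)
sb <- starburst(meth, de[, c("gene", "log2fc")])
write.table(sb, "results/starburst.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat("starburst-flagged genes (delta beta = E minus F):\n")
print(sb[sb$flagged, ])

top_gene <- sb$gene[sb$flagged & sb$quadrant == "hypo_up"][1]
le <- log_normalize(counts[, tum])
corr <- rank_probes_by_correlation(beta[, tum], manifest, top_gene, le[top_gene, ])
cat(sprintf("probe most negatively correlated with %s expression: %s (rho %.3f)\n",
            top_gene, corr$probe_id[1], corr$rho[1]))

idx <- match(alleles$sample_id, colnames(fpkm))
corrected <- correct_nqo1_fpkm(fpkm[top_gene, idx], alleles$Nc, alleles$Nt)
out <- data.frame(alleles, raw_fpkm = round(fpkm[top_gene, idx], 3),
                  corrected_fpkm = round(corrected, 3))
write.table(out, "results/corrected_nqo1.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("mean corrected/raw factor by genotype:\n")
print(round(tapply(corrected / fpkm[top_gene, idx], alleles$genotype, mean), 3))
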