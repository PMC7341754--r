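#!/usr/bin/env Rscript
# Two-step consensus clustering of the biopsy samples: top-3000 SD-ranked
# promoter probes with Euclidean distance split F from E; within E, the
# top-1000 probes with Pearson-correlation distance split E1 from E2.
# Writes the labels, the consensus matrices and the CDF table, and scores
# recovery of the simulated truth.

suppressMessages(library(hbmultiomics))

beta <- read_matrix("results/cohort/beta.tsv", "beta")
manifest <- read_probe_manifest("results/cohort/probe_manifest.tsv")
samples <- read.delim("results/cohort/samples.tsv")

res <- two_step_cluster(beta, manifest, samples$sample_type, seed = 1)

labels <- data.frame(sample_id = names(res$labels), cluster = res$labels)
write.table(labels, "results/methylation_clusters.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_matrix(res$step1$consensus[["2"]], "results/consensus_step1.tsv")
if (!is.null(res$step2)) {
  write_matrix(res$step2$consensus[["2"]], "results/consensus_step2.tsv")
}
write.table(rbind(cbind(step = 1, res$step1$cdf),
                  if (!is.null(res$step2)) cbind(step = 2, res$step2$cdf)),
            "results/consensus_cdf.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("cluster sizes:\n"); print(table(res$labels))
cat("flags:", paste(names(res$flags), unlist(res$flags), collapse = "; "), "\n")
truth <- samples$cluster[match(names(res$labels), samples$sample_id)]
cat("adjusted Rand index vs simulated truth:",
    adjusted_rand_index(res$labels, truth), "\n")
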