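#!/usr/bin/env Rscript
# Generates the synthetic multiomics cohort every later step consumes:
# a methylation beta matrix with three implanted tumour clusters plus
# normal-liver controls, a matching probe manifest, a truth-labelled
# variant-call table, NB expression counts with implanted fold changes,
# rs1800566 allele counts, and sample metadata. Everything is written in
# the pipeline's TSV dialects under results/cohort/.

suppressMessages(library(hbmultiomics))

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- simulation_config(seed = 1)

meth <- simulate_methylation_cohort(cfg)
write_matrix(meth$beta, file.path(out, "beta.tsv"))

man <- meth$manifest
man$gene_symbols <- vapply(man$gene_symbols, paste, character(1), collapse = ";")
write.table(man, file.path(out, "probe_manifest.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

calls <- simulate_variant_cohort(cfg)
write.table(calls, file.path(out, "variant_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

expr <- simulate_expression_cohort(cfg, meth$truth$samples)
write_matrix(expr$counts, file.path(out, "counts.tsv"))
write_matrix(round(expr$fpkm, 4), file.path(out, "fpkm.tsv"))
write.table(expr$alleles, file.path(out, "rs1800566_alleles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

write.table(meth$truth$samples, file.path(out, "samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(meth$truth$probes, file.path(out, "truth_probes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(expr$truth, file.path(out, "truth_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# binding-region intervals as BED (0-based half-open) plus decoy sets for
# the enrichment step
bed <- meth$truth$binding_regions
write.table(data.frame(bed$chrom, bed$start, bed$end),
            file.path(out, "binding_regions.bed"),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
set.seed(2)
for (i in 1:3) {
  st <- sort(sample.int(2e8 - 2000, 30))
  write.table(data.frame(sample(paste0("chr", 1:22), 30, replace = TRUE), st, st + 2000),
              file.path(out, sprintf("decoy_regions_%d.bed", i)),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

cat(sprintf("cohort: %d samples x %d probes, %d variant calls, %d genes\n",
            ncol(meth$beta), nrow(meth$beta), nrow(calls), nrow(expr$counts)))
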