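# Builders for small in-memory fixtures shared across the test files.

# one variant call with every primary criterion passing; override any field
make_call <- function(...) {
  call <- data.frame(
    sample_id = "HBL001", chrom = "chr3", pos = 41266101,
    ref = "C", alt = "T",
    depth = 200L, ref_reads = 160L, alt_reads = 40L, vaf = 0.2,
    mapq = 50, baseq = 30,
    strand_ref_fwd = 80L, strand_alt_fwd = 20L,
    ebcall_p = 1e-30, consequence = "nonsilent_exonic",
    in_snp_db = FALSE, cosmic_solid_mentions = 0L,
    cn_state = "neutral", loh = FALSE,
    gene = "CTNNB1", truncating = FALSE,
    germline_confirmed = NA,
    stringsAsFactors = FALSE
  )
  override <- list(...)
  for (nm in names(override)) call[[nm]] <- override[[nm]]
  call
}

make_sv <- function(...) {
  sv <- data.frame(
    sample_id = "HBL001", sv_type = "translocation",
    ref_pairs = 400L, variant_pairs = 30L,
    overhang_left = 200L, overhang_right = 200L,
    affects_coding_exon = TRUE, on_mito_or_decoy = FALSE,
    stringsAsFactors = FALSE
  )
  override <- list(...)
  for (nm in names(override)) sv[[nm]] <- override[[nm]]
  sv
}

# tiny manifest: every probe promoter-associated Island on chr1 unless overridden
make_manifest <- function(probe_ids, chromosome = "chr1",
                          feature_category = "Promoter_Associated",
                          cgi_relation = "Island",
                          position = NULL, genes = NULL) {
  n <- length(probe_ids)
  if (is.null(position)) position <- seq(1000, by = 1000, length.out = n)
  df <- data.frame(
    probe_id = probe_ids,
    chromosome = rep_len(chromosome, n),
    position = position,
    feature_category = rep_len(feature_category, n),
    cgi_relation = rep_len(cgi_relation, n),
    gene_region = "promoter",
    stringsAsFactors = FALSE
  )
  if (is.null(genes)) genes <- rep("", n)
  df$gene_symbols <- I(lapply(rep_len(genes, n), function(g) {
    if (identical(g, "")) character(0) else strsplit(g, ";", fixed = TRUE)[[1]]
  }))
  class(df) <- c("probe_manifest", "data.frame")
  df
}

# beta matrix of duplicated two-block profiles: m samples per block
duplicate_beta <- function(m = 5, n_probes = 100) {
  a <- c(rep(0.2, n_probes / 2), rep(0.8, n_probes / 2))
  b <- rev(a)
  mat <- cbind(matrix(rep(a, m), n_probes, m), matrix(rep(b, m), n_probes, m))
  dimnames(mat) <- list(sprintf("cg%03d", seq_len(n_probes)),
                        sprintf("S%02d", seq_len(2 * m)))
  mat
}
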