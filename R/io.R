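#' Read a methylation-array probe manifest
#'
#' Parses the TSV projection of an Infinium-style manifest used throughout the
#' workflow. Required columns: `probe_id`, `chromosome`, `feature_category`,
#' `cgi_relation`; optional: `position` (1-based), `gene_symbols`
#' (semicolon-joined), `gene_region`.
#'
#' Enum columns are closed: the recognised category strings
#' (`Promoter_Associated`, `Promoter_Associated_Cell_type_specific`) and CpG
#' island relations (`Island`, `N_Shore`, `S_Shore`, `S_Shelf`, `N_Shelf`,
#' `OpenSea`) are kept verbatim, empty cells become `"missing"`, and any other
#' string maps to the `"other"` escape value so foreign manifests load without
#' inventing annotations.
#'
#' @param path path to a tab-separated manifest with a header row.
#' @return A `data.frame` of class `"probe_manifest"` with one row per probe;
#'   `gene_symbols` is a list-column of character vectors.
#' @export
read_probe_manifest <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  required <- c("probe_id", "chromosome", "feature_category", "cgi_relation")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("probe manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$probe_id)) {
    dup <- unique(df$probe_id[duplicated(df$probe_id)])
    stop("duplicate probe_id in manifest: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  valid_chrom <- c(paste0("chr", 1:22), "chrX", "chrY")
  bad <- !df$chromosome %in% valid_chrom
  if (any(bad)) stop("invalid chromosome value(s): ",
                     paste(unique(df$chromosome[bad]), collapse = ", "))
  df$feature_category <- close_enum(df$feature_category,
    c("Promoter_Associated", "Promoter_Associated_Cell_type_specific", "other"))
  df$cgi_relation <- close_enum(df$cgi_relation,
    c("Island", "N_Shore", "S_Shore", "S_Shelf", "N_Shelf", "OpenSea"))
  if ("gene_region" %in% names(df)) {
    df$gene_region <- close_enum(df$gene_region, c("promoter", "body", "other"))
  } else {
    df$gene_region <- "missing"
  }
  if ("position" %in% names(df)) {
    if (any(!is.na(df$position) & df$position < 1)) stop("probe position must be >= 1")
  }
  gs <- if ("gene_symbols" %in% names(df)) df$gene_symbols else rep(NA_character_, nrow(df))
  df$gene_symbols <- I(lapply(gs, function(x) {
    if (is.na(x) || x == "") character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
  }))
  class(df) <- c("probe_manifest", "data.frame")
  df
}

# empty/NA -> "missing"; unrecognised -> "other"
close_enum <- function(x, allowed) {
  x <- as.character(x)
  out <- ifelse(is.na(x) | x == "", "missing",
                ifelse(x %in% allowed, x, "other"))
  out
}

#' Read a labelled numeric matrix (beta values, counts, or FPKM)
#'
#' TSV layout: first column row labels (probes or genes), first row sample
#' ids. Validation depends on `kind`: beta values must lie in \[0, 1\],
#' counts must be non-negative integers, FPKM must be non-negative.
#'
#' @param path TSV file path.
#' @param kind one of `"beta"`, `"counts"`, `"fpkm"`.
#' @return numeric matrix with row and column names.
#' @export
read_matrix <- function(path, kind = c("beta", "counts", "fpkm")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  rn <- as.character(df[[1]])
  if (anyDuplicated(rn)) stop("duplicate row labels in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- rn
  if (any(is.na(m))) stop("missing cells are not allowed in a ", kind, " matrix")
  validate_matrix(m, kind)
  m
}

validate_matrix <- function(m, kind) {
  if (kind == "beta") {
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("beta value %g outside [0,1] at probe %s, sample %s",
                   m[bad[1, 1], bad[1, 2]],
                   rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    }
  } else if (kind == "counts") {
    bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("count value %g is not a non-negative integer at gene %s, sample %s",
                   m[bad[1, 1], bad[1, 2]],
                   rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    }
  } else {
    if (any(m < 0)) stop("FPKM values must be non-negative")
  }
  invisible(m)
}

#' Write a labelled matrix as TSV
#'
#' Inverse of [read_matrix()]: the first column holds row labels under the
#' header `id`, remaining columns are samples. Round-trips cell-identically.
#'
#' @param m matrix with row and column names.
#' @param path output path.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a catalogue of named region sets from BED files
#'
#' Each BED file (0-based half-open intervals) becomes one named interval set;
#' the set name is the file stem. Strand is ignored, intervals are sorted, and
#' overlapping intervals within a set are kept as-is (no merging).
#'
#' @param paths character vector of BED file paths.
#' @return Named list of `GRanges` (1-based closed coordinates after import),
#'   class `"region_catalog"`.
#' @export
read_region_sets <- function(paths) {
  sets <- lapply(paths, function(p) {
    gr <- tryCatch(rtracklayer::import(p, format = "BED"),
                   error = function(e) stop("failed to read BED ", p, ": ",
                                            conditionMessage(e)))
    if (length(gr) && any(GenomicRanges::width(gr) < 1)) {
      stop("interval with end <= start in ", p)
    }
    GenomicRanges::strand(gr) <- "*"
    GenomicRanges::sort(gr, ignore.strand = TRUE)
  })
  names(sets) <- sub("\\.bed$", "", basename(paths), ignore.case = TRUE)
  class(sets) <- c("region_catalog", "list")
  sets
}

#' Read a variant-call table
#'
#' The TSV dialect carries one call per row with the columns consumed by the
#' filter cascade: `sample_id, chrom, pos, ref, alt, depth, ref_reads,
#' alt_reads, vaf, mapq, baseq, strand_ref_fwd, strand_alt_fwd, ebcall_p,
#' consequence, in_snp_db, cosmic_solid_mentions, cn_state, loh` plus the
#' optional `gene`, `truncating` and `germline_confirmed` columns. Missing
#' quality fields are kept as `NA` (explicitly missing, never silently
#' defaulted); the downstream filter reports them as failure reasons.
#'
#' The `vcf` dialect (requires the VariantAnnotation package) maps INFO keys
#' of the same names onto the same fields, one call per VCF record, with the
#' sample id taken from the single VCF sample column.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return `data.frame` of class `"variant_table"`.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            na.strings = c("NA", ""))
  } else {
    df <- read_variant_vcf(path)
  }
  required <- c("sample_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("variant table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("in_snp_db", "loh", "truncating", "germline_confirmed")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  if ("vaf" %in% names(df) && any(df$vaf < 0 | df$vaf > 1, na.rm = TRUE)) {
    stop("vaf outside [0,1] in ", path)
  }
  cnt <- intersect(c("depth", "ref_reads", "alt_reads"), names(df))
  for (col in cnt) {
    if (any(df[[col]] < 0, na.rm = TRUE)) stop("negative read count in column ", col)
  }
  class(df) <- c("variant_table", "data.frame")
  df
}

read_variant_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading the vcf dialect requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  info <- as.data.frame(VariantAnnotation::info(vcf))
  rr <- SummarizedExperiment::rowRanges(vcf)
  smp <- colnames(vcf)
  if (length(smp) != 1L) stop("vcf dialect expects a single-sample VCF")
  alt <- vapply(VariantAnnotation::alt(vcf),
                function(a) as.character(a)[1], character(1))
  out <- data.frame(
    sample_id = smp,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt,
    stringsAsFactors = FALSE
  )
  cbind(out, info)
}

#' Read sample metadata
#'
#' Clinical/sample annotations: `sample_id`, `sample_type` (biopsy,
#' postchemo, normal_liver, cell_line), optional clinical covariates and the
#' survival source columns consumed by [derive_survival_records()].
#'
#' @param path TSV path.
#' @return `data.frame` of class `"sample_metadata"`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!all(c("sample_id", "sample_type") %in% names(df))) {
    stop("sample metadata requires sample_id and sample_type columns")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  ok_types <- c("biopsy", "postchemo", "normal_liver", "cell_line")
  if (any(!df$sample_type %in% ok_types)) {
    stop("sample_type must be one of: ", paste(ok_types, collapse = ", "))
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}
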