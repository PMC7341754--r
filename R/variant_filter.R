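#' Primary variant-quality filter
#'
#' Applies the eight primary criteria that remove sequencing/mapping errors
#' and variants of unknown significance from a call set:
#' (i) mapping quality >= 20, (ii) base quality >= 15, (iii) nonsilent
#' exonic or splice-site consequence, (iv) strand ratio of variant reads not
#' equal to 0 or 1 (variant support must appear on both strands),
#' (v) read depth >= 100, (vi) both reference and variant read support >= 5,
#' (vii) VAF >= 0.05, and (viii) EBCall error probability < 1e-20.
#' All thresholds are boundary-inclusive exactly as written.
#'
#' A call passes iff all eight criteria hold. Every failed criterion
#' contributes a reason code (`P1_MAPQ` .. `P8_EBCALL`); a criterion whose
#' input field is `NA` fails with the code suffixed `_MISSING` rather than
#' being silently skipped.
#'
#' @param calls a `variant_table` data.frame (see [read_variant_table()]).
#' @param config the `filter` section of [default_config()].
#' @return `calls` with logical `pass` and character `reason_codes`
#'   (semicolon-joined, empty when passing) columns appended.
#' @export
apply_primary_filter <- function(calls, config = default_config()$filter) {
  stopifnot(is.data.frame(calls))
  n <- nrow(calls)
  reasons <- rep(list(character(0)), n)
  add <- function(idx, code) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], code)
    invisible(NULL)
  }
  fld <- function(nm) if (nm %in% names(calls)) calls[[nm]] else rep(NA, n)
  # a rule fails outright on NA input, with an explicit missing-field code
  rule <- function(value_ok, value_na, code) {
    add(value_na, paste0(code, "_MISSING"))
    add(!value_na & !value_ok, code)
  }
  mapq <- fld("mapq"); baseq <- fld("baseq")
  csq <- fld("consequence")
  depth <- fld("depth"); refr <- fld("ref_reads"); altr <- fld("alt_reads")
  vaf <- fld("vaf"); ebp <- fld("ebcall_p")
  saf <- fld("strand_alt_fwd")

  rule(mapq >= config$min_mapq, is.na(mapq), "P1_MAPQ")
  rule(baseq >= config$min_baseq, is.na(baseq), "P2_BASEQ")
  rule(csq %in% c("nonsilent_exonic", "splice_site"), is.na(csq), "P3_CONSEQUENCE")
  strand_na <- is.na(saf) | is.na(altr)
  strand_ok <- !strand_na & altr > 0 & saf >= 1 & saf <= altr - 1
  rule(strand_ok, strand_na, "P4_STRAND")
  rule(depth >= config$min_depth, is.na(depth), "P5_DEPTH")
  reads_na <- is.na(refr) | is.na(altr)
  rule(!reads_na & refr >= config$min_reads & altr >= config$min_reads,
       reads_na, "P6_READS")
  rule(vaf >= config$min_vaf, is.na(vaf), "P7_VAF")
  rule(ebp < config$max_ebcall_p, is.na(ebp), "P8_EBCALL")

  calls$pass <- lengths(reasons) == 0L
  calls$reason_codes <- vapply(reasons, paste, character(1), collapse = ";")
  calls
}

#' Germline/somatic classification of primary-passing calls
#'
#' Excludes likely germline SNPs from the candidate somatic list:
#' (i) variants listed in SNP databases, (ii) VAF >= 0.35 in copy-neutral
#' regions without LOH, (iii) VAF >= 0.25 in CN-gained regions without LOH;
#' (iv) calls with ten or more COSMIC solid-tumour mentions are re-included
#' as somatic regardless of (i)-(iii). Copy-number states other than
#' `neutral`/`gain` (losses, complex) are not named by any exclusion rule, so
#' such calls stay somatic unless SNP-database-listed.
#'
#' @param calls primary-passing `variant_table` rows.
#' @param config the `filter` section of [default_config()].
#' @return `calls` with `label` (`"somatic"`/`"germline"`) and
#'   `germline_codes` columns appended (decisive codes `G1_SNP_DB`,
#'   `G2_VAF_NEUTRAL`, `G3_VAF_GAIN`, plus `G4_COSMIC_RESCUE` when applied).
#' @export
classify_germline_somatic <- function(calls, config = default_config()$filter) {
  n <- nrow(calls)
  snp <- isTRUE_vec(calls$in_snp_db, n)
  loh <- isTRUE_vec(calls$loh, n)
  cn <- if ("cn_state" %in% names(calls)) as.character(calls$cn_state) else rep("other", n)
  vaf <- calls$vaf
  cosmic <- if ("cosmic_solid_mentions" %in% names(calls)) calls$cosmic_solid_mentions else rep(0, n)
  cosmic[is.na(cosmic)] <- 0

  g1 <- snp
  g2 <- !is.na(vaf) & vaf >= config$vaf_neutral & cn == "neutral" & !loh
  g3 <- !is.na(vaf) & vaf >= config$vaf_gain & cn == "gain" & !loh
  rescue <- cosmic >= config$cosmic_rescue
  germ <- (g1 | g2 | g3) & !rescue

  codes <- character(n)
  for (i in seq_len(n)) {
    ci <- c(if (g1[i]) "G1_SNP_DB", if (g2[i]) "G2_VAF_NEUTRAL",
            if (g3[i]) "G3_VAF_GAIN",
            if ((g1[i] || g2[i] || g3[i]) && rescue[i]) "G4_COSMIC_RESCUE")
    codes[i] <- paste(ci, collapse = ";")
  }
  calls$label <- ifelse(germ, "germline", "somatic")
  calls$germline_codes <- codes
  calls
}

isTRUE_vec <- function(x, n) {
  if (is.null(x)) return(rep(FALSE, n))
  out <- as.logical(x)
  out[is.na(out)] <- FALSE
  out
}

#' TERT-promoter rescue filter
#'
#' The promoter region of TERT is covered at low depth (~10x) in the capture
#' design, so the depth-based primary criteria miss all its mutations. A
#' dedicated rule keeps any call with chromosomal position inside
#' chr5:1295105-1295353 and an EBCall p value < 1e-4, bypassing the primary
#' filter entirely.
#'
#' @param calls `variant_table` rows (any calls; the window rule is total).
#' @param config the `tert` section of [default_config()].
#' @return logical vector, `TRUE` where the TERT-promoter rule keeps a call.
#' @export
filter_tert_promoter <- function(calls, config = default_config()$tert) {
  in_window <- calls$chrom == config$chrom &
    calls$pos >= config$start & calls$pos <= config$end
  ebp <- calls$ebcall_p
  out <- in_window & !is.na(ebp) & ebp < config$max_ebcall_p
  out[is.na(out)] <- FALSE
  out
}

#' Structural-variant filter
#'
#' Keeps structural variants with (i) reference read pairs >= 300,
#' (ii) variant read pairs >= 20 and (iii) overhang >= 150 bp on both sides
#' of the breakpoint, then removes (iv) events with breakpoints on
#' mitochondrial/linear DNA and (v) intronic deletions or tandem duplications
#' that do not affect coding exons.
#'
#' @param svs data.frame with columns `sv_type`, `ref_pairs`, `variant_pairs`,
#'   `overhang_left`, `overhang_right`, `affects_coding_exon`,
#'   `on_mito_or_decoy`.
#' @param config the `sv` section of [default_config()].
#' @return `svs` with `pass` and `reason_codes` columns appended
#'   (`SV1_REF_PAIRS`, `SV2_VAR_PAIRS`, `SV3_OVERHANG`, `SV4_MITO`,
#'   `SV5_INTRONIC`).
#' @export
filter_structural_variants <- function(svs, config = default_config()$sv) {
  stopifnot(all(svs$overhang_left >= 0), all(svs$overhang_right >= 0))
  n <- nrow(svs)
  fail <- list(
    SV1_REF_PAIRS = svs$ref_pairs < config$min_ref_pairs,
    SV2_VAR_PAIRS = svs$variant_pairs < config$min_variant_pairs,
    SV3_OVERHANG = pmin(svs$overhang_left, svs$overhang_right) < config$min_overhang,
    SV4_MITO = isTRUE_vec(svs$on_mito_or_decoy, n),
    SV5_INTRONIC = svs$sv_type %in% c("deletion", "tandem_duplication") &
      !isTRUE_vec(svs$affects_coding_exon, n)
  )
  codes <- character(n)
  for (i in seq_len(n)) {
    codes[i] <- paste(names(fail)[vapply(fail, `[`, logical(1), i)], collapse = ";")
  }
  svs$pass <- codes == ""
  svs$reason_codes <- codes
  svs
}

#' Pick up germline truncating APC mutations
#'
#' Germline truncating (nonsense/frameshift) mutations of APC are reported
#' alongside the somatic driver list because of their established role in
#' hepatoblastoma tumourigenesis; they keep the `germline` label.
#'
#' @param calls classified `variant_table` rows with `label`, `gene` and
#'   logical `truncating` columns.
#' @return the subset of germline truncating APC calls.
#' @export
include_germline_apc_truncating <- function(calls) {
  n <- nrow(calls)
  keep <- calls$label == "germline" & calls$gene %in% "APC" &
    isTRUE_vec(calls$truncating, n)
  calls[keep, , drop = FALSE]
}

#' Full variant-filter cascade
#'
#' Runs the primary filter, classifies survivors as somatic or germline with
#' COSMIC rescue, then applies the TERT-promoter special path (which can keep
#' calls the primary depth rules rejected). Verdicts are per-call pure
#' functions of the row, so permuting the input permutes the output.
#'
#' @param calls a `variant_table`.
#' @param config a full [default_config()] object.
#' @return `calls` with `verdict` (`somatic`/`germline`/`rejected`) and
#'   `reason_codes` columns.
#' @export
filter_variants <- function(calls, config = default_config()) {
  pf <- apply_primary_filter(calls, config$filter)
  verdict <- rep("rejected", nrow(pf))
  codes <- pf$reason_codes
  if (any(pf$pass)) {
    cls <- classify_germline_somatic(pf[pf$pass, , drop = FALSE], config$filter)
    verdict[pf$pass] <- cls$label
    codes[pf$pass] <- cls$germline_codes
  }
  tert <- filter_tert_promoter(calls, config$tert)
  verdict[tert] <- "somatic"
  codes[tert] <- ifelse(codes[tert] == "", "TERT_WINDOW",
                        paste("TERT_WINDOW", codes[tert], sep = ";"))
  calls$verdict <- verdict
  calls$reason_codes <- codes
  calls
}

#' Predictive-value validation of the filter
#'
#' Compares filter verdicts against a per-call truth standard
#' (`germline_confirmed`: `TRUE` = truly germline, `FALSE` = truly somatic),
#' with somatic as the positive class. In the study's Sanger validation of 17
#' cases, 19 of 21 calls filtered as somatic were truly somatic and all 173
#' filtered as germline were truly germline.
#'
#' @param verdict character vector of `"somatic"`/`"germline"` verdicts.
#' @param germline_confirmed logical truth vector (same length); `NA` rows are
#'   dropped from the evaluation.
#' @return list with counts `tp`, `fp`, `tn`, `fn` and proportions `ppv`,
#'   `npv` (`NA` when the corresponding denominator is zero).
#' @export
compute_ppv_npv <- function(verdict, germline_confirmed) {
  keep <- !is.na(germline_confirmed) & verdict %in% c("somatic", "germline")
  if (!any(keep)) stop("no evaluable calls: truth column is entirely missing")
  v <- verdict[keep]
  truly_somatic <- !germline_confirmed[keep]
  tp <- sum(v == "somatic" & truly_somatic)
  fp <- sum(v == "somatic" & !truly_somatic)
  tn <- sum(v == "germline" & !truly_somatic)
  fn <- sum(v == "germline" & truly_somatic)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}
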