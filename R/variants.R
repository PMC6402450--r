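VARIANT_COLUMNS <- c("sample_id", "cohort", "contig", "pos", "ref", "alt",
                     "depth", "alt_reads")

#' Validate a somatic variant table
#'
#' The variant table is a plain data.frame, one row per called variant per
#' sample, with columns `sample_id`, `cohort` ("discovery" or "validation"),
#' `contig`, `pos` (1-based), `ref`, `alt` (allele strings; indels are allowed
#' before [remove_indels()]), `depth` and `alt_reads`.
#'
#' @param df data.frame of variant calls.
#' @return the validated data.frame (row order preserved).
#' @export
somatic_variants <- function(df) {
  miss <- setdiff(VARIANT_COLUMNS, names(df))
  if (length(miss))
    stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$cohort %in% c("discovery", "validation")))
    stop("cohort must be 'discovery' or 'validation'")
  df$pos <- as.integer(df$pos)
  df$depth <- as.integer(df$depth)
  df$alt_reads <- as.integer(df$alt_reads)
  bad <- !is.na(df$depth) & !is.na(df$alt_reads) &
    (df$alt_reads < 0L | df$alt_reads > df$depth)
  if (any(bad))
    stop("alt_reads outside [0, depth] for record(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  if (any(df$ref == df$alt))
    stop("ref equals alt for record(s): ",
         paste(utils::head(which(df$ref == df$alt), 5), collapse = ", "))
  df
}

#' Read / write somatic variant tables as TSV
#'
#' @param path TSV with the columns described in [somatic_variants()].
#' @return data.frame of validated variants.
#' @export
read_variants_tsv <- function(path) {
  somatic_variants(utils::read.table(path, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE,
                                     colClasses = c(contig = "character")))
}

#' @rdname read_variants_tsv
#' @param variants variant data.frame.
#' @export
write_variants_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read one sample's calls from a VCF
#'
#' Uses the `DP` and `AD` genotype fields of a single-sample VCF to populate
#' depth and alt-read counts. Multi-allelic records are split into biallelic
#' rows.
#'
#' @param path VCF file (may be uncompressed).
#' @param sample_id sample label to assign.
#' @param cohort "discovery" or "validation".
#' @return data.frame of validated variants.
#' @export
read_variants_vcf <- function(path, sample_id, cohort = "discovery") {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alt)
  i <- rep(seq_along(rr), nalt)
  ad <- VariantAnnotation::geno(vcf)$AD
  dp <- VariantAnnotation::geno(vcf)$DP
  if (is.null(ad) || is.null(dp))
    stop("VCF must carry DP and AD genotype fields: ", path)
  alt_reads <- unlist(lapply(seq_along(rr), function(k) {
    counts <- unlist(ad[k, 1])
    counts[-1][seq_len(nalt[k])]
  }), use.names = FALSE)
  somatic_variants(data.frame(
    sample_id = sample_id, cohort = cohort,
    contig = as.character(GenomicRanges::seqnames(rr))[i],
    pos = GenomicRanges::start(rr)[i],
    ref = as.character(VariantAnnotation::ref(vcf))[i],
    alt = as.character(unlist(alt)),
    depth = as.integer(dp[i, 1]),
    alt_reads = as.integer(alt_reads),
    stringsAsFactors = FALSE))
}

#' Control-panel allele frequencies
#'
#' A population control panel maps variant keys (contig, pos, ref, alt) to
#' allele frequencies; variants absent from the panel have frequency 0. Used
#' to exclude germline polymorphisms (the study's equivalent filtered tumor
#' calls against >60,000 outside controls).
#'
#' @param df data.frame with columns `contig`, `pos`, `ref`, `alt`, `af`.
#' @param panel_size number of control individuals (metadata only).
#' @return object of class `control_panel`.
#' @export
control_panel <- function(df, panel_size = NA_integer_) {
  need <- c("contig", "pos", "ref", "alt", "af")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("control panel missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$af < 0 | df$af > 1)) stop("allele frequencies must lie in [0,1]")
  key <- variant_key(df$contig, df$pos, df$ref, df$alt)
  if (anyDuplicated(key)) stop("duplicate variant keys in control panel")
  structure(list(af = stats::setNames(df$af, key),
                 panel_size = panel_size),
            class = "control_panel")
}

#' @export
print.control_panel <- function(x, ...) {
  cat("control_panel:", length(x$af), "sites,",
      if (is.na(x$panel_size)) "unknown" else x$panel_size, "individuals\n")
  invisible(x)
}

#' Panel allele frequency of variants
#'
#' @param panel a [control_panel()] (or NULL, treated as an empty panel).
#' @param contig,pos,ref,alt vectors describing variants.
#' @return numeric vector of frequencies; 0 for absent keys.
#' @export
panel_frequency <- function(panel, contig, pos, ref, alt) {
  if (is.null(panel)) return(rep(0, length(pos)))
  stopifnot(inherits(panel, "control_panel"))
  af <- panel$af[variant_key(contig, pos, ref, alt)]
  af[is.na(af)] <- 0
  unname(af)
}

#' Read / write a control panel as TSV
#' @param path TSV with columns contig, pos, ref, alt, af.
#' @param panel_size number of control individuals.
#' @return a [control_panel()].
#' @export
read_control_panel_tsv <- function(path, panel_size = NA_integer_) {
  control_panel(utils::read.table(path, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE,
                                  colClasses = c(contig = "character")),
                panel_size = panel_size)
}

#' @rdname read_control_panel_tsv
#' @param panel a [control_panel()].
#' @export
write_control_panel_tsv <- function(panel, path) {
  key <- strsplit(names(panel$af), ":", fixed = TRUE)
  df <- data.frame(contig = vapply(key, `[`, "", 1L),
                   pos = as.integer(vapply(key, `[`, "", 2L)),
                   ref = vapply(key, `[`, "", 3L),
                   alt = vapply(key, `[`, "", 4L),
                   af = unname(panel$af), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
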