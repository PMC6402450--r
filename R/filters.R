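.filter_report <- function(stage, removed, remaining) {
  data.frame(stage = stage, removed = as.integer(removed),
             remaining = as.integer(remaining), stringsAsFactors = FALSE)
}

#' Somatic quality filters: depth and variant allele fraction
#'
#' Retains a call when coverage at the variant site is at least `min_depth`
#' reads and the fraction of reads supporting the mutation is at least
#' `min_alt_fraction` (both bounds inclusive). The fraction comparison is done
#' in exact integer arithmetic (`alt_reads * 10000 >= depth * 10000 * f`) so
#' that a read count sitting exactly on the boundary (e.g. 6 of 30 at 20%) is
#' retained without floating-point artifacts.
#'
#' @param variants variant data.frame (see [somatic_variants()]).
#' @param min_depth minimum read depth (default 21).
#' @param min_alt_fraction minimum variant allele fraction (default 0.20).
#' @return list with `variants` (retained rows, order preserved) and `report`
#'   (a one-row filter report).
#' @export
apply_quality_filters <- function(variants, min_depth = 21L,
                                  min_alt_fraction = 0.20) {
  if (anyNA(variants$depth) || anyNA(variants$alt_reads)) {
    bad <- which(is.na(variants$depth) | is.na(variants$alt_reads))
    stop("missing depth/alt_reads for record(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  frac_scaled <- as.integer(round(min_alt_fraction * 10000))
  keep <- variants$depth >= min_depth &
    variants$alt_reads * 10000L >= variants$depth * frac_scaled
  list(variants = variants[keep, , drop = FALSE],
       report = .filter_report("quality", sum(!keep), sum(keep)))
}

#' Remove insertions and deletions
#'
#' Retains only single-nucleotide substitutions: both alleles must be exactly
#' one base in A/C/G/T.
#'
#' @inheritParams apply_quality_filters
#' @return list with `variants` and `report`.
#' @export
remove_indels <- function(variants) {
  snv <- function(a) a %in% DNA_BASES
  keep <- snv(variants$ref) & snv(variants$alt)
  list(variants = variants[keep, , drop = FALSE],
       report = .filter_report("indel", sum(!keep), sum(keep)))
}

#' Restrict calls to exome capture regions
#'
#' Only variants whose position lies inside a capture interval are retained;
#' this unifies exome- and genome-derived call sets onto the same territory.
#'
#' @inheritParams apply_quality_filters
#' @param regions capture `GRanges` from [capture_regions()].
#' @return list with `variants` and `report`.
#' @export
restrict_to_capture <- function(variants, regions) {
  keep <- in_capture(regions, variants$contig, variants$pos)
  list(variants = variants[keep, , drop = FALSE],
       report = .filter_report("capture", sum(!keep), sum(keep)))
}

#' Germline filtering against matched normals and a control panel
#'
#' A call is removed when the same allele at the same position was seen in the
#' matched normal, or when its control-panel allele frequency is `max_maf` or
#' higher. Retention requires panel frequency strictly below `max_maf`
#' (default 5e-5), so a variant at exactly the threshold is removed.
#'
#' @inheritParams apply_quality_filters
#' @param matched_normal data.frame of germline calls with columns `contig`,
#'   `pos`, `ref`, `alt` and optionally `sample_id` (when present, matching is
#'   per sample); NULL disables matched-normal filtering.
#' @param panel a [control_panel()], or NULL for no panel.
#' @param max_maf population-frequency threshold (strict upper bound).
#' @return list with `variants` and `report`.
#' @export
filter_germline <- function(variants, matched_normal = NULL, panel = NULL,
                            max_maf = 5e-5) {
  in_normal <- rep(FALSE, nrow(variants))
  if (!is.null(matched_normal) && nrow(matched_normal) > 0L) {
    if ("sample_id" %in% names(matched_normal)) {
      nk <- paste(matched_normal$sample_id,
                  variant_key(matched_normal$contig, matched_normal$pos,
                              matched_normal$ref, matched_normal$alt))
      vk <- paste(variants$sample_id,
                  variant_key(variants$contig, variants$pos,
                              variants$ref, variants$alt))
    } else {
      nk <- variant_key(matched_normal$contig, matched_normal$pos,
                        matched_normal$ref, matched_normal$alt)
      vk <- variant_key(variants$contig, variants$pos,
                        variants$ref, variants$alt)
    }
    in_normal <- vk %in% nk
  }
  af <- panel_frequency(panel, variants$contig, variants$pos,
                        variants$ref, variants$alt)
  keep <- !in_normal & af < max_maf
  list(variants = variants[keep, , drop = FALSE],
       report = .filter_report("germline", sum(!keep), sum(keep)))
}

#' Full somatic filter pipeline
#'
#' Applies the four filters in the canonical order quality -> indel removal ->
#' capture restriction -> germline, and accumulates a per-stage report. Each
#' filter is a pure predicate, so the final retained set does not depend on
#' the order; the per-stage removal counts do.
#'
#' @inheritParams apply_quality_filters
#' @inheritParams restrict_to_capture
#' @inheritParams filter_germline
#' @return list with `variants` (the fully filtered table) and `report`
#'   (data.frame with columns `stage`, `removed`, `remaining`; the stage
#'   removals sum to input minus output).
#' @export
filter_variants <- function(variants, regions = NULL, matched_normal = NULL,
                            panel = NULL, min_depth = 21L,
                            min_alt_fraction = 0.20, max_maf = 5e-5) {
  steps <- list()
  s <- apply_quality_filters(variants, min_depth, min_alt_fraction)
  steps[[1]] <- s$report
  s <- remove_indels(s$variants)
  steps[[2]] <- s$report
  if (!is.null(regions)) {
    s <- restrict_to_capture(s$variants, regions)
    steps[[length(steps) + 1L]] <- s$report
  }
  s <- filter_germline(s$variants, matched_normal, panel, max_maf)
  steps[[length(steps) + 1L]] <- s$report
  list(variants = s$variants, report = do.call(rbind, steps))
}
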