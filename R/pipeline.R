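#' End-to-end hot-spot analysis
#'
#' Runs the full path on a raw cohort call set: somatic filtering (quality,
#' indels, capture, germline), consequence annotation, spectrum summary,
#' two-stage hot-spot detection with cohort frequencies, gene-level
#' recurrence filtering, and (optionally) the exome-wide permutation test on
#' the discovery cohort.
#'
#' @param variants raw variant table (see [somatic_variants()]).
#' @param ref a [dna_reference()].
#' @param models list of [gene_model()] objects.
#' @param regions capture `GRanges`.
#' @param panel optional [control_panel()].
#' @param matched_normal optional matched-normal call data.frame.
#' @param cohort_sizes `c(discovery, validation)` sample counts.
#' @param min_samples hot-spot sample threshold (default 2).
#' @param min_tumors gene-level recurrence threshold (default 3).
#' @param denylist previously reported hot-spot genes to omit.
#' @param permutation run the permutation test on discovery mutations?
#' @param R permutation rounds.
#' @param seed permutation seed.
#' @param ... further filter parameters passed to [filter_variants()].
#' @return list with `filtered`, `filter_report`, `annotated`, `spectrum`,
#'   `hotspots`, `recurrent_genes`, and `permutation` (NULL unless requested).
#' @export
run_hotspot_analysis <- function(variants, ref, models, regions,
                                 panel = NULL, matched_normal = NULL,
                                 cohort_sizes = c(36L, 93L),
                                 min_samples = 2L, min_tumors = 3L,
                                 denylist = character(0),
                                 permutation = FALSE, R = 100000L,
                                 seed = NULL, ...) {
  flt <- filter_variants(variants, regions = regions,
                         matched_normal = matched_normal, panel = panel, ...)
  annotated <- annotate_variants(flt$variants, models, ref)
  spectrum <- if (nrow(annotated)) spectrum_summary(annotated) else NULL
  hotspots <- detect_hotspots_staged(annotated, min_samples = min_samples,
                                     cohort_sizes = cohort_sizes,
                                     denylist = denylist)
  perm <- NULL
  if (permutation) {
    disc <- annotated[annotated$cohort == "discovery", , drop = FALSE]
    index <- build_site_index(ref, regions)
    perm <- run_permutation_test(disc, index, models, ref, R = R,
                                 seed = seed)
  }
  list(filtered = flt$variants, filter_report = flt$report,
       annotated = annotated, spectrum = spectrum, hotspots = hotspots,
       recurrent_genes = exclude_low_recurrence_genes(annotated,
                                                      min_tumors),
       permutation = perm)
}
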