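# cluster qualifying coding mutations of one gene by the |delta codon| <= 1
# link relation; returns an integer cluster id per row (input order)
.codon_clusters <- function(codons) {
  ord <- order(codons)
  s <- codons[ord]
  new_cluster <- c(TRUE, diff(s) > 1L)
  cl_sorted <- cumsum(new_cluster)
  cl <- integer(length(codons))
  cl[ord] <- cl_sorted
  cl
}

#' Detect somatic mutation hot spots
#'
#' A hot spot is a cluster of qualifying mutations residing in the same
#' codon, in two adjacent codons, or in the two intronic bases flanking the
#' same CDS exon boundary, carried by at least `min_samples` distinct
#' samples. Codon clusters are the maximal connected components of the
#' "|codon difference| <= 1" relation within a gene, so a chain across codons
#' k, k+1, k+2 merges into a single hot spot whose span is reported.
#' Splice-flank clusters are keyed by (gene, exon boundary), so mutations on
#' both intronic sides of the same boundary form one hot spot.
#'
#' @param annotated annotated mutation data.frame from [annotate_variants()].
#' @param min_samples minimum number of distinct mutated samples (default 2).
#' @param qualifying effect classes that can seed a hot spot; default
#'   missense, nonsense and splice_site (non-synonymous or splice changes).
#' @param denylist gene ids (or symbols) of previously reported hot-spot
#'   genes to omit from the report.
#' @param include_denylisted keep denylisted genes in the output (flagged in
#'   the `denylisted` column) instead of dropping them.
#' @return data.frame with one row per hot spot: `gene_id`, `kind`
#'   ("same_codon", "adjacent_codon" or "splice_flank"), `codon_min`,
#'   `codon_max`, `boundary_pos`, `n_mutations`, `n_samples`, `denylisted`,
#'   plus list-columns `samples`, `positions`, `aa_changes`, `rows` (indices
#'   into `annotated`).
#' @export
detect_hotspots <- function(annotated, min_samples = 2L,
                            qualifying = c("missense", "nonsense",
                                           "splice_site"),
                            denylist = character(0),
                            include_denylisted = FALSE) {
  qual <- which(annotated$effect_class %in% qualifying &
                  !is.na(annotated$gene_id))
  out <- list()
  for (g in unique(annotated$gene_id[qual])) {
    gi <- qual[annotated$gene_id[qual] == g]
    coding <- gi[!is.na(annotated$codon_index[gi])]
    splice <- gi[annotated$effect_class[gi] == "splice_site"]
    clusters <- list()
    if (length(coding)) {
      cl <- .codon_clusters(annotated$codon_index[coding])
      clusters <- c(clusters, split(coding, cl))
    }
    if (length(splice)) {
      clusters <- c(clusters, split(splice, annotated$splice_boundary[splice]))
    }
    for (rows in clusters) {
      samples <- unique(annotated$sample_id[rows])
      if (length(rows) < 2L || length(samples) < min_samples) next
      codons <- annotated$codon_index[rows]
      is_splice <- all(is.na(codons))
      kind <- if (is_splice) "splice_flank"
        else if (max(codons) == min(codons)) "same_codon"
        else "adjacent_codon"
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, kind = kind,
        codon_min = if (is_splice) NA_integer_ else min(codons),
        codon_max = if (is_splice) NA_integer_ else max(codons),
        boundary_pos = if (is_splice)
          annotated$splice_boundary[rows[1]] else NA_integer_,
        n_mutations = length(rows), n_samples = length(samples),
        denylisted = g %in% denylist,
        samples = I(list(samples)),
        positions = I(list(sort(unique(annotated$pos[rows])))),
        aa_changes = I(list(unique(annotated$aa_change[rows]))),
        rows = I(list(rows)),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), kind = character(0),
               codon_min = integer(0), codon_max = integer(0),
               boundary_pos = integer(0), n_mutations = integer(0),
               n_samples = integer(0), denylisted = logical(0),
               samples = I(list()), positions = I(list()),
               aa_changes = I(list()), rows = I(list()))
  if (!include_denylisted) res <- res[!res$denylisted, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count hot-spot clusters under the permutation criterion
#'
#' Counts maximal same/adjacent-codon clusters containing at least
#' `min_mutations` non-synonymous (missense or nonsense) mutations. This is
#' the criterion used for both the observed statistic and the permutation
#' null: a mutation count, not a sample count, and splice-flank clusters are
#' excluded. Set `criterion = "samples"` to require distinct samples instead.
#'
#' @param annotated annotated mutation data.frame.
#' @param min_mutations cluster size threshold (default 2).
#' @param criterion count "mutations" (default) or distinct "samples".
#' @return integer number of qualifying clusters.
#' @export
count_hotspot_clusters <- function(annotated, min_mutations = 2L,
                                   criterion = c("mutations", "samples")) {
  criterion <- match.arg(criterion)
  sel <- which(annotated$effect_class %in% c("missense", "nonsense") &
                 !is.na(annotated$gene_id) & !is.na(annotated$codon_index))
  if (length(sel) < min_mutations) return(0L)
  total <- 0L
  for (g in unique(annotated$gene_id[sel])) {
    gi <- sel[annotated$gene_id[sel] == g]
    cl <- .codon_clusters(annotated$codon_index[gi])
    size <- if (criterion == "mutations") tabulate(cl) else
      vapply(split(annotated$sample_id[gi], cl),
             function(s) length(unique(s)), integer(1))
    total <- total + sum(size >= min_mutations)
  }
  total
}

#' Exclude genes mutated in too few tumors
#'
#' Genes whose nonsilent mutations occur in fewer than `min_tumors` distinct
#' samples are dropped from gene-level candidate lists (the recurrence rule
#' that removes genes mutated in only one or two tumors).
#'
#' @param annotated annotated mutation data.frame.
#' @param min_tumors minimum distinct mutated samples (default 3).
#' @return character vector of retained gene ids.
#' @export
exclude_low_recurrence_genes <- function(annotated, min_tumors = 3L) {
  sel <- annotated$broad_effect == "nonsilent" & !is.na(annotated$gene_id)
  if (!any(sel)) return(character(0))
  counts <- vapply(split(annotated$sample_id[sel], annotated$gene_id[sel]),
                   function(s) length(unique(s)), integer(1))
  names(counts)[counts >= min_tumors]
}

#' Cohort frequency statistics for a hot spot or gene
#'
#' Computes the discovery / validation / combined mutation percentages from
#' distinct-sample counts, with percentages rounded half-up to one decimal.
#' When the whole coding region of the gene was sequenced in both cohorts,
#' the fraction of the gene's mutations that hit any of its hot spots can be
#' reported alongside.
#'
#' @param n_discovery,n_validation distinct mutated samples per cohort
#'   (vectors are accepted and processed element-wise).
#' @param cohort_sizes integer vector `c(discovery, validation)`; defaults to
#'   the 36-sample discovery and 93-sample validation design.
#' @param hotspot_mutations,gene_mutations optional counts of hot-spot-hitting
#'   mutations and of all mutations in the gene, for the hot-spot fraction.
#' @return data.frame with `n_discovery`, `n_validation`, `n_total`,
#'   `pct_discovery`, `pct_validation`, `pct_total`, and (when the optional
#'   counts are given) `hotspot_fraction` ("k/m") and `hotspot_fraction_pct`.
#' @examples
#' compute_frequencies(10, 32)  # 27.8 / 34.4 / 32.6
#' @export
compute_frequencies <- function(n_discovery, n_validation,
                                cohort_sizes = c(36L, 93L),
                                hotspot_mutations = NULL,
                                gene_mutations = NULL) {
  if (any(cohort_sizes <= 0L)) stop("cohort sizes must be positive")
  n_total <- n_discovery + n_validation
  out <- data.frame(
    n_discovery = n_discovery, n_validation = n_validation,
    n_total = n_total,
    pct_discovery = round_half_up(100 * n_discovery / cohort_sizes[1], 1),
    pct_validation = round_half_up(100 * n_validation / cohort_sizes[2], 1),
    pct_total = round_half_up(100 * n_total / sum(cohort_sizes), 1))
  if (!is.null(hotspot_mutations) && !is.null(gene_mutations)) {
    out$hotspot_fraction <- paste0(hotspot_mutations, "/", gene_mutations)
    out$hotspot_fraction_pct <-
      round_half_up(100 * hotspot_mutations / gene_mutations, 1)
  }
  out
}

#' Two-stage (discovery then validation) hot-spot detection
#'
#' Mirrors a discovery/validation design: hot spots are first detected in the
#' discovery cohort; validation mutations are then assigned to the detected
#' spans, and clusters that reach the sample threshold only with validation
#' data are reported too, flagged `validation_emergent`. Cohort frequencies
#' are attached via [compute_frequencies()].
#'
#' @inheritParams detect_hotspots
#' @param cohort_sizes `c(discovery, validation)` sample counts.
#' @return data.frame of hot spots with per-cohort distinct-sample counts,
#'   percentages, and a `validation_emergent` flag.
#' @export
detect_hotspots_staged <- function(annotated, min_samples = 2L,
                                   cohort_sizes = c(36L, 93L),
                                   qualifying = c("missense", "nonsense",
                                                  "splice_site"),
                                   denylist = character(0)) {
  disc <- annotated[annotated$cohort == "discovery", , drop = FALSE]
  hs_disc <- detect_hotspots(disc, min_samples, qualifying, denylist)
  hs_all <- detect_hotspots(annotated, min_samples, qualifying, denylist)
  if (nrow(hs_all) == 0L) {
    hs_all$validation_emergent <- logical(0)
    return(hs_all)
  }
  overlaps_disc <- function(i) {
    cand <- hs_disc[hs_disc$gene_id == hs_all$gene_id[i], , drop = FALSE]
    if (nrow(cand) == 0L) return(FALSE)
    if (hs_all$kind[i] == "splice_flank")
      return(any(!is.na(cand$boundary_pos) &
                   cand$boundary_pos == hs_all$boundary_pos[i]))
    any(!is.na(cand$codon_min) &
          cand$codon_min <= hs_all$codon_max[i] &
          cand$codon_max >= hs_all$codon_min[i])
  }
  hs_all$validation_emergent <- !vapply(seq_len(nrow(hs_all)), overlaps_disc,
                                        logical(1))
  n_disc <- integer(nrow(hs_all))
  n_val <- integer(nrow(hs_all))
  for (i in seq_len(nrow(hs_all))) {
    rows <- hs_all$rows[[i]]
    coh <- annotated$cohort[rows]
    n_disc[i] <- length(unique(annotated$sample_id[rows[coh == "discovery"]]))
    n_val[i] <- length(unique(annotated$sample_id[rows[coh == "validation"]]))
  }
  cbind(hs_all, compute_frequencies(n_disc, n_val, cohort_sizes))
}

#' Merge hot-spot genes with external driver-gene rankings
#'
#' Joins a gene-level hot-spot table with externally computed rankings (for
#' example, published significance rankings supplied as tabular input). The
#' rankings are consumed, never computed.
#'
#' @param gene_table data.frame with a `gene_id` column.
#' @param rankings named list of data.frames, each with columns `gene` and
#'   `rank`. A duplicated gene inside one ranking is an error.
#' @return `gene_table` with one `standing_<name>` column per ranking; genes
#'   absent from a ranking get NA.
#' @export
rank_merge_report <- function(gene_table, rankings = list()) {
  stopifnot(is.data.frame(gene_table), "gene_id" %in% names(gene_table))
  out <- gene_table
  for (nm in names(rankings)) {
    r <- rankings[[nm]]
    if (anyDuplicated(r$gene))
      stop("duplicate gene in ranking '", nm, "': ",
           paste(unique(r$gene[duplicated(r$gene)]), collapse = ", "))
    out[[paste0("standing_", nm)]] <- r$rank[match(out$gene_id, r$gene)]
  }
  out
}
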