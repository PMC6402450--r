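#' Default 18-type spectrum weights
#'
#' A C:G>T:A-dominated substitution spectrum typical of mismatch-repair
#' deficient tumors: the four C>T / G>A types together carry weight 0.545,
#' concentrated at CpG sites where deamination of methylated cytosine drives
#' the excess. The remaining mass is spread over the other classes.
#'
#' @return named numeric vector over [mutation_type_levels()], summing to 1.
#' @export
default_spectrum_weights <- function() {
  w <- c("C>T (at CpG)" = 0.2000, "C>T (not at CpG)" = 0.0725,
         "G>A (at CpG)" = 0.2000, "G>A (not at CpG)" = 0.0725,
         "C>A (at CpG)" = 0.0100, "C>A (not at CpG)" = 0.0300,
         "G>T (at CpG)" = 0.0100, "G>T (not at CpG)" = 0.0300,
         "C>G (at CpG)" = 0.0050, "C>G (not at CpG)" = 0.0150,
         "G>C (at CpG)" = 0.0050, "G>C (not at CpG)" = 0.0150,
         "A>G" = 0.0800, "T>C" = 0.0800,
         "A>T" = 0.0300, "T>A" = 0.0300,
         "A>C" = 0.0575, "T>G" = 0.0575)
  w[mutation_type_levels()]
}

#' Synthetic cohort configuration
#'
#' Collects the generator parameters: the two-cohort design (36 discovery,
#' 93 validation samples by default), the number and size of genes, the
#' per-sample point-mutation burden (Poisson, with the mean as the target
#' median), the 18-type spectrum weights, planted hot spots, decoy rates and
#' control-panel size. All randomness flows from `seed` through named
#' substreams (reference, calls, panel).
#'
#' @param n_discovery,n_validation cohort sizes.
#' @param n_genes number of genes on the synthetic contig.
#' @param mean_cds_length target CDS length in nt (rounded to codons).
#' @param burden_median target median somatic SNVs per sample over the
#'   synthetic capture (a scaled-down stand-in for exome-wide burdens in the
#'   hundreds, matched to the few-tens-of-kb synthetic capture).
#' @param spectrum_weights named weights over [mutation_type_levels()].
#' @param hotspots list of planted hot spots, each a list with `gene`
#'   (id or index), `codon`, `n_discovery`, `n_validation` sample counts.
#' @param decoy_rate fraction of the background count injected per decoy
#'   class (low depth, low allele fraction, indel, off-target, germline) to
#'   exercise every filter stage.
#' @param panel_size nominal number of control individuals.
#' @param seed master seed.
#' @return validated config list of class `cohort_config`.
#' @export
cohort_config <- function(n_discovery = 36L, n_validation = 93L,
                          n_genes = 25L, mean_cds_length = 900L,
                          burden_median = 50, spectrum_weights =
                            default_spectrum_weights(),
                          hotspots = list(), decoy_rate = 0.10,
                          panel_size = 60000L, seed = 1L) {
  stopifnot(n_discovery >= 1L, n_validation >= 0L, n_genes >= 1L,
            mean_cds_length >= 30L, burden_median >= 0, decoy_rate >= 0)
  if (!isTRUE(all.equal(sum(spectrum_weights), 1)))
    stop("spectrum weights must sum to 1")
  miss <- setdiff(mutation_type_levels(), names(spectrum_weights))
  if (length(miss))
    stop("spectrum weights missing type(s): ", paste(miss, collapse = ", "))
  for (h in hotspots) {
    if (!all(c("gene", "codon", "n_discovery", "n_validation") %in% names(h)))
      stop("each planted hotspot needs gene, codon, n_discovery, n_validation")
    if (h$n_discovery > n_discovery || h$n_validation > n_validation)
      stop("planted hot-spot sample counts exceed cohort sizes")
  }
  structure(list(n_discovery = as.integer(n_discovery),
                 n_validation = as.integer(n_validation),
                 n_genes = as.integer(n_genes),
                 mean_cds_length = as.integer(mean_cds_length),
                 burden_median = burden_median,
                 spectrum_weights = spectrum_weights[mutation_type_levels()],
                 hotspots = hotspots, decoy_rate = decoy_rate,
                 panel_size = as.integer(panel_size),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# named substreams off the master seed; kept below 2^31
.sub_seed <- function(seed, stream) {
  offs <- c(reference = 100003L, calls = 200003L, panel = 300007L)
  as.integer((as.numeric(seed) * 31L + offs[[stream]]) %% 2147483647)
}

#' Generate a synthetic reference, gene models and capture regions
#'
#' Lays non-overlapping multi-exon genes (2-4 CDS exons, alternating
#' strands, CDS length a multiple of 3 near the configured mean) along a
#' random contig with intergenic gaps, then derives the capture as the CDS
#' intervals padded by the 2-base splice flanks plus a few off-target
#' intergenic windows. Deterministic given the config seed.
#'
#' @param config a [cohort_config()].
#' @return list with `ref` ([dna_reference()]), `models` (list of
#'   [gene_model()]), `regions` (capture `GRanges`).
#' @export
generate_reference_and_models <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(.sub_seed(config$seed, "reference"))
  n <- config$n_genes
  cursor <- 1L
  models_spec <- vector("list", n)
  off_target <- list()
  for (i in seq_len(n)) {
    gap <- sample(80:200, 1)
    if (i %% 3L == 0L && gap > 120L) {
      # occasional off-target capture window in the intergenic gap
      off_target[[length(off_target) + 1L]] <-
        as.integer(c(cursor + gap %/% 4L, cursor + gap %/% 4L + 39L))
    }
    cursor <- cursor + gap
    codons <- max(10L, round(stats::rnorm(1, config$mean_cds_length / 3,
                                          config$mean_cds_length / 12)))
    total_nt <- codons * 3L
    n_exons <- sample(2:4, 1)
    candidates <- seq(9L, total_nt - 9L, by = 9L)
    n_exons <- min(n_exons, length(candidates) + 1L)
    cuts <- sort(sample(candidates, n_exons - 1L))
    exon_nt <- diff(c(0L, cuts, total_nt))
    strand <- if (i %% 2L == 0L) "-" else "+"
    iv <- matrix(0L, nrow = n_exons, ncol = 2)
    for (e in seq_len(n_exons)) {
      iv[e, 1] <- cursor
      iv[e, 2] <- cursor + exon_nt[e] - 1L
      cursor <- iv[e, 2] + sample(30:80, 1) + 1L
    }
    # cursor already past the last intron; pull back after final exon
    cursor <- iv[n_exons, 2] + 1L
    models_spec[[i]] <- list(id = sprintf("G%03d", i), strand = strand,
                             iv = iv)
  }
  contig_len <- cursor + sample(100:200, 1)
  seqchars <- sample(DNA_BASES, contig_len, replace = TRUE)
  ref <- dna_reference(c(synth1 = paste(seqchars, collapse = "")))
  models <- lapply(models_spec, function(s) {
    gene_model(s$id, paste0(s$id, ".t1"), "synth1", s$strand, s$iv)
  })
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  cds <- do.call(rbind, lapply(models, function(m) m$cds_intervals))
  regions <- capture_regions(
    "synth1",
    start = c(cds[, 1] - 2L, vapply(off_target, `[`, integer(1), 1L)),
    end = c(cds[, 2] + 2L, vapply(off_target, `[`, integer(1), 2L)))
  list(ref = ref, models = models, regions = regions)
}

# deterministically pick a non-synonymous single-base change inside a codon:
# first position/alt (plus-strand scan order) whose substitution changes the
# amino acid without creating a stop from a stop
.pick_nonsyn_change <- function(model, codon, ref) {
  cpos <- codon_to_genomic(model, codon)
  for (p in sort(cpos)) {
    b <- ref_base(ref, p, model$contig)
    for (alt in setdiff(DNA_BASES, b)) {
      cons <- .consequence_one(p, alt, model, ref)
      if (cons$effect_class %in% c("missense", "nonsense"))
        return(list(pos = p, ref = b, alt = alt,
                    effect = cons$effect_class))
    }
  }
  stop("no non-synonymous change available in codon ", codon,
       " of ", model$gene_id)
}

.draw_background <- function(n, index, weights) {
  if (n == 0L)
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  avail <- vapply(.site_class_levels(), function(cl)
    length(index$by_class[[cl]]) > 0L, logical(1))
  ok_types <- mutation_type_levels()[avail[.type_to_class(
    mutation_type_levels())]]
  w <- weights[ok_types] / sum(weights[ok_types])
  types <- sample(ok_types, n, replace = TRUE, prob = w)
  rows <- vapply(types, function(t) {
    pool <- index$by_class[[.type_to_class(t)]]
    pool[sample.int(length(pool), 1L)]
  }, integer(1))
  data.frame(contig = index$sites$contig[rows], pos = index$sites$pos[rows],
             ref = index$sites$base[rows], alt = .type_target(types),
             stringsAsFactors = FALSE)
}

#' Generate per-sample somatic call sets with planted hot spots
#'
#' Background SNVs are drawn per site conditional on reference base and CpG
#' context using the configured 18-type weights (the same stratification the
#' permutation null uses), with per-sample counts Poisson around the burden
#' target and read depths/allele fractions that pass the quality filters.
#' Planted hot spots are injected as a recurrent non-synonymous change at the
#' designated codon in the designated numbers of discovery and validation
#' samples. Decoy variants violating each filter (low depth, low allele
#' fraction, indels, off-target positions, germline polymorphisms) are added
#' at the configured rate so every filter stage is exercised.
#'
#' @param config a [cohort_config()].
#' @param ref,models,regions output of [generate_reference_and_models()].
#' @return list with `variants` (the raw, pre-filter call table) and `truth`
#'   (planted hot-spot records and germline variant keys).
#' @export
generate_somatic_calls <- function(config, ref, models, regions) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(.sub_seed(config$seed, "calls"))
  index <- build_site_index(ref, regions)
  samples <- c(sprintf("D%03d", seq_len(config$n_discovery)),
               sprintf("V%03d", seq_len(config$n_validation)))
  cohorts <- rep(c("discovery", "validation"),
                 c(config$n_discovery, config$n_validation))
  good_depth <- function(n) sample(25:80, n, replace = TRUE)
  good_alt <- function(depth) pmax(as.integer(ceiling(depth * 0.25)),
                                   rbinom(length(depth), depth, 0.45))
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  n_bg_total <- 0L
  for (k in seq_along(samples)) {
    n_bg <- rpois(1, config$burden_median)
    n_bg_total <- n_bg_total + n_bg
    bg <- .draw_background(n_bg, index, config$spectrum_weights)
    if (nrow(bg)) {
      depth <- good_depth(nrow(bg))
      add(cbind(data.frame(sample_id = samples[k], cohort = cohorts[k],
                           stringsAsFactors = FALSE),
                bg, data.frame(depth = depth, alt_reads = good_alt(depth))))
    }
  }
  # planted hot spots: same recurrent change in several samples
  truth_hs <- list()
  disc_ids <- samples[cohorts == "discovery"]
  val_ids <- samples[cohorts == "validation"]
  for (h in config$hotspots) {
    m <- models[[h$gene]]
    if (is.null(m)) stop("planted hotspot names unknown gene: ", h$gene)
    if (h$codon > n_codons(m))
      stop("planted codon ", h$codon, " not coding in ", m$gene_id)
    ch <- .pick_nonsyn_change(m, h$codon, ref)
    carriers <- c(sample(disc_ids, h$n_discovery),
                  if (h$n_validation > 0L) sample(val_ids, h$n_validation))
    depth <- good_depth(length(carriers))
    add(data.frame(sample_id = carriers,
                   cohort = ifelse(carriers %in% disc_ids, "discovery",
                                   "validation"),
                   contig = m$contig, pos = ch$pos, ref = ch$ref,
                   alt = ch$alt, depth = depth,
                   alt_reads = good_alt(depth), stringsAsFactors = FALSE))
    truth_hs[[length(truth_hs) + 1L]] <- data.frame(
      gene_id = m$gene_id, codon = h$codon, pos = ch$pos, ref = ch$ref,
      alt = ch$alt, effect = ch$effect,
      n_discovery = h$n_discovery, n_validation = h$n_validation,
      samples = I(list(carriers)), stringsAsFactors = FALSE)
  }
  # decoys: one class per filter stage
  n_decoy <- max(1L, ceiling(config$decoy_rate * max(n_bg_total, 10L)))
  decoy_sample <- function(n) sample(samples, n, replace = TRUE)
  mk <- function(n) .draw_background(n, index, config$spectrum_weights)
  # low depth (< 21)
  d <- mk(n_decoy); dep <- sample(5:20, n_decoy, replace = TRUE)
  sid <- decoy_sample(n_decoy)
  add(cbind(data.frame(sample_id = sid,
                       cohort = ifelse(sid %in% disc_ids, "discovery",
                                       "validation")),
            d, data.frame(depth = dep,
                          alt_reads = pmax(1L, as.integer(dep * 0.5)))))
  # low allele fraction (< 20%)
  d <- mk(n_decoy); dep <- sample(40:80, n_decoy, replace = TRUE)
  sid <- decoy_sample(n_decoy)
  add(cbind(data.frame(sample_id = sid,
                       cohort = ifelse(sid %in% disc_ids, "discovery",
                                       "validation")),
            d, data.frame(depth = dep,
                          alt_reads = pmax(1L, as.integer(dep * 0.10)))))
  # indels (two-base alternate allele)
  d <- mk(n_decoy); dep <- good_depth(n_decoy)
  d$alt <- paste0(d$ref, d$alt)
  sid <- decoy_sample(n_decoy)
  add(cbind(data.frame(sample_id = sid,
                       cohort = ifelse(sid %in% disc_ids, "discovery",
                                       "validation")),
            d, data.frame(depth = dep, alt_reads = good_alt(dep))))
  # off-target (positions outside the capture)
  contig_len <- nchar(ref[[1]])
  out_pos <- setdiff(seq_len(contig_len),
                     capture_positions(regions)$pos)
  if (length(out_pos)) {
    op <- out_pos[sample.int(length(out_pos), n_decoy, replace = TRUE)]
    b <- ref_base(ref, op, contig_names(ref)[1])
    keep <- b %in% DNA_BASES
    op <- op[keep]; b <- b[keep]
    altb <- vapply(b, function(x) sample(setdiff(DNA_BASES, x), 1),
                   character(1))
    dep <- good_depth(length(op))
    sid <- decoy_sample(length(op))
    add(data.frame(sample_id = sid,
                   cohort = ifelse(sid %in% disc_ids, "discovery",
                                   "validation"),
                   contig = contig_names(ref)[1], pos = op, ref = b,
                   alt = altb, depth = dep, alt_reads = good_alt(dep),
                   stringsAsFactors = FALSE))
  }
  # germline polymorphisms: shared variants destined for the control panel
  g <- mk(max(1L, n_decoy %/% 2L))
  g <- g[!duplicated(variant_key(g$contig, g$pos, g$ref, g$alt)), ,
         drop = FALSE]
  germ_rows <- list()
  for (i in seq_len(nrow(g))) {
    carriers <- sample(samples, sample(2:4, 1))
    dep <- good_depth(length(carriers))
    germ_rows[[i]] <- data.frame(
      sample_id = carriers,
      cohort = ifelse(carriers %in% disc_ids, "discovery", "validation"),
      contig = g$contig[i], pos = g$pos[i], ref = g$ref[i], alt = g$alt[i],
      depth = dep, alt_reads = good_alt(dep), stringsAsFactors = FALSE)
  }
  add(do.call(rbind, germ_rows))
  variants <- somatic_variants(do.call(rbind, rows))
  rownames(variants) <- NULL
  truth <- list(
    hotspots = if (length(truth_hs)) do.call(rbind, truth_hs) else
      data.frame(gene_id = character(0), codon = integer(0)),
    germline = g)
  list(variants = variants, truth = truth)
}

#' Generate a control panel covering the planted germline variants
#'
#' Every planted germline variant receives a population allele frequency at
#' or above the germline-filter threshold (so it is removed downstream);
#' somatic variants are absent from the panel, i.e. frequency 0.
#'
#' @param config a [cohort_config()].
#' @param germline data.frame of germline variants (`truth$germline` from
#'   [generate_somatic_calls()]).
#' @return a [control_panel()].
#' @export
generate_control_panel <- function(config, germline) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(.sub_seed(config$seed, "panel"))
  if (nrow(germline) == 0L)
    return(control_panel(data.frame(contig = character(0), pos = integer(0),
                                    ref = character(0), alt = character(0),
                                    af = numeric(0)),
                         panel_size = config$panel_size))
  af <- stats::runif(nrow(germline), min = 5e-5, max = 5e-3)
  control_panel(cbind(germline[, c("contig", "pos", "ref", "alt")],
                      data.frame(af = af)),
                panel_size = config$panel_size)
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper chaining [generate_reference_and_models()],
#' [generate_somatic_calls()] and [generate_control_panel()].
#'
#' @param config a [cohort_config()].
#' @return list with `ref`, `models`, `regions`, `variants`, `panel`,
#'   `truth`, `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  base <- generate_reference_and_models(config)
  calls <- generate_somatic_calls(config, base$ref, base$models,
                                  base$regions)
  panel <- generate_control_panel(config, calls$truth$germline)
  c(base, list(variants = calls$variants, panel = panel,
               truth = calls$truth, config = config))
}

#' Write a generated cohort to standard files
#'
#' Emits FASTA (reference), GTF and JSON (gene models), BED (capture
#' regions), TSV (per-sample calls and control panel) and JSON (planted
#' ground truth) into a directory.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "reference.fa"),
    gtf = file.path(dir, "genes.gtf"),
    json = file.path(dir, "genes.json"),
    bed = file.path(dir, "capture.bed"),
    calls = file.path(dir, "calls.tsv"),
    panel = file.path(dir, "panel.tsv"),
    truth = file.path(dir, "truth.json"))
  write_reference_fasta(cohort$ref, paths["fasta"])
  write_gene_models_gtf(cohort$models, paths["gtf"])
  write_gene_models_json(cohort$models, paths["json"])
  write_capture_bed(cohort$regions, paths["bed"])
  write_variants_tsv(cohort$variants, paths["calls"])
  write_control_panel_tsv(cohort$panel, paths["panel"])
  truth <- cohort$truth
  truth$hotspots$samples <- lapply(truth$hotspots$samples, identity)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
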