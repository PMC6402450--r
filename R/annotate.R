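#' The 18 mutation-type labels
#'
#' The canonical order of the 18 substitution types used for permutation
#' stratification: the six A/T-source types carry no CpG split, while each of
#' the six C/G-source substitutions is split into "(at CpG)" and
#' "(not at CpG)" by plus-strand reference context.
#'
#' @return character vector of 18 labels.
#' @export
mutation_type_levels <- function() {
  at <- c("A>C", "A>G", "A>T", "T>A", "T>C", "T>G")
  cg <- as.vector(vapply(
    c("C>A", "C>G", "C>T", "G>A", "G>C", "G>T"),
    function(s) paste0(s, c(" (at CpG)", " (not at CpG)")), character(2)))
  c(at[1:3], cg[1:6], cg[7:12], at[4:6])
}

# source-base "site class" backing each mutation type; three A>* types share
# the A sites, C types split by CpG context, etc.
.site_class_levels <- function() c("A", "T", "C_cpg", "C_noncpg",
                                   "G_cpg", "G_noncpg")

.type_to_class <- function(type) {
  src <- substr(type, 1, 1)
  ifelse(src %in% c("A", "T"), src,
         paste0(src, ifelse(grepl("(at CpG)", type, fixed = TRUE),
                            "_cpg", "_noncpg")))
}

.type_target <- function(type) substr(type, 3, 3)

#' Classify a substitution into one of the 18 mutation types
#'
#' Types are assigned from the plus-strand reference base, the alternate
#' base, and CpG context (a C followed by G, or a G preceded by C, on the
#' reference plus strand), regardless of gene strand.
#'
#' @param ref_base plus-strand reference base(s).
#' @param alt_base alternate base(s).
#' @param cpg logical; is the site at a CpG dinucleotide?
#' @return character vector of labels from [mutation_type_levels()].
#' @examples
#' classify_mutation_type("C", "T", cpg = TRUE)   # "C>T (at CpG)"
#' classify_mutation_type("A", "G", cpg = FALSE)  # "A>G"
#' @export
classify_mutation_type <- function(ref_base, alt_base, cpg) {
  if (any(!ref_base %in% DNA_BASES))
    stop("reference base must be one of A/C/G/T")
  if (any(!alt_base %in% DNA_BASES))
    stop("alternate base must be one of A/C/G/T")
  if (any(ref_base == alt_base)) stop("ref and alt base must differ")
  core <- paste0(ref_base, ">", alt_base)
  ifelse(ref_base %in% c("A", "T"), core,
         paste0(core, ifelse(cpg, " (at CpG)", " (not at CpG)")))
}

.broad_effect <- function(effect_class) {
  ifelse(effect_class %in% c("missense", "nonsense", "splice_site"),
         "nonsilent",
         ifelse(effect_class == "synonymous", "silent", "noncoding"))
}

# consequence of a single SNV against a single model; variant ref is the
# plus-strand base and must match the reference
.consequence_one <- function(pos, alt, model, ref) {
  loc <- genomic_to_codon(model, pos)
  out <- list(gene_id = model$gene_id, transcript_id = model$transcript_id,
              codon_index = NA_integer_, aa_ref = NA_character_,
              aa_alt = NA_character_, aa_change = NA_character_,
              effect_class = "noncoding", splice_boundary = NA_integer_)
  if (loc$coding) {
    cpos <- codon_to_genomic(model, loc$codon_index)
    bases <- ref_base(ref, cpos, model$contig)
    sub <- alt
    if (model$strand == "-") {
      bases <- complement_base(bases)
      sub <- complement_base(alt)
    }
    codon_ref <- paste(bases, collapse = "")
    bases[loc$offset + 1L] <- sub
    codon_alt <- paste(bases, collapse = "")
    aa_ref <- translate_codon(codon_ref)
    aa_alt <- translate_codon(codon_alt)
    out$codon_index <- loc$codon_index
    out$aa_ref <- aa_ref
    out$aa_alt <- aa_alt
    out$aa_change <- paste0(aa_three_letter(aa_ref), loc$codon_index,
                            aa_three_letter(aa_alt))
    out$effect_class <- if (aa_ref == aa_alt) "synonymous"
      else if (aa_alt == "*") "nonsense"
      else "missense"  # includes stop-loss: the protein sequence changes
  } else if (loc$region == "intronic" && loc$boundary_distance <= 2L) {
    out$effect_class <- "splice_site"
    out$splice_boundary <- loc$boundary_pos
  }
  out
}

#' Annotate filtered SNVs with codon-level consequences
#'
#' Each variant is annotated against every gene model it overlaps (the gene's
#' CDS span plus the 2-base splice flanks); a variant overlapping no model is
#' reported once with `effect_class = "noncoding"` and no gene. Coding hits
#' substitute the strand-oriented alternate base at the codon offset and
#' translate with the standard genetic code. A change that keeps the amino
#' acid is `synonymous`; a change to a stop codon is `nonsense`; every other
#' protein-changing substitution (including stop-loss) is `missense`.
#' Positions in the first or last two intronic bases flanking a CDS exon are
#' `splice_site`. The broad effect is `nonsilent` for
#' missense/nonsense/splice_site, `silent` for synonymous, else `noncoding`.
#' Each row also receives its 18-way `mutation_type` from plus-strand context.
#'
#' @param variants filtered SNV data.frame (single-base ref and alt).
#' @param models list of [gene_model()] objects.
#' @param ref a [dna_reference()].
#' @return data.frame: the variant columns plus `gene_id`, `transcript_id`,
#'   `codon_index`, `aa_ref`, `aa_alt`, `aa_change`, `effect_class`,
#'   `broad_effect`, `mutation_type`, `splice_boundary`; one row per
#'   (variant, overlapping gene).
#' @export
annotate_variants <- function(variants, models, ref) {
  stopifnot(is.list(models))
  if (nrow(variants) > 0L) {
    rb <- mapply(function(c, p) ref_base(ref, p, c),
                 variants$contig, variants$pos)
    mism <- rb != variants$ref
    if (any(mism))
      stop("variant ref allele disagrees with reference at ",
           paste(utils::head(variant_key(variants$contig, variants$pos,
                                         variants$ref, variants$alt)[mism], 5),
                 collapse = ", "))
  }
  # gene spans padded by the 2-base splice flanks
  span <- do.call(rbind, lapply(models, function(m) {
    s <- gene_span(m)
    data.frame(contig = m$contig, start = s[1] - 2L, end = s[2] + 2L,
               stringsAsFactors = FALSE)
  }))
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    hit <- which(span$contig == v$contig & v$pos >= span$start &
                   v$pos <= span$end)
    cpg <- is_cpg(ref, v$pos, v$contig)
    mt <- classify_mutation_type(v$ref, v$alt, cpg)
    if (length(hit) == 0L) {
      ann <- data.frame(gene_id = NA_character_,
                        transcript_id = NA_character_,
                        codon_index = NA_integer_, aa_ref = NA_character_,
                        aa_alt = NA_character_, aa_change = NA_character_,
                        effect_class = "noncoding",
                        splice_boundary = NA_integer_,
                        stringsAsFactors = FALSE)
    } else {
      ann <- do.call(rbind, lapply(hit, function(h) {
        as.data.frame(.consequence_one(v$pos, v$alt, models[[h]], ref),
                      stringsAsFactors = FALSE)
      }))
    }
    ann$mutation_type <- mt
    rows[[i]] <- cbind(v[rep(1L, nrow(ann)), , drop = FALSE], ann,
                       row.names = NULL)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- cbind(variants,
                 data.frame(gene_id = character(0),
                            transcript_id = character(0),
                            codon_index = integer(0), aa_ref = character(0),
                            aa_alt = character(0), aa_change = character(0),
                            effect_class = character(0),
                            splice_boundary = integer(0),
                            mutation_type = character(0)))
  }
  out$broad_effect <- .broad_effect(out$effect_class)
  rownames(out) <- NULL
  out
}

#' Strand-symmetric substitution spectrum
#'
#' Collapses the 12 directed single-base substitutions into the 6
#' strand-symmetric base-pair classes (C:G>T:A, C:G>A:T, C:G>G:C, T:A>C:G,
#' T:A>A:T, T:A>G:C) and reports counts and fractions. Rows describing the
#' same variant more than once (a variant annotated against several
#' overlapping genes) are collapsed to distinct variants first.
#'
#' @param mutations data.frame with at least `contig`, `pos`, `ref`, `alt`
#'   and `sample_id` columns (an annotated table works as-is).
#' @return data.frame with columns `class`, `n`, `fraction`, in a fixed class
#'   order; fractions sum to 1.
#' @export
spectrum_summary <- function(mutations) {
  if (nrow(mutations) == 0L) stop("no mutations to summarize")
  key <- paste(mutations$sample_id, mutations$contig, mutations$pos,
               mutations$ref, mutations$alt)
  mutations <- mutations[!duplicated(key), , drop = FALSE]
  map <- c("C>T" = "C:G>T:A", "G>A" = "C:G>T:A",
           "C>A" = "C:G>A:T", "G>T" = "C:G>A:T",
           "C>G" = "C:G>G:C", "G>C" = "C:G>G:C",
           "A>G" = "T:A>C:G", "T>C" = "T:A>C:G",
           "A>T" = "T:A>A:T", "T>A" = "T:A>A:T",
           "A>C" = "T:A>G:C", "T>G" = "T:A>G:C")
  cls <- map[paste0(mutations$ref, ">", mutations$alt)]
  if (anyNA(cls)) stop("spectrum_summary requires single-base substitutions")
  lev <- c("C:G>T:A", "C:G>A:T", "C:G>G:C", "T:A>C:G", "T:A>A:T", "T:A>G:C")
  n <- table(factor(cls, levels = lev))
  data.frame(class = lev, n = as.integer(n),
             fraction = as.numeric(n) / sum(n), stringsAsFactors = FALSE)
}
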