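# Shared fixtures and independent oracles for the test suite.

# --- toy fixtures -----------------------------------------------------------

# single-exon plus-strand gene on a small contig; CDS 1..9
toy_plus <- function(seq = "ATGGGATGAT") {
  list(ref = dna_reference(c(chr1 = seq)),
       model = gene_model("gplus", "gplus.t1", "chr1", "+", cbind(1L, 9L)))
}

# two-exon minus-strand gene, CDS intervals (1..6), (10..12):
# codon 1 reads genomic 12,11,10 reverse-complemented
toy_minus <- function(seq = "ACGTACGTACGTACG") {
  list(ref = dna_reference(c(chr1 = seq)),
       model = gene_model("gminus", "gminus.t1", "chr1", "-",
                          rbind(c(1L, 6L), c(10L, 12L))))
}

# a minus-strand gene long enough to carry codon 600 = GTG (valine), with the
# BRAF-like A>T at the middle codon position producing Val600Glu
braf_like_fixture <- function() {
  n_cod <- 601L
  set.seed(600)
  codons <- c("ATG", sample(c("GCT", "GAA", "CTG", "AGC", "ACC"),
                            n_cod - 2L, replace = TRUE), "TGA")
  codons[600L] <- "GTG"
  cds <- paste(codons, collapse = "")
  plus <- reverse_complement(cds)   # gene on the minus strand of the contig
  ref <- dna_reference(c(chr7 = plus))
  model <- gene_model("BRAFL", "BRAFL.t1", "chr7", "-",
                      cbind(1L, nchar(plus)))
  # plus-strand position of codon 600, middle base
  pos <- codon_to_genomic(model, 600L)[2]
  list(ref = ref, model = model, pos = pos)
}

# a bare variant row builder
variant_row <- function(sample_id, contig, pos, ref, alt,
                        cohort = "discovery", depth = 50L,
                        alt_reads = 25L) {
  data.frame(sample_id = sample_id, cohort = cohort, contig = contig,
             pos = as.integer(pos), ref = ref, alt = alt,
             depth = as.integer(depth), alt_reads = as.integer(alt_reads),
             stringsAsFactors = FALSE)
}

# minimal annotated-mutation rows for cluster tests (no genome needed)
annotated_row <- function(sample_id, gene, codon, effect = "missense",
                          cohort = "discovery", boundary = NA_integer_,
                          pos = NA_integer_) {
  data.frame(sample_id = sample_id, cohort = cohort,
             contig = "chr1", pos = pos, ref = "C", alt = "T",
             gene_id = gene, transcript_id = paste0(gene, ".t1"),
             codon_index = as.integer(codon),
             aa_ref = "A", aa_alt = "V",
             aa_change = ifelse(is.na(codon), NA,
                                paste0("Ala", codon, "Val")),
             effect_class = effect,
             splice_boundary = as.integer(boundary),
             mutation_type = "C>T (not at CpG)",
             broad_effect = hotspotr:::.broad_effect(effect),
             stringsAsFactors = FALSE)
}

# random gene model + matching reference for property tests
random_gene_fixture <- function(n_codons = sample(5:40, 1),
                                n_exons = sample(1:4, 1),
                                strand = sample(c("+", "-"), 1)) {
  total <- n_codons * 3L
  cuts <- if (n_exons > 1L)
    sort(sample(seq_len(total - 1L), n_exons - 1L)) else integer(0)
  exon_nt <- diff(c(0L, cuts, total))
  cursor <- sample(1:10, 1)
  iv <- matrix(0L, n_exons, 2)
  for (e in seq_len(n_exons)) {
    iv[e, 1] <- cursor
    iv[e, 2] <- cursor + exon_nt[e] - 1L
    cursor <- iv[e, 2] + sample(5:20, 1) + 1L
  }
  contig_len <- cursor + 10L
  seq <- paste(sample(c("A", "C", "G", "T"), contig_len, replace = TRUE),
               collapse = "")
  list(ref = dna_reference(c(ctg = seq)),
       model = gene_model("rg", "rg.t1", "ctg", strand, iv))
}

# --- independent oracles ----------------------------------------------------

# splice-then-translate oracle: extract CDS by substring per exon, reverse
# complement for minus strand, translate with Biostrings machinery
oracle_translate_cds <- function(model, ref) {
  seq <- unclass(ref)[[model$contig]]
  parts <- vapply(seq_len(nrow(model$cds_intervals)), function(i) {
    substr(seq, model$cds_intervals[i, 1], model$cds_intervals[i, 2])
  }, character(1))
  cds <- paste(parts, collapse = "")
  if (model$strand == "-")
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

# brute-force hot-spot oracle: enumerate all mutation pairs, link pairs in
# the same gene with |codon difference| <= 1 (or identical splice boundary),
# take connected components with igraph, then apply the thresholds
oracle_clusters <- function(annotated,
                            qualifying = c("missense", "nonsense",
                                           "splice_site")) {
  idx <- which(annotated$effect_class %in% qualifying &
                 !is.na(annotated$gene_id))
  n <- length(idx)
  edges <- integer(0)
  if (n > 1L) {
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      i <- idx[a]; j <- idx[b]
      if (annotated$gene_id[i] != annotated$gene_id[j]) next
      ci <- annotated$codon_index[i]; cj <- annotated$codon_index[j]
      linked <- if (!is.na(ci) && !is.na(cj)) abs(ci - cj) <= 1L
        else if (is.na(ci) && is.na(cj))
          identical(annotated$splice_boundary[i],
                    annotated$splice_boundary[j]) &&
            !is.na(annotated$splice_boundary[i])
        else FALSE
      if (linked) edges <- c(edges, a, b)
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  lapply(split(idx, comp), identity)
}

# oracle count under the permutation criterion (>= min non-synonymous
# mutations per component, coding only)
oracle_count_clusters <- function(annotated, min_mutations = 2L,
                                  criterion = "mutations") {
  comps <- oracle_clusters(annotated, qualifying = c("missense", "nonsense"))
  comps <- Filter(function(rows) all(!is.na(annotated$codon_index[rows])),
                  comps)
  sizes <- vapply(comps, function(rows) {
    if (criterion == "mutations") length(rows)
    else length(unique(annotated$sample_id[rows]))
  }, integer(1))
  sum(sizes >= min_mutations)
}

# oracle hot-spot list matching detect_hotspots semantics (>=2 mutations and
# >= min_samples distinct samples)
oracle_hotspots <- function(annotated, min_samples = 2L) {
  comps <- oracle_clusters(annotated)
  keep <- Filter(function(rows) {
    length(rows) >= 2L &&
      length(unique(annotated$sample_id[rows])) >= min_samples
  }, comps)
  sig <- vapply(keep, function(rows) {
    paste(annotated$gene_id[rows[1]],
          paste(sort(rows), collapse = ","))
  }, character(1))
  sort(unname(sig))
}

# signature of detect_hotspots output comparable to oracle_hotspots
detected_signature <- function(hs, annotated) {
  if (nrow(hs) == 0L) return(character(0))
  sort(vapply(seq_len(nrow(hs)), function(i) {
    paste(hs$gene_id[i], paste(sort(hs$rows[[i]]), collapse = ","))
  }, character(1)))
}

# random annotated tables for the detector-vs-oracle property suite
random_annotated <- function(n = sample(2:12, 1), n_genes = 2L,
                             n_samples = 4L, max_codon = 8L) {
  effects <- sample(c("missense", "nonsense", "synonymous", "splice_site",
                      "noncoding"), n, replace = TRUE,
                    prob = c(.4, .15, .2, .15, .1))
  genes <- paste0("g", sample(seq_len(n_genes), n, replace = TRUE))
  codon <- ifelse(effects %in% c("missense", "nonsense", "synonymous"),
                  sample(seq_len(max_codon), n, replace = TRUE),
                  NA_integer_)
  boundary <- ifelse(effects == "splice_site",
                     sample(c(100L, 200L), n, replace = TRUE), NA_integer_)
  genes[effects == "noncoding"] <- NA_character_
  do.call(rbind, lapply(seq_len(n), function(i) {
    annotated_row(paste0("s", sample(seq_len(n_samples), 1)),
                  genes[i], codon[i], effects[i], boundary = boundary[i])
  }))
}
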