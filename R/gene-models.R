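#' Construct a CDS gene model
#'
#' A gene model is one canonical transcript: a strand, and an ordered set of
#' non-overlapping CDS intervals (1-based, closed) on one contig. The model
#' precomputes the genomic positions of the coding sequence in translation
#' order, which defines the codon numbering used for all consequence calls.
#'
#' @param gene_id gene identifier.
#' @param transcript_id transcript identifier (the canonical transcript whose
#'   CDS defines codon numbering).
#' @param contig contig name.
#' @param strand "+" or "-".
#' @param cds_intervals two-column matrix (or data.frame) of 1-based closed
#'   genomic intervals `[start, end]`; any order, they are sorted internally.
#' @param gene_symbol display symbol; defaults to `gene_id`.
#' @return an object of class `gene_model` with elements `gene_id`,
#'   `gene_symbol`, `transcript_id`, `contig`, `strand`, `cds_intervals`
#'   (sorted matrix), `cds_length`, and `coding_pos` (genomic positions of the
#'   CDS, 5' to 3' in translation order, so `coding_pos[1:3]` is codon 1).
#' @export
gene_model <- function(gene_id, transcript_id, contig, strand, cds_intervals,
                       gene_symbol = gene_id) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  iv <- as.matrix(cds_intervals)
  storage.mode(iv) <- "integer"
  if (ncol(iv) != 2L || nrow(iv) < 1L)
    stop("cds_intervals must have >= 1 row and 2 columns (start, end)")
  if (any(iv[, 1] > iv[, 2]))
    stop("CDS interval with start > end in transcript ", transcript_id)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1L, 1] <= iv[-nrow(iv), 2]))
    stop("overlapping CDS intervals in transcript ", transcript_id)
  cds_length <- sum(iv[, 2] - iv[, 1] + 1L)
  if (cds_length %% 3L != 0L)
    stop("CDS length ", cds_length, " not divisible by 3 in transcript ",
         transcript_id)
  coding_pos <- if (strand == "+") {
    unlist(lapply(seq_len(nrow(iv)), function(i) iv[i, 1]:iv[i, 2]),
           use.names = FALSE)
  } else {
    unlist(lapply(rev(seq_len(nrow(iv))), function(i) iv[i, 2]:iv[i, 1]),
           use.names = FALSE)
  }
  structure(
    list(gene_id = gene_id, gene_symbol = gene_symbol,
         transcript_id = transcript_id, contig = contig, strand = strand,
         cds_intervals = iv, cds_length = cds_length,
         coding_pos = as.integer(coding_pos)),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model ", x$gene_symbol, " (", x$transcript_id, ") ", x$contig,
      ":", min(x$cds_intervals), "-", max(x$cds_intervals), " (", x$strand,
      "), ", nrow(x$cds_intervals), " CDS exon(s), ", x$cds_length,
      " nt = ", x$cds_length %/% 3L, " codons\n", sep = "")
  invisible(x)
}

#' Number of codons in a gene model
#' @param model a [gene_model()].
#' @return integer codon count.
#' @export
n_codons <- function(model) model$cds_length %/% 3L

#' Genomic span of a gene model's CDS
#' @param model a [gene_model()].
#' @return integer vector `c(start, end)` on the genome.
#' @export
gene_span <- function(model) {
  c(min(model$cds_intervals[, 1]), max(model$cds_intervals[, 2]))
}

#' Map a genomic position to codon coordinates
#'
#' Coding positions map to `(codon_index, offset)` with `offset` in 0..2 along
#' the translation direction. Non-coding positions return `coding = FALSE`
#' together with the region ("intronic" when the position lies between CDS
#' exons, "flanking" otherwise), the distance to the nearest CDS exon edge,
#' and that edge's genomic coordinate. Splice-flank classification downstream
#' uses intronic positions with distance 1 or 2.
#'
#' @param model a [gene_model()].
#' @param pos 1-based genomic position on the model's contig.
#' @param contig optional contig name to check against the model.
#' @return list with elements `coding`, `codon_index`, `offset`, `region`,
#'   `boundary_distance`, `boundary_pos` (NA where not applicable).
#' @examples
#' gm <- gene_model("g", "t", "chr1", "+", cbind(1, 9))
#' genomic_to_codon(gm, 5)  # codon 2, offset 1
#' @export
genomic_to_codon <- function(model, pos, contig = NULL) {
  stopifnot(inherits(model, "gene_model"), length(pos) == 1L)
  if (!is.null(contig) && contig != model$contig)
    stop("position is on contig ", contig, " but model is on ", model$contig)
  idx <- match(as.integer(pos), model$coding_pos)
  if (!is.na(idx)) {
    return(list(coding = TRUE,
                codon_index = ((idx - 1L) %/% 3L) + 1L,
                offset = (idx - 1L) %% 3L,
                region = "coding",
                boundary_distance = NA_integer_,
                boundary_pos = NA_integer_))
  }
  iv <- model$cds_intervals
  span <- gene_span(model)
  # distance to nearest exon edge, and that edge
  edges <- c(iv[, 1], iv[, 2])
  d <- abs(pos - edges)
  k <- which.min(d)
  list(coding = FALSE, codon_index = NA_integer_, offset = NA_integer_,
       region = if (pos >= span[1] && pos <= span[2]) "intronic" else "flanking",
       boundary_distance = as.integer(d[k]),
       boundary_pos = as.integer(edges[k]))
}

#' Genomic positions of a codon
#'
#' @param model a [gene_model()].
#' @param codon_index codon number in 1..[n_codons()].
#' @return integer vector of the 3 genomic positions, in translation order
#'   (for minus-strand genes these descend).
#' @export
codon_to_genomic <- function(model, codon_index) {
  stopifnot(inherits(model, "gene_model"), length(codon_index) == 1L)
  if (codon_index < 1L || codon_index > n_codons(model))
    stop("codon_index ", codon_index, " outside 1..", n_codons(model))
  model$coding_pos[(codon_index - 1L) * 3L + 1:3]
}

#' Load gene models from GTF or JSON
#'
#' Reads canonical-transcript CDS structures. The GTF dialect uses `CDS`
#' feature rows grouped by `transcript_id` (with `gene_id`, and `gene_name`
#' when present). The JSON dialect is an array of objects
#' `{gene, transcript, contig, strand, cds: [[start, end], ...]}` with
#' 1-based closed intervals and an optional `symbol` field. Every transcript
#' must have a CDS length divisible by 3; violations raise an error naming
#' the transcript.
#'
#' @param path file path.
#' @param dialect "gtf", "json", or "auto" (by file extension).
#' @return list of [gene_model()] objects, named by gene id.
#' @export
load_gene_models <- function(path, dialect = c("auto", "gtf", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "gtf"
  }
  models <- switch(dialect,
    gtf = .load_models_gtf(path),
    json = .load_models_json(path))
  if (length(models) == 0L) stop("no CDS transcripts found in ", path)
  stats::setNames(models, vapply(models, `[[`, character(1), "gene_id"))
}

.load_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) return(list())
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stop("GTF CDS records lack transcript_id attributes: ", path)
  tx <- split(seq_along(gr), gr$transcript_id)
  lapply(tx, function(i) {
    sub <- gr[i]
    strand <- as.character(S4Vectors::runValue(GenomicRanges::strand(sub)))
    if (length(unique(strand)) != 1L || strand[1] == "*")
      stop("transcript ", sub$transcript_id[1], " has inconsistent strand")
    symbol <- if (!is.null(sub$gene_name) && !is.na(sub$gene_name[1]))
      sub$gene_name[1] else sub$gene_id[1]
    gene_model(gene_id = sub$gene_id[1], transcript_id = sub$transcript_id[1],
               contig = as.character(GenomicRanges::seqnames(sub))[1],
               strand = strand[1],
               cds_intervals = cbind(GenomicRanges::start(sub),
                                     GenomicRanges::end(sub)),
               gene_symbol = symbol)
  })
}

.load_models_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    need <- c("gene", "transcript", "contig", "strand", "cds")
    miss <- setdiff(need, names(r))
    if (length(miss))
      stop("gene-model JSON record missing field(s): ",
           paste(miss, collapse = ", "))
    iv <- do.call(rbind, lapply(r$cds, function(p) as.integer(unlist(p))))
    gene_model(gene_id = r$gene, transcript_id = r$transcript,
               contig = r$contig, strand = r$strand, cds_intervals = iv,
               gene_symbol = r$symbol %||% r$gene)
  })
}

#' Write gene models as JSON
#' @param models list of [gene_model()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gene_models_json <- function(models, path) {
  recs <- lapply(models, function(m) {
    list(gene = m$gene_id, symbol = m$gene_symbol,
         transcript = m$transcript_id, contig = m$contig, strand = m$strand,
         cds = lapply(seq_len(nrow(m$cds_intervals)),
                      function(i) m$cds_intervals[i, ]))
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE)
  invisible(path)
}

#' Write gene models as GTF
#' @param models list of [gene_model()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gene_models_gtf <- function(models, path) {
  rows <- lapply(models, function(m) {
    data.frame(
      seqname = m$contig, source = "hotspotr", feature = "CDS",
      start = m$cds_intervals[, 1], end = m$cds_intervals[, 2],
      score = ".", strand = m$strand, frame = ".",
      attribute = sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_name "%s";',
        m$gene_id, m$transcript_id, m$gene_symbol),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Spliced CDS sequence of a model
#'
#' Concatenates the CDS in translation order, complementing for minus-strand
#' models; the result is the mRNA-sense coding sequence.
#'
#' @param model a [gene_model()].
#' @param ref a [dna_reference()].
#' @return character scalar of length `cds_length`.
#' @export
cds_sequence <- function(model, ref) {
  b <- ref_base(ref, model$coding_pos, model$contig)
  if (model$strand == "-") b <- complement_base(b)
  paste(b, collapse = "")
}
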