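#' In-memory reference sequence set
#'
#' A minimal container for one or more reference contigs, stored as uppercase
#' character strings over the DNA alphabet (A, C, G, T, N). Lookup is 1-based.
#'
#' @param sequences named character vector; names are contig names, values the
#'   contig sequences. Lowercase input is upcased.
#' @return an object of class `dna_reference`.
#' @examples
#' ref <- dna_reference(c(chr1 = "ACGT"))
#' ref_base(ref, 2)
#' @export
dna_reference <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("every reference sequence must be named by its contig")
  if (anyDuplicated(names(sequences)))
    stop("duplicated contig names in reference")
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0L)) stop("empty reference sequence")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("reference contains non-DNA characters in contig(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  structure(as.list(sequences), class = "dna_reference")
}

#' @export
print.dna_reference <- function(x, ...) {
  cat("dna_reference with", length(x), "contig(s):\n")
  for (nm in names(x)) cat("  ", nm, ": ", nchar(x[[nm]]), " bp\n", sep = "")
  invisible(x)
}

#' Contig names of a reference
#' @param ref a [dna_reference()].
#' @return character vector of contig names.
#' @export
contig_names <- function(ref) names(ref)

.get_contig <- function(ref, contig = NULL) {
  stopifnot(inherits(ref, "dna_reference"))
  if (is.null(contig)) {
    if (length(ref) != 1L)
      stop("reference has ", length(ref), " contigs; specify `contig`")
    return(ref[[1L]])
  }
  seq <- ref[[contig]]
  if (is.null(seq)) stop("unknown contig: ", contig)
  seq
}

#' Reference base at 1-based positions
#'
#' @param ref a [dna_reference()].
#' @param pos integer vector of 1-based positions.
#' @param contig contig name; may be omitted for a single-contig reference.
#' @return character vector of bases.
#' @export
ref_base <- function(ref, pos, contig = NULL) {
  seq <- .get_contig(ref, contig)
  if (any(pos < 1L | pos > nchar(seq)))
    stop("position out of range for contig of length ", nchar(seq))
  substring(seq, pos, pos)
}

#' Base and immediate neighbors at a position
#'
#' Returns the reference base at each position together with the preceding and
#' following base. Neighbors that fall outside the contig are reported as "N".
#'
#' @inheritParams ref_base
#' @return data.frame with columns `base`, `before`, `after`.
#' @examples
#' ref <- dna_reference(c(chr1 = "ACGT"))
#' context_at(ref, 1)  # A with N before, C after
#' @export
context_at <- function(ref, pos, contig = NULL) {
  seq <- .get_contig(ref, contig)
  n <- nchar(seq)
  if (any(pos < 1L | pos > n))
    stop("position out of range for contig of length ", n)
  base <- substring(seq, pos, pos)
  before <- ifelse(pos > 1L, substring(seq, pos - 1L, pos - 1L), "N")
  after <- ifelse(pos < n, substring(seq, pos + 1L, pos + 1L), "N")
  data.frame(base = base, before = before, after = after,
             stringsAsFactors = FALSE)
}

#' CpG status of reference positions
#'
#' A position is "at CpG" when its plus-strand base is a C immediately
#' followed by G, or a G immediately preceded by C. Positions with an N
#' neighbor, or with any other base, are not at CpG.
#'
#' @inheritParams ref_base
#' @return logical vector.
#' @export
is_cpg <- function(ref, pos, contig = NULL) {
  ctx <- context_at(ref, pos, contig)
  (ctx$base == "C" & ctx$after == "G") | (ctx$base == "G" & ctx$before == "C")
}

#' Read a reference FASTA
#' @param path FASTA file.
#' @return a [dna_reference()].
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  dna_reference(stats::setNames(as.character(ss), nm))
}

#' Write a reference FASTA
#' @param ref a [dna_reference()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_reference_fasta <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(unlist(unclass(ref)))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
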