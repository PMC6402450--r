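#' Round half away from zero
#'
#' Fixed-point rounding where ties go up (0.05 -> 0.1), the convention used in
#' the cohort frequency tables. Base [round()] rounds half to even, which would
#' turn 27.75 into 27.7 rather than 27.8.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

DNA_BASES <- c("A", "C", "G", "T")

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

complement_base <- function(base) {
  out <- .complement[base]
  if (anyNA(out)) stop("cannot complement non-DNA base: ",
                       paste(unique(base[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T/N.
#' @return character scalar.
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  paste(rev(complement_base(strsplit(x, "", fixed = TRUE)[[1]])), collapse = "")
}

variant_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# translate a codon string with the standard genetic code; "*" is stop
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  if (anyNA(aa)) stop("cannot translate codon: ",
                      paste(unique(codon[is.na(aa)]), collapse = ", "))
  unname(aa)
}

.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", `*` = "Ter")

aa_three_letter <- function(aa) unname(.AA3[aa])
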