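#' Build a normalized capture-region set
#'
#' Capture regions are the genomic intervals targeted by the exome enrichment
#' kit: the universe both for retained somatic calls and for permutation
#' placement. In memory they are a merged (reduced), sorted
#' [GenomicRanges::GRanges] with 1-based closed coordinates; on disk they are
#' BED (0-based half-open), converted on read/write by rtracklayer.
#'
#' @param contig contig names, or a `GRanges` (in which case the other
#'   arguments are ignored).
#' @param start,end 1-based closed interval bounds.
#' @return merged `GRanges`.
#' @export
capture_regions <- function(contig, start = NULL, end = NULL) {
  gr <- if (methods::is(contig, "GRanges")) contig else
    GenomicRanges::GRanges(contig, IRanges::IRanges(start, end))
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' Read capture regions from BED
#' @param path BED file (0-based half-open on disk).
#' @return merged `GRanges` (1-based closed in memory).
#' @export
read_capture_bed <- function(path) {
  capture_regions(rtracklayer::import(path, format = "BED"))
}

#' Write capture regions to BED
#' @param regions `GRanges` of capture intervals.
#' @param path output BED file.
#' @return invisibly, `path`.
#' @export
write_capture_bed <- function(regions, path) {
  rtracklayer::export(capture_regions(regions), path, format = "BED")
  invisible(path)
}

#' Membership of positions in capture regions
#'
#' @param regions `GRanges` from [capture_regions()].
#' @param contig contig name(s), recycled against `pos`.
#' @param pos 1-based positions.
#' @return logical vector.
#' @export
in_capture <- function(regions, contig, pos) {
  if (length(pos) == 0L) return(logical(0))
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
  GenomicRanges::countOverlaps(q, regions) > 0L
}

#' Enumerate every base covered by the capture
#'
#' @param regions `GRanges` from [capture_regions()].
#' @return data.frame with columns `contig`, `pos` (1-based), one row per
#'   covered base.
#' @export
capture_positions <- function(regions) {
  regions <- capture_regions(regions)
  if (length(regions) == 0L)
    return(data.frame(contig = character(0), pos = integer(0)))
  w <- GenomicRanges::width(regions)
  data.frame(
    contig = rep(as.character(GenomicRanges::seqnames(regions)), w),
    pos = unlist(lapply(seq_along(regions), function(i) {
      GenomicRanges::start(regions)[i]:GenomicRanges::end(regions)[i]
    }), use.names = FALSE),
    stringsAsFactors = FALSE)
}
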