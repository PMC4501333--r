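#' Read aligned intervals from a BED file
#'
#' Reads a BED3/BED6 file into a `GRanges` (1-based closed internally;
#' the file is 0-based half-open). Strand is honoured when present.
#'
#' @param path BED file path.
#' @param layout optional `GenomeLayout`; when supplied, reads on unknown
#'   chromosomes or beyond chromosome ends raise an error.
#' @return a `GRanges` of reads.
#' @export
read_bed <- function(path, layout = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(layout)) validate_reads(gr, layout)
  gr
}

#' Write intervals to a BED6 file
#' @param gr a `GRanges`; `name` and `score` metadata columns are used
#'   when present.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Validate reads against a genome layout
#'
#' Rejects reads on chromosomes absent from the layout (error names the
#' chromosome) and reads extending past a chromosome end.
#'
#' @param reads a `GRanges`.
#' @param layout a `GenomeLayout`.
#' @return the reads, invisibly, if valid.
#' @export
validate_reads <- function(reads, layout) {
  chr <- as.character(GenomeInfoDb::seqnames(reads))
  unknown <- setdiff(unique(chr), names(layout$chroms))
  if (length(unknown))
    stop("reads on chromosome(s) not in layout: ",
         paste(unknown, collapse = ", "))
  ends <- BiocGenerics::end(reads)
  lens <- layout$chroms[chr]
  if (any(ends > lens)) {
    bad <- which(ends > lens)[1]
    stop(sprintf("read beyond chromosome end: %s:%d-%d (length %d)",
                 chr[bad], BiocGenerics::start(reads)[bad] - 1L,
                 ends[bad], lens[chr[bad]]))
  }
  if (any(BiocGenerics::start(reads) < 1L))
    stop("read with negative start coordinate")
  invisible(reads)
}

#' Collapse duplicate reads to unique stacks
#'
#' Identical (chrom, start, strand) combinations are collapsed to a single
#' read, mirroring the use of uniquely aligned reads converted to unique
#' stack height profiles.
#'
#' @param reads a `GRanges`.
#' @return deduplicated `GRanges`.
#' @export
dedup_reads <- function(reads) {
  key <- paste(as.character(GenomeInfoDb::seqnames(reads)),
               BiocGenerics::start(reads),
               as.character(BiocGenerics::strand(reads)), sep = ":")
  reads[!duplicated(key)]
}
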