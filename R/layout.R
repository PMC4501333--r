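#' Genome layout: chromosome sizes and bin geometry
#'
#' A `GenomeLayout` fixes the coordinate system for all binned tracks:
#' an ordered set of chromosomes with lengths, and a bin size (default
#' 20 bp). Coordinates are 0-based half-open externally (BED convention);
#' bins are indexed 1..ceiling(length / bin_size), bin `i` covering
#' `[(i-1)*bin_size, i*bin_size)`.
#'
#' @param chrom_sizes named integer vector (or two-column data.frame of
#'   name, length) of chromosome lengths in bp.
#' @param bin_size bin width in bp.
#' @return an object of class `GenomeLayout`.
#' @export
genome_layout <- function(chrom_sizes, bin_size = 20L) {
  if (is.data.frame(chrom_sizes)) {
    sizes <- as.numeric(chrom_sizes[[2]])
    names(sizes) <- as.character(chrom_sizes[[1]])
    chrom_sizes <- sizes
  }
  if (is.null(names(chrom_sizes)) || anyNA(names(chrom_sizes)))
    stop("chrom_sizes must be named by chromosome")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be > 0")
  if (bin_size <= 0) stop("bin_size must be > 0")
  structure(
    list(chroms = stats::setNames(as.integer(chrom_sizes), names(chrom_sizes)),
         bin_size = as.integer(bin_size)),
    class = "GenomeLayout"
  )
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat("GenomeLayout:", length(x$chroms), "chromosome(s),",
      sum(as.numeric(x$chroms)), "bp, bin size", x$bin_size, "bp\n")
  invisible(x)
}

#' Number of bins per chromosome
#' @param layout a `GenomeLayout`.
#' @return named integer vector of bin counts.
#' @export
n_bins <- function(layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  stats::setNames(as.integer(ceiling(layout$chroms / layout$bin_size)),
                  names(layout$chroms))
}

#' Bin index of a 0-based position
#' @param pos 0-based bp position(s).
#' @param layout a `GenomeLayout`.
#' @return 1-based bin index.
#' @export
pos_to_bin <- function(pos, layout) {
  as.integer(pos %/% layout$bin_size) + 1L
}

#' 0-based start coordinate of a 1-based bin index
#' @param bin 1-based bin index.
#' @param layout a `GenomeLayout`.
#' @export
bin_start <- function(bin, layout) (bin - 1L) * layout$bin_size

#' Read a two-column chrom-sizes file
#' @param path file with columns chrom, length.
#' @param bin_size bin width passed to [genome_layout()].
#' @export
read_chrom_sizes <- function(path, bin_size = 20L) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  genome_layout(stats::setNames(df$length, df$chrom), bin_size)
}

#' Write a chrom-sizes file
#' @param layout a `GenomeLayout`.
#' @param path output path.
#' @export
write_chrom_sizes <- function(layout, path) {
  utils::write.table(
    data.frame(chrom = names(layout$chroms), length = layout$chroms),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Seqinfo for a layout (for GRanges interop)
#' @param layout a `GenomeLayout`.
#' @return a [GenomeInfoDb::Seqinfo] object.
#' @export
layout_seqinfo <- function(layout) {
  GenomeInfoDb::Seqinfo(seqnames = names(layout$chroms),
                        seqlengths = unname(layout$chroms))
}
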