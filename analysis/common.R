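# Shared plumbing for the numbered analysis drivers: seed handling and
# deterministic reconstruction of the synthetic study dataset. Every
# driver regenerates its inputs from the seed rather than reading large
# intermediates, so any script can be run on its own.

suppressMessages(library(poliiscan))

get_seed <- function(default = 1L) {
  args <- commandArgs(trailingOnly = TRUE)
  i <- which(args == "--seed")
  if (length(i) == 1 && i < length(args)) as.integer(args[i + 1]) else default
}

results_dir <- function() {
  d <- file.path("results")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

build_dataset <- function(seed) synthetic_mini_dataset(seed = seed)

run_detection <- function(ds) {
  detect(ds$reads, ds$layout, detection_config(),
         mappability = ds$mappability, input_reads = ds$input)
}

truth_granges <- function(ds) {
  GenomicRanges::GRanges(ds$features$chrom,
                         IRanges::IRanges(ds$features$center - ds$features$width / 2,
                                          ds$features$center + ds$features$width / 2))
}

union_granges <- function(det) {
  GenomicRanges::GRanges(det$union$chrom,
                         IRanges::IRanges(det$union$start + 1, det$union$end))
}
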