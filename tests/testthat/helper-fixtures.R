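# Shared fixture builders. Everything is generated in code; no files.

toy_layout <- function(len = 2000L, bin = 20L, name = "chrT") {
  genome_layout(stats::setNames(as.integer(len), name), bin)
}

# GRanges reads from plain vectors (0-based starts, BED-style)
make_reads <- function(chrom, start0, width = 36L, strand = "+") {
  GenomicRanges::GRanges(rep(chrom, length.out = length(start0)),
                         IRanges::IRanges(start = start0 + 1L, width = width),
                         strand = rep(strand, length.out = length(start0)))
}

# A smoothed RPM track carrying one or more triangular peaks on a flat
# background; values set analytically (no sampling).
peak_track <- function(layout, centers_bp, heights, width_bp = 600,
                       background = 5) {
  nb <- n_bins(layout)[[1]]
  B <- layout$bin_size
  v <- rep(background, nb)
  mids <- (seq_len(nb) - 0.5) * B
  for (i in seq_along(centers_bp)) {
    tri <- pmax(0, 1 - abs(mids - centers_bp[i]) / (width_bp / 2))
    v <- v + (heights[i] - background) * tri
  }
  binned_track(layout, v, normalization = "rpm", library_size = 1e6,
               smoothed = TRUE)
}

# Random processed fixture for oracle-equivalence testing: flat
# background plus 0-3 planted triangular peaks, optional masked and
# blacklisted bins, plus random reads for tag statistics.
random_fixture <- function(seed) {
  set.seed(seed)
  len <- sample(2000:10000, 1)
  layout <- toy_layout(len)
  nb <- n_bins(layout)[[1]]
  bg <- runif(1, 2, 8)
  v <- bg + rnorm(nb, 0, bg / 10)
  npk <- sample(0:3, 1)
  centers <- if (npk) sort(sample(seq(400, len - 400, by = 20), npk)) else numeric(0)
  B <- layout$bin_size
  mids <- (seq_len(nb) - 0.5) * B
  for (cc in centers) {
    w <- sample(c(300, 500, 700), 1)
    h <- runif(1, 4, 12) * bg
    v <- v + h * pmax(0, 1 - abs(mids - cc) / (w / 2))
  }
  v <- pmax(v, 0)
  mask <- integer(nb)
  if (runif(1) < 0.5) mask[sample(nb, sample(1:3, 1))] <- 1L   # masked
  if (runif(1) < 0.3) mask[sample(nb, sample(1:2, 1))] <- 3L   # blacklisted
  tr <- binned_track(layout, v, mask = list(chrT = mask),
                     normalization = "rpm", library_size = 1e6)
  tr <- smooth_track(tr)
  nreads <- rpois(1, len / 3)
  reads <- make_reads("chrT", sample(0:(len - 36), nreads, replace = TRUE))
  list(track = tr, reads = reads, layout = layout)
}

empty_truth <- function(conditions = "LD") {
  df <- data.frame(id = character(), chrom = character(), center = numeric(),
                   width = numeric(), stage = character(),
                   motif = character(), stringsAsFactors = FALSE)
  for (cond in conditions) df[[paste0("m_", cond)]] <- numeric()
  df
}

# one-feature truth table for small simulations
one_feature_truth <- function(chrom, center, width = 600,
                              multipliers = c(LD = 1, LD_DMI = 1,
                                              HD = 8, HD_DMI = 8),
                              stage = "HD_primed", motif = "none") {
  df <- data.frame(id = "T001", chrom = chrom, center = center,
                   width = width, stage = stage, motif = motif,
                   stringsAsFactors = FALSE)
  for (cond in names(multipliers))
    df[[paste0("m_", cond)]] <- multipliers[[cond]]
  df
}
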