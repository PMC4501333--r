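#' @importFrom methods is
NULL

# Mask channel codes shared by all binned tracks.
MASK_VALID <- 0L
MASK_MASKED <- 1L
MASK_INTERPOLATED <- 2L
MASK_BLACKLISTED <- 3L

#' Mask channel codes of a binned track
#'
#' @return named integer vector mapping state names to codes:
#'   valid = 0, masked = 1, interpolated = 2, blacklisted = 3.
#' @export
mask_codes <- function() {
  c(valid = MASK_VALID, masked = MASK_MASKED,
    interpolated = MASK_INTERPOLATED, blacklisted = MASK_BLACKLISTED)
}

#' Construct a binned track from per-bin values
#'
#' Builds a `BinnedTrack` directly from per-chromosome value vectors,
#' e.g. for externally computed coverage or for tests.
#'
#' @param layout a `GenomeLayout`.
#' @param values named list of per-bin numeric vectors (or a single
#'   vector for a one-chromosome layout).
#' @param mask optional mask list (defaults to all-valid); see
#'   [mask_codes()].
#' @param normalization "raw" or "rpm".
#' @param library_size total reads behind the track.
#' @param smoothed whether the values are already smoothed.
#' @return a `BinnedTrack`.
#' @export
binned_track <- function(layout, values, mask = NULL,
                         normalization = "raw", library_size = NA_integer_,
                         smoothed = FALSE) {
  if (is.numeric(values)) {
    values <- stats::setNames(list(values), names(layout$chroms)[1])
  }
  nb <- n_bins(layout)
  if (!identical(unname(lengths(values)[names(layout$chroms)]),
                 unname(as.integer(nb))))
    stop("values are not aligned to the layout's bins")
  if (is.null(mask)) mask <- lapply(values, function(v) integer(length(v)))
  new_binned_track(layout, values, mask, normalization, library_size,
                   smoothed)
}

new_binned_track <- function(layout, values, mask, normalization, library_size,
                             smoothed = FALSE) {
  structure(
    list(layout = layout, values = values, mask = mask,
         normalization = normalization, library_size = library_size,
         smoothed = smoothed),
    class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  nb <- sum(lengths(x$values))
  cat(sprintf(
    "BinnedTrack: %d bins (%d bp), %s, library %d, %d masked / %d interpolated / %d blacklisted%s\n",
    nb, x$layout$bin_size, x$normalization, x$library_size,
    sum(unlist(x$mask) == MASK_MASKED),
    sum(unlist(x$mask) == MASK_INTERPOLATED),
    sum(unlist(x$mask) == MASK_BLACKLISTED),
    if (isTRUE(x$smoothed)) ", smoothed" else ""))
  invisible(x)
}

check_same_layout <- function(a, b) {
  if (!identical(a$layout$chroms, b$layout$chroms) ||
      !identical(a$layout$bin_size, b$layout$bin_size))
    stop("tracks have mismatched genome layouts")
}

#' Genome-wide mean signal over usable bins
#'
#' Mean of the per-bin values over valid and (optionally) interpolated
#' bins, across all chromosomes. Blacklisted and masked bins are excluded.
#'
#' @param track a `BinnedTrack`.
#' @param include_interpolated include interpolated bins in the mean.
#' @export
track_mean <- function(track, include_interpolated = TRUE) {
  codes <- if (include_interpolated) c(MASK_VALID, MASK_INTERPOLATED) else MASK_VALID
  v <- unlist(track$values, use.names = FALSE)
  m <- unlist(track$mask, use.names = FALSE)
  keep <- m %in% codes
  if (!any(keep)) return(0)
  mean(v[keep])
}

#' Bin read coverage into a USHP track
#'
#' Converts aligned reads to a unique stack height profile (USHP): the
#' per-base pileup of uniquely aligned reads, summarised per bin (mean
#' per-base depth by default). This is the raw coverage signal all
#' downstream steps operate on. Reads are taken as already unique;
#' `dedup = TRUE` additionally collapses identical (chrom, start, strand)
#' stacks, an option for raw aligned data still carrying PCR duplicates.
#'
#' @param reads a `GRanges` of aligned reads.
#' @param layout a `GenomeLayout`.
#' @param summary per-bin summary of the per-base pileup: `"mean"`
#'   (default; preserves tag-count arithmetic downstream) or `"max"`.
#' @param dedup collapse duplicate (chrom, start, strand) reads first.
#' @return a raw `BinnedTrack` with an all-valid mask and the retained
#'   read count as `library_size`.
#' @export
bin_coverage <- function(reads, layout, summary = c("mean", "max"),
                         dedup = FALSE) {
  summary <- match.arg(summary)
  validate_reads(reads, layout)
  if (dedup) reads <- dedup_reads(reads)
  chroms <- names(layout$chroms)
  rchr <- as.character(GenomeInfoDb::seqnames(reads))
  values <- vector("list", length(chroms))
  names(values) <- chroms
  for (ch in chroms) {
    len <- layout$chroms[[ch]]
    nb <- as.integer(ceiling(len / layout$bin_size))
    sel <- rchr == ch
    if (!any(sel)) {
      values[[ch]] <- numeric(nb)
      next
    }
    ir <- IRanges::IRanges(start = BiocGenerics::start(reads)[sel],
                           end = BiocGenerics::end(reads)[sel])
    cov <- IRanges::coverage(ir, width = len)
    starts <- seq.int(1L, len, by = layout$bin_size)
    widths <- pmin(layout$bin_size, len - starts + 1L)
    vw <- IRanges::Views(cov, start = starts, width = widths)
    values[[ch]] <- if (summary == "mean") IRanges::viewMeans(vw)
                    else as.numeric(IRanges::viewMaxs(vw))
  }
  mask <- lapply(values, function(v) integer(length(v)))
  new_binned_track(layout, values, mask, "raw", length(reads))
}

#' Normalize a track to reads per million (RPM)
#'
#' Applies the library-size normalization factor `1e6 / library_size`
#' to every bin, so tracks with different sequencing depths are
#' comparable.
#'
#' @param track a raw `BinnedTrack` with `library_size > 0`.
#' @return the RPM-normalized track.
#' @export
normalize_rpm <- function(track) {
  stopifnot(inherits(track, "BinnedTrack"))
  if (track$normalization == "rpm")
    stop("track is already RPM-normalized")
  if (is.null(track$library_size) || track$library_size <= 0)
    stop("library_size must be > 0 for RPM normalization")
  f <- 1e6 / track$library_size
  track$values <- lapply(track$values, function(v) v * f)
  track$normalization <- "rpm"
  track
}

#' Mask bins of low mappability and no signal
#'
#' Flags bins whose mappability (alignability/uniqueness score in \[0,1\])
#' falls below `threshold` *and* whose signal is at or below `max_signal`
#' (default 0: no coverage). Such bins are artifactual coverage gaps, not
#' true signal deserts, and are later candidates for interpolation.
#'
#' @param track a `BinnedTrack`.
#' @param mappability per-bin mappability, as a named list of numeric
#'   vectors aligned to the track layout (one vector per chromosome).
#' @param threshold mappability below which a bin can be masked.
#' @param max_signal highest signal a maskable bin may carry.
#' @return the track with masked bins flagged.
#' @export
mask_low_mappability <- function(track, mappability, threshold = 0.5,
                                 max_signal = 0) {
  stopifnot(inherits(track, "BinnedTrack"))
  if (!identical(lengths(mappability)[names(track$values)],
                 lengths(track$values)))
    stop("mappability is not aligned to the track layout")
  for (ch in names(track$values)) {
    hit <- mappability[[ch]] < threshold & track$values[[ch]] <= max_signal &
      track$mask[[ch]] == MASK_VALID
    track$mask[[ch]][hit] <- MASK_MASKED
    track$values[[ch]][hit] <- 0
  }
  track
}

#' Interpolate masked bins next to enriched signal
#'
#' Masked bins flanked, within `scan_distance` bins on each side, by valid
#' bins are assigned the mean of the nearest valid upstream and downstream
#' bin values, provided the stronger flank is at least `enrich_fold` times
#' the genome-wide mean (i.e. the gap interrupts an enriched region, not
#' background). Isolated masked deserts stay masked.
#'
#' @param track a `BinnedTrack` with a mask channel.
#' @param scan_distance bins searched on each side for a valid neighbor.
#' @param enrich_fold enrichment floor for the flanking signal, as a
#'   multiple of the genome-wide mean.
#' @return the track with qualifying bins interpolated.
#' @export
interpolate_masked <- function(track, scan_distance = 3L, enrich_fold = 2) {
  stopifnot(inherits(track, "BinnedTrack"))
  gmean <- track_mean(track, include_interpolated = FALSE)
  floor_val <- enrich_fold * gmean
  for (ch in names(track$values)) {
    m <- track$mask[[ch]]
    v <- track$values[[ch]]
    idx <- which(m == MASK_MASKED)
    if (!length(idx)) next
    n <- length(v)
    for (i in idx) {
      up <- NA_real_
      for (d in seq_len(scan_distance)) {
        j <- i - d
        if (j >= 1L && m[j] == MASK_VALID) { up <- v[j]; break }
      }
      dn <- NA_real_
      for (d in seq_len(scan_distance)) {
        j <- i + d
        if (j <= n && m[j] == MASK_VALID) { dn <- v[j]; break }
      }
      if (!is.na(up) && !is.na(dn) && max(up, dn) >= floor_val) {
        v[i] <- (up + dn) / 2
        m[i] <- MASK_INTERPOLATED
      }
    }
    track$values[[ch]] <- v
    track$mask[[ch]] <- m
  }
  track
}

#' Smooth a track with a 3-bin (60 bp) moving average
#'
#' Recalculates each usable bin as the moving average of the 60 bp window
#' centered on it (the bin and its two neighbors at 20 bp bins). Masked
#' and blacklisted bins contribute nothing and are not changed; bins at
#' chromosome ends average the available neighbors only, avoiding
#' artificial edge slopes from zero padding.
#'
#' @param track a `BinnedTrack`.
#' @return the smoothed track (flagged `smoothed`).
#' @export
smooth_track <- function(track) {
  stopifnot(inherits(track, "BinnedTrack"))
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    m <- track$mask[[ch]]
    ok <- m == MASK_VALID | m == MASK_INTERPOLATED
    n <- length(v)
    vv <- ifelse(ok, v, NA_real_)
    left <- c(NA_real_, vv[-n])
    right <- c(vv[-1], NA_real_)
    mat <- cbind(left, vv, right)
    sm <- rowMeans(mat, na.rm = TRUE)
    sm[!ok] <- v[!ok]
    sm[is.nan(sm)] <- v[is.nan(sm)]
    track$values[[ch]] <- sm
  }
  track$smoothed <- TRUE
  track
}

#' Blacklist bins with excessive input (no-ChIP) signal
#'
#' Bins where the input track exceeds `fold` times the genome-wide input
#' mean mark regions of artifactual sequencing depth; they are flagged
#' blacklisted and excluded from slope scoring and feature detection
#' (region removal rather than arithmetic subtraction, since the goal is
#' removing false-positive peaks).
#'
#' @param track the ChIP `BinnedTrack` (RPM).
#' @param input_track the input/control `BinnedTrack` (RPM, same layout).
#' @param fold blacklist threshold as a multiple of the input mean.
#' @return the track with blacklisted bins flagged.
#' @export
blacklist_input <- function(track, input_track, fold = 10) {
  stopifnot(inherits(track, "BinnedTrack"), inherits(input_track, "BinnedTrack"))
  check_same_layout(track, input_track)
  if (track$normalization != "rpm" || input_track$normalization != "rpm")
    stop("both tracks must be RPM-normalized before input blacklisting")
  imean <- track_mean(input_track)
  thr <- fold * imean
  for (ch in names(track$values)) {
    hit <- input_track$values[[ch]] > thr
    track$mask[[ch]][hit] <- MASK_BLACKLISTED
  }
  track
}

#' Per-bin USHP slope scores
#'
#' Each bin is assigned the slope `(value[i+3] - value[i-3]) / 100`:
#' the difference of the smoothed USHP 60 bp downstream vs 60 bp upstream
#' of the bin, divided by 100 bp. Slopes are undefined within 3 bins of a
#' chromosome end and wherever the 7-bin neighborhood touches a masked or
#' blacklisted bin.
#'
#' @param track a smoothed `BinnedTrack`.
#' @param offset_bins half-window in bins (default 3 = 60 bp at 20 bp bins).
#' @param divisor slope denominator in bp (the profile's stated 100 bp).
#' @return a `SlopeTrack` with per-bin `slopes` and `defined` flags.
#' @export
slope_scores <- function(track, offset_bins = 3L, divisor = 100) {
  stopifnot(inherits(track, "BinnedTrack"))
  if (!isTRUE(track$smoothed))
    stop("slope_scores expects a smoothed track")
  slopes <- list(); defined <- list()
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    m <- track$mask[[ch]]
    n <- length(v)
    s <- rep(NA_real_, n)
    d <- logical(n)
    if (n > 2L * offset_bins) {
      i <- seq.int(offset_bins + 1L, n - offset_bins)
      s[i] <- (v[i + offset_bins] - v[i - offset_bins]) / divisor
      usable <- m == MASK_VALID | m == MASK_INTERPOLATED
      # defined only where the whole +/- offset window is usable
      bad <- cumsum(c(0L, !usable))
      d[i] <- (bad[i + offset_bins + 1L] - bad[i - offset_bins]) == 0L
      s[!d] <- NA_real_
    }
    slopes[[ch]] <- s
    defined[[ch]] <- d
  }
  structure(list(layout = track$layout, slopes = slopes, defined = defined,
                 offset_bins = as.integer(offset_bins), divisor = divisor),
            class = "SlopeTrack")
}

#' @export
print.SlopeTrack <- function(x, ...) {
  cat(sprintf("SlopeTrack: %d bins, %d defined\n",
              sum(lengths(x$slopes)), sum(unlist(x$defined))))
  invisible(x)
}

#' Write a binned track as bedGraph
#' @param track a `BinnedTrack`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  grl <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    len <- track$layout$chroms[[ch]]
    starts <- seq.int(1L, len, by = track$layout$bin_size)
    GenomicRanges::GRanges(ch, IRanges::IRanges(
      start = starts, end = pmin(starts + track$layout$bin_size - 1L, len)),
      score = v)
  })
  gr <- suppressWarnings(do.call(c, grl))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write the mask channel as BED with the flag in the name field
#'
#' Runs of masked, interpolated and blacklisted bins are written as BED
#' intervals named by their mask state.
#'
#' @param track a `BinnedTrack`.
#' @param path output path.
#' @export
write_mask_bed <- function(track, path) {
  codes <- mask_codes()
  grl <- list()
  for (ch in names(track$mask)) {
    m <- track$mask[[ch]]
    for (state in c("masked", "interpolated", "blacklisted")) {
      idx <- which(m == codes[[state]])
      if (!length(idx)) next
      r <- IRanges::reduce(IRanges::IRanges(start = idx, width = 1L))
      B <- track$layout$bin_size
      grl[[length(grl) + 1L]] <- GenomicRanges::GRanges(
        ch,
        IRanges::IRanges(start = (BiocGenerics::start(r) - 1L) * B + 1L,
                         end = pmin(BiocGenerics::end(r) * B,
                                    track$layout$chroms[[ch]])),
        name = state)
    }
  }
  gr <- if (length(grl)) suppressWarnings(do.call(c, grl))
        else GenomicRanges::GRanges()
  rtracklayer::export(sort(gr), path, format = "BED")
  invisible(path)
}

#' Read a bedGraph file onto a layout's bins
#'
#' Interval scores are averaged per base over each bin (so bin-aligned
#' files round-trip exactly).
#'
#' @param path bedGraph path.
#' @param layout a `GenomeLayout`.
#' @return a raw `BinnedTrack` (library size unknown, set to `NA`).
#' @export
read_bedgraph <- function(path, layout) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  chroms <- names(layout$chroms)
  values <- vector("list", length(chroms)); names(values) <- chroms
  gchr <- as.character(GenomeInfoDb::seqnames(gr))
  for (ch in chroms) {
    len <- layout$chroms[[ch]]
    nb <- as.integer(ceiling(len / layout$bin_size))
    sel <- gchr == ch
    if (!any(sel)) { values[[ch]] <- numeric(nb); next }
    ir <- IRanges::IRanges(BiocGenerics::start(gr)[sel],
                           pmin(BiocGenerics::end(gr)[sel], len))
    cov <- IRanges::coverage(ir, weight = gr$score[sel], width = len)
    starts <- seq.int(1L, len, by = layout$bin_size)
    widths <- pmin(layout$bin_size, len - starts + 1L)
    values[[ch]] <- IRanges::viewMeans(IRanges::Views(cov, start = starts,
                                                      width = widths))
  }
  mask <- lapply(values, function(v) integer(length(v)))
  new_binned_track(layout, values, mask, "raw", NA_integer_)
}

#' Full track-processing chain for one ChIP library
#'
#' Runs bin -> mappability mask -> interpolate -> smooth -> RPM ->
#' input blacklist, the order used throughout: masking and interpolation
#' operate on raw binned signal, smoothing precedes slope scoring, and
#' blacklisting compares RPM-normalized ChIP and input.
#'
#' @param reads `GRanges` of ChIP reads.
#' @param layout `GenomeLayout`.
#' @param mappability optional per-bin mappability list.
#' @param input_reads optional `GRanges` of input (no-ChIP) reads.
#' @param mappability_threshold,interp_scan,interp_fold,input_fold
#'   see the individual steps.
#' @param smooth,rpm toggle smoothing / RPM normalization.
#' @return a processed `BinnedTrack` ready for [slope_scores()].
#' @export
process_track <- function(reads, layout, mappability = NULL,
                          input_reads = NULL,
                          mappability_threshold = 0.5,
                          interp_scan = 3L, interp_fold = 2,
                          input_fold = 10, smooth = TRUE, rpm = TRUE) {
  tr <- bin_coverage(reads, layout)
  if (!is.null(mappability)) {
    tr <- mask_low_mappability(tr, mappability, mappability_threshold)
    tr <- interpolate_masked(tr, interp_scan, interp_fold)
  }
  if (smooth) tr <- smooth_track(tr)
  if (rpm) tr <- normalize_rpm(tr)
  if (!is.null(input_reads)) {
    itr <- normalize_rpm(bin_coverage(input_reads, layout))
    tr <- blacklist_input(tr, itr, input_fold)
  }
  tr
}
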