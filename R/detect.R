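#' Detection configuration
#'
#' Bundles every constant of the slope-based feature detector. The
#' defaults are the published constants of the procedure: 400 bp maximum
#' pairing gap, peak-to-trough merge ratio 2.5, 2 kb neighbor clustering
#' expanded +/-1 kb for local background, 3.5-fold enrichment over the
#' local background mean, and a signal threshold of >= 20 tags per feature
#' or a tag density of 14.5 tags/bp. The slope threshold is not a
#' published constant; `NA` (default) selects it per track as
#' `slope_threshold_frac` times the genome-wide mean USHP divided by the
#' slope divisor (100 bp), i.e. a rise of half the mean signal across the
#' slope window.
#'
#' @param slope_threshold absolute slope threshold (USHP/bp), or `NA` for
#'   the per-track automatic rule.
#' @param slope_threshold_frac fraction of genome mean defining the
#'   automatic slope threshold.
#' @param pairing_max_gap maximum bp between a rising run's 3' end and a
#'   falling run's 5' start.
#' @param merge_ratio peak-to-trough ratio below which adjacent features
#'   are merged.
#' @param merge_max_gap maximum bp between the facing edges of two
#'   features for them to count as adjacent for merging; an unresolved
#'   multiplet's peaklets essentially abut, so this keeps the ratio rule
#'   from chaining across distant peaks.
#' @param neighbor_cluster_gap bp within which features are grouped into
#'   one local-background domain.
#' @param background_flank bp added to each side of a domain.
#' @param enrichment_fold required ratio of feature maximum to local
#'   background mean.
#' @param min_tags minimum tag count per feature.
#' @param min_density minimum tag density (tags/bp), the alternative
#'   signal threshold.
#' @return a `DetectionConfig` list.
#' @export
detection_config <- function(slope_threshold = NA_real_,
                             slope_threshold_frac = 0.5,
                             pairing_max_gap = 400,
                             merge_ratio = 2.5,
                             merge_max_gap = 400,
                             neighbor_cluster_gap = 2000,
                             background_flank = 1000,
                             enrichment_fold = 3.5,
                             min_tags = 20,
                             min_density = 14.5) {
  cfg <- list(slope_threshold = slope_threshold,
              slope_threshold_frac = slope_threshold_frac,
              pairing_max_gap = pairing_max_gap,
              merge_ratio = merge_ratio,
              merge_max_gap = merge_max_gap,
              neighbor_cluster_gap = neighbor_cluster_gap,
              background_flank = background_flank,
              enrichment_fold = enrichment_fold,
              min_tags = min_tags, min_density = min_density)
  nums <- cfg[setdiff(names(cfg), "slope_threshold")]
  if (any(unlist(nums) <= 0)) stop("all DetectionConfig values must be positive")
  if (!is.na(slope_threshold) && slope_threshold <= 0)
    stop("slope_threshold must be positive")
  structure(cfg, class = "DetectionConfig")
}

#' Automatic slope threshold for a track
#' @param track a processed `BinnedTrack`.
#' @param frac fraction of the genome-wide mean USHP.
#' @param divisor the slope divisor in bp.
#' @export
auto_slope_threshold <- function(track, frac = 0.5, divisor = 100) {
  frac * track_mean(track) / divisor
}

#' Maximal runs of thresholded slope bins
#'
#' Scans a `SlopeTrack` for maximal runs of consecutive defined bins with
#' slope above `+threshold` (positive runs) or below `-threshold`
#' (negative runs). Runs never span undefined or blacklisted bins, since
#' those bins have no defined slope.
#'
#' @param slopes a `SlopeTrack`.
#' @param threshold positive slope threshold (USHP/bp).
#' @return data.frame with columns chrom, start_bin, end_bin, sign
#'   ("positive"/"negative"), extremum_slope.
#' @export
find_slope_runs <- function(slopes, threshold) {
  stopifnot(inherits(slopes, "SlopeTrack"))
  if (!is.numeric(threshold) || is.na(threshold) || threshold <= 0)
    stop("slope threshold must be a positive number")
  out <- list()
  for (ch in names(slopes$slopes)) {
    s <- slopes$slopes[[ch]]
    d <- slopes$defined[[ch]]
    state <- integer(length(s))
    state[d & !is.na(s) & s > threshold] <- 1L
    state[d & !is.na(s) & s < -threshold] <- -1L
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0L
    if (!any(keep)) next
    for (j in which(keep)) {
      bins <- starts[j]:ends[j]
      ext <- if (r$values[j] > 0L) max(s[bins]) else min(s[bins])
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bin = starts[j], end_bin = ends[j],
        sign = if (r$values[j] > 0L) "positive" else "negative",
        extremum_slope = ext, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start_bin = integer(),
                      end_bin = integer(), sign = character(),
                      extremum_slope = numeric(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start_bin), , drop = FALSE]
}

empty_features <- function() {
  data.frame(id = character(), chrom = character(), start = numeric(),
             end = numeric(), summit_bin = integer(), summit = numeric(),
             max_ushp = numeric(), tag_count = numeric(),
             tag_density = numeric(), status = character(),
             merged_from = character(), stringsAsFactors = FALSE)
}

#' Pair rising runs with falling runs into candidate features
#'
#' Each positive (rising) slope run is joined with the nearest downstream
#' negative (falling) run whose 5' start lies within `pairing_max_gap` bp
#' of the positive run's 3' end. Each negative run is consumed at most
#' once; when two rising runs compete for one falling run the one with
#' the smaller gap wins (ties to the earlier run). Unpaired runs are
#' discarded. The feature interval spans the rising run's start to the
#' falling run's end (bp, 0-based half-open).
#'
#' @param runs data.frame from [find_slope_runs()].
#' @param layout a `GenomeLayout`.
#' @param config a `DetectionConfig`.
#' @return candidate features data.frame.
#' @export
pair_runs <- function(runs, layout, config = detection_config()) {
  feats <- empty_features()
  if (!nrow(runs)) return(feats)
  B <- layout$bin_size
  rows <- list()
  for (ch in unique(runs$chrom)) {
    rr <- runs[runs$chrom == ch, , drop = FALSE]
    pos <- rr[rr$sign == "positive", , drop = FALSE]
    neg <- rr[rr$sign == "negative", , drop = FALSE]
    if (!nrow(pos) || !nrow(neg)) next
    # gap from 3' end of rising run to 5' start of falling run, in bp
    cand <- list()
    for (p in seq_len(nrow(pos))) {
      dn <- which(neg$start_bin > pos$end_bin[p])
      if (!length(dn)) next
      gaps <- (neg$start_bin[dn] - 1L) * B - pos$end_bin[p] * B
      j <- dn[which.min(gaps)]   # nearest downstream
      g <- min(gaps)
      if (g <= config$pairing_max_gap)
        cand[[length(cand) + 1L]] <- c(p = p, j = j, gap = g)
    }
    if (!length(cand)) next
    cm <- do.call(rbind, cand)
    # each negative run consumed once: smallest gap wins, ties to earlier run
    cm <- cm[order(cm[, "j"], cm[, "gap"], cm[, "p"]), , drop = FALSE]
    cm <- cm[!duplicated(cm[, "j"]), , drop = FALSE]
    for (r in seq_len(nrow(cm))) {
      p <- cm[r, "p"]; j <- cm[r, "j"]
      start <- (pos$start_bin[p] - 1L) * B
      end <- min(neg$end_bin[j] * B, layout$chroms[[ch]])
      rows[[length(rows) + 1L]] <- data.frame(
        id = NA_character_, chrom = ch, start = start, end = end,
        summit_bin = NA_integer_, summit = NA_real_, max_ushp = NA_real_,
        tag_count = NA_real_, tag_density = NA_real_, status = "candidate",
        merged_from = "", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(feats)
  feats <- do.call(rbind, rows)
  feats <- feats[order(feats$chrom, feats$start), , drop = FALSE]
  feats$id <- sprintf("F%05d", seq_len(nrow(feats)))
  rownames(feats) <- NULL
  feats
}

feature_bins <- function(chrom, start, end, layout) {
  b1 <- pos_to_bin(start, layout)
  b2 <- pos_to_bin(end - 1, layout)
  seq.int(b1, b2)
}

#' Annotate features with summit, maximum USHP and tag statistics
#'
#' @param features features data.frame.
#' @param track processed `BinnedTrack` (summit and max from its values).
#' @param reads deduplicated `GRanges` of the track's raw reads (tag
#'   counts), or `NULL` to skip tag statistics.
#' @return the annotated data.frame.
#' @export
annotate_features <- function(features, track, reads = NULL) {
  if (!nrow(features)) return(features)
  layout <- track$layout
  for (i in seq_len(nrow(features))) {
    bins <- feature_bins(features$chrom[i], features$start[i],
                         features$end[i], layout)
    v <- track$values[[features$chrom[i]]][bins]
    k <- which.max(v)
    features$summit_bin[i] <- bins[k]
    features$summit[i] <- bin_start(bins[k], layout) + layout$bin_size / 2
    features$max_ushp[i] <- v[k]
  }
  if (!is.null(reads)) {
    fgr <- GenomicRanges::GRanges(
      features$chrom,
      IRanges::IRanges(start = features$start + 1, end = features$end))
    features$tag_count <- GenomicRanges::countOverlaps(fgr, reads)
    features$tag_density <- features$tag_count / (features$end - features$start)
  }
  features
}

#' Merge poorly resolved multiplets by peak-to-trough ratio
#'
#' Adjacent features are compared via the ratio of the smaller of the two
#' summit maxima to the trough (minimum smoothed USHP strictly between the
#' two summits); ratios below `merge_ratio` mean the peaks are not
#' resolved and the pair is merged into one feature spanning both.
#' Applied left-to-right to a fixpoint. A zero trough yields an infinite
#' ratio (no merge); summits in adjacent bins (no intervening trough bin)
#' are treated as unresolved and merged.
#'
#' @param features annotated features data.frame (sorted).
#' @param track smoothed `BinnedTrack`.
#' @param config a `DetectionConfig`.
#' @param reads optional reads for re-annotating merged features.
#' @return the merged, re-annotated features.
#' @export
merge_multiplets <- function(features, track, config = detection_config(),
                             reads = NULL) {
  if (nrow(features) < 2L) return(features)
  features <- features[order(features$chrom, features$start), , drop = FALSE]
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i < nrow(features)) {
      a <- features[i, ]; b <- features[i + 1L, ]
      if (a$chrom == b$chrom && b$start - a$end <= config$merge_max_gap) {
        sa <- a$summit_bin; sb <- b$summit_bin
        v <- track$values[[a$chrom]]
        trough <- if (sb > sa + 1L) min(v[(sa + 1L):(sb - 1L)])
                  else min(a$max_ushp, b$max_ushp)
        ratio <- if (trough <= 0) Inf else min(a$max_ushp, b$max_ushp) / trough
        if (ratio < config$merge_ratio) {
          parts <- c(
            if (nzchar(a$merged_from)) a$merged_from else a$id,
            if (nzchar(b$merged_from)) b$merged_from else b$id)
          features$start[i] <- min(a$start, b$start)
          features$end[i] <- max(a$end, b$end)
          features$merged_from[i] <- paste(parts, collapse = ",")
          if (b$max_ushp > a$max_ushp) {
            features$summit_bin[i] <- sb
            features$summit[i] <- b$summit
            features$max_ushp[i] <- b$max_ushp
          }
          features <- features[-(i + 1L), , drop = FALSE]
          merged_any <- TRUE
          next
        }
      }
      i <- i + 1L
    }
    if (!merged_any) break
  }
  rownames(features) <- NULL
  annotate_features(features, track, reads)
}

#' Filter features by local background enrichment
#'
#' Features whose centers lie within `neighbor_cluster_gap` of each other
#' are chained into a domain; the domain is expanded by
#' `background_flank` on each side; the local background is the mean USHP
#' of domain bins not inside any feature (valid or interpolated bins
#' only). A feature passes iff its maximum is at least `enrichment_fold`
#' times that mean. Domains with no background bins accept their features
#' with a warning (background undefined).
#'
#' @param features merged features data.frame.
#' @param track processed `BinnedTrack`.
#' @param config a `DetectionConfig`.
#' @return features with status set to `background_filtered` where failed.
#' @export
local_background_filter <- function(features, track,
                                    config = detection_config()) {
  if (!nrow(features)) return(features)
  layout <- track$layout
  for (ch in unique(features$chrom)) {
    idx <- which(features$chrom == ch)
    idx <- idx[order(features$start[idx])]
    centers <- (features$start[idx] + features$end[idx]) / 2
    grp <- cumsum(c(1, diff(centers) > config$neighbor_cluster_gap))
    # bins covered by any feature on this chromosome (peak-associated)
    nb <- length(track$values[[ch]])
    inpeak <- logical(nb)
    for (i in idx) {
      bins <- feature_bins(ch, features$start[i], features$end[i], layout)
      inpeak[bins] <- TRUE
    }
    m <- track$mask[[ch]]
    usable <- m == MASK_VALID | m == MASK_INTERPOLATED
    for (g in unique(grp)) {
      gi <- idx[grp == g]
      dstart <- max(0, min(features$start[gi]) - config$background_flank)
      dend <- min(layout$chroms[[ch]], max(features$end[gi]) +
                    config$background_flank)
      dbins <- feature_bins(ch, dstart, dend, layout)
      bg <- dbins[!inpeak[dbins] & usable[dbins]]
      if (!length(bg)) {
        warning(sprintf(
          "no background bins in domain %s:%d-%d; features accepted",
          ch, dstart, dend))
        next
      }
      bgmean <- mean(track$values[[ch]][bg])
      fail <- features$max_ushp[gi] < config$enrichment_fold * bgmean
      features$status[gi[fail]] <- "background_filtered"
    }
  }
  features
}

#' Filter features by tag count or tag density
#'
#' A feature passes iff `tag_count >= min_tags` or
#' `tag_density >= min_density` (raw deduplicated counts).
#'
#' @param features features data.frame with tag statistics.
#' @param config a `DetectionConfig`.
#' @return features with status set; survivors become `accepted`.
#' @export
signal_threshold_filter <- function(features, config = detection_config()) {
  if (!nrow(features)) return(features)
  pass <- features$tag_count >= config$min_tags |
    features$tag_density >= config$min_density
  cand <- features$status == "candidate"
  features$status[cand & !pass] <- "signal_filtered"
  features$status[cand & pass] <- "accepted"
  features
}

#' Detect RNAPII features on one processed track
#'
#' Runs slope scoring, run finding, run pairing, multiplet merging, local
#' background filtering and the signal threshold in sequence, returning
#' every candidate with its final status.
#'
#' @param track processed (smoothed) `BinnedTrack`.
#' @param reads the track's raw reads (`GRanges`) for tag statistics.
#' @param config a `DetectionConfig`.
#' @return features data.frame; accepted features have
#'   `status == "accepted"`.
#' @export
detect_features <- function(track, reads, config = detection_config()) {
  thr <- config$slope_threshold
  if (is.na(thr))
    thr <- auto_slope_threshold(track, config$slope_threshold_frac)
  slopes <- slope_scores(track)
  runs <- find_slope_runs(slopes, thr)
  feats <- pair_runs(runs, track$layout, config)
  if (!nrow(feats)) return(feats)
  feats <- annotate_features(feats, track, reads)
  feats <- merge_multiplets(feats, track, config, reads)
  feats <- local_background_filter(feats, track, config)
  feats <- signal_threshold_filter(feats, config)
  feats
}

#' Convert accepted features to a GRanges
#' @param features features data.frame.
#' @param only_accepted restrict to accepted features.
#' @export
features_to_granges <- function(features, only_accepted = TRUE) {
  if (only_accepted)
    features <- features[features$status == "accepted", , drop = FALSE]
  if (!nrow(features))
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(start = features$start + 1, end = features$end),
    id = features$id, summit = features$summit,
    max_ushp = features$max_ushp,
    # BED6-compatible name/score so write_bed() emits usable peak files
    name = features$id,
    score = pmin(1000, round(features$max_ushp)))
}

#' Detect features per condition and build the union set
#'
#' Processes each condition identically, detects features per track, and
#' coordinate-merges the accepted calls across conditions into a union
#' set with per-track provenance (a peak call present in more than one
#' track becomes a single union feature).
#'
#' @param reads_by_condition named list of `GRanges` read sets.
#' @param layout `GenomeLayout`.
#' @param config `DetectionConfig`.
#' @param mappability optional per-bin mappability list.
#' @param input_reads optional input `GRanges` shared by all conditions.
#' @return list with `per_condition` (features data.frames), `tracks`
#'   (processed `BinnedTrack`s) and `union` (data.frame with provenance
#'   flags `in_<condition>` and a representative summit).
#' @export
detect <- function(reads_by_condition, layout, config = detection_config(),
                   mappability = NULL, input_reads = NULL) {
  stopifnot(length(reads_by_condition) >= 1, !is.null(names(reads_by_condition)))
  conds <- names(reads_by_condition)
  tracks <- lapply(reads_by_condition, process_track, layout = layout,
                   mappability = mappability, input_reads = input_reads)
  per <- mapply(function(tr, rd) detect_features(tr, rd, config),
                tracks, reads_by_condition, SIMPLIFY = FALSE)
  grl <- lapply(per, features_to_granges)
  all_gr <- suppressWarnings(do.call(c, unname(grl)))
  if (!length(all_gr)) {
    union <- data.frame(id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        summit = numeric(), stringsAsFactors = FALSE)
    for (cd in conds) union[[paste0("in_", cd)]] <- logical()
    return(list(per_condition = per, tracks = tracks, union = union))
  }
  red <- GenomicRanges::reduce(all_gr)
  union <- data.frame(
    id = sprintf("U%05d", seq_along(red)),
    chrom = as.character(GenomeInfoDb::seqnames(red)),
    start = BiocGenerics::start(red) - 1,
    end = BiocGenerics::end(red),
    summit = NA_real_, stringsAsFactors = FALSE)
  best <- rep(-Inf, length(red))
  for (cd in conds) {
    g <- grl[[cd]]
    hit <- GenomicRanges::findOverlaps(g, red)
    flag <- logical(length(red))
    flag[S4Vectors::subjectHits(hit)] <- TRUE
    union[[paste0("in_", cd)]] <- flag
    if (length(hit)) {
      qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
      for (r in seq_along(qh)) {
        if (g$max_ushp[qh[r]] > best[sh[r]]) {
          best[sh[r]] <- g$max_ushp[qh[r]]
          union$summit[sh[r]] <- g$summit[qh[r]]
        }
      }
    }
  }
  list(per_condition = per, tracks = tracks, union = union)
}

#' Write a feature table as TSV
#' @param features features data.frame.
#' @param path output path.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
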