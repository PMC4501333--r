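#' Fraction of peaks co-localized with a second peak set
#'
#' In the default summit mode, a peak of `a` co-localizes with `b` when
#' its summit lies within `window` bp of some summit of `b`
#' (summit-to-summit distance, inclusive). In "any" mode, any interval
#' overlap counts. Note the summit mode is order-sensitive: it reports
#' the fraction of `a`'s peaks, not a symmetric statistic.
#'
#' @param a,b peak data.frames with columns chrom, start, end, summit
#'   (bp; summit may be NA, then the interval midpoint is used).
#' @param window maximum summit distance in bp (default 200).
#' @param mode "summit" or "any".
#' @return list(fraction, flags) where flags marks each peak of `a`.
#' @export
overlap_fraction <- function(a, b, window = 200, mode = c("summit", "any")) {
  mode <- match.arg(mode)
  if (!nrow(a)) return(list(fraction = NA_real_, flags = logical(0)))
  summit_of <- function(x) {
    s <- x$summit
    if (is.null(s)) s <- rep(NA_real_, nrow(x))
    ifelse(is.na(s), (x$start + x$end) / 2, s)
  }
  if (mode == "summit") {
    sa <- summit_of(a); sb <- summit_of(b)
    flags <- logical(nrow(a))
    for (ch in unique(a$chrom)) {
      ai <- which(a$chrom == ch)
      sbv <- sort(sb[b$chrom == ch])
      if (!length(sbv)) next
      idx <- findInterval(sa[ai], sbv)
      lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(sbv))
      nearest <- pmin(abs(sa[ai] - sbv[lo]), abs(sa[ai] - sbv[hi]))
      flags[ai] <- nearest <= window
    }
  } else {
    ga <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1, a$end))
    gb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1, b$end))
    flags <- GenomicRanges::countOverlaps(ga, gb) > 0
  }
  list(fraction = mean(flags), flags = flags)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of observing at least `k` co-occupied sites in a cluster
#' of `n` sites, when `K` of the `N` population sites are co-occupied,
#' under draws without replacement:
#' `p = sum_{i=k..min(n,K)} C(K,i) C(N-K,n-i) / C(N,n)`, accumulated in
#' log space.
#'
#' @param k observed overlap count in the cluster.
#' @param n cluster size.
#' @param K genome-wide overlap count.
#' @param N population size.
#' @return an `EnrichmentResult` list with the p-value.
#' @export
hypergeom_enrichment <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > n || n > N || K > N || k > K)
    stop("inconsistent hypergeometric counts (need k <= min(n, K), n,K <= N)")
  if (k == 0) {
    p <- 1
  } else {
    i <- k:min(n, K)
    p <- exp(log_sum_exp(stats::dhyper(i, K, N - K, n, log = TRUE)))
    p <- min(p, 1)
  }
  structure(list(overlap_count = k, cluster_size = n,
                 genome_wide_overlaps = K, population = N, p_value = p),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("hypergeometric enrichment: k=%d n=%d K=%d N=%d p=%.4g\n",
              x$overlap_count, x$cluster_size, x$genome_wide_overlaps,
              x$population, x$p_value))
  invisible(x)
}

#' Per-cluster co-occupancy enrichment
#'
#' Given a logical co-occupancy flag per site and a cluster label per
#' site, tests each cluster's overlap count against the genome-wide rate
#' with the upper-tail hypergeometric probability.
#'
#' @param cluster character/integer vector of cluster labels.
#' @param cooccupied logical vector, same length.
#' @param adjust optionally apply Benjamini-Hochberg across clusters.
#' @return data.frame: cluster, k, n, K, N, p_value (and p_adjusted).
#' @export
cluster_cooccupancy_enrichment <- function(cluster, cooccupied,
                                           adjust = FALSE) {
  stopifnot(length(cluster) == length(cooccupied))
  N <- length(cluster); K <- sum(cooccupied)
  out <- lapply(sort(unique(cluster)), function(cl) {
    sel <- cluster == cl
    r <- hypergeom_enrichment(sum(cooccupied[sel]), sum(sel), K, N)
    data.frame(cluster = cl, k = r$overlap_count, n = r$cluster_size,
               K = K, N = N, p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Anchored signal density matrix
#'
#' Samples a track in fixed bins across `[summit - flank, summit + flank)`
#' of each anchor, for density heat maps (e.g. TF signal within a 4 kb
#' window of differential RNAPII peaks). Rows keep the supplied anchor
#' order. Anchors too close to a chromosome end are padded with `NA` and
#' flagged.
#'
#' @param anchors data.frame with chrom and summit (bp).
#' @param track a `BinnedTrack`.
#' @param flank half-window in bp (default 2000, i.e. a 4 kb window).
#' @param bin sampling bin in bp (must equal the track bin size).
#' @param cap optional saturation cap applied to the values.
#' @return list(matrix, truncated) where matrix is anchors x
#'   (2*flank/bin) and truncated flags padded rows.
#' @export
density_matrix <- function(anchors, track, flank = 2000, bin = 20,
                           cap = NULL) {
  if (bin != track$layout$bin_size)
    stop("sampling bin must equal the track bin size")
  ncol_ <- as.integer(2 * flank / bin)
  mat <- matrix(NA_real_, nrow(anchors), ncol_)
  truncated <- logical(nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[i]
    v <- track$values[[ch]]
    center_bin <- pos_to_bin(anchors$summit[i], track$layout)
    half <- ncol_ %/% 2L
    bins <- seq.int(center_bin - half, center_bin + half - 1L)
    ok <- bins >= 1L & bins <= length(v)
    truncated[i] <- !all(ok)
    mat[i, ok] <- v[bins[ok]]
  }
  if (!is.null(cap)) mat <- pmin(mat, cap)
  rownames(mat) <- if (!is.null(anchors$id)) anchors$id else NULL
  list(matrix = mat, truncated = truncated)
}

#' Build a titration series container
#'
#' @param strengths sites x concentrations matrix of RPM peak strengths.
#' @param concentrations ordered numeric concentrations (ascending).
#' @param detect_threshold RPM threshold for a site to count as detected.
#' @param cobound_threshold RPM threshold a co-bound site must meet at
#'   every concentration.
#' @return a `TitrationSeries`.
#' @export
titration_series <- function(strengths, concentrations,
                             detect_threshold = 1.0,
                             cobound_threshold = 0.5) {
  if (length(concentrations) < 2) stop("need >= 2 concentrations")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be ascending")
  if (ncol(strengths) != length(concentrations))
    stop("strengths columns must match concentrations")
  structure(list(strengths = as.matrix(strengths),
                 concentrations = concentrations,
                 detect_threshold = detect_threshold,
                 cobound_threshold = cobound_threshold),
            class = "TitrationSeries")
}

#' Classify sites across an in vitro titration
#'
#' A site is *detected* at a concentration when its strength is at least
#' the detect threshold (1 RPM); *co-bound* when it meets the co-bound
#' threshold (0.5 RPM) at every concentration; *gained* when it is below
#' the detect threshold at all lower concentrations and detected at the
#' highest. Remaining sites are "other". Also reports the number of sites
#' above the detect threshold per concentration.
#'
#' @param series a `TitrationSeries`.
#' @return list(classification, detected (logical matrix),
#'   counts_detected per concentration).
#' @export
titration_analysis <- function(series) {
  stopifnot(inherits(series, "TitrationSeries"))
  s <- series$strengths
  det <- s >= series$detect_threshold
  cobound <- apply(s >= series$cobound_threshold, 1, all)
  ncol_ <- ncol(s)
  gained <- det[, ncol_] & !apply(det[, -ncol_, drop = FALSE], 1, any)
  cls <- rep("other", nrow(s))
  cls[gained] <- "gained"
  cls[cobound] <- "co-bound"
  list(classification = cls, detected = det,
       counts_detected = colSums(det))
}

#' Strongest and weakest n sites of a peak set
#'
#' Ranks peaks by strength (RPM) and returns the top-n and bottom-n
#' subsets; ties are broken by genomic coordinate for determinism.
#'
#' @param peaks data.frame with chrom, start, end (or summit) and
#'   strength columns.
#' @param n subset size (default 1000).
#' @return list(strongest, weakest) data.frames.
#' @export
rank_extremes <- function(peaks, n = 1000) {
  if (n > nrow(peaks)) stop("n exceeds the number of peaks")
  ord <- order(-peaks$strength, peaks$chrom, peaks$start)
  N <- nrow(peaks)
  list(strongest = peaks[ord[seq_len(n)], , drop = FALSE],
       weakest = peaks[ord[seq.int(N - n + 1L, N)], , drop = FALSE])
}
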