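#' IUPAC motif pattern
#'
#' @param iupac consensus string over the IUPAC alphabet
#'   (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @param name pattern name.
#' @return a `MotifPattern`.
#' @export
motif_pattern <- function(iupac, name = iupac) {
  iupac <- toupper(iupac)
  if (!nzchar(iupac)) stop("empty motif pattern")
  ok <- strsplit(iupac, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP)
  if (!all(ok)) stop("invalid IUPAC letter(s) in pattern: ", iupac)
  structure(list(iupac = iupac, name = name), class = "MotifPattern")
}

#' Built-in C/EBP-family motif patterns
#'
#' * `hybrid` — TTKCATCA, the composite C/EBP half-site + AP-1 half-site
#'   motif bound by the C/EBPbeta-ATF4 heterodimer;
#' * `canonical` — TTGCNNAA, the palindromic C/EBP homodimer consensus;
#' * `heterodimer` — TTRSATCA, the generalized two-inverted-half-site
#'   hybrid family.
#' @return named list of `MotifPattern`s.
#' @export
builtin_motifs <- function() {
  list(hybrid = motif_pattern("TTKCATCA", "hybrid"),
       canonical = motif_pattern("TTGCNNAA", "canonical"),
       heterodimer = motif_pattern("TTRSATCA", "heterodimer"))
}

as_pattern <- function(pattern) {
  if (inherits(pattern, "MotifPattern")) pattern else motif_pattern(pattern)
}

#' Scan a sequence for an IUPAC motif on both strands
#'
#' Reports every position where the pattern matches the forward strand,
#' or where its reverse complement matches (reported on the minus
#' strand). Pattern ambiguity codes match their base sets; `N` in the
#' *sequence* matches only an `N` pattern position, never a concrete
#' letter. A palindromic hit whose plus- and minus-strand spans coincide
#' is reported once, on the plus strand.
#'
#' @param sequence DNA as a character string or `DNAString`
#'   (letters A,C,G,T,N).
#' @param pattern a `MotifPattern` or IUPAC string.
#' @param both_strands scan the reverse complement too.
#' @return data.frame of hits: start (0-based), end (exclusive), strand,
#'   matched_sequence (as read on the hit strand), pattern.
#' @export
scan_motif <- function(sequence, pattern, both_strands = TRUE) {
  pattern <- as_pattern(pattern)
  if (is.character(sequence)) {
    bad <- gsub("[ACGTNacgtn]", "", sequence)
    if (nzchar(bad)) stop("invalid letters in sequence: ", substr(bad, 1, 10))
    sequence <- Biostrings::DNAString(toupper(sequence))
  }
  p <- Biostrings::DNAString(pattern$iupac)
  hits <- list()
  fwd <- Biostrings::matchPattern(p, sequence, fixed = "subject")
  if (length(fwd))
    hits$fwd <- data.frame(
      start = BiocGenerics::start(fwd) - 1L,
      end = BiocGenerics::end(fwd),
      strand = "+",
      matched_sequence = as.character(fwd),
      pattern = pattern$name, stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- Biostrings::matchPattern(Biostrings::reverseComplement(p),
                                   sequence, fixed = "subject")
    if (length(rc))
      hits$rev <- data.frame(
        start = BiocGenerics::start(rc) - 1L,
        end = BiocGenerics::end(rc),
        strand = "-",
        matched_sequence = as.character(
          Biostrings::reverseComplement(Biostrings::DNAStringSet(rc))),
        pattern = pattern$name, stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), matched_sequence = character(),
                      pattern = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, hits)
  # palindromic dedup: identical spans on both strands count once (+)
  key <- paste(df$start, df$end)
  dup_minus <- df$strand == "-" & key %in% key[df$strand == "+"]
  df <- df[!dup_minus, , drop = FALSE]
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Classify a region by hybrid vs canonical motif content
#'
#' @param sequence DNA string of the region.
#' @param patterns list with elements `hybrid` and `canonical`
#'   (default [builtin_motifs()]).
#' @param both_strands scan both strands.
#' @return one of "hybrid_only", "canonical_only", "both", "none".
#' @export
classify_region <- function(sequence, patterns = builtin_motifs(),
                            both_strands = TRUE) {
  h <- nrow(scan_motif(sequence, patterns$hybrid, both_strands)) > 0
  c_ <- nrow(scan_motif(sequence, patterns$canonical, both_strands)) > 0
  if (h && c_) "both" else if (h) "hybrid_only"
  else if (c_) "canonical_only" else "none"
}

#' Hamming distance between two concrete DNA strings
#'
#' @param a,b equal-length strings over A,C,G,T.
#' @return number of mismatching positions.
#' @export
motif_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  if (!all(c(va, vb) %in% c("A", "C", "G", "T")))
    stop("motif_distance requires concrete bases (A/C/G/T)")
  sum(va != vb)
}

#' Select the motif-mining window of a feature
#'
#' The window is centered on the bins scoring in the top 25th percentile
#' of USHP values within the feature (nearest-rank 75th percentile
#' threshold, inclusive). Spans shorter than `min_size` are expanded
#' symmetrically about the span midpoint to `min_size` (clipped at
#' chromosome ends); spans longer than `max_size` exclude the feature
#' from motif mining.
#'
#' @param feature one-row features data.frame (chrom, start, end, id).
#' @param track processed `BinnedTrack`.
#' @param min_size,max_size window size limits in bp.
#' @return one-row data.frame (feature_id, chrom, start, end, source) or
#'   `NULL` when the feature is excluded.
#' @export
select_window <- function(feature, track, min_size = 400, max_size = 600) {
  layout <- track$layout
  if (feature$end - feature$start < layout$bin_size)
    stop("feature shorter than one bin")
  bins <- feature_bins(feature$chrom, feature$start, feature$end, layout)
  v <- track$values[[feature$chrom]][bins]
  srt <- sort(v)
  thr <- srt[ceiling(0.75 * length(srt))]
  top <- bins[v >= thr]
  span_start <- bin_start(min(top), layout)
  span_end <- bin_start(max(top), layout) + layout$bin_size
  if (span_end - span_start > max_size) return(NULL)
  if (span_end - span_start < min_size) {
    mid <- (span_start + span_end) / 2
    span_start <- floor(mid - min_size / 2)
    span_end <- span_start + min_size
    len <- layout$chroms[[feature$chrom]]
    if (span_start < 0) { span_end <- span_end - span_start; span_start <- 0 }
    if (span_end > len) { span_start <- max(0, span_start - (span_end - len)); span_end <- len }
    src <- "expanded_to_min"
  } else src <- "natural"
  data.frame(feature_id = feature$id, chrom = feature$chrom,
             start = span_start, end = span_end, source = src,
             stringsAsFactors = FALSE)
}

#' Select and merge motif windows for a feature set
#'
#' Applies [select_window()] to every accepted feature and merges
#' overlapping windows into single intervals (a peak called in more than
#' one track yields one window).
#'
#' @param features features data.frame (accepted rows are used).
#' @param track processed `BinnedTrack`.
#' @param min_size,max_size window size limits.
#' @return windows data.frame; merged rows have `source = "merged"` and
#'   comma-separated feature ids.
#' @export
select_windows <- function(features, track, min_size = 400, max_size = 600) {
  acc <- if ("status" %in% names(features))
    features[features$status == "accepted", , drop = FALSE] else features
  rows <- list()
  for (i in seq_len(nrow(acc))) {
    w <- select_window(acc[i, ], track, min_size, max_size)
    if (!is.null(w)) rows[[length(rows) + 1L]] <- w
  }
  if (!length(rows))
    return(data.frame(feature_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      source = character(), stringsAsFactors = FALSE))
  merge_windows(do.call(rbind, rows))
}

#' Merge overlapping motif windows
#' @param windows windows data.frame.
#' @return windows with overlapping intervals merged into single rows.
#' @export
merge_windows <- function(windows) {
  if (nrow(windows) < 2) return(windows)
  gr <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$start + 1, windows$end))
  red <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(gr, red)
  out <- data.frame(
    feature_id = vapply(seq_along(red), function(j)
      paste(windows$feature_id[S4Vectors::queryHits(ov)[
        S4Vectors::subjectHits(ov) == j]], collapse = ","),
      character(1)),
    chrom = as.character(GenomeInfoDb::seqnames(red)),
    start = BiocGenerics::start(red) - 1,
    end = BiocGenerics::end(red), stringsAsFactors = FALSE)
  n_src <- vapply(seq_along(red), function(j)
    sum(S4Vectors::subjectHits(ov) == j), integer(1))
  out$source <- ifelse(n_src > 1, "merged",
                       windows$source[match(out$feature_id, windows$feature_id)])
  out
}

#' Extract window sequences from a genome
#' @param windows windows data.frame.
#' @param genome a named `DNAStringSet`.
#' @return character vector of sequences.
#' @export
window_sequences <- function(windows, genome) {
  vapply(seq_len(nrow(windows)), function(i) {
    ch <- windows$chrom[i]
    if (!ch %in% names(genome)) stop("chromosome not in genome: ", ch)
    if (windows$end[i] > length(genome[[ch]]))
      stop("window beyond chromosome end: ", ch)
    as.character(Biostrings::subseq(genome[[ch]], windows$start[i] + 1,
                                    windows$end[i]))
  }, character(1))
}

#' Scan genomic windows for a motif
#' @param windows windows data.frame.
#' @param genome named `DNAStringSet`.
#' @param pattern `MotifPattern` or IUPAC string.
#' @param both_strands scan both strands.
#' @return data.frame of genomic hits (chrom, start, end, strand,
#'   matched_sequence, pattern, window).
#' @export
scan_windows <- function(windows, genome, pattern, both_strands = TRUE) {
  seqs <- window_sequences(windows, genome)
  out <- list()
  for (i in seq_along(seqs)) {
    h <- scan_motif(seqs[i], pattern, both_strands)
    if (nrow(h)) {
      h$chrom <- windows$chrom[i]
      h$start <- h$start + windows$start[i]
      h$end <- h$end + windows$start[i]
      h$window <- i
      out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), matched_sequence = character(),
                      pattern = character(), chrom = character(),
                      window = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Motif frequency per stage group with exact binomial CIs
#'
#' Fraction of each group's windows containing at least one motif hit,
#' with a Clopper-Pearson 95% confidence interval. Empty groups are
#' reported with `NA` fractions.
#'
#' @param windows windows data.frame with a `group` column.
#' @param genome named `DNAStringSet`.
#' @param pattern `MotifPattern` or IUPAC string.
#' @param conf_level CI level.
#' @return data.frame: group, n, hits, fraction, ci_lower, ci_upper.
#' @export
cluster_motif_frequency <- function(windows, genome, pattern,
                                    conf_level = 0.95) {
  stopifnot("group" %in% names(windows))
  if (!nrow(windows))
    return(data.frame(group = character(), n = integer(), hits = integer(),
                      fraction = numeric(), ci_lower = numeric(),
                      ci_upper = numeric(), stringsAsFactors = FALSE))
  seqs <- window_sequences(windows, genome)
  has_hit <- vapply(seqs, function(s)
    nrow(scan_motif(s, pattern)) > 0, logical(1), USE.NAMES = FALSE)
  groups <- unique(windows$group)
  out <- lapply(groups, function(g) {
    sel <- windows$group == g
    n <- sum(sel); k <- sum(has_hit[sel])
    if (n == 0)
      return(data.frame(group = g, n = 0L, hits = 0L, fraction = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_))
    bt <- stats::binom.test(k, n, conf.level = conf_level)
    data.frame(group = g, n = n, hits = k, fraction = k / n,
               ci_lower = bt$conf.int[1], ci_upper = bt$conf.int[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
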