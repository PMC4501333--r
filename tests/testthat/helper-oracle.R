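# Independent brute-force oracles. These re-derive the detection,
# counting and enrichment rules with plain loops, sharing no code with
# the package implementation.

# per-base pileup averaged per bin, via an explicit base-position loop
oracle_pileup <- function(reads, layout, chrom = names(layout$chroms)[1]) {
  len <- layout$chroms[[chrom]]
  depth <- numeric(len)
  sel <- as.character(GenomeInfoDb::seqnames(reads)) == chrom
  st <- BiocGenerics::start(reads)[sel]
  en <- BiocGenerics::end(reads)[sel]
  for (i in seq_along(st))
    for (p in st[i]:min(en[i], len)) depth[p] <- depth[p] + 1
  nb <- ceiling(len / layout$bin_size)
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    lo <- (b - 1) * layout$bin_size + 1
    hi <- min(b * layout$bin_size, len)
    out[b] <- mean(depth[lo:hi])
  }
  out
}

# naive count of reads overlapping each 0-based half-open interval
oracle_count <- function(starts0, ends, reads) {
  rs <- BiocGenerics::start(reads)
  re <- BiocGenerics::end(reads)
  rch <- as.character(GenomeInfoDb::seqnames(reads))
  function(chrom, s0, e) {
    n <- 0L
    for (i in seq_along(rs))
      if (rch[i] == chrom && rs[i] <= e && re[i] >= s0 + 1) n <- n + 1L
    n
  }
}

# brute-force re-derivation of the whole feature-detection chain
oracle_detect <- function(track, reads, config = detection_config()) {
  layout <- track$layout
  B <- layout$bin_size
  off <- 3L
  usable_all <- unlist(lapply(names(track$values), function(ch)
    track$mask[[ch]] %in% c(0L, 2L)))
  vals_all <- unlist(track$values, use.names = FALSE)
  thr <- config$slope_threshold
  if (is.na(thr))
    thr <- config$slope_threshold_frac * mean(vals_all[usable_all]) / 100

  counter <- oracle_count(reads = reads)
  feats <- list()
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    m <- track$mask[[ch]]
    usable <- m %in% c(0L, 2L)
    n <- length(v)
    s <- rep(NA_real_, n); def <- logical(n)
    for (i in seq_len(n)) {
      if (i > off && i <= n - off && all(usable[(i - off):(i + off)])) {
        s[i] <- (v[i + off] - v[i - off]) / 100
        def[i] <- TRUE
      }
    }
    # maximal runs
    runs <- list(); cur_sign <- 0L; cur_start <- NA_integer_
    flush <- function(endi) {
      if (cur_sign != 0L)
        runs[[length(runs) + 1L]] <<- list(start = cur_start, end = endi,
                                           sign = cur_sign)
    }
    for (i in seq_len(n)) {
      sg <- 0L
      if (def[i] && s[i] > thr) sg <- 1L
      if (def[i] && s[i] < -thr) sg <- -1L
      if (sg != cur_sign) { flush(i - 1L); cur_sign <- sg; cur_start <- i }
    }
    flush(n)
    pos <- Filter(function(r) r$sign == 1L, runs)
    neg <- Filter(function(r) r$sign == -1L, runs)
    # each rising run proposes its nearest downstream falling run
    props <- list()
    for (pi in seq_along(pos)) {
      bestj <- NA_integer_; bestgap <- Inf
      for (ni in seq_along(neg)) {
        if (neg[[ni]]$start > pos[[pi]]$end) {
          gap <- (neg[[ni]]$start - 1) * B - pos[[pi]]$end * B
          if (gap < bestgap) { bestgap <- gap; bestj <- ni }
        }
      }
      if (!is.na(bestj) && bestgap <= config$pairing_max_gap)
        props[[length(props) + 1L]] <- list(p = pi, j = bestj, gap = bestgap)
    }
    # each falling run consumed once: smallest gap, tie to earlier run
    for (ni in seq_along(neg)) {
      cand <- Filter(function(x) x$j == ni, props)
      if (!length(cand)) next
      gaps <- vapply(cand, function(x) x$gap, numeric(1))
      ps <- vapply(cand, function(x) x$p, numeric(1))
      best <- order(gaps, ps)[1]
      pi <- cand[[best]]$p
      feats[[length(feats) + 1L]] <- list(
        chrom = ch, start = (pos[[pi]]$start - 1) * B,
        end = min(neg[[ni]]$end * B, layout$chroms[[ch]]))
    }
  }
  if (!length(feats))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), status = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(feats, as.data.frame))
  df <- df[order(df$chrom, df$start), , drop = FALSE]

  annot <- function(df) {
    for (i in seq_len(nrow(df))) {
      bins <- (df$start[i] %/% B + 1):((df$end[i] - 1) %/% B + 1)
      v <- track$values[[df$chrom[i]]]
      best <- bins[1]
      for (b in bins) if (v[b] > v[best]) best <- b
      df$summit_bin[i] <- best
      df$max_ushp[i] <- v[best]
      df$tag_count[i] <- counter(df$chrom[i], df$start[i], df$end[i])
      df$tag_density[i] <- df$tag_count[i] / (df$end[i] - df$start[i])
    }
    df
  }
  df <- annot(df)

  # multiplet merging, left-to-right to fixpoint
  repeat {
    changed <- FALSE
    i <- 1L
    while (i < nrow(df)) {
      if (df$chrom[i] == df$chrom[i + 1] &&
          df$start[i + 1] - df$end[i] <= config$merge_max_gap) {
        v <- track$values[[df$chrom[i]]]
        sa <- df$summit_bin[i]; sb <- df$summit_bin[i + 1]
        trough <- if (sb > sa + 1) {
          tt <- Inf
          for (b in (sa + 1):(sb - 1)) tt <- min(tt, v[b])
          tt
        } else min(df$max_ushp[i], df$max_ushp[i + 1])
        ratio <- if (trough <= 0) Inf
                 else min(df$max_ushp[i], df$max_ushp[i + 1]) / trough
        if (ratio < config$merge_ratio) {
          df$end[i] <- max(df$end[i], df$end[i + 1])
          if (df$max_ushp[i + 1] > df$max_ushp[i]) {
            df$max_ushp[i] <- df$max_ushp[i + 1]
            df$summit_bin[i] <- df$summit_bin[i + 1]
          }
          df <- df[-(i + 1), , drop = FALSE]
          changed <- TRUE
          next
        }
      }
      i <- i + 1L
    }
    if (!changed) break
  }
  rownames(df) <- NULL
  df <- annot(df)
  df$status <- "candidate"

  # local background filter
  for (ch in unique(df$chrom)) {
    idx <- which(df$chrom == ch)
    v <- track$values[[ch]]
    m <- track$mask[[ch]]
    nb <- length(v)
    inpeak <- logical(nb)
    for (i in idx)
      for (b in (df$start[i] %/% B + 1):((df$end[i] - 1) %/% B + 1))
        inpeak[b] <- TRUE
    centers <- (df$start[idx] + df$end[idx]) / 2
    ord <- order(centers); idx <- idx[ord]; centers <- centers[ord]
    g <- 1L; groups <- integer(length(idx)); groups[1] <- 1L
    for (i in seq_along(idx)[-1]) {
      if (centers[i] - centers[i - 1] > config$neighbor_cluster_gap)
        g <- g + 1L
      groups[i] <- g
    }
    for (gg in unique(groups)) {
      gi <- idx[groups == gg]
      d1 <- max(0, min(df$start[gi]) - config$background_flank)
      d2 <- min(layout$chroms[[ch]], max(df$end[gi]) + config$background_flank)
      bsum <- 0; bn <- 0L
      for (b in (d1 %/% B + 1):((d2 - 1) %/% B + 1)) {
        if (!inpeak[b] && m[b] %in% c(0L, 2L)) { bsum <- bsum + v[b]; bn <- bn + 1L }
      }
      if (bn == 0L) next
      bmean <- bsum / bn
      for (i in gi)
        if (df$max_ushp[i] < config$enrichment_fold * bmean)
          df$status[i] <- "background_filtered"
    }
  }
  for (i in seq_len(nrow(df))) {
    if (df$status[i] != "candidate") next
    df$status[i] <- if (df$tag_count[i] >= config$min_tags ||
                        df$tag_density[i] >= config$min_density)
      "accepted" else "signal_filtered"
  }
  df
}

# exhaustive hypergeometric upper tail by enumerating all C(N, n) draws
oracle_hyper <- function(k, n, K, N) {
  pop <- c(rep(1L, K), rep(0L, N - K))
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(ix) sum(pop[ix]) >= k))
}

# naive all-pairs summit co-localization
oracle_overlap_fraction <- function(a, b, window) {
  sa <- ifelse(is.na(a$summit), (a$start + a$end) / 2, a$summit)
  sb <- ifelse(is.na(b$summit), (b$start + b$end) / 2, b$summit)
  hits <- logical(nrow(a))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      if (a$chrom[i] == b$chrom[j] && abs(sa[i] - sb[j]) <= window)
        hits[i] <- TRUE
  mean(hits)
}
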