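#' Condition names used throughout
#'
#' The four experimental RNAPII conditions, in canonical order: low
#' density, low density + adipogenic cocktail (DMI), high density, high
#' density + DMI.
#' @export
CONDITIONS <- c("LD", "LD_DMI", "HD", "HD_DMI")

#' Tag counts per feature across condition tracks
#'
#' Counts deduplicated reads overlapping each feature interval in every
#' condition and scales each column to a common library size (reads per
#' million), so occupancy is comparable across tracks of different
#' sequencing depth.
#'
#' @param features union features data.frame (columns chrom, start, end,
#'   id; 0-based half-open).
#' @param readsets named list of `GRanges`, one per condition; order and
#'   names define the matrix columns.
#' @param scale common library size (default 1e6, i.e. RPM).
#' @param pseudocount pseudocount carried with the matrix for downstream
#'   ratio/log operations.
#' @return a `ConditionMatrix`: list(feature_ids, conditions, counts,
#'   raw_counts, pseudocount).
#' @export
count_feature_tags <- function(features, readsets, scale = 1e6,
                               pseudocount = 1) {
  if (is.null(names(readsets)) || any(!nzchar(names(readsets))))
    stop("readsets must be a named list (one per condition)")
  fgr <- GenomicRanges::GRanges(
    features$chrom, IRanges::IRanges(features$start + 1, features$end))
  raw <- sapply(readsets, function(r) GenomicRanges::countOverlaps(fgr, r))
  raw <- matrix(raw, nrow = nrow(features),
                dimnames = list(features$id, names(readsets)))
  libs <- vapply(readsets, length, numeric(1))
  counts <- sweep(raw, 2, scale / libs, `*`)
  structure(list(feature_ids = features$id, conditions = names(readsets),
                 counts = counts, raw_counts = raw,
                 pseudocount = pseudocount),
            class = "ConditionMatrix")
}

#' Build a ConditionMatrix from a ready-made count matrix
#' @param counts features x conditions numeric matrix.
#' @param pseudocount pseudocount for ratio/log operations.
#' @export
condition_matrix <- function(counts, pseudocount = 1) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("U%05d", seq_len(nrow(counts)))
  structure(list(feature_ids = rownames(counts),
                 conditions = colnames(counts), counts = counts,
                 raw_counts = counts, pseudocount = pseudocount),
            class = "ConditionMatrix")
}

#' All pairwise condition comparisons
#' @param conditions character vector of condition names.
#' @return data.frame with columns a, b and pair label "a_vs_b".
#' @export
condition_pairs <- function(conditions = CONDITIONS) {
  cb <- utils::combn(conditions, 2)
  data.frame(a = cb[1, ], b = cb[2, ],
             pair = paste(cb[1, ], cb[2, ], sep = "_vs_"),
             stringsAsFactors = FALSE)
}

#' Two-fold up/no-change/down attributes per pairwise comparison
#'
#' For every pair (a, b) of conditions a feature is `up` if
#' `(b + pc) / (a + pc) >= fold`, `down` if `<= 1/fold`, otherwise `nc`
#' (no change). With four conditions there are six pairs, hence an
#' attribute vector of six values per feature.
#'
#' @param cm a `ConditionMatrix`.
#' @param fold fold-change threshold (default 2).
#' @return character matrix features x pairs with values up/nc/down.
#' @export
assign_attributes <- function(cm, fold = 2) {
  stopifnot(inherits(cm, "ConditionMatrix"))
  pc <- cm$pseudocount
  if (pc <= 0) stop("pseudocount must be > 0")
  pairs <- condition_pairs(cm$conditions)
  out <- matrix("nc", nrow = nrow(cm$counts), ncol = nrow(pairs),
                dimnames = list(cm$feature_ids, pairs$pair))
  for (j in seq_len(nrow(pairs))) {
    ratio <- (cm$counts[, pairs$b[j]] + pc) / (cm$counts[, pairs$a[j]] + pc)
    out[ratio >= fold, j] <- "up"
    out[ratio <= 1 / fold, j] <- "down"
  }
  out
}

#' Map attribute vectors to differentiation stage groups
#'
#' Collapses the six-comparison attribute vector into the four stage
#' groups of the adipogenic commitment model, via a documented mapping on
#' the two informative comparisons (LD vs HD for density response, HD vs
#' HD+DMI for cocktail response):
#' * `DMI_induced` — up in HD vs HD+DMI (cocktail-responsive at high
#'   density), checked first;
#' * `HD_primed` — up in LD vs HD without DMI induction;
#' * `uncommitted` — down in LD vs HD (LD-favoring) without DMI induction;
#' * `ambiguous` — everything else (including constitutive features).
#'
#' @param attributes character matrix from [assign_attributes()].
#' @param density_pair,dmi_pair the comparisons used by the mapping.
#' @return character vector of stage labels, one per feature.
#' @export
group_stage <- function(attributes, density_pair = "LD_vs_HD",
                        dmi_pair = "HD_vs_HD_DMI") {
  if (!all(c(density_pair, dmi_pair) %in% colnames(attributes)))
    stop("attribute matrix lacks the comparisons needed for stage grouping")
  dens <- attributes[, density_pair]
  dmi <- attributes[, dmi_pair]
  out <- rep("ambiguous", nrow(attributes))
  out[dmi == "up"] <- "DMI_induced"
  out[dmi != "up" & dens == "up"] <- "HD_primed"
  out[dmi != "up" & dens == "down"] <- "uncommitted"
  names(out) <- rownames(attributes)
  out
}

#' Log2 fold-change heatmap matrix
#'
#' Each entry is `log2((count + pc) / (row mean + pc))`: the log2 fold
#' change of the condition-specific tag count relative to the mean tag
#' count over all four tracks at that feature.
#'
#' @param cm a `ConditionMatrix`.
#' @return numeric matrix of log2 ratios (class `HeatmapMatrix`).
#' @export
log2_heatmap <- function(cm) {
  stopifnot(inherits(cm, "ConditionMatrix"))
  pc <- cm$pseudocount
  rm <- rowMeans(cm$counts)
  out <- log2((cm$counts + pc) / (rm + pc))
  class(out) <- c("HeatmapMatrix", class(out))
  out
}

# k-means++ seeding: spread initial centers by sampling points with
# probability proportional to squared distance from the nearest chosen
# center. Deterministic under set.seed.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  if (k > 1L) {
    d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) i <- sample.int(n, 1L)
      else i <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- x[i, ]
      nd <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, nd)
    }
  }
  centers
}

#' Deterministic k-means clustering of heatmap rows
#'
#' Standard k-means (Lloyd iterations, 300-iteration cap) on the rows of
#' a log2 matrix, with k-means++ initialization under a fixed seed so
#' repeated runs are bit-identical.
#'
#' @param x numeric matrix (rows = features).
#' @param k number of clusters (>= 1).
#' @param seed integer RNG seed.
#' @param iter_max iteration cap.
#' @return list(labels, centers, tot_withinss, k, seed).
#' @export
kmeans_cluster <- function(x, k, seed = 1L, iter_max = 300L) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds the number of features")
  if (k < 1) stop("k must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  if (k == 1L) {
    ctr <- matrix(colMeans(x), 1L)
    return(list(labels = stats::setNames(rep(1L, nrow(x)), rownames(x)),
                centers = ctr,
                tot_withinss = sum(sweep(x, 2, ctr[1, ])^2),
                k = 1L, seed = seed))
  }
  ctrs <- kmeanspp_centers(x, k)
  # duplicate initial centers break stats::kmeans; jitter-free fallback:
  ctrs <- unique(ctrs)
  while (nrow(ctrs) < k) {
    extra <- x[sample.int(nrow(x), k - nrow(ctrs)), , drop = FALSE]
    ctrs <- unique(rbind(ctrs, extra))
  }
  km <- suppressWarnings(
    stats::kmeans(x, centers = ctrs, iter.max = iter_max,
                  algorithm = "Lloyd"))
  list(labels = stats::setNames(km$cluster, rownames(x)),
       centers = km$centers, tot_withinss = km$tot.withinss,
       k = k, seed = seed)
}

#' Two-level clustering of a condition matrix
#'
#' Assigns attributes and stage groups, then k-means-clusters the log2
#' heatmap rows within each stage group for heatmap ordering, allocating
#' the total `k` across groups proportionally to group size (at least one
#' cluster per non-empty group). Cluster labels are numbered so that
#' groups appear in the order uncommitted, HD_primed, DMI_induced,
#' ambiguous.
#'
#' @param cm a `ConditionMatrix`.
#' @param k total number of clusters (default 19).
#' @param seed RNG seed for k-means.
#' @param fold attribute fold-change threshold.
#' @return list(attributes, stage, heatmap, labels, k, seed).
#' @export
cluster_features <- function(cm, k = 19L, seed = 1L, fold = 2) {
  att <- assign_attributes(cm, fold)
  stage <- group_stage(att)
  hm <- log2_heatmap(cm)
  order_groups <- c("uncommitted", "HD_primed", "DMI_induced", "ambiguous")
  sizes <- vapply(order_groups, function(g) sum(stage == g), numeric(1))
  nonempty <- order_groups[sizes > 0]
  alloc <- round(k * sizes[nonempty] / sum(sizes[nonempty]))
  alloc <- pmin(pmax(alloc, 1), sizes[nonempty])
  labels <- stats::setNames(integer(length(stage)), names(stage))
  offset <- 0L
  for (g in nonempty) {
    rows <- which(stage == g)
    kk <- as.integer(alloc[[g]])
    cl <- kmeans_cluster(hm[rows, , drop = FALSE], kk, seed = seed)
    labels[rows] <- offset + cl$labels
    offset <- offset + kk
  }
  list(attributes = att, stage = stage, heatmap = hm, labels = labels,
       k = offset, seed = seed)
}

#' Write a heatmap matrix in CDT (clustered data table) text format
#'
#' Minimal CDT output (GID/NAME/GWEIGHT columns plus data), loadable by
#' TreeView-compatible viewers.
#'
#' @param hm numeric matrix of log2 ratios with rownames.
#' @param path output path.
#' @export
write_cdt <- function(hm, path) {
  df <- data.frame(GID = rownames(hm), NAME = rownames(hm), GWEIGHT = 1,
                   hm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to label permutation), ~0 for random.
#'
#' @param a,b label vectors of equal length.
#' @return the ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(length(a), 2)
  expected <- ai * bj / nn
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}
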