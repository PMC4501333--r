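#' @title Synthetic data generation
#' @description Deterministic generators for genomes, mappability tracks,
#'   condition-structured ChIP-seq read stacks and in vitro titration
#'   series, with full ground-truth tables. Every generator is a pure
#'   function of its parameters and seed (Mersenne-Twister).
#' @name synthetic
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

#' Sample a concrete instance of an IUPAC pattern
#'
#' Each ambiguity code is replaced by one of its bases, uniformly at
#' random (uses the current RNG state).
#'
#' @param pattern `MotifPattern` or IUPAC string.
#' @return concrete DNA string.
#' @export
iupac_instance <- function(pattern) {
  pattern <- as_pattern(pattern)
  letters <- strsplit(pattern$iupac, "")[[1]]
  paste(vapply(letters, function(l) {
    opts <- strsplit(Biostrings::IUPAC_CODE_MAP[[l]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

#' Generate a random genome with planted motif instances
#'
#' Background bases are i.i.d. at the stated GC fraction; planted
#' instances are written verbatim at their recorded positions (reverse
#' complemented for minus-strand plants). Overlapping plants are an
#' error.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param gc GC fraction of the background.
#' @param plants data.frame with columns chrom, pos (0-based), instance
#'   (concrete DNA string), strand; or `NULL`.
#' @param seed RNG seed.
#' @return list(genome = named `DNAStringSet`, truth = the plants table).
#' @export
generate_genome <- function(chrom_lengths, gc = 0.41, plants = NULL,
                            seed = 1L) {
  with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- lapply(chrom_lengths, function(len)
      paste(sample(names(probs), len, replace = TRUE, prob = probs),
            collapse = ""))
    if (!is.null(plants) && nrow(plants)) {
      for (ch in unique(plants$chrom)) {
        p <- plants[plants$chrom == ch, , drop = FALSE]
        p <- p[order(p$pos), , drop = FALSE]
        ends <- p$pos + nchar(p$instance)
        if (nrow(p) > 1 && any(p$pos[-1] < ends[-nrow(p)]))
          stop("overlapping planted motif instances on ", ch)
        if (any(ends > chrom_lengths[[ch]]))
          stop("planted instance beyond chromosome end on ", ch)
        s <- seqs[[ch]]
        for (i in seq_len(nrow(p))) {
          inst <- p$instance[i]
          if (p$strand[i] == "-")
            inst <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(inst)))
          substr(s, p$pos[i] + 1, p$pos[i] + nchar(inst)) <- inst
        }
        seqs[[ch]] <- s
      }
    }
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(chrom_lengths)
    list(genome = genome, truth = plants)
  })
}

#' Generate a mappability track with planted zero-score gaps
#'
#' Score 1.0 everywhere except the planted gaps (0.0). Overlapping gaps
#' are merged silently.
#'
#' @param layout a `GenomeLayout`.
#' @param gaps data.frame with chrom, start_bin, end_bin (1-based,
#'   inclusive), or `NULL`.
#' @return list(scores = per-chromosome list of per-bin scores,
#'   truth = the gap table).
#' @export
generate_mappability <- function(layout, gaps = NULL) {
  nb <- n_bins(layout)
  scores <- lapply(nb, function(n) rep(1.0, n))
  names(scores) <- names(layout$chroms)
  if (!is.null(gaps) && nrow(gaps)) {
    for (i in seq_len(nrow(gaps))) {
      ch <- gaps$chrom[i]
      bins <- max(1L, gaps$start_bin[i]):min(nb[[ch]], gaps$end_bin[i])
      scores[[ch]][bins] <- 0.0
    }
  }
  list(scores = scores, truth = gaps)
}

#' Per-stage condition multipliers
#'
#' The four planted response patterns over (LD, LD+DMI, HD, HD+DMI):
#' uncommitted features are LD-favoring, HD-primed respond to density
#' alone, DMI-induced respond to cocktail at high density, and ambiguous
#' features are constitutive.
#'
#' @param enrichment summit fold-enrichment of an "on" condition.
#' @return named list of 4-vectors.
#' @export
stage_multipliers <- function(enrichment = 8) {
  e <- enrichment
  list(uncommitted = c(LD = e, LD_DMI = e, HD = 1, HD_DMI = 1),
       HD_primed = c(LD = 1, LD_DMI = 1, HD = e, HD_DMI = e),
       DMI_induced = c(LD = 1, LD_DMI = 1, HD = 1, HD_DMI = e),
       ambiguous = c(LD = e, LD_DMI = e, HD = e, HD_DMI = e))
}

#' Plant differential features across the genome
#'
#' Places `n` features (balanced over the four stage patterns) on a
#' jittered regular grid so neighbors stay well separated, and assigns
#' each a motif class (hybrid / canonical / none) at the configured
#' per-stage frequencies (exact counts, randomly allocated).
#'
#' @param layout a `GenomeLayout`.
#' @param n number of features.
#' @param width feature width in bp.
#' @param enrichment summit fold-enrichment for "on" conditions.
#' @param margin bp excluded at chromosome ends.
#' @param hybrid_frac,canonical_frac named per-stage planting
#'   frequencies for the hybrid and canonical motifs.
#' @param seed RNG seed.
#' @return truth data.frame: id, chrom, center, width, the four
#'   multipliers, stage, motif.
#' @export
plant_features <- function(layout, n = 60, width = 600, enrichment = 8,
                           margin = 10000,
                           hybrid_frac = c(uncommitted = 0.07,
                                           HD_primed = 0.27,
                                           DMI_induced = 0.04,
                                           ambiguous = 0),
                           canonical_frac = c(uncommitted = 0.13,
                                              HD_primed = 0.08,
                                              DMI_induced = 0.23,
                                              ambiguous = 0),
                           seed = 1L) {
  with_seed(seed, {
    lens <- layout$chroms
    n_per <- round(n * lens / sum(lens))
    n_per[length(n_per)] <- n - sum(n_per[-length(n_per)])
    rows <- list()
    for (ci in seq_along(lens)) {
      ch <- names(lens)[ci]
      k <- n_per[ci]
      if (k == 0) next
      usable <- lens[ci] - 2 * margin
      spacing <- usable / k
      jit <- stats::runif(k, -spacing / 5, spacing / 5)
      centers <- round(margin + (seq_len(k) - 0.5) * spacing + jit)
      rows[[ci]] <- data.frame(chrom = ch, center = centers,
                               stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    n <- nrow(truth)
    stages <- rep(names(stage_multipliers()), length.out = n)
    truth$stage <- sample(stages)
    mult <- stage_multipliers(enrichment)
    mm <- t(vapply(truth$stage, function(s) mult[[s]], numeric(4)))
    colnames(mm) <- paste0("m_", CONDITIONS)
    truth <- cbind(truth, mm)
    truth$width <- width
    truth$motif <- "none"
    for (s in unique(truth$stage)) {
      idx <- which(truth$stage == s)
      nh <- round(hybrid_frac[[s]] * length(idx))
      nc_ <- round(canonical_frac[[s]] * length(idx))
      pick <- sample(idx, min(nh + nc_, length(idx)))
      truth$motif[pick[seq_len(nh)]] <- "hybrid"
      if (nc_ > 0 && length(pick) > nh)
        truth$motif[pick[(nh + 1):length(pick)]] <- "canonical"
    }
    truth$id <- sprintf("T%03d", seq_len(n))
    rownames(truth) <- NULL
    truth[, c("id", "chrom", "center", "width", paste0("m_", CONDITIONS),
              "stage", "motif")]
  })
}

#' Read-simulation configuration
#'
#' @param coverage mean raw coverage (per-base pileup depth) of the
#'   background.
#' @param read_length read length in bp.
#' @param background one of "poisson" (default) or "nbinom".
#' @param dispersion negative-binomial dispersion (var = mu + disp*mu^2)
#'   when `background = "nbinom"`.
#' @param peak_shape positional density of peak reads: "triangular"
#'   (default), "rectangular" or "bimodal".
#' @return a `ReadSimConfig` list.
#' @export
read_sim_config <- function(coverage = 30, read_length = 36,
                            background = c("poisson", "nbinom"),
                            dispersion = 0.3,
                            peak_shape = c("triangular", "rectangular",
                                           "bimodal")) {
  background <- match.arg(background)
  peak_shape <- match.arg(peak_shape)
  stopifnot(coverage >= 0, read_length > 0, dispersion > 0)
  structure(list(coverage = coverage, read_length = read_length,
                 rate = coverage / read_length, background = background,
                 dispersion = dispersion, peak_shape = peak_shape),
            class = "ReadSimConfig")
}

sample_background_n <- function(mu, config) {
  if (config$background == "poisson") stats::rpois(1, mu)
  else stats::rnbinom(1, mu = mu, size = 1 / config$dispersion)
}

peak_offsets <- function(n, width, shape) {
  half <- width / 2
  switch(shape,
         triangular = round(half * (stats::runif(n) + stats::runif(n) - 1)),
         rectangular = round(stats::runif(n, -half, half)),
         bimodal = round(stats::rnorm(n, mean = sample(c(-1, 1), n,
                                                       replace = TRUE) * half / 2,
                                      sd = width / 12)))
}

make_reads_gr <- function(chrom, starts, read_length, len, layout) {
  starts <- pmax(1L, pmin(as.integer(starts), len - read_length + 1L))
  GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = starts, width = read_length),
    strand = sample(c("+", "-"), length(starts), replace = TRUE))
}

#' Simulate condition-structured ChIP-seq read sets
#'
#' Per condition: background reads at the configured rate (Poisson or
#' negative binomial totals, uniform positions), plus peak reads for each
#' planted feature with triangular positional density over the feature
#' width. A multiplier `m` plants `(m - 1) * rate * width / 2` expected
#' peak reads, which makes the expected summit pileup `m`-fold the
#' background level. Reads overlapping mappability gaps are removed
#' (unalignable), so gap bins carry zero coverage.
#'
#' @param features truth table from [plant_features()].
#' @param layout a `GenomeLayout`.
#' @param config a `ReadSimConfig`.
#' @param gaps optional mappability gap table (chrom, start_bin, end_bin).
#' @param conditions condition names (columns `m_<cond>` must exist).
#' @param seed RNG seed.
#' @return list(reads = named list of `GRanges`, truth = features with
#'   expected raw tag counts per condition appended).
#' @export
simulate_tracks <- function(features, layout, config = read_sim_config(),
                            gaps = NULL, conditions = CONDITIONS,
                            seed = 1L) {
  rl <- config$read_length
  rate <- config$rate
  with_seed(seed, {
    reads <- list()
    for (cond in conditions) {
      grl <- list()
      for (ci in seq_along(layout$chroms)) {
        ch <- names(layout$chroms)[ci]
        len <- layout$chroms[[ci]]
        nbg <- sample_background_n(rate * len, config)
        starts <- sample.int(len - rl + 1L, nbg, replace = TRUE)
        grl[[length(grl) + 1L]] <- make_reads_gr(ch, starts, rl, len, layout)
      }
      fsel <- features
      for (i in seq_len(nrow(fsel))) {
        m <- fsel[[paste0("m_", cond)]][i]
        mu <- (m - 1) * rate * fsel$width[i] / 2
        if (mu <= 0) next
        np <- stats::rpois(1, mu)
        if (np == 0) next
        ch <- fsel$chrom[i]
        len <- layout$chroms[[ch]]
        centers <- fsel$center[i] + peak_offsets(np, fsel$width[i],
                                                 config$peak_shape)
        starts <- centers - rl %/% 2L
        grl[[length(grl) + 1L]] <- make_reads_gr(ch, starts, rl, len, layout)
      }
      gr <- suppressWarnings(do.call(c, grl))
      if (!is.null(gaps) && nrow(gaps)) {
        ggr <- GenomicRanges::GRanges(
          gaps$chrom,
          IRanges::IRanges(start = (gaps$start_bin - 1L) * layout$bin_size + 1L,
                           end = pmin(gaps$end_bin * layout$bin_size,
                                      layout$chroms[gaps$chrom])))
        gr <- gr[GenomicRanges::countOverlaps(gr, ggr) == 0]
      }
      reads[[cond]] <- sort(gr)
    }
    truth <- features
    for (cond in conditions) {
      m <- features[[paste0("m_", cond)]]
      truth[[paste0("exp_", cond)]] <-
        rate * features$width + (m - 1) * rate * features$width / 2
    }
    list(reads = reads, truth = truth)
  })
}

#' Simulate an input (no-ChIP) read set with planted artifact regions
#'
#' Uniform background plus rectangular high-depth artifact regions
#' (`spike_fold` times the background rate, reads fully inside the
#' region), for testing input blacklisting.
#'
#' @param layout a `GenomeLayout`.
#' @param artifacts data.frame with chrom, start_bin, end_bin (1-based
#'   bins), or `NULL`.
#' @param config a `ReadSimConfig` (background rate reused).
#' @param spike_fold artifact depth as a multiple of background.
#' @param seed RNG seed.
#' @return list(reads = `GRanges`, truth = artifacts table).
#' @export
simulate_input <- function(layout, artifacts = NULL,
                           config = read_sim_config(), spike_fold = 50,
                           seed = 1L) {
  rl <- config$read_length
  rate <- config$rate
  with_seed(seed, {
    grl <- list()
    for (ci in seq_along(layout$chroms)) {
      ch <- names(layout$chroms)[ci]
      len <- layout$chroms[[ci]]
      nbg <- stats::rpois(1, rate * len)
      starts <- sample.int(len - rl + 1L, nbg, replace = TRUE)
      grl[[length(grl) + 1L]] <- make_reads_gr(ch, starts, rl, len, layout)
    }
    if (!is.null(artifacts) && nrow(artifacts)) {
      B <- layout$bin_size
      for (i in seq_len(nrow(artifacts))) {
        ch <- artifacts$chrom[i]
        len <- layout$chroms[[ch]]
        a1 <- (artifacts$start_bin[i] - 1L) * B + 1L
        a2 <- min(artifacts$end_bin[i] * B, len)
        w <- a2 - a1 + 1L
        if (w < rl) next
        np <- stats::rpois(1, (spike_fold - 1) * rate * w)
        starts <- sample.int(w - rl + 1L, np, replace = TRUE) + a1 - 1L
        grl[[length(grl) + 1L]] <- make_reads_gr(ch, starts, rl, len, layout)
      }
    }
    list(reads = sort(suppressWarnings(do.call(c, grl))), truth = artifacts)
  })
}

#' Simulate an in vitro cistromics titration series
#'
#' Expected site strength follows the simple occupancy law
#' `depth * c / (c + Kd)` (a generator-side testing device, not a fitted
#' binding model). Read counts are Poisson, *coupled* across
#' concentrations by binomial thinning from the top concentration so
#' each site's counts are non-decreasing in concentration, emulating a
#' titration of one library.
#'
#' @param kds per-site dissociation constants (same units as
#'   concentrations).
#' @param concentrations ascending titration concentrations.
#' @param depth saturated site strength in RPM.
#' @param library_size reads per cistrome (1 RPM = library_size/1e6
#'   reads).
#' @param detect_threshold,cobound_threshold RPM thresholds.
#' @param seed RNG seed.
#' @return list(series = sampled `TitrationSeries`, expected = noise-free
#'   `TitrationSeries`, truth = data.frame(kd, expected_class)).
#' @export
make_ivc_series <- function(kds, concentrations = c(0.1, 0.25, 1, 10),
                            depth = 4, library_size = 2e7,
                            detect_threshold = 1.0, cobound_threshold = 0.5,
                            seed = 1L) {
  stopifnot(all(kds > 0), all(concentrations > 0))
  expected <- outer(kds, concentrations,
                    function(kd, c_) depth * c_ / (c_ + kd))
  colnames(expected) <- paste0("c", concentrations)
  exp_series <- titration_series(expected, concentrations,
                                 detect_threshold, cobound_threshold)
  exp_cls <- titration_analysis(exp_series)$classification
  per_read <- library_size / 1e6
  sampled <- with_seed(seed, {
    top <- stats::rpois(length(kds), expected[, ncol(expected)] * per_read)
    out <- matrix(0, length(kds), length(concentrations))
    out[, ncol(out)] <- top
    for (j in rev(seq_len(ncol(out) - 1L))) {
      ratio <- expected[, j] / expected[, j + 1L]
      out[, j] <- stats::rbinom(length(kds), out[, j + 1L], ratio)
    }
    out / per_read
  })
  colnames(sampled) <- colnames(expected)
  list(series = titration_series(sampled, concentrations, detect_threshold,
                                 cobound_threshold),
       expected = exp_series,
       truth = data.frame(kd = kds, expected_class = exp_cls,
                          stringsAsFactors = FALSE))
}

#' The packaged mini synthetic dataset
#'
#' Two 500 kb chromosomes, 60 planted features (15 per stage pattern,
#' 8-fold summit enrichment, 600 bp wide), 30x mean background coverage
#' of 36 bp reads per condition, hybrid/canonical motif instances planted
#' at per-stage frequencies, six 3-bin mappability gaps, two input
#' artifact regions, and a 200-site IVC titration. Everything is a pure
#' function of `seed`.
#'
#' @param seed RNG seed.
#' @param n_features number of planted features.
#' @param enrichment summit fold-enrichment.
#' @param coverage background coverage.
#' @param chrom_length length of each of the two chromosomes.
#' @param n_gaps number of background mappability gaps.
#' @param ivc_sites number of IVC sites.
#' @return list with layout, genome, features (truth), reads (per
#'   condition), input, mappability, gaps, artifacts, ivc, config.
#' @export
synthetic_mini_dataset <- function(seed = 1L, n_features = 60,
                                   enrichment = 8, coverage = 30,
                                   chrom_length = 500000L, n_gaps = 6,
                                   ivc_sites = 200) {
  layout <- genome_layout(c(chrS1 = chrom_length, chrS2 = chrom_length))
  config <- read_sim_config(coverage = coverage)
  features <- plant_features(layout, n = n_features,
                             enrichment = enrichment, seed = seed)
  # motif plants at feature centers
  plants <- with_seed(seed + 11L, {
    sel <- features$motif != "none"
    if (any(sel)) {
      pats <- builtin_motifs()
      data.frame(
        chrom = features$chrom[sel],
        pos = features$center[sel] - 4L,
        instance = vapply(features$motif[sel], function(m)
          iupac_instance(pats[[m]]), character(1)),
        strand = sample(c("+", "-"), sum(sel), replace = TRUE),
        stringsAsFactors = FALSE)
    } else NULL
  })
  gen <- generate_genome(stats::setNames(rep(chrom_length, 2),
                                         names(layout$chroms)),
                         gc = 0.41, plants = plants, seed = seed + 1L)
  # mappability gaps in background, away from features and chrom ends
  gaps <- with_seed(seed + 2L, {
    nb <- n_bins(layout)
    rows <- list()
    fgr <- GenomicRanges::GRanges(
      features$chrom,
      IRanges::IRanges(features$center - features$width,
                       features$center + features$width))
    tries <- 0
    while (length(rows) < n_gaps && tries < 200) {
      tries <- tries + 1
      ch <- sample(names(layout$chroms), 1)
      sb <- sample.int(nb[[ch]] - 100L, 1) + 50L
      cand <- GenomicRanges::GRanges(
        ch, IRanges::IRanges((sb - 1L) * layout$bin_size + 1L,
                             (sb + 2L) * layout$bin_size))
      if (GenomicRanges::countOverlaps(cand, fgr) == 0)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start_bin = sb, end_bin = sb + 2L,
          stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  mapp <- generate_mappability(layout, gaps)
  sim <- simulate_tracks(features, layout, config, gaps = gaps,
                         seed = seed + 3L)
  artifacts <- data.frame(chrom = c("chrS1", "chrS2"),
                          start_bin = c(2000L, 15000L),
                          end_bin = c(2009L, 15009L),
                          stringsAsFactors = FALSE)
  input <- simulate_input(layout, artifacts, config, seed = seed + 4L)
  kds <- with_seed(seed + 5L, 10^stats::runif(ivc_sites, -2, 2))
  ivc <- make_ivc_series(kds, seed = seed + 6L)
  list(layout = layout, genome = gen$genome, motif_truth = gen$truth,
       features = sim$truth, reads = sim$reads, input = input$reads,
       mappability = mapp$scores, gaps = gaps, artifacts = artifacts,
       ivc = ivc, config = config, seed = seed)
}
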