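test_that("genome generation plants motifs verbatim and is deterministic", {
  lens <- c(chrM = 5000L)
  plants <- data.frame(chrom = "chrM", pos = 100L, instance = "TTGCATCA",
                       strand = "+", stringsAsFactors = FALSE)
  gen <- generate_genome(lens, gc = 0.5, plants = plants, seed = 3)
  h <- scan_motif(as.character(gen$genome[["chrM"]]), "TTKCATCA")
  expect_true(any(h$start == 100 & h$strand == "+"))
  # minus-strand plant is recovered on the minus strand
  plants2 <- data.frame(chrom = "chrM", pos = 200L, instance = "TTTCATCA",
                        strand = "-", stringsAsFactors = FALSE)
  gen2 <- generate_genome(lens, gc = 0.5, plants = plants2, seed = 3)
  h2 <- scan_motif(as.character(gen2$genome[["chrM"]]), "TTKCATCA")
  expect_true(any(h2$start == 200 & h2$strand == "-"))
  # same seed twice gives identical sequence bytes
  expect_identical(as.character(gen$genome),
                   as.character(generate_genome(lens, 0.5, plants, 3)$genome))
  # overlapping plants are an error
  bad <- data.frame(chrom = "chrM", pos = c(100L, 104L),
                    instance = "TTGCATCA", strand = "+",
                    stringsAsFactors = FALSE)
  expect_error(generate_genome(lens, 0.5, bad, 3), "overlap")
})

test_that("background motif hit rate matches the closed-form expectation", {
  L <- 100000L
  gen <- generate_genome(c(chrB = L), gc = 0.5, seed = 8)
  hits <- scan_motif(as.character(gen$genome[["chrB"]]), "TTKCATCA")
  expected <- 2 * (L - 7) * (1 / 4)^7 * (2 / 4)
  expect_lt(abs(nrow(hits) - expected), 3 * sqrt(expected))
})

test_that("mappability gaps mask exactly the planted bins and interpolate inside peaks", {
  layout <- genome_layout(c(chrA = 100000L))
  truth <- one_feature_truth("chrA", 50000)
  # one gap inside the peak shoulder, one in background
  gaps <- data.frame(chrom = "chrA",
                     start_bin = c(2495L, 1000L), end_bin = c(2497L, 1002L),
                     stringsAsFactors = FALSE)
  mp <- generate_mappability(layout, gaps)
  expect_equal(sum(mp$scores$chrA == 0), 6L)
  sim <- simulate_tracks(truth, layout, read_sim_config(coverage = 10),
                         gaps = gaps, seed = 13)
  tr <- bin_coverage(sim$reads$HD, layout)
  # gap bins carry zero coverage -> masked exactly
  tr <- mask_low_mappability(tr, mp$scores)
  masked <- which(tr$mask$chrA == mask_codes()["masked"])
  expect_equal(sort(masked), sort(c(1000:1002, 2495:2497)))
  # interpolation restores the in-peak gap (enriched flanks), not the
  # background gap
  ti <- interpolate_masked(tr)
  expect_true(all(ti$mask$chrA[2495:2497] == mask_codes()["interpolated"]))
  expect_true(all(ti$mask$chrA[1000:1002] == mask_codes()["masked"]))
  # the feature is still recovered through the gap (the read-depleted
  # shoulder can split the call in two, but the summit region is covered)
  tproc <- process_track(sim$reads$HD, layout, mappability = mp$scores)
  f <- detect_features(tproc, sim$reads$HD)
  acc <- f[f$status == "accepted", ]
  expect_gte(nrow(acc), 1L)
  expect_true(any(acc$start < 50300 & acc$end > 49700))
})

test_that("input artifacts are blacklisted exactly", {
  layout <- genome_layout(c(chrA = 100000L))
  artifacts <- data.frame(chrom = "chrA", start_bin = 2000L,
                          end_bin = 2009L, stringsAsFactors = FALSE)
  inp <- simulate_input(layout, artifacts, read_sim_config(coverage = 10),
                        spike_fold = 50, seed = 19)
  chip <- simulate_tracks(one_feature_truth("chrA", 50000), layout,
                          read_sim_config(coverage = 10), seed = 20)
  tr <- normalize_rpm(bin_coverage(chip$reads$HD, layout))
  itr <- normalize_rpm(bin_coverage(inp$reads, layout))
  out <- blacklist_input(tr, itr)
  bl <- which(out$mask$chrA == mask_codes()["blacklisted"])
  expect_equal(bl, 2000:2009)
})

test_that("condition multipliers drive detection and exact attribute closure", {
  layout <- genome_layout(c(chrA = 100000L))
  truth <- one_feature_truth("chrA", 50000,
                             multipliers = c(LD = 1, LD_DMI = 1, HD = 8,
                                             HD_DMI = 8))
  sim <- simulate_tracks(truth, layout, read_sim_config(coverage = 10),
                         seed = 23)
  det <- detect(sim$reads, layout)
  expect_equal(sum(det$per_condition$HD$status == "accepted"), 1L)
  expect_equal(sum(det$per_condition$LD$status == "accepted"), 0L)
  # truth-table closure: expected counts reproduce the multiplier-implied
  # attributes exactly, with no sampling
  exp_counts <- as.matrix(sim$truth[, paste0("exp_", CONDITIONS)])
  colnames(exp_counts) <- CONDITIONS
  cm <- condition_matrix(exp_counts, pseudocount = 1e-6)
  att <- assign_attributes(cm)
  expect_equal(unname(att[1, "LD_vs_HD"]), "up")
  expect_equal(unname(att[1, "HD_vs_HD_DMI"]), "nc")
  expect_equal(unname(group_stage(att)), "HD_primed")
})

test_that("attribute closure holds for every stage pattern", {
  mult <- stage_multipliers(8)
  rate_w <- 0.278 * 600
  for (s in names(mult)) {
    m <- mult[[s]]
    counts <- matrix(rate_w * (1 + (m - 1) / 2), 1,
                     dimnames = list("f", CONDITIONS))
    att <- assign_attributes(condition_matrix(counts, pseudocount = 1e-6))
    expect_equal(unname(group_stage(att)), s, label = s)
  }
})

test_that("doubling the library at fixed per-read structure leaves RPM unchanged", {
  layout <- genome_layout(c(chrA = 100000L))
  truth <- one_feature_truth("chrA", 50000)
  s1 <- simulate_tracks(truth, layout, read_sim_config(coverage = 10),
                        seed = 29)
  t1 <- normalize_rpm(bin_coverage(s1$reads$HD, layout))
  t2 <- normalize_rpm(bin_coverage(c(s1$reads$HD, s1$reads$HD), layout))
  ks <- suppressWarnings(stats::ks.test(t1$values$chrA, t2$values$chrA))
  expect_gt(ks$p.value, 0.01)
  expect_equal(t1$values$chrA, t2$values$chrA)
})

test_that("IVC titrations reproduce saturation-binding logic", {
  # saturated sites are co-bound, barely-reachable sites are gained
  kds <- c(rep(1e-4, 20), rep(10, 20))
  ivc <- make_ivc_series(kds, library_size = 1e8, seed = 37)
  expect_equal(ivc$truth$expected_class,
               c(rep("co-bound", 20), rep("gained", 20)))
  out <- titration_analysis(ivc$series)
  expect_equal(out$classification, ivc$truth$expected_class)
  # detected counts are monotone non-decreasing in concentration
  kds2 <- 10^seq(-2, 2, length.out = 100)
  ivc2 <- make_ivc_series(kds2, seed = 38)
  counts <- titration_analysis(ivc2$series)$counts_detected
  expect_true(all(diff(counts) >= 0))
  # strength at mid-concentration anti-correlates with Kd
  mid <- ivc2$series$strengths[, 3]
  expect_lte(stats::cor(kds2, mid, method = "spearman"), -0.8)
})

test_that("planted hybrid-motif frequencies are recovered per stage group", {
  ds <- synthetic_mini_dataset(seed = 61, chrom_length = 300000L)
  det <- detect(ds$reads, ds$layout, detection_config(),
                mappability = ds$mappability, input_reads = ds$input)
  cm <- count_feature_tags(det$union, ds$reads)
  cl <- cluster_features(cm, k = 19, seed = 61)
  windows <- list()
  for (cond in names(det$per_condition)) {
    w <- select_windows(det$per_condition[[cond]], det$tracks[[cond]])
    if (nrow(w)) windows[[cond]] <- w
  }
  windows <- merge_windows(do.call(rbind, windows))
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1,
                                                 windows$end))
  ugr <- GenomicRanges::GRanges(det$union$chrom,
                                IRanges::IRanges(det$union$start + 1,
                                                 det$union$end))
  ovw <- GenomicRanges::findOverlaps(wgr, ugr, select = "first")
  windows$group <- ifelse(is.na(ovw), "ambiguous", unname(cl$stage[ovw]))
  freq <- cluster_motif_frequency(windows, ds$genome, "TTKCATCA")
  # expected screen-positive rate = planted OR chance background hit;
  # background from the closed-form per-window rate at GC 0.41
  gc <- 0.41
  pT <- (1 - gc) / 2; pC <- gc / 2
  p_strand <- pT^3 * pT^2 * pC^2 * (pC + pT)   # T,T,K,C,A,T,C,A
  planted <- c(uncommitted = round(0.07 * 15) / 15,
               HD_primed = round(0.27 * 15) / 15,
               DMI_induced = round(0.04 * 15) / 15)
  for (g in names(planted)) {
    row <- freq[freq$group == g, ]
    expect_equal(row$n, 15L, label = g)
    lw <- 420  # typical window length
    bg <- 1 - (1 - p_strand)^(2 * (lw - 7))
    expected <- 1 - (1 - planted[[g]]) * (1 - bg)
    expect_gte(expected, row$ci_lower)
    expect_lte(expected, row$ci_upper)
  }
})

test_that("generators are pure functions of their seed", {
  layout <- genome_layout(c(chrA = 50000L))
  truth <- one_feature_truth("chrA", 25000)
  a <- simulate_tracks(truth, layout, read_sim_config(coverage = 5), seed = 7)
  b <- simulate_tracks(truth, layout, read_sim_config(coverage = 5), seed = 7)
  expect_identical(a, b)
  c_ <- simulate_tracks(truth, layout, read_sim_config(coverage = 5), seed = 8)
  expect_false(identical(a$reads$HD, c_$reads$HD))
  i1 <- make_ivc_series(c(0.1, 1, 10), seed = 4)
  i2 <- make_ivc_series(c(0.1, 1, 10), seed = 4)
  expect_identical(i1, i2)
})
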