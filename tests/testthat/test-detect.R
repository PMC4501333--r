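test_that("slope runs are maximal, signed and threshold-gated", {
  layout <- toy_layout(6000L)
  # one triangular peak: exactly one rising and one falling run
  tr <- peak_track(layout, 3000, 50)
  runs <- find_slope_runs(slope_scores(tr), 0.02)
  expect_equal(nrow(runs), 2L)
  expect_equal(runs$sign, c("positive", "negative"))
  expect_true(runs$extremum_slope[1] > 0 && runs$extremum_slope[2] < 0)
  # constant track: no runs
  flat <- binned_track(layout, rep(6, 300), smoothed = TRUE,
                       normalization = "rpm", library_size = 1e6)
  expect_equal(nrow(find_slope_runs(slope_scores(flat), 0.02)), 0L)
  # two separated peaks: four runs at hand-computed locations
  tr2 <- peak_track(layout, c(1500, 4500), c(50, 40))
  runs2 <- find_slope_runs(slope_scores(tr2), 0.02)
  expect_equal(nrow(runs2), 4L)
  expect_equal(runs2$sign, c("positive", "negative", "positive", "negative"))
  expect_true(runs2$end_bin[2] < runs2$start_bin[3])
  # hand-check: the first rising run lies on the left flank of peak 1
  # (slopes look 60 bp ahead, so the run starts up to 4 bins early)
  expect_true(runs2$start_bin[1] * 20 >= 1500 - 300 - 80 &&
              runs2$end_bin[1] * 20 <= 1500 + 80)
  expect_error(find_slope_runs(slope_scores(tr), 0), "positive")
})

test_that("run pairing respects the 400 bp cutoff and nearest-downstream rule", {
  layout <- toy_layout(6000L)
  cfg <- detection_config()
  mkruns <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
      data.frame(chrom = "chrT", start_bin = r[1], end_bin = r[2],
                 sign = ifelse(r[3] > 0, "positive", "negative"),
                 extremum_slope = r[3], stringsAsFactors = FALSE)))
  }
  # rise ends at bin 50 (bp 1000); fall starts at bp 1500: gap 500 > 400
  runs <- mkruns(c(40, 50, 1), c(76, 85, -1))
  expect_equal(nrow(pair_runs(runs, layout, cfg)), 0L)
  # fall starts at bp 1300: gap 300 <= 400 -> one feature spanning runs
  runs <- mkruns(c(40, 50, 1), c(66, 75, -1))
  f <- pair_runs(runs, layout, cfg)
  expect_equal(nrow(f), 1L)
  expect_equal(f$start, 39 * 20)
  expect_equal(f$end, 75 * 20)
  # two downstream falls at gaps 100 and 300: paired to the nearer
  runs <- mkruns(c(40, 50, 1), c(56, 60, -1), c(66, 75, -1))
  f <- pair_runs(runs, layout, cfg)
  expect_equal(nrow(f), 1L)
  expect_equal(f$end, 60 * 20)
})

test_that("multiplet merging follows the peak-to-trough ratio rule", {
  layout <- toy_layout(10000L)
  cfg <- detection_config()
  # build a track with two peaklets and a controllable trough
  doublet_track <- function(h1, h2, trough) {
    nb <- n_bins(layout)[[1]]
    v <- rep(1, nb)
    v[100:110] <- seq(1, h1, length.out = 11)
    v[110:120] <- seq(h1, trough, length.out = 11)
    v[120:130] <- seq(trough, h2, length.out = 11)
    v[130:140] <- seq(h2, 1, length.out = 11)
    binned_track(layout, v, smoothed = TRUE, normalization = "rpm",
                 library_size = 1e6)
  }
  feats <- function(tr) {
    f <- data.frame(id = c("a", "b"), chrom = "chrT",
                    start = c(99, 119) * 20, end = c(119, 139) * 20,
                    summit_bin = NA_integer_, summit = NA_real_,
                    max_ushp = NA_real_, tag_count = 0, tag_density = 0,
                    status = "candidate", merged_from = "",
                    stringsAsFactors = FALSE)
    annotate_features(f, tr)
  }
  # maxima 10 and 8, trough 5 -> ratio 1.6 < 2.5: merged
  tr <- doublet_track(10, 8, 5)
  m <- merge_multiplets(feats(tr), tr, cfg)
  expect_equal(nrow(m), 1L)
  expect_equal(m$merged_from, "a,b")
  expect_equal(m$max_ushp, 10)
  # maxima 10 and 9, trough 2 -> ratio 4.5: not merged
  tr <- doublet_track(10, 9, 2)
  expect_equal(nrow(merge_multiplets(feats(tr), tr, cfg)), 2L)
  # zero trough means infinite ratio: no merge
  tr <- doublet_track(10, 8, 0)
  expect_equal(nrow(merge_multiplets(feats(tr), tr, cfg)), 2L)
  # chain of three peaklets with pairwise ratios < 2.5 collapses to one
  nb <- n_bins(layout)[[1]]
  v <- rep(1, nb)
  v[100:158] <- c(seq(1, 10, length.out = 11), seq(10, 7, length.out = 10)[-1],
                  seq(7, 10, length.out = 11)[-1], seq(10, 7, length.out = 10)[-1],
                  seq(7, 10, length.out = 11)[-1], seq(10, 1, length.out = 11)[-1])
  tr3 <- binned_track(layout, v, smoothed = TRUE, normalization = "rpm",
                      library_size = 1e6)
  f3 <- data.frame(id = c("a", "b", "c"), chrom = "chrT",
                   start = c(99, 119, 139) * 20, end = c(119, 139, 160) * 20,
                   summit_bin = NA_integer_, summit = NA_real_,
                   max_ushp = NA_real_, tag_count = 0, tag_density = 0,
                   status = "candidate", merged_from = "",
                   stringsAsFactors = FALSE)
  f3 <- annotate_features(f3, tr3)
  m3 <- merge_multiplets(f3, tr3, cfg)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$merged_from, "a,b,c")
})

test_that("local background filter uses 2 kb domains expanded by 1 kb", {
  layout <- toy_layout(20000L)
  nb <- n_bins(layout)[[1]]
  v <- rep(10, nb)
  # two features 1.5 kb apart sharing one background domain
  v[200:220] <- 35   # max 35 vs mean 10 -> accepted (3.5x, inclusive)
  v[280:300] <- 30   # max 30 -> rejected
  tr <- binned_track(layout, v, smoothed = TRUE, normalization = "rpm",
                     library_size = 1e6)
  f <- data.frame(id = c("a", "b"), chrom = "chrT",
                  start = c(199, 279) * 20, end = c(220, 300) * 20,
                  summit_bin = NA_integer_, summit = NA_real_,
                  max_ushp = NA_real_, tag_count = 0, tag_density = 0,
                  status = "candidate", merged_from = "",
                  stringsAsFactors = FALSE)
  f <- annotate_features(f, tr)
  out <- local_background_filter(f, tr, detection_config())
  expect_equal(out$status, c("candidate", "background_filtered"))
  # hand-check the shared background mean: all non-peak bins are 10
  expect_equal(out$max_ushp, c(35, 30))
})

test_that("signal threshold accepts by count OR density", {
  cfg <- detection_config()
  f <- data.frame(id = c("a", "b", "c"), chrom = "chrT",
                  start = c(0, 1000, 2000), end = c(500, 1002, 2500),
                  summit_bin = 1L, summit = 1, max_ushp = 1,
                  tag_count = c(25, 10, 10),
                  tag_density = c(25 / 500, 5, 10 / 500),
                  status = "candidate", merged_from = "",
                  stringsAsFactors = FALSE)
  out <- signal_threshold_filter(f, cfg)
  expect_equal(out$status, c("accepted", "signal_filtered", "signal_filtered"))
  # the density route alone suffices at >= 14.5 tags/bp
  f$tag_density[2] <- 20
  expect_equal(signal_threshold_filter(f, cfg)$status[2], "accepted")
})

test_that("flat tracks of any level yield zero features", {
  layout <- toy_layout(20000L)
  for (level in c(0.5, 5, 50)) {
    tr <- binned_track(layout, rep(level, n_bins(layout)[[1]]),
                       smoothed = TRUE, normalization = "rpm",
                       library_size = 1e6)
    reads <- make_reads("chrT", seq(0, 19000, by = 100))
    f <- detect_features(tr, reads, detection_config())
    expect_equal(nrow(f), 0L)
  }
})

test_that("accepted features do not overlap and detection is translation-invariant", {
  fx <- random_fixture(101)
  f <- detect_features(fx$track, fx$reads, detection_config())
  acc <- f[f$status == "accepted", ]
  if (nrow(acc) > 1) {
    acc <- acc[order(acc$start), ]
    expect_true(all(acc$start[-1] >= acc$end[-nrow(acc)]))
  }
  # translating everything by a whole number of bins shifts calls exactly
  shift_bins <- 25L
  layout2 <- toy_layout(fx$layout$chroms[[1]] + shift_bins * 20L)
  v <- fx$track$values$chrT
  m <- fx$track$mask$chrT
  tr2 <- binned_track(layout2, c(rep(v[1], shift_bins), v),
                      mask = list(chrT = c(rep(0L, shift_bins), m)),
                      normalization = "rpm", library_size = 1e6,
                      smoothed = TRUE)
  reads2 <- GenomicRanges::shift(fx$reads, shift_bins * 20L)
  f2 <- detect_features(tr2, reads2, detection_config(
    slope_threshold = auto_slope_threshold(fx$track, 0.5)))
  f1 <- detect_features(fx$track, fx$reads, detection_config(
    slope_threshold = auto_slope_threshold(fx$track, 0.5)))
  acc1 <- f1[f1$status == "accepted", ]
  acc2 <- f2[f2$status == "accepted", ]
  skip_if(nrow(acc1) == 0, "fixture produced no accepted features")
  # interior features translate exactly (edge-of-chromosome calls may differ)
  expect_equal(acc2$start, acc1$start + shift_bins * 20L)
  expect_equal(acc2$end, acc1$end + shift_bins * 20L)
})

test_that("raising thresholds never increases accepted features", {
  # enrichment_fold only gates the background filter: monotone on any input
  for (seed in c(202, 303, 404)) {
    fx <- random_fixture(seed)
    base_thr <- auto_slope_threshold(fx$track, 0.5)
    n_acc <- function(fold) {
      f <- detect_features(fx$track, fx$reads,
                           detection_config(slope_threshold = base_thr,
                                            enrichment_fold = fold))
      sum(f$status == "accepted")
    }
    counts <- vapply(c(3.5, 5, 7, 10), n_acc, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
  # slope threshold: on a clean unimodal peak the call count steps 1 -> 0
  layout <- toy_layout(10000L)
  tr <- peak_track(layout, 5000, 50)
  reads <- make_reads("chrT", rep(seq(4500, 5500, by = 20), each = 3))
  n_slope <- vapply(c(0.01, 0.05, 0.2, 1), function(thr) {
    f <- detect_features(tr, reads, detection_config(slope_threshold = thr))
    sum(f$status == "accepted")
  }, numeric(1))
  expect_true(all(diff(n_slope) <= 0))
  expect_equal(n_slope[1], 1)
  expect_equal(n_slope[4], 0)
})

test_that("multi-condition detection unions calls with provenance", {
  layout <- genome_layout(c(chrA = 100000L))
  truth <- one_feature_truth("chrA", 50000)
  sim <- simulate_tracks(truth, layout, read_sim_config(coverage = 10),
                         seed = 5)
  det <- detect(sim$reads, layout)
  # feature found at high density, absent at low density
  expect_equal(sum(det$per_condition$HD$status == "accepted"), 1L)
  expect_equal(sum(det$per_condition$LD$status == "accepted"), 0L)
  expect_equal(nrow(det$union), 1L)
  expect_true(det$union$in_HD & det$union$in_HD_DMI)
  expect_false(det$union$in_LD)
  expect_true(abs(det$union$summit - 50000) < 300)
  # union never exceeds the sum of per-track accepted counts
  tot <- sum(sapply(det$per_condition, function(f) sum(f$status == "accepted")))
  expect_lte(nrow(det$union), tot)
  # single condition: union equals that condition's accepted set
  det1 <- detect(sim$reads["HD"], layout)
  expect_equal(nrow(det1$union),
               sum(det1$per_condition$HD$status == "accepted"))
})
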