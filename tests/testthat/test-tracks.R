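test_that("bin_coverage matches uniform and brute-force pileups", {
  layout <- toy_layout(2000L)
  # three identical 20 bp reads exactly tiling bin 3 -> stack height 3
  reads <- make_reads("chrT", rep(40L, 3), width = 20L)
  tr <- bin_coverage(reads, layout)
  expect_equal(tr$values$chrT[3], 3.0)
  expect_equal(sum(tr$values$chrT[-3]), 0)
  expect_equal(tr$library_size, 3L)
  # dedup collapses identical stacks when asked
  trd <- bin_coverage(reads, layout, dedup = TRUE)
  expect_equal(trd$values$chrT[3], 1.0)
  # empty read set -> all-zero track
  tr0 <- bin_coverage(make_reads("chrT", integer(0)), layout)
  expect_true(all(unlist(tr0$values) == 0))
  # random reads agree with the per-base pileup oracle
  set.seed(42)
  reads <- make_reads("chrT", sample(0:(2000 - 36), 50, replace = TRUE))
  tr <- bin_coverage(reads, layout)
  expect_equal(unname(tr$values$chrT), oracle_pileup(reads, layout))
})

test_that("bin_coverage rejects out-of-range and unknown chromosomes", {
  layout <- toy_layout(2000L)
  expect_error(bin_coverage(make_reads("chrT", 1990L), layout),
               "beyond chromosome end")
  expect_error(bin_coverage(make_reads("chrX", 10L), layout), "chrX")
})

test_that("RPM normalization scales by 1e6/library and guards misuse", {
  layout <- toy_layout(2000L)
  tr <- binned_track(layout, rep(5, 100), library_size = 2e6)
  rpm <- normalize_rpm(tr)
  expect_equal(rpm$values$chrT[1], 2.5)
  expect_equal(rpm$normalization, "rpm")
  expect_error(normalize_rpm(rpm), "already")
  # library of exactly 1e6 is the identity
  tr1 <- binned_track(layout, rep(5, 100), library_size = 1e6)
  expect_equal(normalize_rpm(tr1)$values$chrT, tr1$values$chrT)
  # doubling the library halves RPM at equal raw values
  tr2 <- binned_track(layout, rep(5, 100), library_size = 2e6)
  expect_equal(normalize_rpm(tr2)$values$chrT,
               normalize_rpm(tr1)$values$chrT / 2)
  expect_error(normalize_rpm(binned_track(layout, rep(1, 100),
                                          library_size = 0)), "library_size")
})

test_that("low-mappability masking requires both low score and no signal", {
  layout <- toy_layout(2000L)
  v <- rep(0, 100); v[10] <- 4
  tr <- binned_track(layout, v)
  mp <- list(chrT = rep(1, 100))
  expect_equal(sum(unlist(mask_low_mappability(tr, mp)$mask)), 0)
  mp$chrT[c(5, 10)] <- 0
  m2 <- mask_low_mappability(tr, mp)
  expect_equal(which(m2$mask$chrT == mask_codes()["masked"]), 5L)  # bin 10 has signal
  expect_error(mask_low_mappability(tr, list(chrT = rep(1, 99))), "aligned")
})

test_that("interpolation fills enriched gaps and leaves deserts masked", {
  layout <- toy_layout(2000L)
  v <- rep(1, 100)
  v[40] <- 4; v[42] <- 8; v[41] <- 0
  mask <- integer(100); mask[41] <- 1L
  tr <- binned_track(layout, v, mask = list(chrT = mask))
  out <- interpolate_masked(tr)
  expect_equal(out$values$chrT[41], 6.0)
  expect_equal(unname(out$mask$chrT[41]), unname(mask_codes()["interpolated"]))
  # masked bin at chromosome start has no upstream neighbor: stays masked
  mask2 <- integer(100); mask2[1] <- 1L
  tr2 <- binned_track(layout, v, mask = list(chrT = mask2))
  expect_equal(unname(interpolate_masked(tr2)$mask$chrT[1]),
               unname(mask_codes()["masked"]))
  # a 3-bin gap inside a peak: all three get the mean of the flanks
  v3 <- rep(1, 100); v3[50] <- 10; v3[54] <- 20; v3[51:53] <- 0
  mask3 <- integer(100); mask3[51:53] <- 1L
  tr3 <- binned_track(layout, v3, mask = list(chrT = mask3))
  out3 <- interpolate_masked(tr3)
  expect_equal(unname(out3$values$chrT[51:53]), rep(15, 3))
  # masked desert in flat background (flanks below enrichment floor)
  v4 <- rep(1, 100); v4[60:62] <- 0
  mask4 <- integer(100); mask4[60:62] <- 1L
  out4 <- interpolate_masked(binned_track(layout, v4, mask = list(chrT = mask4)))
  expect_true(all(out4$mask$chrT[60:62] == mask_codes()["masked"]))
})

test_that("smoothing is a 3-bin moving average preserving mass and edges", {
  layout <- toy_layout(100L)
  tr <- binned_track(layout, c(0, 3, 6, 0, 0))
  sm <- smooth_track(tr)
  expect_equal(sm$values$chrT[2], 3.0)
  expect_equal(sm$values$chrT[1], 1.5)  # edge averages available neighbors
  # constant track unchanged
  trc <- binned_track(layout, rep(7, 5))
  expect_equal(smooth_track(trc)$values$chrT, rep(7, 5))
  # random track equals the brute-force windowed mean
  set.seed(7)
  layout2 <- toy_layout(2000L)
  v <- runif(100, 0, 10)
  sm2 <- smooth_track(binned_track(layout2, v))$values$chrT
  brute <- sapply(seq_along(v), function(i)
    mean(v[max(1, i - 1):min(length(v), i + 1)]))
  expect_equal(unname(sm2), brute)
  # mass conservation on zero-padded interior
  v3 <- c(0, 0, 0, runif(94, 0, 5), 0, 0, 0)
  sm3 <- smooth_track(binned_track(layout2, v3))$values$chrT
  expect_equal(sum(sm3), sum(v3), tolerance = 1e-6)
})

test_that("input blacklisting flags only high-depth input bins", {
  layout <- toy_layout(2000L)
  chip <- binned_track(layout, rep(5, 100), normalization = "rpm",
                       library_size = 1e6)
  iv <- rep(1, 100); iv[33] <- 50
  input <- binned_track(layout, iv, normalization = "rpm",
                        library_size = 1e6)
  out <- blacklist_input(chip, input)
  expect_equal(which(out$mask$chrT == mask_codes()["blacklisted"]), 33L)
  # flat input blacklists nothing
  flat <- binned_track(layout, rep(1, 100), normalization = "rpm",
                       library_size = 1e6)
  expect_equal(sum(blacklist_input(chip, flat)$mask$chrT), 0)
  expect_error(blacklist_input(chip, binned_track(toy_layout(4000L),
                                                  rep(1, 200),
                                                  normalization = "rpm",
                                                  library_size = 1e6)),
               "layout")
  expect_error(blacklist_input(binned_track(layout, rep(5, 100)), input),
               "RPM")
})

test_that("slope scores follow the 60 bp offset / 100 bp divisor rule", {
  layout <- toy_layout(2000L)
  v <- rep(10, 100); v[20] <- 30   # value 60 bp downstream of bin 17
  tr <- binned_track(layout, v, smoothed = TRUE)
  sl <- slope_scores(tr)
  expect_equal(sl$slopes$chrT[17], (30 - 10) / 100)
  expect_equal(sl$slopes$chrT[23], (10 - 30) / 100)
  # constant track: all defined slopes are zero
  slc <- slope_scores(binned_track(layout, rep(4, 100), smoothed = TRUE))
  expect_true(all(slc$slopes$chrT[slc$defined$chrT] == 0))
  # undefined within 3 bins of ends
  expect_false(any(slc$defined$chrT[c(1:3, 98:100)]))
  expect_true(all(slc$defined$chrT[4:97]))
  # mirrored track: slopes negate exactly
  set.seed(11)
  v2 <- runif(100)
  s_f <- slope_scores(binned_track(layout, v2, smoothed = TRUE))$slopes$chrT
  s_r <- slope_scores(binned_track(layout, rev(v2), smoothed = TRUE))$slopes$chrT
  expect_equal(s_f[4:97], -rev(s_r)[4:97])
  # monotone non-decreasing track: defined slopes >= 0
  s_m <- slope_scores(binned_track(layout, sort(v2), smoothed = TRUE))
  expect_true(all(s_m$slopes$chrT[s_m$defined$chrT] >= 0))
  # undefined across masked bins
  mask <- integer(100); mask[50] <- 1L
  s_k <- slope_scores(binned_track(layout, v2, mask = list(chrT = mask),
                                   smoothed = TRUE))
  expect_false(any(s_k$defined$chrT[47:53]))
  expect_error(slope_scores(binned_track(layout, v2)), "smoothed")
})

test_that("RPM values are invariant when reads and library double together", {
  layout <- toy_layout(2000L)
  set.seed(3)
  reads <- make_reads("chrT", sample(0:1960, 200, replace = TRUE))
  tr1 <- normalize_rpm(bin_coverage(reads, layout))
  tr2 <- normalize_rpm(bin_coverage(c(reads, reads), layout))
  expect_equal(tr1$values$chrT, tr2$values$chrT)
})

test_that("bedGraph and chrom-sizes round-trip through files", {
  layout <- toy_layout(2000L)
  set.seed(5)
  tr <- bin_coverage(make_reads("chrT", sample(0:1960, 80, TRUE)), layout)
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, layout)
  expect_equal(back$values$chrT, unname(tr$values$chrT), tolerance = 1e-8)
  cs <- tempfile()
  write_chrom_sizes(layout, cs)
  l2 <- read_chrom_sizes(cs)
  expect_equal(l2$chroms, layout$chroms)
  # mask channel exports as BED runs named by state
  v <- rep(0, 100); mask <- integer(100)
  mask[11:13] <- 1L; mask[40] <- 3L
  trm <- binned_track(layout, v, mask = list(chrT = mask))
  mb <- tempfile(fileext = ".bed")
  write_mask_bed(trm, mb)
  bed <- read_bed(mb)
  expect_equal(sort(unique(bed$name)), c("blacklisted", "masked"))
  msk <- bed[bed$name == "masked"]
  expect_equal(BiocGenerics::start(msk) - 1L, 10L * 20L)
  expect_equal(BiocGenerics::end(msk), 13L * 20L)
})
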