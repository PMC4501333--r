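#!/usr/bin/env Rscript
# Stage 2: track processing and slope-based feature detection.
#
# Processes each condition's reads into masked, interpolated, smoothed,
# RPM-normalized 20 bp USHP tracks, detects RNAPII features as paired
# rising/falling slope runs with multiplet merging and local-background /
# signal filtering, and unions the per-condition calls. Reports recall
# and precision against the planted truth.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "common.R"))

seed <- get_seed()
ds <- build_dataset(seed)
det <- run_detection(ds)
out <- results_dir()

for (cond in names(det$per_condition))
  write_features(det$per_condition[[cond]],
                 file.path(out, sprintf("features_%s.tsv", cond)))
write.table(det$union, file.path(out, "union_features.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

acc <- sapply(det$per_condition, function(f) sum(f$status == "accepted"))
cat("accepted features per condition:\n"); print(acc)

tgr <- truth_granges(ds); ugr <- union_granges(det)
recall <- mean(GenomicRanges::countOverlaps(tgr, ugr) > 0)
precision <- mean(GenomicRanges::countOverlaps(ugr, tgr) > 0)
cat(sprintf("union features: %d | recall %.3f | precision %.3f\n",
            nrow(det$union), recall, precision))
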