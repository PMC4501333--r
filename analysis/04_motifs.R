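#!/usr/bin/env Rscript
# Stage 4: motif window selection and hybrid vs canonical screening.
#
# Selects 400-600 bp motif-mining windows centered on each feature's
# top-quartile USHP bins, merges overlapping windows across condition
# tracks, screens them for the hybrid (TTKCATCA) and canonical C/EBP
# (TTGCNNAA) consensus on both strands, and summarizes frequencies per
# stage group with exact binomial confidence intervals.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "common.R"))

seed <- get_seed()
ds <- build_dataset(seed)
det <- run_detection(ds)
out <- results_dir()

cm <- count_feature_tags(det$union, ds$reads)
cl <- cluster_features(cm, k = 19, seed = seed)

windows <- list()
for (cond in names(det$per_condition)) {
  w <- select_windows(det$per_condition[[cond]], det$tracks[[cond]])
  if (nrow(w)) windows[[cond]] <- w
}
windows <- merge_windows(do.call(rbind, windows))
wgr <- GenomicRanges::GRanges(windows$chrom,
                              IRanges::IRanges(windows$start + 1, windows$end))
ov <- GenomicRanges::findOverlaps(wgr, union_granges(det), select = "first")
windows$group <- ifelse(is.na(ov), "ambiguous", unname(cl$stage[ov]))

freq_h <- cluster_motif_frequency(windows, ds$genome, "TTKCATCA")
freq_c <- cluster_motif_frequency(windows, ds$genome, "TTGCNNAA")
freq_h$pattern <- "hybrid"; freq_c$pattern <- "canonical"
hits <- scan_windows(windows, ds$genome, "TTKCATCA")

write.table(windows, file.path(out, "motif_windows.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rbind(freq_h, freq_c), file.path(out, "motif_frequencies.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(hits, file.path(out, "hybrid_hits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d motif windows (lengths %d-%d bp)\n", nrow(windows),
            min(windows$end - windows$start), max(windows$end - windows$start)))
cat("hybrid motif frequency per stage group:\n")
print(freq_h[, c("group", "n", "hits", "fraction")])
cat("canonical C/EBP motif frequency per stage group:\n")
print(freq_c[, c("group", "n", "hits", "fraction")])
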