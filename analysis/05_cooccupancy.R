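#!/usr/bin/env Rscript
# Stage 5: co-occupancy enrichment and anchored density matrices.
#
# Tests whether hybrid-motif presence is enriched in specific stage
# groups with the upper-tail hypergeometric probability (cluster overlap
# vs the genome-wide rate), and samples HD-track signal in a 4 kb window
# around every union feature summit for density heat maps.

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

seqs <- window_sequences(windows, ds$genome)
has_hybrid <- vapply(seqs, function(s)
  nrow(scan_motif(s, "TTKCATCA")) > 0, logical(1), USE.NAMES = FALSE)
enr <- cluster_cooccupancy_enrichment(windows$group, has_hybrid,
                                      adjust = TRUE)
write.table(enr, file.path(out, "cooccupancy_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("hybrid-motif co-occupancy enrichment per stage group:\n")
print(enr)

dm <- density_matrix(det$union, det$tracks$HD, flank = 2000,
                     bin = ds$layout$bin_size)
write.table(round(dm$matrix, 4), file.path(out, "density_matrix_HD.tsv"),
            sep = "\t", quote = FALSE, row.names = TRUE, col.names = NA)
profile <- colMeans(dm$matrix, na.rm = TRUE)
cat(sprintf("density matrix: %d anchors x %d bins; center/edge signal %.1f / %.1f RPM\n",
            nrow(dm$matrix), ncol(dm$matrix),
            profile[length(profile) / 2], profile[1]))
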