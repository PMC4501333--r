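#!/usr/bin/env Rscript
# Stage 3: differential occupancy clustering.
#
# Counts RPM-scaled tags per union feature across the four condition
# tracks, assigns two-fold up/nc/down attributes for all six pairwise
# comparisons, maps attribute patterns to stage groups, and k-means-
# clusters log2 fold-change rows within groups for heatmap ordering.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "common.R"))

seed <- get_seed()
ds <- build_dataset(seed)
det <- run_detection(ds)
out <- results_dir()

cm <- count_feature_tags(det$union, ds$reads)
cl <- cluster_features(cm, k = 19, seed = seed)

write.table(cbind(id = det$union$id, round(cm$counts, 2)),
            file.path(out, "condition_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(id = det$union$id, stage = cl$stage,
                       cluster = cl$labels, cl$attributes,
                       check.names = FALSE),
            file.path(out, "clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_cdt(cl$heatmap, file.path(out, "heatmap.cdt"))

cat("stage groups of union features:\n")
print(table(cl$stage))
ov <- GenomicRanges::findOverlaps(union_granges(det), truth_granges(ds),
                                  select = "first")
matched <- !is.na(ov)
cat(sprintf("stage assignment accuracy vs truth: %.3f (n=%d)\n",
            mean(cl$stage[matched] == ds$features$stage[ov[matched]]),
            sum(matched)))
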