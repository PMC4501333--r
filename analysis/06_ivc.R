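#!/usr/bin/env Rscript
# Stage 6: in vitro cistromics titration analysis.
#
# Applies the 1 RPM detection and 0.5 RPM co-bound thresholds across the
# simulated C/EBPbeta titration, classifies sites as co-bound / gained /
# other, and ranks the strongest and weakest sites at the top
# concentration.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "common.R"))

seed <- get_seed()
ds <- build_dataset(seed)
out <- results_dir()

ivc <- ds$ivc
res <- titration_analysis(ivc$series)

write.table(data.frame(kd = ivc$truth$kd,
                       expected = ivc$truth$expected_class,
                       observed = res$classification),
            file.path(out, "ivc_classification.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(concentration = ivc$series$concentrations,
                       detected = res$counts_detected),
            file.path(out, "ivc_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("sites detected (>= 1 RPM) per concentration:\n")
print(setNames(res$counts_detected, ivc$series$concentrations))
cat(sprintf("classification accuracy vs truth: %.3f\n",
            mean(res$classification == ivc$truth$expected_class)))

peaks <- data.frame(chrom = "ivc", start = seq_along(ivc$truth$kd) * 1000,
                    end = seq_along(ivc$truth$kd) * 1000 + 200,
                    summit = seq_along(ivc$truth$kd) * 1000 + 100,
                    strength = ivc$series$strengths[, ncol(ivc$series$strengths)])
ex <- rank_extremes(peaks, n = 50)
cat(sprintf("strongest-50 mean Kd %.3f vs weakest-50 mean Kd %.3f\n",
            mean(ivc$truth$kd[as.integer(rownames(ex$strongest))]),
            mean(ivc$truth$kd[as.integer(rownames(ex$weakest))])))
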