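#!/usr/bin/env Rscript
# Stage 1: build the synthetic study dataset.
#
# Two 500 kb chromosomes; 60 RNAPII enhancers planted at 8-fold summit
# enrichment, 15 per condition-response pattern (uncommitted, HD-primed,
# DMI-induced, constitutive/ambiguous); 30x background coverage of 36 bp
# reads per condition track; hybrid/canonical C/EBP motifs planted at
# stage-specific frequencies; mappability gaps and input artifacts; and a
# 200-site in vitro titration. Writes the ground-truth tables.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "common.R"))

seed <- get_seed()
ds <- build_dataset(seed)
out <- results_dir()

write.table(ds$features, file.path(out, "truth_features.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ds$gaps, file.path(out, "truth_mappability_gaps.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ds$artifacts, file.path(out, "truth_input_artifacts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ds$ivc$truth, file.path(out, "truth_ivc.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_chrom_sizes(ds$layout, file.path(out, "chrom_sizes.txt"))

cat(sprintf("seed %d: %d planted features on %d chromosomes\n",
            seed, nrow(ds$features), length(ds$layout$chroms)))
print(table(ds$features$stage, ds$features$motif))
cat(sprintf("reads per condition: %s\n",
            paste(sprintf("%s=%d", names(ds$reads), sapply(ds$reads, length)),
                  collapse = ", ")))
cat("truth tables written under", out, "\n")
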