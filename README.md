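# poliiscan

Annotation of stage-specific RNA polymerase II (RNAPII) enhancers from
ChIP-seq coverage, and everything downstream of it: differential
occupancy clustering across culture conditions, hybrid vs canonical
C/EBP motif screening, hypergeometric co-occupancy enrichment, anchored
density matrices, and in vitro cistromics (IVC) titration analysis. A
deterministic synthetic-data generator with complete ground truth drives
the whole workflow, so every analysis in this repository runs from
scratch on one machine with no downloads.

## The science

RNAPII is recruited to active enhancers genome-wide, so RNAPII ChIP-seq
coverage alone can annotate regulatory elements. In human mesenchymal
stem cells, seeding density (low, LD vs high, HD) and an adipogenic
cocktail (DMI) stage adipocyte commitment; enhancers split into
*uncommitted* (LD-favoring), *HD-primed* (density-responsive), and
*DMI-induced* groups. HD-primed enhancers carry a non-canonical hybrid
C/EBP–AP-1 motif (`TTKCATCA`, bound by the C/EBPβ–ATF4 heterodimer),
DMI-induced enhancers the palindromic C/EBP consensus (`TTGCNNAA`).

The detector works on the *unique stack height profile* (USHP): per-base
read pileup in 20 bp bins, mappability-masked, gap-interpolated,
smoothed with a 60 bp moving average, RPM-normalized, and input-
blacklisted. Each bin gets a slope score

    slope[i] = (USHP[i+3] − USHP[i−3]) / 100        (bins of 20 bp)

and a feature is a maximal run of positive slopes paired to the nearest
downstream run of negative slopes (≤ 400 bp apart), with poorly resolved
multiplets merged at peak-to-trough ratio < 2.5, a local-background test
(maximum ≥ 3.5× the mean of non-peak bins in the ±1 kb-expanded 2 kb
domain), and a signal threshold (≥ 20 tags or ≥ 14.5 tags/bp). Feature
occupancy across the four condition tracks is reduced to two-fold
up/nc/down attributes per pairwise comparison, mapped to stage groups,
and k-means-ordered for log2 fold-change heat maps.

## Worked example

```r
library(poliiscan)
ds  <- synthetic_mini_dataset(seed = 1)   # 60 planted enhancers, 4 tracks
det <- detect(ds$reads, ds$layout, detection_config(),
              mappability = ds$mappability, input_reads = ds$input)
sapply(det$per_condition, function(f) sum(f$status == "accepted"))
#>     LD LD_DMI     HD HD_DMI
#>     30     30     30     45
nrow(det$union)
#> [1] 60
```

Each condition recovers exactly the features planted as "on" in it (15
uncommitted + 15 constitutive at LD; those plus 15 HD-primed at HD; all
45 non-LD-specific at HD+DMI), and the union of the four call sets is
the 60 planted enhancers. Clustering the union by differential
occupancy:

```r
cm <- count_feature_tags(det$union, ds$reads)
cl <- cluster_features(cm, k = 19, seed = 1)
table(cl$stage)
#>   ambiguous DMI_induced   HD_primed uncommitted
#>          15          15          15          15
```

which matches the planted stage labels feature-for-feature. The motif
screen on 400–600 bp windows centered on each feature's top-quartile
USHP bins finds the planted hybrid-motif gradient across groups
(HD-primed 5/15 ≈ 33%, uncommitted 3/15, DMI-induced 2/15 at seed 1 —
planted frequencies 27%/7%/4% plus chance hits), and the IVC titration
analysis classifies 200 simulated sites against the 1 RPM detection /
0.5 RPM co-bound thresholds with 96.5% agreement to the binding-law
ground truth, with detected-site counts rising monotonically along the
titration (74, 99, 123, 167).

The numbered scripts under `analysis/` run these stages as a narrative
workflow (`Rscript analysis/02_detect.R --seed 1`, etc.) and write their
tables under `results/`.

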