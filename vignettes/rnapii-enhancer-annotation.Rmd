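---
title: "Slope-based annotation of stage-specific RNAPII enhancers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slope-based annotation of stage-specific RNAPII enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poliiscan)
```

# The problem

RNA polymerase II (RNAPII) is recruited to active enhancers genome-wide,
so RNAPII ChIP-seq coverage can annotate cis-regulatory elements without
knowing in advance which transcription factors drive them. In human
mesenchymal stem cells (hMSCs), culture density and an adipogenic
cocktail (DMI: dexamethasone, IBMX, insulin, with indomethacin) stage the
commitment to adipocytes, and enhancers fall into groups by when RNAPII
arrives: *uncommitted* elements favored at low density (LD),
*HD-primed* elements switched on by high density (HD) alone, and
*DMI-induced* elements requiring the cocktail. HD-primed enhancers are
distinguished by a non-canonical *hybrid* C/EBP--AP-1 motif (consensus
`TTKCATCA`) bound by the C/EBP&beta;--ATF4 heterodimer, whereas
DMI-induced enhancers carry the palindromic canonical C/EBP motif
(`TTGCNNAA`).

`poliiscan` re-implements this workflow as a tested, deterministic
pipeline: coverage-track processing, slope-based feature detection,
differential-occupancy clustering, consensus motif screening,
hypergeometric co-occupancy enrichment, anchored density matrices, and
the analysis of in vitro cistromics (IVC) protein titrations. A
synthetic-data generator with complete ground truth supplies the study
conditions, so the whole analysis runs from scratch with no downloads.

# Track model

The coverage signal is the *unique stack height profile* (USHP): the
per-base pileup of uniquely aligned reads, summarized in 20 bp bins. The
per-bin summary is the **mean** per-base depth (a `max` option exists);
the mean preserves the arithmetic linking bin values to tag counts used
by the filters downstream.

Processing order is **mask &rarr; interpolate &rarr; smooth &rarr;
RPM-normalize &rarr; input-blacklist**:

* *Mappability masking.* Bins with alignability below 0.5 (on a [0,1]
  uniqueness score) **and** no coverage are flagged masked: they are
  artifactual gaps, not true signal deserts. Bins with signal are never
  masked regardless of score.
* *Interpolation.* A masked bin flanked within 3 bins on each side by
  valid bins receives the mean of the nearest valid upstream and
  downstream values, provided the stronger flank is at least 2&times;
  the genome-wide mean — the gap interrupts an enriched region.
  Isolated masked deserts stay masked. Both the scan distance and the
  enrichment floor are configurable.
* *Smoothing.* Each usable bin becomes the moving average of the 60 bp
  window centered on it (the bin and its two neighbors). Chromosome
  ends average the available neighbors only; zero-padding would
  manufacture artificial edge slopes.
* *RPM normalization.* Values are scaled by `1e6 / library_size` so
  tracks of different depth are comparable.
* *Input blacklisting.* Bins where the RPM-normalized input (no-ChIP)
  track exceeds 10&times; its genome-wide mean are excluded from
  detection. "Subtraction" of such regions is implemented as removal
  rather than arithmetic differencing, because the purpose is to remove
  false-positive peaks, not to adjust signal levels.

The slope score of bin *i* is `(USHP[i+3] − USHP[i−3]) / 100`: the
difference between the smoothed values 60 bp downstream and 60 bp
upstream, divided by 100 bp. The literal divisor 100 is retained even
though the two bin centers are 120 bp apart; it is a constant of the
published score and only rescales the (free) slope threshold. Slopes are
undefined within 3 bins of a chromosome end and wherever the 7-bin
window touches a masked or blacklisted bin.

## On read deduplication

`dedup_reads()` collapses identical (chromosome, start, strand) stacks
and is available as an option (`bin_coverage(dedup = TRUE)`) for raw
aligned data that still carries PCR duplicates. It is **off by
default**: the generator emits already-unique reads (it simulates no
duplication process), and at desk-scale depths (30&times; background)
collapsing coincidental collisions saturates the profile at two reads
per base-strand, capping the attainable summit/background ratio below
the detector's 3.5-fold local-background threshold — a regime
genome-scale libraries never approach.

# Feature detection

RNAPII features are intervals spanning a maximal run of positive slopes
paired with the nearest downstream maximal run of negative slopes, with
at most 400 bp between the rising run's 3&prime; end and the falling
run's 5&prime; start. Each falling run is consumed at most once; when
two rising runs compete, the smaller gap wins (ties to the earlier run).

**Slope threshold.** The publication never states its threshold, so it
is a free parameter. The default is automatic per track:
0.5 &times; (genome-wide mean USHP) / 100 — i.e. a rise of half the mean
signal across the slope window. This was calibrated once on the packaged
synthetic dataset (it sits several noise standard deviations above flat
background at 30&times; coverage while sensitive to 8-fold peaks) and is
deliberately scale-free: doubling a library leaves calls unchanged.

**Multiplet merging.** Adjacent features are merged when the
peak-to-trough ratio falls below 2.5, so a poorly resolved multiplet is
treated as a single feature. The ratio is defined as
`min(max_left, max_right) / trough`, the trough being the minimum
smoothed USHP strictly between the two summits — the conservative
choice: merging happens only when the *weaker* peak fails to separate
from the valley. A zero trough yields an infinite ratio (no merge);
summits in adjacent bins are unresolved by construction and merge.
Merging runs left-to-right to a fixpoint and applies only to features
whose facing edges are within 400 bp (`merge_max_gap`): an unresolved
multiplet's peaklets essentially abut, and without a proximity bound the
ratio rule chains a strong peak to weak bumps tens of kb away (observed
on synthetic data as 38 kb merged monsters).

**Local background filter.** Features whose centers lie within 2 kb are
chained into a domain; the domain is expanded by &plusmn;1 kb;
the background is the mean USHP of domain bins not covered by any
feature (valid and interpolated bins only). A feature passes iff its
maximum is &ge; 3.5&times; that mean — inclusive, since the rule
describes which features are *used*. A domain with no background bins
accepts its features with a logged warning.

**Signal threshold.** A feature passes iff it has &ge; 20 tags or a tag
density &ge; 14.5 tags/bp, applied to raw counts. A density of 14.5
tags/bp is implausibly high for real libraries — almost certainly a
units artifact in the original description (per 100 bp would be
plausible) — so it is implemented as printed but exposed in
`detection_config()`.

Per-condition accepted features are coordinate-merged into a union set
with per-track provenance, so a peak called in several tracks is one
union feature.

# Differential occupancy and stage groups

For every union feature, tag counts are taken in all four condition
tracks (LD, LD+DMI, HD, HD+DMI) and scaled to a common library size.
Each of the six pairwise comparisons gets one attribute with a
pseudocount guard (default 1 normalized tag): *up* if
`(b+pc)/(a+pc) >= 2`, *down* if `<= 0.5`, else *nc*.

The original analysis reduced the 3^6 attribute combinations to 19
clusters in three functional categories plus an ambiguous remainder; the
exact reduction table is not published. The package therefore uses a
documented two-level scheme: a mapping on the two informative
comparisons assigns each feature to a stage group —

| group | rule |
|---|---|
| DMI_induced | up in HD vs HD+DMI (checked first) |
| HD_primed | up in LD vs HD, without DMI induction |
| uncommitted | down in LD vs HD, without DMI induction |
| ambiguous | everything else (incl. constitutive features) |

— and k-means (k-means++ seeding under a fixed seed, Lloyd iterations,
300-iteration cap; default total k = 19, allocated across groups by
size) orders features within groups for heat maps. Heatmap entries are
`log2((count + pc) / (row mean + pc))`, the fold change of each
condition against the feature's four-track mean.

# Motif windows and screening

Motif mining uses a window centered on the bins scoring in the top 25th
percentile of USHP within each feature (nearest-rank percentile,
inclusive). Spans shorter than 400 bp expand symmetrically about the
span midpoint to 400 bp (clipped at chromosome ends); spans longer than
600 bp exclude the feature. Windows overlapping across condition tracks
merge into single intervals.

Screening is consensus-string matching of IUPAC patterns on both strands
(assumed, as the original does not state strandedness; configurable).
`N` in the *genome* never matches a concrete pattern letter. A
palindromic hit whose two strand matches coincide is reported once —
frequencies count regions, not hits, so this is presentation only.
Regions containing both motifs count toward both frequencies.

A screening caveat worth stating: the canonical `TTGCNNAA` consensus has
only six informative positions, so by the closed-form background rate
roughly a fifth of 400–600 bp windows contain a chance hit; observed
canonical frequencies ride on that baseline. The hybrid `TTKCATCA`
(7.5 informative positions) has a ~3% per-window background, which is
why planted hybrid frequencies are recoverable within exact binomial
confidence intervals while canonical frequencies are tested against the
expected screen-positive rate (planted &cup; background).

# Co-occupancy enrichment, density matrices, IVC

Cluster-level co-occupancy uses the upper-tail hypergeometric
probability `p = Σ_{i≥k} C(K,i)C(N−K,n−i)/C(N,n)`, accumulated in log
space, comparing a cluster's overlap count against the genome-wide rate;
no multiple-testing correction by default (matching how raw
hypergeometric thresholds are reported), Benjamini–Hochberg on request.
Summit co-localization between peak sets uses a 200 bp summit-to-summit
window by default — a documented package default, not a claim about the
original analysis, which never states its overlap distance (the visual
4 kb window belongs to density heat maps, which `density_matrix()`
samples as anchors &times; 20 bp bins across &plusmn;2 kb, rows kept in
caller order, optional saturation cap).

IVC titrations are analyzed with the published RPM thresholds: a site is
*detected* at &ge; 1 RPM, *co-bound* if &ge; 0.5 RPM at every
concentration, and *gained* if below the detection threshold at all
lower concentrations but detected at the top — the narrative "gained"
category made precise. `rank_extremes()` returns the strongest- and
weakest-1000 sites with coordinate tie-breaks for determinism.

# The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes,
with full ground truth:

* **Genome**: i.i.d. bases at GC 0.41 (human-like) with concrete motif
  instances planted verbatim at recorded positions and strands.
* **Features**: 60 features, 600 bp wide, on two 500 kb chromosomes,
  placed on a jittered grid (&ge; ~10 kb spacing), 15 per stage pattern
  with summit multipliers (LD, LD+DMI, HD, HD+DMI): uncommitted
  (8,8,1,1), HD-primed (1,1,8,8), DMI-induced (1,1,1,8), ambiguous
  (8,8,8,8) (constitutive). Hybrid motifs are planted in 27% / 7% / 4%
  of HD-primed / uncommitted / DMI-induced features and canonical motifs
  in 8% / 13% / 23%, echoing the biology the screen should recover.
* **Reads**: Poisson background (negative binomial with dispersion 0.3
  available) at 30&times; coverage of 36 bp reads per condition; peak
  reads with triangular positional density (rectangular and bimodal
  shapes available for stress-testing the merge rule). A multiplier *m*
  adds `(m−1)·rate·width/2` expected reads, making the expected summit
  pileup exactly *m*-fold background and the expected feature tag count
  `rate·width·(1+(m−1)/2)`; the expected attribute vector from these
  counts reproduces the planted stage label exactly, with no sampling.
* **Mappability**: score 1 everywhere except planted 3-bin gaps at 0;
  reads overlapping a gap are dropped (unalignable), so gap bins carry
  exactly zero coverage.
* **Input**: uniform background plus rectangular 50&times; artifact
  regions whose reads stay inside the region, so the blacklisted bins
  equal the planted truth exactly.
* **IVC**: expected site strength `depth · c/(c + Kd)` — a simple
  occupancy law used purely as a test device, not a claim that the
  assay fits this model. Sampled counts are Poisson but *coupled* across
  concentrations by binomial thinning from the top concentration, so
  each site's counts are non-decreasing in concentration, as in a
  titration of one library.

Everything is a pure function of (parameters, seed) under the
Mersenne-Twister generator; repeated runs are byte-identical.

What the generator does **not** emulate: PCR duplicates and sequencing
error, fragment-size distributions and strand-shifted read pairs,
copy-number and chromatin-accessibility structure in the background,
correlated replicates, and motif instances outside planted sites beyond
i.i.d. chance. Passing tests therefore demonstrate the *procedures*
are implemented correctly and recover planted structure under idealized
noise — not that the thresholds are optimal for any particular real
library.

# Problem sizes and numerical choices

The packaged study conditions are two 500 kb chromosomes at 30&times;
coverage (~0.9 M reads per track), chosen so the full workflow runs in
tens of seconds; the background false-discovery analysis uses 1 Mb
single-chromosome simulations across 20 seeds; clustering recovery uses
200 features at log2 noise &sigma; = 0.2; the motif background check
uses 100 kb of uniform DNA where the expected hybrid hit count has the
closed form `2(L−7)(1/4)^7(1/2)`.

Other numerics: percentiles use the nearest-rank method; k-means uses a
relative tolerance via a 300-iteration Lloyd cap with k-means++ seeding
(duplicate seeds are re-drawn); the hypergeometric tail is accumulated
with a log-sum-exp; ties in `rank_extremes` and run pairing break by
coordinate; zero-trough ratios are infinite; an empty stage group is
reported as not applicable rather than zero.

# Known limitations

* The slope-threshold monotonicity one might expect ("higher threshold,
  never more features") is not strict in pathological cases: shrinking
  runs can release a falling run previously consumed by a competing
  rising run and create a new pairing. The enrichment-fold filter is
  strictly monotone.
* Features wider than ~600 bp with top-quartile spans beyond 600 bp are
  excluded from motif mining by design (as published); on data with
  broad domains this discards real elements.
* The stage-group mapping is a faithful *stand-in* for an unpublished
  19-cluster reduction; cluster-level results should be read at the
  group level, and the ambiguous group absorbs what the original
  flagged as clusters 17–19.
* Attribute calls use a pseudocount of 1 normalized tag; for very
  shallow libraries the two-fold rule near zero counts is
  pseudocount-dominated, as any such rule must be.

# A worked run

```{r, eval = FALSE}
ds  <- synthetic_mini_dataset(seed = 1)
det <- detect(ds$reads, ds$layout, detection_config(),
              mappability = ds$mappability, input_reads = ds$input)
cm  <- count_feature_tags(det$union, ds$reads)
cl  <- cluster_features(cm, k = 19, seed = 1)
table(cl$stage)
```

The numbered scripts under `analysis/` run the same stages as a
narrative workflow and write their tables under `results/`;
`scripts/acceptance.R` recomputes the headline quantities from scratch
into a single JSON file.
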