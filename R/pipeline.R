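#' Pipeline configuration
#'
#' One structured object holding every tunable constant of the workflow,
#' round-trippable through YAML. Defaults are the published constants of
#' the procedure (20 bp bins, 400 bp pairing, merge ratio 2.5, 2 kb /
#' +/-1 kb background domains, 3.5-fold enrichment, >=20 tags or 14.5
#' tags/bp, 2-fold attributes, 400-600 bp motif windows, 200 bp overlap
#' window, 1.0 / 0.5 RPM titration thresholds, top/bottom 1000 sites).
#'
#' @param bin_size track bin size (bp).
#' @param mappability_threshold,interp_scan,interp_fold,input_fold track
#'   processing constants (see the tracks functions).
#' @param slope_threshold,slope_threshold_frac,pairing_max_gap,merge_ratio,neighbor_cluster_gap,background_flank,enrichment_fold,min_tags,min_density
#'   detection constants (see [detection_config()]).
#' @param k,cluster_seed,pseudocount,fold clustering constants.
#' @param motif_hybrid,motif_canonical IUPAC patterns screened.
#' @param window_min,window_max motif window size limits (bp).
#' @param overlap_window summit co-localization distance (bp).
#' @param ivc_detect,ivc_cobound titration thresholds (RPM).
#' @param rank_n size of the strongest/weakest site subsets.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(bin_size = 20,
                            mappability_threshold = 0.5,
                            interp_scan = 3, interp_fold = 2,
                            input_fold = 10,
                            slope_threshold = NA, slope_threshold_frac = 0.5,
                            pairing_max_gap = 400, merge_ratio = 2.5,
                            merge_max_gap = 400,
                            neighbor_cluster_gap = 2000,
                            background_flank = 1000, enrichment_fold = 3.5,
                            min_tags = 20, min_density = 14.5,
                            k = 19, cluster_seed = 1, pseudocount = 1,
                            fold = 2,
                            motif_hybrid = "TTKCATCA",
                            motif_canonical = "TTGCNNAA",
                            window_min = 400, window_max = 600,
                            overlap_window = 200,
                            ivc_detect = 1.0, ivc_cobound = 0.5,
                            rank_n = 1000) {
  cfg <- as.list(environment())
  num <- !names(cfg) %in% c("motif_hybrid", "motif_canonical")
  cfg[num] <- lapply(cfg[num], as.numeric)
  structure(cfg, class = "PipelineConfig")
}

#' Write a pipeline config as YAML
#' @param config a `PipelineConfig`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline config from YAML (unknown keys rejected)
#' @param path YAML path.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, x)
}

detection_from_config <- function(config) {
  detection_config(
    slope_threshold = config$slope_threshold,
    slope_threshold_frac = config$slope_threshold_frac,
    pairing_max_gap = config$pairing_max_gap,
    merge_ratio = config$merge_ratio,
    merge_max_gap = config$merge_max_gap,
    neighbor_cluster_gap = config$neighbor_cluster_gap,
    background_flank = config$background_flank,
    enrichment_fold = config$enrichment_fold,
    min_tags = config$min_tags, min_density = config$min_density)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Executes tracks -> detect -> cluster -> motifs -> cooccupancy (and the
#' IVC titration analysis) on a dataset from [synthetic_mini_dataset()],
#' writes every stage's tables under `outdir`, and records a manifest
#' with parameter values, seed and per-file MD5 checksums.
#'
#' @param dataset a dataset list from [synthetic_mini_dataset()].
#' @param outdir output directory (created if needed).
#' @param config a `PipelineConfig`.
#' @param write_tracks also export processed tracks as bedGraph.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(dataset, outdir, config = pipeline_config(),
                         write_tracks = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(name) { f <- file.path(outdir, name); files <<- c(files, f); f }
  dcfg <- detection_from_config(config)

  det <- run_stage("detect", detect(
    dataset$reads, dataset$layout, dcfg,
    mappability = dataset$mappability, input_reads = dataset$input))
  for (cond in names(det$per_condition))
    write_features(det$per_condition[[cond]],
                   put(sprintf("features_%s.tsv", cond)))
  utils::write.table(det$union, put("union_features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (write_tracks)
    for (cond in names(det$tracks))
      write_bedgraph(det$tracks[[cond]], put(sprintf("track_%s.bedGraph", cond)))

  cl <- run_stage("cluster", {
    cm <- count_feature_tags(det$union, dataset$reads,
                             pseudocount = config$pseudocount)
    cluster_features(cm, k = as.integer(config$k),
                     seed = as.integer(config$cluster_seed),
                     fold = config$fold)
  })
  utils::write.table(
    data.frame(id = det$union$id, stage = cl$stage, cluster = cl$labels,
               cl$attributes, check.names = FALSE),
    put("clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_cdt(cl$heatmap, put("heatmap.cdt"))

  mot <- run_stage("motifs", {
    windows <- list()
    for (cond in names(det$per_condition)) {
      w <- select_windows(det$per_condition[[cond]], det$tracks[[cond]],
                          config$window_min, config$window_max)
      if (nrow(w)) windows[[cond]] <- w
    }
    windows <- merge_windows(do.call(rbind, windows))
    # group windows by the stage of the union feature they overlap
    wgr <- GenomicRanges::GRanges(windows$chrom,
                                  IRanges::IRanges(windows$start + 1, windows$end))
    ugr <- GenomicRanges::GRanges(det$union$chrom,
                                  IRanges::IRanges(det$union$start + 1, det$union$end))
    ov <- GenomicRanges::findOverlaps(wgr, ugr, select = "first")
    windows$group <- ifelse(is.na(ov), "ambiguous", unname(cl$stage[ov]))
    freq_h <- cluster_motif_frequency(windows, dataset$genome,
                                      config$motif_hybrid)
    freq_c <- cluster_motif_frequency(windows, dataset$genome,
                                      config$motif_canonical)
    freq_h$pattern <- "hybrid"; freq_c$pattern <- "canonical"
    hits <- scan_windows(windows, dataset$genome, config$motif_hybrid)
    list(windows = windows, freq = rbind(freq_h, freq_c), hits = hits)
  })
  utils::write.table(mot$windows, put("motif_windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mot$freq, put("motif_frequencies.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mot$hits, put("hybrid_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  coo <- run_stage("cooccupancy", {
    seqs <- window_sequences(mot$windows, dataset$genome)
    has_hybrid <- vapply(seqs, function(s)
      nrow(scan_motif(s, config$motif_hybrid)) > 0, logical(1),
      USE.NAMES = FALSE)
    enr <- cluster_cooccupancy_enrichment(mot$windows$group, has_hybrid)
    dm <- density_matrix(det$union, det$tracks$HD,
                         flank = 2000, bin = dataset$layout$bin_size)
    list(enrichment = enr, density = dm)
  })
  utils::write.table(coo$enrichment, put("cooccupancy_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(round(coo$density$matrix, 4), put("density_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = TRUE,
                     col.names = NA)

  ivc <- run_stage("ivc", titration_analysis(dataset$ivc$series))
  utils::write.table(
    data.frame(kd = dataset$ivc$truth$kd, class = ivc$classification),
    put("ivc_classification.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(concentration = dataset$ivc$series$concentrations,
               detected = ivc$counts_detected),
    put("ivc_counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "poliiscan",
    version = as.character(utils::packageVersion("poliiscan")),
    seed = dataset$seed,
    parameters = unclass(config),
    stages = c("tracks", "detect", "cluster", "motifs", "cooccupancy"),
    n_union_features = nrow(det$union),
    files = lapply(stats::setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, detect = det, cluster = cl,
                 motifs = mot, cooccupancy = coo, ivc = ivc))
}
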