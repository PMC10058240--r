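#' Generate the full synthetic data bundle for a scenario
#'
#' Runs the synthetic generators in order -- genomes and annotations for
#' both species, motif planting, DNase cut profiles (species A) and the
#' two-species expression experiment -- and returns every artefact with
#' its ground truth.
#'
#' @param scenario A [synthetic_scenario()].
#' @param dnase Simulate cut profiles (set `FALSE` to skip the DNase arm
#'   for expression-only work).
#' @return List with `scenario`, `genome_a`, `genome_b`, `annotation_a`,
#'   `annotation_b`, `pwms`, `group_map`, `truth_a`, `truth_b`,
#'   `profiles`, `control`, `expr_a`, `expr_b`, `ortholog_map`,
#'   `expr_truth`.
#' @export
generate_scenario_data <- function(scenario, dnase = TRUE) {
  ga <- generate_genome_and_annotation(scenario, "A")
  gb <- generate_genome_and_annotation(scenario, "B")
  la <- generate_motif_landscape(scenario, ga$genome, ga$annotation, ga$truth)
  lb <- generate_motif_landscape(scenario, gb$genome, gb$annotation, gb$truth)
  cuts <- if (dnase) simulate_cut_profiles(scenario, la$genome, la$truth) else
    list(profiles = NULL, control = NULL)
  ex <- simulate_expression(scenario, ga$annotation, gb$annotation)
  list(scenario = scenario,
       genome_a = la$genome, genome_b = lb$genome,
       annotation_a = ga$annotation, annotation_b = gb$annotation,
       pwms = la$pwms, group_map = la$group_map,
       truth_a = la$truth, truth_b = lb$truth,
       profiles = cuts$profiles, control = cuts$control,
       expr_a = ex$expr_a, expr_b = ex$expr_b,
       ortholog_map = ex$ortholog_map, expr_truth = ex$truth)
}

#' Run the full de-etiolation cistrome analysis on a synthetic scenario
#'
#' Executes the analysis stages in order: simulate, peak calling per time
#' point, DHS set classification, hexamer bias estimation, footprint
#' detection, FLR computation and filtering, footprint extension, motif
#' scanning, enrichment and binding trajectories, expression
#' normalisation and DE calling, and the cross-species induction
#' comparison.  Intermediates and a machine-readable report are written
#' under `outdir` when given.
#'
#' @param scenario A [synthetic_scenario()] (its seed drives every
#'   stage).
#' @param outdir Output directory (`NULL` to skip persisting files).
#' @param detect_time Time point (label) whose profile is footprinted
#'   (default the dark sample, where constitutively bound factors are
#'   occupied).
#' @param p_threshold Motif-scan p-value threshold.
#' @return The report: a nested list of per-stage summaries (also
#'   written as `report.json` when `outdir` is given).
#' @export
run_pipeline <- function(scenario, outdir = NULL, detect_time = NULL,
                        p_threshold = 1e-4) {
  data <- generate_scenario_data(scenario)
  .assert(!is.null(data$control), "pipeline requires the deproteinated control profile")
  tp <- scenario$time_points
  report <- list(schema = "etiofoot-report/1", seed = scenario$seed)

  # --- peaks and DHS sets -------------------------------------------------
  peaks <- lapply(data$profiles, call_peaks)
  sets <- classify_dhs_sets(peaks)
  spot <- vapply(names(peaks), function(t) spot_score(data$profiles[[t]], peaks[[t]]),
                 numeric(1))
  report$accessibility <- list(
    n_peaks = vapply(peaks, length, integer(1)),
    spot_scores = spot,
    n_hyperconserved = length(sets$hyperconserved),
    n_light_specific = length(sets$light_specific))

  # --- bias and footprints ------------------------------------------------
  bias <- estimate_hexamer_bias(data$control, data$genome_a)
  if (is.null(detect_time)) detect_time <- as.character(min(tp))
  fps_by_time <- lapply(names(data$profiles), function(t) {
    fp <- detect_footprints(data$profiles[[t]], sets$hyperconserved)
    if (length(fp) >= 20) {
      footprint_flr(fp, data$profiles[[t]], bias, data$genome_a)$footprints
    } else fp
  })
  names(fps_by_time) <- names(data$profiles)
  filt <- lapply(fps_by_time, function(fp) {
    if (length(fp) && !is.null(fp$flr)) filter_footprints(fp) else
      list(retained = fp, report = data.frame())
  })
  report$footprints <- list(
    n_detected = vapply(fps_by_time, length, integer(1)),
    n_retained = vapply(filt, function(f) length(f$retained), integer(1)),
    flr_reduction = vapply(filt, function(f)
      if (nrow(f$report)) f$report$reduction[1] else NA_real_, numeric(1)))

  # --- motif scanning of extended footprints ------------------------------
  scanned <- lapply(filt, function(f) {
    ext <- extend_footprints(f$retained, 4L)
    if (!length(ext)) return(data.frame())
    h <- scan_genome(data$pwms, data$genome_a, ext, p_threshold = p_threshold)
    if (nrow(h)) assign_groups(h, data$group_map) else h
  })

  # --- enrichment against the hyperconserved background -------------------
  loci <- gene_locus_windows(data$annotation_a)
  bg_regions <- GenomicRanges::intersect(sets$hyperconserved,
                                         GenomicRanges::reduce(loci, ignore.strand = TRUE))
  bg_hits <- scan_genome(data$pwms, data$genome_a, bg_regions, p_threshold = p_threshold)
  enr <- NULL
  if (nrow(bg_hits)) {
    bg_hits <- assign_groups(bg_hits, data$group_map)
    background <- background_frequencies(bg_hits, data$group_map)
    q_hits <- scanned[[detect_time]]
    if (is.data.frame(q_hits) && nrow(q_hits)) {
      enr <- enrichment_log_ratio(q_hits, background)
    }
  }
  report["enrichment"] <- list(if (is.null(enr)) NULL else
    list(groups = enr$group, log_ratio = enr$log_ratio))

  # --- binding trajectories -----------------------------------------------
  nonempty <- vapply(scanned, function(h) is.data.frame(h) && nrow(h) > 0, logical(1))
  traj_cor <- NULL
  if (sum(nonempty) == length(tp)) {
    props <- dgf_motif_proportions(scanned)
    centered <- mean_center_trajectories(props)
    # a scenario with purely constitutive binding has no trajectory
    # variance; leave the stage empty rather than reporting NA correlations
    if (nrow(centered) >= 3 && stats::sd(centered[, 1]) > 0) {
      traj_cor <- dark_light_correlation(centered)
    }
  }
  report["trajectories"] <- list(if (is.null(traj_cor)) NULL else as.list(traj_cor))

  # --- TSS profiles and locus fold change ---------------------------------
  light_lr <- tss_profile(data$profiles[[which.min(abs(tp - 2))]],
                          data$annotation_a, mode = "logratio",
                          profile_b = data$profiles[[1]])
  up <- light_lr$offsets >= -500 & light_lr$offsets < 0
  far <- light_lr$offsets >= 500 & light_lr$offsets <= 2000
  lfc <- locus_fold_change(data$profiles[[length(tp)]], data$profiles[[1]],
                           sets$hyperconserved)
  report$tss <- list(upstream_mean_log2 = mean(light_lr$values[up]),
                     distal_mean_log2 = mean(light_lr$values[far]),
                     median_locus_fold_change = stats::median(lfc$fold_change))

  # --- expression ---------------------------------------------------------
  norm_a <- sample_mean_scale(quantile_normalize(data$expr_a))
  norm_b <- sample_mean_scale(quantile_normalize(data$expr_b))
  de <- detect_de_genes(data$expr_a, contrast = tp[1:2])
  c4_ogs <- data$expr_truth$orthogroup[data$expr_truth$class == "c4"]
  cmp <- induction_comparison(norm_a, norm_b, data$ortholog_map, gene_set = c4_ogs)
  report$expression <- list(
    n_tested = nrow(de), n_robust = sum(de$robust),
    n_method_a = sum(de$call_a), n_method_b = sum(de$call_b),
    c4_mean_contrast = mean(cmp$contrast[!cmp$missing]))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (t in names(peaks)) write_peaks_bed(peaks[[t]], file.path(outdir, sprintf("peaks_t%s.bed", t)))
    write_peaks_bed(sets$hyperconserved, file.path(outdir, "dhs_hyperconserved.bed"))
    write_peaks_bed(sets$light_specific, file.path(outdir, "dhs_light_specific.bed"))
    fp0 <- filt[[detect_time]]$retained
    if (length(fp0)) write_footprints_bed(fp0, file.path(outdir, "footprints_retained.bed"))
    if (!is.null(enr)) {
      utils::write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    utils::write.table(de, file.path(outdir, "de_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cmp, file.path(outdir, "species_contrast.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_report(report, file.path(outdir, "report.json"))
  }
  report
}

#' Write a pipeline report as schema-versioned JSON
#'
#' @param report Nested list of per-stage summaries (missing stages may
#'   be `NULL`; their keys are preserved).
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  .assert(length(report) > 0, "nothing to report")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
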