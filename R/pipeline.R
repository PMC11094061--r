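# End-to-end orchestration: simulate -> quantify -> call -> classify ->
# motifs -> enrich, with reproducible seeds and a machine-readable manifest.

#' Pipeline run configuration
#'
#' Collects every analysis threshold next to the simulation configuration
#' so each cutoff appearing in an output file is traceable to one object
#' (serialized into every stage output's header).
#'
#' @param sim a [sim_config()] describing the synthetic input (the pipeline
#'   currently drives the simulator; real data enters through the module
#'   functions directly).
#' @param dpdui_threshold,alpha,nonchange_band event-calling thresholds
#'   (see [adjust_and_call()]).
#' @param ratio_floor,ratio_threshold CD28 ratio parameters (see
#'   [cd28_ratio()]).
#' @param pdui_long_cut,pdui_short_cut basal PDUI bin boundaries.
#' @param pas_flank upstream extent (nt) for PAS signal scanning.
#' @param motif,motif_exclude target / excluded motif for positional maps.
#' @param motif_window,motif_smooth sliding-window and running-mean widths.
#' @param motif_span offset span of the positional map.
#' @param test_method `"fisher"` or `"t"` (see [test_event()]).
#' @param search_min,min_mean_depth,min_fit_gain fit guards (see
#'   [fit_two_segment()]).
#' @param stages character vector of stages to run, in dependency order.
#' @return An `apa_run_config` list.
#' @export
apa_run_config <- function(sim = sim_config(),
                           dpdui_threshold = 20, alpha = 0.05,
                           nonchange_band = 3,
                           ratio_floor = 1, ratio_threshold = 2,
                           pdui_long_cut = 66, pdui_short_cut = 33,
                           pas_flank = 100,
                           motif = "AAUAUA", motif_exclude = "AAUAAA",
                           motif_window = 10, motif_smooth = 5,
                           motif_span = c(-100, 100),
                           test_method = c("fisher", "t"),
                           search_min = 100, min_mean_depth = 1,
                           min_fit_gain = 0.05,
                           stages = c("simulate", "quantify", "call",
                                      "classify", "motifs", "enrich")) {
  test_method <- match.arg(test_method)
  stopifnot(inherits(sim, "sim_config"))
  for (v in c(dpdui_threshold, alpha, nonchange_band, ratio_floor,
              ratio_threshold, pdui_long_cut, pdui_short_cut, pas_flank,
              motif_window, motif_smooth)) {
    stop_if(!is.numeric(v) || v <= 0, "thresholds must be positive numbers")
  }
  structure(list(sim = sim, dpdui_threshold = dpdui_threshold, alpha = alpha,
                 nonchange_band = nonchange_band, ratio_floor = ratio_floor,
                 ratio_threshold = ratio_threshold,
                 pdui_long_cut = pdui_long_cut,
                 pdui_short_cut = pdui_short_cut,
                 pas_flank = pas_flank, motif = motif,
                 motif_exclude = motif_exclude,
                 motif_window = motif_window, motif_smooth = motif_smooth,
                 motif_span = motif_span, test_method = test_method,
                 search_min = search_min, min_mean_depth = min_mean_depth,
                 min_fit_gain = min_fit_gain, stages = stages),
            class = "apa_run_config")
}

# Header metadata for one stage's outputs: the seed, package version and
# only the parameters that stage consumes, so an upstream output is
# byte-stable under changes to downstream-only thresholds.
stage_meta <- function(config, keys) {
  c(list(seed = config$sim$seed,
         apashift_version = as.character(packageVersion("apashift"))),
    config[keys])
}

#' Run the full synthetic APA analysis pipeline
#'
#' Executes the stages in dependency order inside `outdir`: simulation
#' (truth table, BED, FASTA, per-sample bedGraphs, manifest), coverage
#' loading and RPM normalization through the file-based path, joint
#' two-segment fitting, event testing and calling for every stimulated
#' condition against the reference, classification (direction counts, basal
#' bins, temporal classes, CD28 ratios, cross-condition correlations),
#' motif analysis (PAS strength and positional maps per event group), and
#' overlap enrichment of the shortened gene sets. Every stage output is a
#' TSV with a `#`-commented header carrying the seed, package version and
#' the thresholds that stage consumed; `run_manifest.json` records the full
#' configuration hash and lists all outputs with md5 checksums.
#'
#' @param config an [apa_run_config()].
#' @param outdir run directory (created; stage outputs land in
#'   subdirectories).
#' @param gene_sets optional named list of gene-id vectors used as
#'   annotation sets for enrichment; by default the simulator's
#'   RBM3-regulated truth set is used.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_apa_pipeline <- function(config = apa_run_config(), outdir,
                             gene_sets = NULL) {
  stopifnot(inherits(config, "apa_run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim_dir <- file.path(outdir, "sim")
  stages <- config$stages

  config_path <- file.path(outdir, "config.yaml")
  cfg_list <- config
  class(cfg_list) <- NULL
  cfg_list$sim <- unclass(cfg_list$sim)
  yaml::write_yaml(cfg_list, config_path)
  config_md5 <- unname(tools::md5sum(config_path))
  fit_meta <- stage_meta(config, c("search_min", "min_mean_depth",
                                   "min_fit_gain"))
  call_meta <- stage_meta(config, c("dpdui_threshold", "alpha",
                                    "nonchange_band", "test_method"))
  classify_meta <- stage_meta(config, c("dpdui_threshold", "alpha",
                                        "nonchange_band", "ratio_floor",
                                        "ratio_threshold", "pdui_long_cut",
                                        "pdui_short_cut"))
  motif_meta <- stage_meta(config, c("pas_flank", "motif", "motif_exclude",
                                     "motif_window", "motif_smooth"))
  enrich_meta <- stage_meta(config, c("alpha"))
  outputs <- config_path
  results <- list(config = config)

  need <- function(stage, what) {
    stop_if(is.null(results[[what]]),
            "stage '", stage, "' requires upstream stage output '", what,
            "' which was not produced")
  }

  if ("simulate" %in% stages) {
    truth <- generate_truth(config$sim)
    ann <- write_annotation_and_sequence(truth, sim_dir)
    simulate_coverage(truth, outdir = sim_dir)
    truth_path <- file.path(sim_dir, "truth.tsv")
    write_truth_table(truth, truth_path)
    results$truth <- truth
    results$annotation <- ann
    outputs <- c(outputs, ann$bed, ann$fasta, truth_path,
                 file.path(sim_dir, "samples.tsv"))
  }

  if ("quantify" %in% stages) {
    need("quantify", "truth")
    anno <- read_utr_bed(results$annotation$bed)
    cov <- load_coverage_set(file.path(sim_dir, "samples.tsv"), anno)
    fits <- fit_all_genes(cov, search_min = config$search_min,
                          min_mean_depth = config$min_mean_depth,
                          min_fit_gain = config$min_fit_gain)
    fits_path <- file.path(outdir, "fits.tsv")
    write_tsv_header(fits_table(fits), fits_path, fit_meta)
    # browser-style averaged track for the reference condition
    avg_path <- file.path(outdir,
                          paste0(config$sim$conditions[1], "_mean.bedGraph"))
    write_condition_bedgraph(cov, config$sim$conditions[1], avg_path)
    results$annotations <- anno
    results$coverage <- cov
    results$fits <- fits
    outputs <- c(outputs, fits_path, avg_path)
  }

  conds <- config$sim$conditions
  ref <- conds[1]
  stim_conds <- conds[-1]

  if ("call" %in% stages) {
    need("call", "fits")
    events <- list()
    for (stim in stim_conds) {
      ev <- call_apa_events(results$fits, ref, stim,
                            method = config$test_method)
      ev <- adjust_and_call(ev, dpdui_threshold = config$dpdui_threshold,
                            alpha = config$alpha,
                            nonchange_band = config$nonchange_band)
      path <- file.path(outdir, paste0("events_", stim, ".tsv"))
      write_tsv_header(ev, path, call_meta)
      events[[stim]] <- ev
      outputs <- c(outputs, path)
    }
    results$events <- events
  }

  if ("classify" %in% stages) {
    need("classify", "events")
    events <- results$events
    tab <- event_comparison_table(events)
    summary_rows <- list()
    for (stim in names(events)) {
      d <- direction_summary(events[[stim]])
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        metric = paste0("direction_", names(d)), comparison = stim,
        value = as.numeric(d))
    }
    bins <- table(basal_pdui_bin(tab$basal_pdui,
                                 short_cut = config$pdui_short_cut,
                                 long_cut = config$pdui_long_cut))
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      metric = paste0("basal_bin_", names(bins)), comparison = "all",
      value = as.numeric(bins))

    temporal <- list()
    for (stimulus in unique(sub("_(8|48)h$", "", stim_conds))) {
      c8 <- paste0(stimulus, "_8h"); c48 <- paste0(stimulus, "_48h")
      if (all(c(c8, c48) %in% names(events))) {
        cls <- temporal_classify(tab[[paste0("call_", c8)]],
                                 tab[[paste0("call_", c48)]])
        temporal[[stimulus]] <- data.frame(gene_id = tab$gene_id,
                                           stimulus = stimulus,
                                           class = as.character(cls))
        tt <- table(cls)
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          metric = paste0("temporal_", names(tt)), comparison = stimulus,
          value = as.numeric(tt))
      }
    }

    ratios <- list()
    for (tp in c("8h", "48h")) {
      ccd3 <- paste0("CD3_", tp); ccd28 <- paste0("CD3CD28_", tp)
      dc3 <- tab[[paste0("dpdui_", ccd3)]]
      dc28 <- tab[[paste0("dpdui_", ccd28)]]
      if (is.null(dc3) || is.null(dc28)) next
      sig28 <- tab[[paste0("call_", ccd28)]] %in% c("shortened", "lengthened")
      keep <- sig28 & !is.na(dc3) & !is.na(dc28)
      if (!any(keep)) next
      rr <- cd28_ratio(dc28[keep], dc3[keep], floor = config$ratio_floor,
                       threshold = config$ratio_threshold)
      ratios[[tp]] <- cbind(data.frame(gene_id = tab$gene_id[keep],
                                       timepoint = tp), rr)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        metric = "cd28_enhanced_fraction", comparison = tp,
        value = mean(rr$enhanced[!rr$discordant]))
      corr <- condition_correlation(dc3[keep], dc28[keep])
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        metric = c("pearson_r", "regression_slope"), comparison = tp,
        value = c(corr$r, corr$slope))
    }

    summary_df <- do.call(rbind, summary_rows)
    sum_path <- file.path(outdir, "summary.tsv")
    write_tsv_header(summary_df, sum_path, classify_meta)
    class_path <- file.path(outdir, "gene_classes.tsv")
    write_tsv_header(tab, class_path, classify_meta)
    results$comparison_table <- tab
    results$temporal <- temporal
    results$ratios <- ratios
    results$summary <- summary_df
    outputs <- c(outputs, sum_path, class_path)
  }

  if ("motifs" %in% stages) {
    need("motifs", "fits")
    seqs <- Biostrings::readDNAStringSet(results$annotation$fasta)
    sites <- pas_sites(results$fits, results$annotations)
    windows <- suppressWarnings(extract_pas_windows(sites, seqs))
    strength <- pas_strength_summary(windows, flank = config$pas_flank)
    strength_path <- file.path(outdir, "pas_strength.tsv")
    write_tsv_header(strength, strength_path, motif_meta)

    groups <- NULL
    if (!is.null(results$events)) {
      tab <- results$comparison_table %||% event_comparison_table(results$events)
      e8 <- grep("_8h$", names(results$events), value = TRUE)[1]
      e48 <- grep("_48h$", names(results$events), value = TRUE)[1]
      if (!is.na(e8) && !is.na(e48)) {
        cls <- temporal_classify(tab[[paste0("call_", e8)]],
                                 tab[[paste0("call_", e48)]])
        groups <- list(
          shortened_8h = tab$gene_id[tab[[paste0("call_", e8)]] == "shortened"],
          shortened_48h_only = tab$gene_id[cls == "48h_only" &
                                tab[[paste0("call_", e48)]] == "shortened"],
          non_changing = tab$gene_id[tab[[paste0("call_", e8)]] == "non_changing"])
      }
    }
    if (!is.null(groups)) {
      prof <- compare_profiles(windows, groups, motif = config$motif,
                               exclude = config$motif_exclude,
                               window_nt = config$motif_window,
                               smooth_nt = config$motif_smooth,
                               span = config$motif_span)
      prof_path <- file.path(outdir, "motif_profiles.tsv")
      write_tsv_header(prof, prof_path, motif_meta)
      results$profiles <- prof
      outputs <- c(outputs, prof_path)
    }
    results$windows <- windows
    results$pas_strength <- strength
    outputs <- c(outputs, strength_path)
  }

  if ("enrich" %in% stages) {
    need("enrich", "events")
    assessable <- unique(unlist(lapply(results$events, `[[`, "gene_id")))
    queries <- list()
    for (stim in names(results$events)) {
      ev <- results$events[[stim]]
      ids <- ev$gene_id[ev$call == "shortened"]
      if (length(ids)) queries[[paste0("shortened_", stim)]] <- ids
    }
    sets <- gene_sets %||% list(
      rbm3_truth = results$truth$genes$gene_id[results$truth$genes$rbm3_regulated])
    if (length(queries) && length(sets)) {
      enr <- batch_enrichment(queries, sets, assessable,
                              alpha = config$alpha)
      enr_path <- file.path(outdir, "enrichment.tsv")
      write_tsv_header(enr, enr_path, enrich_meta)
      results$enrichment <- enr
      outputs <- c(outputs, enr_path)
    }
  }

  manifest <- list(
    seed = config$sim$seed,
    config_md5 = config_md5,
    apashift_version = as.character(packageVersion("apashift")),
    stages = stages,
    outputs = data.frame(path = outputs,
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
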