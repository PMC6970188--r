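#' Default end-to-end pipeline configuration
#'
#' A flat, fully explicit configuration for [run_pipeline()]: every tunable
#' parameter of the simulate - normalize - call peaks - statistics chain
#' appears here and can be overridden (nested lists are merged key-wise).
#' RPA peaks are called on the log2(RPA/input) enrichment track (the log
#' scale bounds the heavy-tailed hotspot intensities, which makes the
#' z-scored threshold stable across seeds and genome sizes). The thresholds
#' `z_rpa_ctrl` and `z_rpa_mut` were calibrated once against the default
#' fixture and frozen: resection-flank signal covers over half of the
#' genome, so the genome-wide mean sits well above the inter-hotspot
#' background and the background/signal boundary lies below it in z units;
#' the mutant map, with most hotspots suppressed, has a lower baseline and
#' hence its own threshold.
#'
#' @param seed master seed; the generator uses it directly and derived
#'   streams are documented in [sim_config()].
#' @param ... overrides, e.g. `sim = list(n_hotspots = 10)`,
#'   `classify = list(fc_up = 2)`.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42, ...) {
  cfg <- list(
    sim = list(seed = seed),
    peaks = list(z_rpa_ctrl = -0.88, z_rpa_mut = 0, z_k56 = 1.2,
                 min_width_bins = 3, merge_gap_bins = 2),
    normalize = list(pseudocount = 1.0),
    classify = list(fc_up = 1.5, flank_bp = 2000),
    reldist = list(n_perm = 99, seed = seed + 10),
    random_sites = list(n = 1000, seed = seed + 11),
    anchor = list(window_bp = 2000, n_bins = 80, summary = "median"),
    metagene = list(body_bins = 50, flank_bp = 500, flank_bins = 10,
                    summary = "median"),
    expression = list(seed = seed + 12))
  over <- list(...)
  for (k in names(over)) {
    if (is.list(over[[k]]) && is.list(cfg[[k]]))
      cfg[[k]][names(over[[k]])] <- over[[k]]
    else cfg[[k]] <- over[[k]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Differential RPA peak analysis of a control/mutant track pair
#'
#' The control-versus-mutant arm of the pipeline as one call: normalizes
#' each RPA track to input (log2 ratio), calls peaks on the normalized
#' tracks with the per-track calibrated thresholds, and classifies every
#' control peak as eliminated, unaffected or increased using the raw
#' (linear) tracks for the fold-change split.
#'
#' @param tracks named list with `RPA_ctrl`, `RPA_mut` and `input`
#'   [signal_track()]s (e.g. `simulate_fixture()$tracks`).
#' @param config a [pipeline_config()] supplying thresholds,
#'   `classify$fc_up`, `classify$flank_bp` and the pseudocount.
#' @return List with `ctrl_peaks`, `mut_peaks` ([peak_set()]s) and
#'   `classification` ([overlap_classify()] result).
#' @export
classify_rpa_maps <- function(tracks, config = pipeline_config()) {
  pk <- config$peaks
  pc <- config$normalize$pseudocount
  ctrl_norm <- log2_ratio(tracks$RPA_ctrl, tracks$input, pc)
  mut_norm <- log2_ratio(tracks$RPA_mut, tracks$input, pc)
  ctrl_peaks <- call_peaks(ctrl_norm, pk$z_rpa_ctrl, pk$min_width_bins,
                           pk$merge_gap_bins)
  mut_peaks <- call_peaks(mut_norm, pk$z_rpa_mut, pk$min_width_bins,
                          pk$merge_gap_bins)
  cl <- overlap_classify(ctrl_peaks, mut_peaks, tracks$RPA_ctrl,
                         tracks$RPA_mut, fc_up = config$classify$fc_up,
                         flank_bp = config$classify$flank_bp)
  list(ctrl_peaks = ctrl_peaks, mut_peaks = mut_peaks, classification = cl)
}

#' Run the full analysis pipeline on a synthetic fixture
#'
#' Executes, in order: fixture generation; H3K56ac normalization
#' ([double_ratio()] against input and H3 occupancy); peak calling on the
#' normalized H3K56ac track and on both RPA tracks; relative-distance
#' colocalization of H3K56ac peaks against every annotation class with a
#' shuffle null; anchor profiles of H3K56ac and RPA over hotspot midpoints
#' and matched random sites; control-versus-mutant peak classification;
#' locus enrichment (BUD23like versus rDNAlike) and control/mutant fold
#' change at BUD23like; replicate track correlation; and the
#' expression-association test. Writes `results.json`, peak BED files, the
#' classification table and a `run.log` into `out_dir`.
#'
#' @param config a [pipeline_config()] or a path to a YAML file with the
#'   same structure.
#' @param out_dir output directory.
#' @param write_tracks also write the five bedGraph tracks (off by default;
#'   they are reproducible from the manifest).
#' @return The results list, invisibly; `results.json` holds the same
#'   content.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         write_tracks = FALSE) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_("reading YAML configs requires the yaml package")
    config <- do.call(pipeline_config, yaml::yaml.load_file(config))
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", "run", sprintf(fmt, ...))
    cat(msg, "\n", sep = "", file = logf, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    log_line("stage: %s", name)
    tryCatch(expr, error = function(e)
      stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  unlink(logf)
  log_line("meiochip pipeline, package version %s",
           as.character(utils::packageVersion("meiochip")))

  sim_cfg <- do.call(sim_config, config$sim)
  log_line("generator seed %d", sim_cfg$seed)
  sim <- stage("simulate", simulate_fixture(sim_cfg))
  truth <- sim$truth
  genome <- truth$genome
  forbid <- if (n_features(truth$cold_region) > 0) truth$cold_region else NULL

  k56_norm <- stage("normalize", double_ratio(
    sim$tracks$H3K56ac, sim$tracks$input, sim$tracks$H3,
    pseudocount = config$normalize$pseudocount))

  pk <- config$peaks
  k56_peaks <- stage("callpeaks", call_peaks(
    k56_norm, pk$z_k56, pk$min_width_bins, pk$merge_gap_bins))
  # with no planted hotspots the RPA maps are background-only and threshold
  # calling against their own baseline is undefined; report empty peak sets
  rpa_background_only <- nrow(truth$hotspots) == 0L
  if (rpa_background_only) {
    log_line("no hotspots planted: RPA peak calling and classification skipped")
    rpa_ctrl_peaks <- peak_set(genome, data.frame(), label = "peaks")
    rpa_mut_peaks <- peak_set(genome, data.frame(), label = "peaks")
    rpa <- NULL
  } else {
    rpa <- stage("callpeaks", classify_rpa_maps(sim$tracks, config))
    rpa_ctrl_peaks <- rpa$ctrl_peaks
    rpa_mut_peaks <- rpa$mut_peaks
  }
  write_peaks(k56_peaks, file.path(out_dir, "H3K56ac_peaks.bed"))
  write_peaks(rpa_ctrl_peaks, file.path(out_dir, "RPA_ctrl_peaks.bed"))
  write_peaks(rpa_mut_peaks, file.path(out_dir, "RPA_mut_peaks.bed"))

  hs <- truth$hotspots
  hs_fs <- feature_set(genome, if (nrow(hs) == 0) data.frame() else
    data.frame(chrom = hs$chrom, start = hs$mid, end = hs$mid + 1,
               name = hs$name, stringsAsFactors = FALSE), label = "hotspots")

  reldist <- list()
  if (n_features(k56_peaks) > 1) {
    ref_sets <- c(truth$aux, list(hotspots = hs_fs, RPA_ctrl_peaks = rpa_ctrl_peaks,
                                  RPA_mut_peaks = rpa_mut_peaks))
    for (nm in names(ref_sets)) {
      ref <- ref_sets[[nm]]
      if (n_features(ref) < 2) next
      reldist[[nm]] <- stage(paste0("reldist:", nm), {
        en <- empirical_null(k56_peaks, ref, "mean_reldist",
                             n_perm = config$reldist$n_perm,
                             seed = config$reldist$seed, forbidden = forbid)
        obs <- relative_distance(k56_peaks, ref)
        list(mean = obs$mean, median = obs$median, n_used = obs$n_used,
             n_skipped = obs$n_skipped, null_mean = mean(en$null),
             p_left = en$p_left, p_right = en$p_right)
      })
    }
  }

  profiles <- stage("profiles", {
    rnd <- random_sites(genome, max(nrow(hs), 100),
                        seed = config$random_sites$seed, forbidden = forbid)
    an <- config$anchor
    out <- list()
    if (nrow(hs) > 0) {
      out$k56_at_hotspots <- anchor_profile(k56_norm, hs_fs, an$window_bp,
                                            an$n_bins, an$summary)
      out$rpa_ctrl_at_hotspots <- anchor_profile(sim$tracks$RPA_ctrl, hs_fs,
                                                 an$window_bp, an$n_bins, an$summary)
    }
    out$rpa_ctrl_at_random <- anchor_profile(sim$tracks$RPA_ctrl, rnd,
                                             an$window_bp, an$n_bins, an$summary)
    mg <- config$metagene
    out$k56_metagene <- metagene(k56_norm, truth$genes, mg$body_bins,
                                 mg$flank_bp, mg$flank_bins, mg$summary)
    out
  })

  classification <- if (is.null(rpa))
    overlap_classify(rpa_ctrl_peaks, rpa_mut_peaks, sim$tracks$RPA_ctrl,
                     sim$tracks$RPA_mut, fc_up = config$classify$fc_up,
                     flank_bp = config$classify$flank_bp)
  else rpa$classification
  utils::write.table(classification$table,
                     file.path(out_dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  quant <- stage("quantify", {
    out <- list()
    if (!is.null(truth$named_loci$BUD23like) &&
        !is.null(truth$named_loci$rDNAlike)) {
      le <- locus_enrichment(sim$tracks$RPA_ctrl, truth$named_loci$BUD23like,
                             truth$named_loci$rDNAlike)
      li <- locus_enrichment(sim$tracks$input, truth$named_loci$BUD23like,
                             truth$named_loci$rDNAlike)
      fc <- fold_change_between(sim$tracks$RPA_ctrl, sim$tracks$RPA_mut,
                                truth$named_loci$BUD23like)
      out <- list(rpa_BUD23like_vs_rDNAlike = le$ratio,
                  input_BUD23like_vs_rDNAlike = li$ratio,
                  fold_change_ctrl_over_mut_BUD23like = fc$ratio)
    }
    rep2 <- simulate_tracks(truth, noise_seed = sim_cfg$seed + 5)
    out$replicate_pearson_rpa <- track_pearson(sim$tracks$RPA_ctrl,
                                               rep2$RPA_ctrl)
    out
  })

  expr_assoc <- if (n_features(k56_peaks) > 0 && nrow(truth$gene_table) > 0) {
    stage("exprassoc", {
      ea <- tryCatch(expression_association(sim$expression, truth$genes,
                                            k56_peaks,
                                            seed = config$expression$seed),
                     error = function(e) NULL)
      if (is.null(ea)) NULL else
        list(p_greater = ea$test_greater$p, p_two_sided = ea$test_two_sided$p,
             n_group1 = ea$n_group1, n_random = ea$n_random,
             median_group1 = ea$median_group1, median_random = ea$median_random)
    })
  } else NULL

  results <- list(
    config = list(sim = unclass(sim_cfg),
                  pipeline = unclass(config)),
    n_hotspots_planted = nrow(hs),
    rpa_background_only = rpa_background_only,
    peak_counts = list(H3K56ac = n_features(k56_peaks),
                       RPA_ctrl = n_features(rpa_ctrl_peaks),
                       RPA_mut = n_features(rpa_mut_peaks)),
    classification = list(
      total = classification$total,
      eliminated = unname(classification$counts[["eliminated"]]),
      unaffected = unname(classification$counts[["unaffected"]]),
      increased = unname(classification$counts[["increased"]]),
      retained = classification$total -
        unname(classification$counts[["eliminated"]]),
      eliminated_pct = classification$eliminated_pct,
      empty = classification$total == 0),
    reldist = reldist,
    profiles = lapply(profiles, function(p)
      list(summary = p$summary, n = p$n)),
    quantification = quant,
    expression_association = expr_assoc)
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  if (write_tracks)
    for (tr in names(sim$tracks))
      write_bedgraph(sim$tracks[[tr]], file.path(out_dir, paste0(tr, ".bedGraph")))
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(results$config, cfg_path, auto_unbox = TRUE, digits = NA)
  log_line("config md5 %s", unname(tools::md5sum(cfg_path)))
  log_line("done")
  invisible(results)
}

#' Render a human-readable summary of a pipeline run
#'
#' Reads `results.json` from a [run_pipeline()] output directory and writes
#' a markdown summary (`report.md`) of the headline quantities: peak
#' counts, the eliminated/unaffected/increased classification with its
#' thresholds, locus fold changes, relative-distance summaries and the
#' expression association. Regeneration is idempotent.
#'
#' @param results_dir a [run_pipeline()] output directory.
#' @return Character vector of report lines, invisibly; also written to
#'   `report.md`.
#' @export
make_report <- function(results_dir) {
  path <- file.path(results_dir, "results.json")
  if (!file.exists(path)) stop_("make_report: no results.json in %s", results_dir)
  res <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("classification", "peak_counts", "config")
  miss <- setdiff(need, names(res))
  if (length(miss) > 0)
    stop_("make_report: results.json is missing field '%s'", miss[1])
  cl <- res$classification
  lines <- c(
    "# Pipeline summary",
    "",
    sprintf("Planted hotspots: %d", res$n_hotspots_planted),
    sprintf("Peaks called: H3K56ac %d, RPA ctrl %d, RPA mutant %d",
            res$peak_counts$H3K56ac, res$peak_counts$RPA_ctrl,
            res$peak_counts$RPA_mut),
    "",
    "## Control vs mutant RPA peak classification",
    "")
  if (isTRUE(cl$empty)) {
    lines <- c(lines, "No control peaks (empty classification).")
  } else {
    lines <- c(lines,
      sprintf("- eliminated: %d of %d (%.1f%%)", cl$eliminated, cl$total,
              cl$eliminated_pct),
      sprintf("- retained: %d (unaffected %d, increased %d at fold change >= %.2g over midpoint +/- %d bp)",
              cl$retained, cl$unaffected, cl$increased,
              res$config$pipeline$classify$fc_up,
              as.integer(res$config$pipeline$classify$flank_bp)))
  }
  q <- res$quantification
  if (!is.null(q$fold_change_ctrl_over_mut_BUD23like))
    lines <- c(lines, "", "## Locus quantification", "",
      sprintf("- RPA ctrl/mut fold change at BUD23like: %.3g",
              q$fold_change_ctrl_over_mut_BUD23like),
      sprintf("- RPA enrichment BUD23like vs rDNAlike: %.3g (input control: %.3g)",
              q$rpa_BUD23like_vs_rDNAlike, q$input_BUD23like_vs_rDNAlike),
      sprintf("- replicate RPA Pearson r: %.3f", q$replicate_pearson_rpa))
  if (length(res$reldist) > 0) {
    lines <- c(lines, "", "## H3K56ac peak relative distances", "")
    for (nm in names(res$reldist)) {
      r <- res$reldist[[nm]]
      lines <- c(lines, sprintf(
        "- vs %s: mean %.3f (shuffle null %.3f), p_left %.3g, p_right %.3g",
        nm, r$mean, r$null_mean, r$p_left, r$p_right))
    }
  }
  ea <- res$expression_association
  if (!is.null(ea))
    lines <- c(lines, "", "## Expression association", "",
      sprintf("- peak-associated genes (n=%d) vs random genes (n=%d): one-sided p = %.3g",
              ea$n_group1, ea$n_random, ea$p_greater),
      sprintf("- median expression %.3g vs %.3g", ea$median_group1,
              ea$median_random))
  writeLines(lines, file.path(results_dir, "report.md"))
  invisible(lines)
}
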