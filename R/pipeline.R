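#' Run configuration for the end-to-end pipeline
#'
#' Wraps a [phantom_config()] together with stage parameters. The trial
#' mode sets the visit schedule (monthly to week 24, semi-annual to week
#' 96, or annual to week 144) and whether the final pre-onset interval
#' visit is excluded from analysis (monthly mode only, mirroring the
#' exclusion of the -4-week scan).
#'
#' @param phantom a [phantom_config()] (its `trial_mode` drives the
#'   schedule).
#' @param detection_min_voxels new-lesion detection size threshold.
#' @param roi_min_voxels ROI pair size filter (10 voxels = 30 mm^3).
#' @param roi_dist_mm lesion exclusion radius (mm).
#' @param lts_fraction trimming fraction of the longitudinal fits.
#' @param n_bins probability-atlas bins.
#' @param min_coverage mean-atlas coverage threshold (fraction of cohort).
#' @param adjust multiplicity adjustment for LS means.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(phantom = phantom_config(),
                       detection_min_voxels = 3L,
                       roi_min_voxels = 10L,
                       roi_dist_mm = 2,
                       lts_fraction = 0.5,
                       n_bins = 12L,
                       min_coverage = 0.25,
                       adjust = "holm") {
  structure(list(phantom = phantom,
                 detection_min_voxels = detection_min_voxels,
                 roi_min_voxels = roi_min_voxels,
                 roi_dist_mm = roi_dist_mm,
                 lts_fraction = lts_fraction,
                 n_bins = n_bins, min_coverage = min_coverage,
                 adjust = adjust,
                 exclude_last_interval =
                   phantom$trial_mode == "synergy_monthly"),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), f)
  unname(tools::md5sum(f))
}

write_stage_table <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# config_hash: ", hash), con)
  close(con)
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Run the full backward-analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> calibrate/normalize -> track -> ROIs -> weighted
#' mixed-model statistics -> atlases, returning all intermediate products
#' and writing report tables (LS means by time per contrast and channel;
#' probability-bin tables; QC counts) to `out_dir` when given. Every output
#' table carries the config hash, so reruns with the same configuration are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir optional report directory.
#' @param cohort optionally, a pre-generated cohort (e.g. from
#'   [read_cohort()]); defaults to simulating from the config.
#' @param channels normalized channels to model.
#' @param verbose print stage progress.
#' @return list of class `"nawm_run"`: cohort, calibrations, events,
#'   roi_pairs, qc, sample_table, models (per channel x contrast with LS
#'   means), atlases (HC/PwMS/difference/probability/bins, trend test, ROI
#'   bin distributions), config, config_hash.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         cohort = NULL, channels = c("nmtr", "nt1", "nt2"),
                         verbose = FALSE) {
  say <- function(...) if (verbose) message("[nawmtrack] ", ...)
  hash <- config_hash(config)
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(cohort)) cohort <- generate_cohort(config$phantom)
    say("simulated ", length(cohort$subjects), " subjects, ",
        length(cohort$hcs), " healthy controls")

    stage <- "normalize"
    calibrations <- list()
    for (h in cohort$hcs) {
      sid <- h$scanner_id
      if (is.null(calibrations[[sid]])) calibrations[[sid]] <- calibrate_mtr(h)
    }
    subjects <- lapply(cohort$subjects, function(s)
      normalize_series(s, calibrations[[s$scanner_id]],
                       fraction = config$lts_fraction))

    stage <- "track"
    events <- lapply(subjects, find_lesion_events,
                     min_voxels = config$detection_min_voxels)

    stage <- "rois"
    rois <- mapply(function(s, ev) derive_roi_pairs(s, ev,
                     min_voxels = config$roi_min_voxels,
                     dist_mm = config$roi_dist_mm),
                   subjects, events, SIMPLIFY = FALSE)
    qc <- do.call(rbind, lapply(rois, `[[`, "qc"))

    stage <- "stats"
    tabs <- mapply(function(s, r) build_sample_table(s, r$pairs,
                     exclude_last_interval = config$exclude_last_interval),
                   subjects, rois, SIMPLIFY = FALSE)
    sample_table <- bind_sample_tables(tabs)
    models <- list()
    if (nrow(sample_table) > 0) {
      sample_table$time <- factor(sample_table$weeks_before_onset)
      for (ch in channels) {
        for (ctr in unique(sample_table$contrast)) {
          sub <- sample_table[sample_table$channel == ch &
                                sample_table$contrast == ctr, ]
          if (nrow(sub) < 4 || length(unique(sub$subject_id)) < 2 ||
              length(unique(sub$time)) < 1) next
          fit <- tryCatch(
            fit_weighted_lmm(value ~ time, droplevels(sub)),
            error = function(e) NULL)
          if (is.null(fit)) next
          models[[paste(ch, ctr, sep = ".")]] <-
            list(fit = fit, ls_means = ls_means(fit, "time",
                                                adjust = config$adjust))
        }
      }
    }

    stage <- "atlas"
    hc_nmtr <- lapply(cohort$hcs, function(h)
      normalize_mtr(h$timepoints[[1]]$volumes$mtr,
                    calibrations[[h$scanner_id]]))
    lab <- tissue_labels()
    hc_masks <- lapply(cohort$hcs, function(h)
      h$timepoints[[1]]$tissue == lab["wm"])
    pw_nmtr <- lapply(subjects, function(s) s$timepoints[[1]]$normalized$nmtr)
    pw_masks <- lapply(subjects, compute_overall_nawm,
                       dist_mm = config$roi_dist_mm)
    hc_atlas <- build_mean_atlas(hc_nmtr, hc_masks, "HC", config$min_coverage)
    pw_atlas <- build_mean_atlas(pw_nmtr, pw_masks, "PwMS", config$min_coverage)
    diff_atlas <- difference_atlas(hc_atlas, pw_atlas)
    les_final <- lapply(subjects, function(s)
      s$timepoints[[length(s$timepoints)]]$lesion_mask)
    prob_atlas <- build_probability_atlas(les_final)
    support <- cohort$template$labels == lab["wm"]
    bins <- discretize_probability(prob_atlas, n_bins = config$n_bins,
                                   support = support)
    trend <- tryCatch({
      bm <- rbind(bin_subject_means(hc_nmtr, hc_masks, bins, "HC"),
                  bin_subject_means(pw_nmtr, pw_masks, bins, "PwMS"))
      trend_test(bm, bin_linear = TRUE)
    }, error = function(e) list(error = conditionMessage(e)))
    roi_classes <- list(
      prelesion = Reduce(`|`, c(list(array(FALSE, dim(support))),
        lapply(unlist(lapply(rois, `[[`, "pairs"), recursive = FALSE),
               `[[`, "prelesion_mask"))),
      contralateral = Reduce(`|`, c(list(array(FALSE, dim(support))),
        lapply(unlist(lapply(rois, `[[`, "pairs"), recursive = FALSE),
               `[[`, "contralateral_mask"))),
      overall = Reduce(`|`, c(list(array(FALSE, dim(support))), pw_masks)))
    roi_bins <- roi_bin_distribution(roi_classes, bins)

    list(cohort = cohort, calibrations = calibrations, subjects = subjects,
         events = events, rois = rois, qc = qc, sample_table = sample_table,
         models = models,
         atlases = list(hc = hc_atlas, pwms = pw_atlas, difference = diff_atlas,
                        probability = prob_atlas, bins = bins, trend = trend,
                        roi_bins = roi_bins),
         config = config, config_hash = hash)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  class(res) <- "nawm_run"
  if (!is.null(out_dir)) write_run_report(res, out_dir)
  res
}

#' Write the pipeline report bundle
#'
#' Emits TSV tables (sample table, LS means per model, QC counts, event
#' table, ROI-by-bin distribution) and a JSON run summary; every table
#' carries the config hash.
#'
#' @param run a `"nawm_run"` from [run_pipeline()].
#' @param out_dir target directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- run$config_hash
  write_stage_table(run$sample_table, file.path(out_dir, "sample_table.tsv"), h)
  write_stage_table(run$qc, file.path(out_dir, "roi_qc.tsv"), h)
  write_stage_table(lesion_event_table(unlist(run$events, recursive = FALSE)),
                    file.path(out_dir, "lesion_events.tsv"), h)
  lsm <- do.call(rbind, lapply(names(run$models), function(nm) {
    cbind(data.frame(model = nm, stringsAsFactors = FALSE),
          run$models[[nm]]$ls_means)
  }))
  if (is.null(lsm)) lsm <- data.frame()
  write_stage_table(lsm, file.path(out_dir, "ls_means.tsv"), h)
  write_stage_table(run$atlases$roi_bins, file.path(out_dir, "roi_bins.tsv"), h)
  summary <- list(
    config_hash = h,
    n_subjects = length(run$cohort$subjects),
    n_hc = length(run$cohort$hcs),
    n_events = sum(vapply(run$events, length, integer(1))),
    n_accepted_pairs = sum(vapply(run$rois,
                                  function(r) length(r$pairs), integer(1))),
    qc_rejections = as.list(table(run$qc$status)),
    trend_p = if (!is.null(run$atlases$trend$p.value))
      run$atlases$trend$p.value else NA)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands: `simulate` (write a cohort),
#' `normalize`, `track`, `rois`, `stats`, `atlas` (run the pipeline up to
#' and including that stage on a simulated or on-disk cohort, writing that
#' stage's tables) and `run` (everything). Intended to be called from the
#' installed script `inst/cli/nawmtrack.R`:
#' `Rscript nawmtrack.R <subcommand> --config cfg.yaml --out DIR`.
#'
#' @param args character vector of command-line arguments (default: from
#'   the calling process).
#' @return exit status, invisibly.
#' @export
nawm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  subcommands <- c("simulate", "normalize", "track", "rois", "stats",
                   "atlas", "run")
  if (length(args) == 0 || !(args[1] %in% subcommands)) {
    cat("usage: nawmtrack.R <", paste(subcommands, collapse = " | "),
        "> [--config cfg.yaml] [--cohort DIR] [--out DIR] [--seed N]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "YAML file of phantom/run parameters"),
    optparse::make_option("--cohort", type = "character", default = NULL,
                          help = "existing cohort directory (from simulate)"),
    optparse::make_option("--out", type = "character", default = "nawm_out",
                          help = "output directory"),
    optparse::make_option("--seed", type = "integer", default = NULL,
                          help = "override the config seed"),
    optparse::make_option("--channel", type = "character", default = "all",
                          help = "normalize: one of mtr|t1|t2|all"),
    optparse::make_option("--bins", type = "integer", default = NULL,
                          help = "atlas: number of probability bins"),
    optparse::make_option("--min-coverage", type = "double", default = NULL,
                          dest = "min_coverage",
                          help = "atlas: minimum coverage fraction"),
    optparse::make_option("--overwrite", action = "store_true",
                          default = FALSE, help = "allow overwriting outputs")))
  opt <- optparse::parse_args(parser, args = args[-1])

  pc_args <- if (!is.null(opt$config)) yaml::read_yaml(opt$config) else list()
  run_keys <- c("detection_min_voxels", "roi_min_voxels", "roi_dist_mm",
                "lts_fraction", "n_bins", "min_coverage", "adjust")
  rc_args <- pc_args[intersect(names(pc_args), run_keys)]
  pc_args <- pc_args[setdiff(names(pc_args), run_keys)]
  if (!is.null(opt$seed)) pc_args$seed <- opt$seed
  if (!is.null(opt$bins)) rc_args$n_bins <- opt$bins
  if (!is.null(opt$min_coverage)) rc_args$min_coverage <- opt$min_coverage
  phantom <- do.call(phantom_config, pc_args)
  config <- do.call(run_config, c(list(phantom = phantom), rc_args))

  cohort <- if (!is.null(opt$cohort)) read_cohort(opt$cohort) else NULL

  if (cmd == "simulate") {
    cohort <- generate_cohort(phantom)
    write_cohort(cohort, opt$out, overwrite = opt$overwrite)
    cat("cohort written to ", opt$out, "\n")
    return(invisible(0L))
  }
  run <- run_pipeline(config, out_dir = if (cmd == "run") opt$out else NULL,
                      cohort = cohort, verbose = TRUE)
  if (cmd != "run") {
    dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
    h <- run$config_hash
    switch(cmd,
      normalize = {
        cal_dir <- file.path(opt$out, "calibrations")
        dir.create(cal_dir, showWarnings = FALSE)
        for (sid in names(run$calibrations))
          write_calibration(run$calibrations[[sid]],
                            file.path(cal_dir, paste0(sid, ".json")))
        chans <- if (opt$channel == "all") c("nmtr", "nt1", "nt2")
                 else paste0("n", sub("^n", "", opt$channel))
        for (s in run$subjects) {
          sdir <- file.path(opt$out, s$subject_id)
          dir.create(sdir, showWarnings = FALSE)
          for (tp in s$timepoints) {
            for (ch in chans) {
              write_nifti(tp$normalized[[ch]],
                          file.path(sdir, sprintf("%s_wk-%03d_%s.nii.gz",
                                                  s$subject_id, tp$week, ch)),
                          pixdim = s$pixdim)
            }
          }
        }
      },
      track = write_stage_table(
        lesion_event_table(unlist(run$events, recursive = FALSE)),
        file.path(opt$out, "lesion_events.tsv"), h),
      rois = write_stage_table(run$qc, file.path(opt$out, "roi_qc.tsv"), h),
      stats = {
        write_stage_table(run$sample_table,
                          file.path(opt$out, "sample_table.tsv"), h)
        lsm <- do.call(rbind, lapply(names(run$models), function(nm)
          cbind(data.frame(model = nm), run$models[[nm]]$ls_means)))
        write_stage_table(if (is.null(lsm)) data.frame() else lsm,
                          file.path(opt$out, "ls_means.tsv"), h)
      },
      atlas = write_stage_table(run$atlases$roi_bins,
                                file.path(opt$out, "roi_bins.tsv"), h))
  }
  cat("done: ", cmd, " -> ", opt$out, "\n")
  invisible(0L)
}
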