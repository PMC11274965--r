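#' Run the full analysis from one configuration
#'
#' Orchestrates every stage — synthetic cohort simulation, preprocessing,
#' ROI decoding, group effect maps, and the EMG/gaze control decoders —
#' and writes CSV tables, NIfTI maps and a JSON summary to `output_dir`.
#' Deterministic: rerunning with the same configuration reproduces every
#' number.
#'
#' The configuration may be a [simulation_config()] or the path of a
#' YAML/JSON file whose fields override the defaults of
#' [simulation_config()] (top-level keys `simulation`, `mvpa`, `emap`,
#' `controls`).
#'
#' @param config a `simulation_config`, or a path to a YAML/JSON config file
#' @param output_dir directory for outputs (created if missing); `NULL`
#'   skips writing
#' @param contrasts decoding contrasts to run
#' @param emap_contrast contrast for the group effect map (`NULL` skips)
#' @param run_controls also run the EMG and gaze control decoders
#' @param smoothing_fwhm_mm preprocessing smoothing FWHM (mm)
#' @param emap_fwhm_mm group effect-map smoothing FWHM (mm)
#' @param n_bins histogram bins for the effect-map NMI estimate
#' @return an `analysis_report`: list with `condition_table` (ROI x
#'   condition contrasts), `laterality_table` (ROI x timepoints), optional
#'   `group_emap`, optional `controls`, and the `config`
#' @export
run_full_analysis <- function(config, output_dir = NULL,
                              contrasts = .CONTRASTS,
                              emap_contrast = "left-vs-right@imageryT2",
                              run_controls = TRUE,
                              smoothing_fwhm_mm = 8, emap_fwhm_mm = 5,
                              n_bins = 16L) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "simulation_config"))
  cohort <- decode_cohort(config, contrasts = contrasts,
                          smoothing_fwhm_mm = smoothing_fwhm_mm)
  summary_tab <- summarize_accuracy(cohort)
  cond_contrasts <- intersect(
    c("fixation-vs-intention", "intention-vs-imagery"), contrasts)
  lat_contrasts <- grep("^left-vs-right", contrasts, value = TRUE)
  condition_table <- summary_tab[summary_tab$contrast %in% cond_contrasts, ]
  laterality_table <- summary_tab[summary_tab$contrast %in% lat_contrasts, ]

  group_emap <- NULL
  if (!is.null(emap_contrast))
    group_emap <- group_effect_map(config, emap_contrast,
                                   smoothing_fwhm_mm = smoothing_fwhm_mm,
                                   emap_fwhm_mm = emap_fwhm_mm,
                                   n_bins = n_bins)

  controls <- NULL
  if (run_controls) {
    sch <- generate_schedule(config$n_runs_per_hand,
                             tr_seconds = config$tr_seconds,
                             seed = config$seed + 5L)
    emg <- simulate_emg(sch, sampling_hz = 500, seed = config$seed + 6L)
    gaze <- simulate_gaze(sch, seed = config$seed + 7L)
    controls <- list(emg = emg_decode(emg, sch, seed = config$seed),
                     eye = eye_decode(gaze, sch, seed = config$seed))
  }

  report <- structure(
    list(condition_table = condition_table,
         laterality_table = laterality_table,
         cohort = cohort, group_emap = group_emap, controls = controls,
         config = config),
    class = "analysis_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' Group effect map for one contrast over the whole cohort
#'
#' Computes one effect map per cross-validation fold and participant on the
#' combined voxels of all ROIs (4 folds x n participants maps), averages
#' the normalized maps, and smooths the averaged map.
#'
#' @param config a [simulation_config()]
#' @param contrast decoding contrast
#' @param smoothing_fwhm_mm preprocessing smoothing FWHM (mm)
#' @param emap_fwhm_mm smoothing FWHM of the averaged map (mm)
#' @param n_bins histogram bins for the NMI estimate
#' @param n_folds cross-validation folds per participant
#' @param flip_labels swap the +1/-1 design labels (negates the map)
#' @return an `effect_map` with the smoothed group `volume`
#' @export
group_effect_map <- function(config, contrast = "left-vs-right@imageryT2",
                             smoothing_fwhm_mm = 8, emap_fwhm_mm = 5,
                             n_bins = 16L, n_folds = 4L,
                             flip_labels = FALSE) {
  masks <- config_roi_masks(config)
  union_mask <- Reduce(function(a, b) a | b,
                       lapply(masks, `[[`, "mask"))
  union_roi <- new_roi_mask("all_rois", union_mask)
  maps <- list()
  for (p in seq_len(config$n_participants)) {
    sessions <- simulate_participant(config, p)
    parts <- lapply(sessions, function(bold) {
      if (smoothing_fwhm_mm > 0) bold <- smooth_bold(bold, smoothing_fwhm_mm)
      z <- z_normalize(apply_mask(bold$data, union_roi))
      labels <- schedule_to_labels(bold$schedule, config$delay_trs)
      extract_condition_features(z, labels, contrast,
                                 session = bold$session)
    })
    samples <- pool_samples(parts)
    # folds are fixed before any label flip so that swapping the design
    # labels changes only their orientation, never the fold composition
    folds <- .make_folds(samples, n_folds, config$seed + 13L * p)
    if (flip_labels) samples$labels <- -samples$labels
    for (f in seq_len(n_folds)) {
      train <- new_labeled_samples(
        samples$features[folds != f, , drop = FALSE],
        samples$labels[folds != f], contrast = contrast)
      model <- train_linear_svm(train)
      maps[[length(maps) + 1L]] <- effect_values(model, train,
                                                 n_bins = n_bins)
    }
  }
  group_average_emaps(maps, fwhm_mm = emap_fwhm_mm, mask = union_roi,
                      voxel_size_mm = config$voxel_size_mm)
}

#' Load a simulation configuration from YAML or JSON
#'
#' Recognized keys (all optional, under a top-level `simulation` section or
#' at the top level) mirror the arguments of [simulation_config()];
#' `roi_amplitude_scale` rescales all default amplitudes.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file
#' @return a `simulation_config`
#' @export
load_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  sim <- if (!is.null(cfg$simulation)) cfg$simulation else cfg
  args <- sim[intersect(names(sim),
                        names(formals(simulation_config)))]
  if (!is.null(sim$roi_amplitude_scale))
    args$roi_specs <- default_roi_specs(sim$roi_amplitude_scale)
  do.call(simulation_config, args)
}

#' Write an analysis report to disk
#'
#' Emits `condition_accuracy.csv` and `laterality_accuracy.csv` (the two
#' summary-table layouts), per-participant accuracies, control-decoder
#' tables, the group effect map as NIfTI, and `summary.json` with the
#' configuration snapshot and seeds.
#'
#' @param report an `analysis_report`
#' @param output_dir output directory (created if missing)
#' @return `output_dir`, invisibly
#' @export
write_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(output_dir, ...)
  utils::write.csv(report$condition_table, p("condition_accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(report$laterality_table, p("laterality_accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$cohort),
                   p("participant_accuracy.csv"), row.names = FALSE)
  if (!is.null(report$controls)) {
    ctrl <- do.call(rbind, lapply(c(report$controls$emg,
                                    report$controls$eye), function(cv)
      data.frame(decoder = cv$roi, contrast = cv$contrast,
                 mean_acc = cv$mean, sem = cv$sem,
                 n_folds = length(cv$fold_accuracies))))
    utils::write.csv(ctrl, p("control_accuracy.csv"), row.names = FALSE)
  }
  if (!is.null(report$group_emap))
    write_emap_nifti(report$group_emap, p("group_emap.nii"),
                     voxel_size_mm = report$config$voxel_size_mm)
  cfg <- report$config
  cfg$label_volume <- NULL
  jsonlite::write_json(
    list(config = cfg, seed = report$config$seed,
         package_version = as.character(utils::packageVersion("intentmvpa"))),
    p("summary.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(output_dir)
}
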