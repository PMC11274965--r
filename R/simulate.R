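#' Synthetic data with the statistical structure of a cued-imagery study
#'
#' The generator emulates what the decoding analysis assumes about the real
#' experiment: condition- and laterality-specific multivoxel patterns inside
#' designated ROIs, a fixed hemodynamic delay (a 2-TR shift of the block
#' boxcar, with no convolution kernel), additive Gaussian noise, and
#' per-participant jitter of the pattern templates. Companion generators
#' produce multichannel EMG with a TR-periodic MR gradient artifact and 2D
#' fixation-jitter gaze traces, each with optional planted laterality signal
#' for positive-control tests.
#'
#' @name synthetic_data
NULL

#' Per-ROI effect specification
#'
#' @param roi_name parcel name
#' @param n_informative_voxels number of voxels carrying planted patterns
#' @param condition_amplitude pattern amplitude (z-units) distinguishing
#'   fixation / intention / imagery
#' @param laterality_amplitude pattern amplitude (z-units) distinguishing
#'   left from right trials
#' @return a list of class `roi_effect_spec`
#' @export
roi_effect_spec <- function(roi_name, n_informative_voxels = 60L,
                            condition_amplitude = 1.0,
                            laterality_amplitude = 0.0) {
  stopifnot(condition_amplitude >= 0, laterality_amplitude >= 0,
            n_informative_voxels >= 0)
  structure(list(roi_name = roi_name,
                 n_informative_voxels = as.integer(n_informative_voxels),
                 condition_amplitude = condition_amplitude,
                 laterality_amplitude = laterality_amplitude),
            class = "roi_effect_spec")
}

#' Synthetic parcel volume
#'
#' Eight disjoint 6 x 6 x 4 cuboid parcels (integer labels 1-8) on the
#' working grid, standing in for the Brodmann-area compositions of the eight
#' study ROIs.
#'
#' @param grid integer length-3 grid shape (default `c(24, 24, 16)`)
#' @return integer 3D array of labels (0 = background) with attribute
#'   `roi_names` (names for labels 1-8)
#' @export
synthetic_parcel_volume <- function(grid = c(24L, 24L, 16L)) {
  stopifnot(all(grid >= c(22, 22, 10)))
  lab <- array(0L, grid)
  roi_names <- c("PPC", "PMC", "SMA", "M1", "somatosensory",
                 "DLPFC", "frontopolar", "posterior_cingulate")
  x0 <- c(1L, 9L, 17L, 9L)          # corners within one z slab
  y0 <- c(1L, 1L, 1L, 9L)
  z_lo <- 3L
  z_hi <- grid[3] - 5L
  for (i in 1:8) {
    j <- ((i - 1L) %% 4L) + 1L
    z0 <- if (i <= 4L) z_lo else z_hi
    lab[x0[j]:(x0[j] + 5L), y0[j]:(y0[j] + 5L), z0:(z0 + 3L)] <- i
  }
  attr(lab, "roi_names") <- roi_names
  lab
}

#' Simulation configuration
#'
#' The default configuration fixes the study conditions used throughout the
#' package's tests: a 24 x 24 x 16 grid of 3.3 x 3.3 x 5 mm voxels, eight
#' parcels, 60 informative voxels per informative parcel, laterality
#' amplitude 1.0 z-units in the PPC/PMC/SMA parcels and 0.6 in
#' M1/somatosensory (0 elsewhere), condition amplitude 1.0 everywhere except
#' 0.3 in the frontopolar parcel, unit-variance Gaussian noise, a 2-TR
#' delay, 10 participants, one session of 20 trials per hand, seed 42.
#'
#' @param grid grid shape (3 integers)
#' @param voxel_size_mm voxel edge lengths, mm
#' @param roi_specs list of [roi_effect_spec()]; parcel names must exist in
#'   the label volume
#' @param noise_sd additive Gaussian noise sd (z-units), > 0 unless exactly 0
#'   for noiseless checks
#' @param pattern_jitter_sd per-participant sd of pattern jitter around the
#'   group template
#' @param delay_trs hemodynamic delay in TRs
#' @param n_participants,n_sessions,n_runs_per_hand cohort dimensions
#' @param tr_seconds repetition time, seconds
#' @param seed master seed for the cohort
#' @return a list of class `simulation_config`
#' @export
simulation_config <- function(grid = c(24L, 24L, 16L),
                              voxel_size_mm = c(3.3, 3.3, 5.0),
                              roi_specs = default_roi_specs(),
                              noise_sd = 1.0,
                              pattern_jitter_sd = 0.2,
                              delay_trs = 2L,
                              n_participants = 10L,
                              n_sessions = 1L,
                              n_runs_per_hand = 20L,
                              tr_seconds = 1.5,
                              seed = 42L) {
  stopifnot(noise_sd >= 0, pattern_jitter_sd >= 0, delay_trs >= 0,
            n_participants >= 1, n_sessions >= 1)
  labels <- synthetic_parcel_volume(grid)
  roi_names <- attr(labels, "roi_names")
  for (sp in roi_specs) {
    if (!sp$roi_name %in% roi_names)
      stop("unknown parcel name: ", sp$roi_name)
    if (sp$n_informative_voxels > sum(labels == match(sp$roi_name, roi_names)))
      stop("n_informative_voxels exceeds parcel size for ", sp$roi_name)
  }
  structure(list(grid = as.integer(grid), voxel_size_mm = voxel_size_mm,
                 roi_specs = roi_specs, noise_sd = noise_sd,
                 pattern_jitter_sd = pattern_jitter_sd,
                 delay_trs = as.integer(delay_trs),
                 n_participants = as.integer(n_participants),
                 n_sessions = as.integer(n_sessions),
                 n_runs_per_hand = as.integer(n_runs_per_hand),
                 tr_seconds = tr_seconds, seed = as.integer(seed),
                 label_volume = labels),
            class = "simulation_config")
}

#' Default per-ROI effect amplitudes
#'
#' Encodes the qualitative ordering the analysis is expected to recover:
#' strongest laterality information in PPC/PMC/SMA, intermediate in
#' M1/somatosensory, none in DLPFC/frontopolar/posterior cingulate; the
#' condition contrast present everywhere but weak frontopolar.
#'
#' @param amplitude_scale multiplier applied to every amplitude (0 gives a
#'   null cohort)
#' @return list of `roi_effect_spec`
#' @export
default_roi_specs <- function(amplitude_scale = 1.0) {
  lat <- c(PPC = 1.0, PMC = 1.0, SMA = 1.0, M1 = 0.6, somatosensory = 0.6,
           DLPFC = 0.0, frontopolar = 0.0, posterior_cingulate = 0.0)
  cond <- c(PPC = 1.0, PMC = 1.0, SMA = 1.0, M1 = 1.0, somatosensory = 1.0,
            DLPFC = 1.0, frontopolar = 0.3, posterior_cingulate = 1.0)
  lapply(names(lat), function(nm)
    roi_effect_spec(nm, n_informative_voxels = 60L,
                    condition_amplitude = cond[[nm]] * amplitude_scale,
                    laterality_amplitude = lat[[nm]] * amplitude_scale))
}

new_bold_dataset <- function(data, grid, voxel_size_mm, tr_seconds,
                             participant_id, session, schedule) {
  structure(list(data = data, grid = grid, voxel_size_mm = voxel_size_mm,
                 tr_seconds = tr_seconds, participant_id = participant_id,
                 session = session, schedule = schedule),
            class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat("<bold_dataset>", x$participant_id, "session", x$session, "-",
      nrow(x$data), "TRs x", ncol(x$data), "voxels\n")
  invisible(x)
}

# Group pattern templates: one draw per ROI from the cohort seed, shared by
# all participants. Returns per ROI a list of pattern vectors over the
# informative voxel indices (grid indices).
.group_templates <- function(config) {
  labels <- config$label_volume
  roi_names <- attr(labels, "roi_names")
  local_seed(config$seed, {
    lapply(config$roi_specs, function(sp) {
      idx <- which(labels == match(sp$roi_name, roi_names))
      inf <- sort(sample(idx, sp$n_informative_voxels))
      list(spec = sp, voxels = inf,
           p_int = stats::rnorm(length(inf)),
           p_img = stats::rnorm(length(inf)),
           p_left = stats::rnorm(length(inf)),
           p_right = stats::rnorm(length(inf)))
    })
  })
}

# Noise-free design signal (TR x voxel) for one session, before the delay
# shift, from the participant-specific patterns.
.design_signal <- function(schedule, patterns, n_vox) {
  total <- n_trs(schedule)
  sig <- matrix(0, total, n_vox)
  occ <- schedule_to_labels(schedule, delay_trs = 0L)
  for (pt in patterns) {
    sp <- pt$spec
    v <- pt$voxels
    for (t in seq_len(total)) {
      cond <- occ$condition[t]
      if (cond == "fixation") next
      base <- if (cond == "intention") sp$condition_amplitude * pt$p_int
              else sp$condition_amplitude * pt$p_img
      side <- if (occ$laterality[t] == "left")
                sp$laterality_amplitude * pt$p_left
              else sp$laterality_amplitude * pt$p_right
      sig[t, v] <- sig[t, v] + base + side
    }
  }
  sig
}

#' Simulate one participant's BOLD sessions
#'
#' The signal model: baseline 0; during each non-fixation block the ROI's
#' condition pattern (amplitude x a fixed template) plus its laterality
#' pattern is added to the informative voxels; the whole design signal is
#' shifted forward by `delay_trs` (the hemodynamic delay); iid Gaussian
#' noise of `noise_sd` is added everywhere. Patterns are the group templates
#' jittered once per participant by `pattern_jitter_sd`. Bit-identical under
#' the same `(config, participant_index)`.
#'
#' @param config a [simulation_config()]
#' @param participant_index 1-based participant number
#' @return a list of `bold_dataset`, one per session; each carries its
#'   `event_schedule`
#' @export
simulate_participant <- function(config, participant_index) {
  stopifnot(inherits(config, "simulation_config"), participant_index >= 1)
  templates <- .group_templates(config)
  n_vox <- prod(config$grid)
  pid <- sprintf("sub-%02d", participant_index)
  pseed <- config$seed + 7919L * as.integer(participant_index)
  patterns <- local_seed(pseed, {
    lapply(templates, function(pt) {
      for (f in c("p_int", "p_img", "p_left", "p_right"))
        pt[[f]] <- pt[[f]] +
          stats::rnorm(length(pt[[f]]), sd = config$pattern_jitter_sd)
      pt
    })
  })
  sessions <- vector("list", config$n_sessions)
  for (s in seq_len(config$n_sessions)) {
    sch <- generate_schedule(config$n_runs_per_hand,
                             tr_seconds = config$tr_seconds,
                             seed = pseed + 101L * s,
                             participant_id = pid, session = s)
    total <- n_trs(sch)
    sig <- .design_signal(sch, patterns, n_vox)
    d <- config$delay_trs
    obs <- matrix(0, total, n_vox)
    if (total > d) obs[(d + 1L):total, ] <- sig[seq_len(total - d), ]
    if (config$noise_sd > 0)
      obs <- obs + local_seed(pseed + 211L * s,
        matrix(stats::rnorm(length(obs), sd = config$noise_sd),
               nrow(obs), ncol(obs)))
    sessions[[s]] <- new_bold_dataset(obs, config$grid, config$voxel_size_mm,
                                      config$tr_seconds, pid, s, sch)
  }
  sessions
}

#' ROI masks for a simulation configuration
#' @param config a [simulation_config()]
#' @return named list of `roi_mask`, one per parcel
#' @export
config_roi_masks <- function(config) {
  labels <- config$label_volume
  roi_names <- attr(labels, "roi_names")
  masks <- lapply(seq_along(roi_names), function(i)
    compose_roi(labels, i, roi_names[i]))
  names(masks) <- roi_names
  masks
}

# fixed TR-periodic gradient-artifact waveform on [0, 1) phase; identical in
# every TR so template subtraction can remove it exactly
.artifact_waveform <- function(n_samples) {
  phase <- (seq_len(n_samples) - 1) / n_samples
  sin(2 * pi * 11 * phase) + 0.6 * sign(sin(2 * pi * 29 * phase)) +
    0.3 * sin(2 * pi * 97 * phase)
}

#' Simulate a multichannel EMG recording
#'
#' Six bipolar channels of Gaussian baseline noise plus a fixed TR-periodic
#' MR gradient-artifact waveform. For positive-control tests a
#' laterality-locked amplitude burst (extra Gaussian power on the left-arm
#' channels 1-3 during left trials, right-arm channels 4-6 during right
#' trials, within intention and imagery blocks) can be planted; the null
#' control uses `burst_amplitude = 0`.
#'
#' @param schedule an `event_schedule`
#' @param sampling_hz sampling rate; `sampling_hz * tr_seconds` must be an
#'   integer (5000 Hz at TR 1.5 s gives 7500 samples per TR)
#' @param artifact_amplitude gradient-artifact scale, arbitrary µV units
#' @param burst_amplitude planted laterality burst sd (0 = null)
#' @param noise_sd baseline noise sd
#' @param seed integer seed
#' @return an `emg_recording`: list with `data` (channels x samples),
#'   `sampling_hz`, `markers` (1-based TR start samples), `tr_seconds`,
#'   `channel_names`
#' @export
simulate_emg <- function(schedule, sampling_hz = 5000, artifact_amplitude = 10,
                         burst_amplitude = 0, noise_sd = 1, seed = 1L) {
  spt <- sampling_hz * attr(schedule, "tr_seconds")
  if (abs(spt - round(spt)) > 1e-9)
    stop("sampling_hz * tr_seconds must be an integer number of samples")
  spt <- as.integer(round(spt))
  total_trs <- n_trs(schedule)
  n_samp <- total_trs * spt
  n_ch <- 6L
  data <- local_seed(seed,
    matrix(stats::rnorm(n_ch * n_samp, sd = noise_sd), n_ch, n_samp))
  if (artifact_amplitude > 0 && total_trs > 0) {
    art <- artifact_amplitude * .artifact_waveform(spt)
    data <- data + matrix(rep(art, total_trs), n_ch, n_samp, byrow = TRUE)
  }
  if (burst_amplitude > 0) {
    occ <- schedule_to_labels(schedule, delay_trs = 0L)
    burst <- local_seed(seed + 1L,
      matrix(stats::rnorm(n_ch * n_samp, sd = burst_amplitude), n_ch, n_samp))
    for (t in seq_len(total_trs)) {
      if (occ$condition[t] == "fixation") next
      ch <- if (occ$laterality[t] == "left") 1:3 else 4:6
      cols <- ((t - 1L) * spt + 1L):(t * spt)
      data[ch, cols] <- data[ch, cols] + burst[ch, cols]
    }
  }
  structure(list(data = data, sampling_hz = sampling_hz,
                 markers = if (n_samp == 0L) integer(0)
                           else seq(1L, n_samp, by = spt),
                 tr_seconds = attr(schedule, "tr_seconds"),
                 channel_names = paste0("emg", 1:6)),
            class = "emg_recording")
}

#' Simulate a 2D gaze recording
#'
#' Fixation jitter around screen centre at the eye-tracker rate. The null
#' control has no laterality dependence; a positive control adds a
#' laterality-dependent horizontal offset of `drift_amplitude` during
#' intention and imagery blocks. Blink gaps are injected as invalid samples.
#'
#' @param schedule an `event_schedule`
#' @param sampling_hz sampling rate (60 Hz typical)
#' @param drift_amplitude horizontal offset in degrees (0 = null)
#' @param jitter_sd fixation jitter sd in degrees
#' @param blink_rate per-sample probability of a missing (blink) sample
#' @param seed integer seed
#' @return a `gaze_recording`: list with `data` (samples x 2), `valid`
#'   logical vector, `sampling_hz`, `tr_seconds`, `n_trs`
#' @export
simulate_gaze <- function(schedule, sampling_hz = 60, drift_amplitude = 0,
                          jitter_sd = 0.3, blink_rate = 0.02, seed = 1L) {
  stopifnot(sampling_hz > 0, blink_rate >= 0, blink_rate < 1)
  spt <- sampling_hz * attr(schedule, "tr_seconds")
  if (abs(spt - round(spt)) > 1e-9)
    stop("sampling_hz * tr_seconds must be an integer number of samples")
  spt <- as.integer(round(spt))
  total_trs <- n_trs(schedule)
  n <- total_trs * spt
  out <- local_seed(seed, {
    xy <- matrix(stats::rnorm(2L * n, sd = jitter_sd), n, 2L)
    valid <- stats::runif(n) >= blink_rate
    list(xy = xy, valid = valid)
  })
  xy <- out$xy
  if (drift_amplitude != 0 && total_trs > 0) {
    occ <- schedule_to_labels(schedule, delay_trs = 0L)
    for (t in seq_len(total_trs)) {
      if (occ$condition[t] == "fixation") next
      rows <- ((t - 1L) * spt + 1L):(t * spt)
      sgn <- if (occ$laterality[t] == "left") -1 else 1
      xy[rows, 1L] <- xy[rows, 1L] + sgn * drift_amplitude
    }
  }
  structure(list(data = xy, valid = out$valid, sampling_hz = sampling_hz,
                 tr_seconds = attr(schedule, "tr_seconds"), n_trs = total_trs),
            class = "gaze_recording")
}

#' Write a BOLD dataset as 4D NIfTI
#'
#' @param bold a `bold_dataset`
#' @param path output `.nii` path
#' @return `path`, invisibly
#' @export
write_bold_nifti <- function(bold, path) {
  arr <- array(t(bold$data), c(bold$grid, nrow(bold$data)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(bold$voxel_size_mm, bold$tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI into a TR x voxel matrix
#' @param path `.nii` path
#' @return list with `data` (TR x voxel), `grid`, `voxel_size_mm`
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stopifnot(length(d) == 4L)
  data <- t(matrix(img, prod(d[1:3]), d[4]))
  list(data = data, grid = d[1:3],
       voxel_size_mm = RNifti::pixdim(img)[1:3])
}

#' Write an EMG or gaze recording as CSV with a JSON sidecar
#'
#' @param rec an `emg_recording` or `gaze_recording`
#' @param path output `.csv` path; the sidecar replaces the extension with
#'   `.json`
#' @return `path`, invisibly
#' @export
write_recording_csv <- function(rec, path) {
  if (inherits(rec, "emg_recording")) {
    n <- ncol(rec$data)
    df <- data.frame(time_s = (seq_len(n) - 1) / rec$sampling_hz,
                     t(rec$data))
    names(df) <- c("time_s", rec$channel_names)
    meta <- list(type = "emg", sampling_hz = rec$sampling_hz,
                 tr_seconds = rec$tr_seconds, tr_markers = rec$markers)
  } else {
    n <- nrow(rec$data)
    df <- data.frame(time_s = (seq_len(n) - 1) / rec$sampling_hz,
                     x = rec$data[, 1], y = rec$data[, 2],
                     valid = as.integer(rec$valid))
    meta <- list(type = "gaze", sampling_hz = rec$sampling_hz,
                 tr_seconds = rec$tr_seconds)
  }
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
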