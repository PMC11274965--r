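test_that("gradient-artifact template subtraction removes periodic artifacts", {
  sch <- generate_schedule(3, seed = 6)
  # pure artifact, no noise: TR-periodicity forces an exact template
  emg <- simulate_emg(sch, sampling_hz = 500, artifact_amplitude = 5,
                      noise_sd = 0, seed = 1)
  corr <- gradient_artifact_correct(emg)
  expect_lt(max(abs(corr$data)), 1e-10)
  # artifact + noise: energy at the TR-harmonic frequencies drops to the
  # noise floor (spectral oracle)
  emg2 <- simulate_emg(sch, sampling_hz = 500, artifact_amplitude = 5,
                       noise_sd = 1, seed = 2)
  corr2 <- gradient_artifact_correct(emg2)
  harmonic_energy <- function(x, n_trs) {
    p <- Mod(stats::fft(x))^2
    bins <- 1L + n_trs * seq_len((length(x) / n_trs - 1) %/% 2)
    sum(p[bins])
  }
  before <- harmonic_energy(emg2$data[1, ], n_trs(sch))
  after <- harmonic_energy(corr2$data[1, ], n_trs(sch))
  # the corrected artifact+noise signal equals the corrected noise-only
  # signal (same noise realization): correction is linear and exact on the
  # periodic part
  noise_only <- simulate_emg(sch, sampling_hz = 500, artifact_amplitude = 0,
                             noise_sd = 1, seed = 2)
  floor_e <- harmonic_energy(
    gradient_artifact_correct(noise_only)$data[1, ], n_trs(sch))
  expect_lt(after, 0.01 * before)
  expect_equal(after, floor_e, tolerance = 1e-6)
  # too few TRs for the template
  expect_error(gradient_artifact_correct(
    simulate_emg(generate_schedule(0), sampling_hz = 500, seed = 1)),
    "complete TRs")
})

test_that("waveform length follows the documented window rule", {
  # constant signal: WL = 0 in every window
  n_win <- length(oracle_window_starts(1000, 120, 108))
  expect_equal(waveform_length(rep(3, 1000), 500), rep(0, n_win))
  # forced sum of |differences| on a rectified toy trace
  expect_equal(waveform_length(c(0, 1, 0, 1), sampling_hz = 1000,
                               window_ms = 4, overlap_ms = 0), 3)
  # window count for one TR at 5000 Hz, 240 ms window / 24 ms overlap,
  # against the sliding-window enumeration oracle
  x <- rnorm(7500)
  got <- waveform_length(x, 5000)
  expect_length(got, length(oracle_window_starts(7500, 1200, 1080)))
  expect_equal(got, oracle_wl(x, 1200, 1080))
  expect_error(waveform_length(rnorm(100), 5000), "longer than")
  # adding a positive offset to a positive signal leaves WL unchanged
  xp <- abs(rnorm(2000)) + 1
  expect_equal(waveform_length(xp + 5, 500), waveform_length(xp, 500))
})

test_that("the KL transform matches an eigendecomposition oracle", {
  set.seed(15)
  f <- matrix(rnorm(15), 5, 3)
  kl <- klt(f, n_components = 3)
  # orthonormal basis
  expect_equal(crossprod(kl$basis), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # full-rank retention reconstructs the input
  rec <- kl$scores %*% t(kl$basis) + rep(kl$center, each = 5)
  expect_equal(rec, f, tolerance = 1e-10)
  # components agree with eigen(cov) up to sign
  eig <- eigen(stats::cov(f))
  for (k in 1:3)
    expect_equal(abs(sum(kl$basis[, k] * eig$vectors[, k])), 1,
                 tolerance = 1e-8)
  # total variance preserved when all components kept
  expect_equal(sum(apply(kl$scores, 2, stats::var)),
               sum(diag(stats::cov(f))), tolerance = 1e-10)
  expect_error(klt(f, n_components = 4), "exceeds")
})

test_that("the ANN emits probabilities and learns separable data", {
  blobs <- make_blobs(20, 2, 2.5, seed = 16)
  net <- train_ann(blobs$x, blobs$y, hidden_units = 6, seed = 1)
  pred <- predict(net, blobs$x)
  expect_true(all(pred$prob > 0 & pred$prob < 1))
  expect_equal(mean(pred$labels == blobs$y), 1)   # positive control
  # determinism
  net2 <- train_ann(blobs$x, blobs$y, hidden_units = 6, seed = 1)
  expect_identical(net$W1, net2$W1)
  expect_error(train_ann(blobs$x, rep(1, 40)), "both classes")
  expect_error(predict(net, matrix(1, 1, 5)), "dimension")
})

test_that("EMG decoding segments trials correctly and detects planted bursts", {
  sch <- generate_schedule(20, seed = 8)
  emg <- simulate_emg(sch, sampling_hz = 500, burst_amplitude = 0, seed = 3)
  feats <- intentmvpa:::.emg_trial_features(
    gradient_artifact_correct(emg), sch, 240, 24)
  # 40-trial schedule: 40 intention segments and 3 x 40 imagery TR segments
  expect_equal(nrow(feats$intention$features), 40L)
  expect_equal(sum(vapply(paste0("imageryT", 1:3),
                          function(tp) nrow(feats[[tp]]$features),
                          numeric(1))), 120L)
  # planted laterality bursts are decoded near-perfectly
  sch2 <- generate_schedule(10, seed = 8)
  emg2 <- simulate_emg(sch2, sampling_hz = 500, burst_amplitude = 8,
                       noise_sd = 0.5, seed = 4)
  res <- emg_decode(emg2, sch2, seed = 1, timepoints = "intention")
  expect_gte(res$intention$mean, 90)
  expect_length(res$intention$fold_accuracies, 10L)
})

test_that("gaze decoding removes blinks and finds planted offsets", {
  sch <- generate_schedule(10, seed = 9)
  # two-point degenerate geometry: each class collapses to one position
  gz <- simulate_gaze(sch, drift_amplitude = 2, jitter_sd = 0,
                      blink_rate = 0, seed = 5)
  gz$data <- round(gz$data, 12)
  res <- eye_decode(gz, sch, seed = 1, timepoints = "intention")
  expect_equal(res$intention$mean, 100)
  # realistic positive control
  gz2 <- simulate_gaze(sch, drift_amplitude = 3, jitter_sd = 0.3, seed = 5)
  res2 <- eye_decode(gz2, sch, seed = 1, timepoints = "imageryT2")
  expect_gte(res2$imageryT2$mean, 95)
  # a trial whose TR contains no valid samples is dropped with a warning
  gz3 <- simulate_gaze(sch, seed = 6)
  occ <- schedule_to_labels(sch, 0L)
  t_int <- which(occ$condition == "intention")[1]
  gz3$valid[((t_int - 1) * 90 + 1):(t_int * 90)] <- FALSE
  expect_warning(res3 <- eye_decode(gz3, sch, seed = 1,
                                    timepoints = "intention"),
                 "dropped")
})
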