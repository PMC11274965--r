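toy_session <- function(noise_sd = 0, n_runs = 3L, seed = 42L) {
  cfg <- tiny_config(noise_sd = noise_sd, n_runs_per_hand = n_runs,
                     seed = seed)
  bold <- simulate_participant(cfg, 1)[[1]]
  list(cfg = cfg, bold = bold,
       labels = schedule_to_labels(bold$schedule, cfg$delay_trs))
}

test_that("block features average the delayed TRs of each block", {
  s <- toy_session()
  dat <- s$bold$data
  feats <- extract_condition_features(dat, s$labels, "fixation-vs-intention")
  # a 1-TR intention block's feature is that TR's voxel vector
  int_trs <- which(s$labels$usable & s$labels$condition == "intention")
  first_int_trial <- s$labels$trial_id[int_trs[1]]
  row <- which(feats$labels == -1 &
                 feats$trial_id == first_int_trial)
  expect_equal(feats$features[row, ], dat[int_trs[1], ])
  # labels: +1 = first condition named (fixation), -1 = second (intention)
  expect_equal(sum(feats$labels == 1), 6L)   # 6 fixation blocks
  expect_equal(sum(feats$labels == -1), 6L)
})

test_that("laterality features pick the single delayed timepoint TR", {
  sch <- generate_schedule(20, seed = 4)
  lab <- schedule_to_labels(sch, 2L)
  dat <- matrix(rnorm(n_trs(sch) * 5), n_trs(sch), 5)
  f <- extract_condition_features(dat, lab, "left-vs-right@intention")
  expect_equal(nrow(f$features), 40L)
  expect_equal(sum(f$labels == 1), 20L)  # left = +1
  expect_equal(sum(f$labels == -1), 20L)
  # noiseless: left and right imagery features differ by the planted pattern
  s <- toy_session()
  fi <- extract_condition_features(s$bold$data, s$labels,
                                   "left-vs-right@imageryT1")
  left <- fi$features[fi$labels == 1, , drop = FALSE]
  right <- fi$features[fi$labels == -1, , drop = FALSE]
  expect_equal(max(apply(left, 2, function(v) max(v) - min(v))), 0)
  expect_gt(sum(left[1, ] != right[1, ]), 0)
  expect_error(extract_condition_features(dat, lab, "left-vs-right@imageryT9"))
})

test_that("the linear SVM satisfies symmetry and duplication invariances", {
  # two mirrored 1D points: boundary at zero, both classified correctly
  s <- intentmvpa:::new_labeled_samples(matrix(c(-1, 1), 2, 1), c(-1, 1))
  m <- train_linear_svm(s)
  expect_equal(m$w0, 0, tolerance = 1e-8)
  expect_equal(predict_labels(m, s$features), s$labels)
  # duplicating every sample leaves the solution unchanged
  blobs <- make_blobs(10, 3, 1.5, seed = 1)
  s1 <- intentmvpa:::new_labeled_samples(blobs$x, blobs$y)
  s2 <- intentmvpa:::new_labeled_samples(rbind(blobs$x, blobs$x),
                                         c(blobs$y, blobs$y))
  m1 <- train_linear_svm(s1); m2 <- train_linear_svm(s2)
  expect_equal(m1$w, m2$w, tolerance = 1e-4)
  expect_error(train_linear_svm(
    intentmvpa:::new_labeled_samples(matrix(1:4, 2), c(1, 1))),
    "both classes")
})

test_that("SVM weights agree with an independent quadratic-program oracle", {
  blobs <- make_blobs(15, 4, 2, seed = 7)
  s <- intentmvpa:::new_labeled_samples(blobs$x, blobs$y)
  m <- train_linear_svm(s)
  qp <- oracle_svm_qp(blobs$x, blobs$y)
  cosine <- sum(m$w * qp$w) / sqrt(sum(m$w^2) * sum(qp$w^2))
  expect_gt(cosine, 0.999)
  expect_equal(m$w0, qp$w0, tolerance = 0.05)
})

test_that("decision values are the affine SVM output and antisymmetric", {
  m <- structure(list(w = c(1, -2, 0.5), w0 = 0.25, C = 1e5),
                 class = "linear_svm")
  x <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, -1, 4))
  expect_equal(decision_values(m, x), c(0.25, -0.25, 6.25))  # dot products
  expect_equal(decision_values(m, rep(0, 3)), m$w0)
  expect_error(decision_values(m, matrix(1, 1, 2)), "dimension")
  # swapping training labels flips the decision values
  blobs <- make_blobs(10, 3, 2, seed = 2)
  s <- intentmvpa:::new_labeled_samples(blobs$x, blobs$y)
  sflip <- intentmvpa:::new_labeled_samples(blobs$x, -blobs$y)
  dv <- decision_values(train_linear_svm(s), blobs$x)
  dvf <- decision_values(train_linear_svm(sflip), blobs$x)
  expect_equal(dv, -dvf, tolerance = 1e-5)
})

test_that("cross-validation is stratified, bounded and scheme-aware", {
  blobs <- make_blobs(20, 4, 3, seed = 3)
  s <- intentmvpa:::new_labeled_samples(blobs$x, blobs$y)
  cv <- cross_validate(s, "kfold4", seed = 1)
  expect_length(cv$fold_accuracies, 4L)
  expect_equal(cv$mean, 100)              # perfectly separable
  expect_equal(cv$sem, 0)
  loo <- cross_validate(s, "loo")
  expect_length(loo$fold_accuracies, 40L)
  expect_equal(loo$mean, 100)
  small <- intentmvpa:::new_labeled_samples(matrix(rnorm(12), 6),
                                            c(1, 1, 1, -1, -1, -1))
  expect_error(cross_validate(small, "kfold4"), "fold count")
})

test_that("accuracy is invariant to consistent relabeling and null voxels", {
  blobs <- make_blobs(12, 5, 1, seed = 4)
  s <- intentmvpa:::new_labeled_samples(blobs$x, blobs$y)
  sflip <- intentmvpa:::new_labeled_samples(blobs$x, -blobs$y)
  # folds are class-stratified, so flip folds match after relabeling
  a <- cross_validate(s, "loo")
  b <- cross_validate(sflip, "loo")
  expect_equal(a$fold_accuracies, b$fold_accuracies)
  # appending an all-zero (flagged-constant) voxel changes nothing
  szero <- intentmvpa:::new_labeled_samples(cbind(blobs$x, 0), blobs$y)
  expect_equal(cross_validate(szero, "loo")$mean, a$mean)
})

test_that("decoding recovers the planted amplitude ordering", {
  cfg <- tiny_config(n_participants = 2L, seed = 11L)
  cohort <- decode_cohort(cfg, contrasts = "left-vs-right@imageryT2",
                          rois = c("PPC", "DLPFC"), smoothing_fwhm_mm = 0)
  tab <- summarize_accuracy(cohort)
  acc <- setNames(tab$mean_acc, tab$roi)
  expect_gt(acc[["PPC"]], acc[["DLPFC"]])
  expect_gt(acc[["PPC"]], 80)
})
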