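#' Physiological control decoders
#'
#' Two control analyses verify that fMRI decoding is not driven by overt
#' muscle or eye activity: (1) EMG decoding — gradient-artifact template
#' subtraction, waveform-length features from a moving window, a
#' Karhunen-Loeve transform to principal-component space, and a
#' feed-forward neural network, validated with 10-fold cross-validation;
#' (2) gaze decoding — per-TR direct linear discriminant analysis of pupil
#' position, also 10-fold cross-validated. On real data both should sit at
#' chance; the synthetic generators provide null and positive controls.
#'
#' @name control_decoding
NULL

#' MR gradient-artifact correction by template subtraction
#'
#' The scanner's gradient switching contaminates simultaneous EMG with a
#' TR-periodic artifact. A template is formed by averaging the signal over
#' the first `n_template_trs` TR-long segments (per channel) and subtracted
#' from every TR segment. A perfectly TR-periodic artifact is removed
#' exactly.
#'
#' @param emg an `emg_recording`
#' @param n_template_trs number of TR segments averaged into the template
#' @return the corrected `emg_recording`
#' @export
gradient_artifact_correct <- function(emg, n_template_trs = 5L) {
  spt <- as.integer(round(emg$sampling_hz * emg$tr_seconds))
  n_seg <- ncol(emg$data) %/% spt
  if (n_seg < n_template_trs)
    stop("recording has fewer than ", n_template_trs, " complete TRs")
  for (ch in seq_len(nrow(emg$data))) {
    seg <- matrix(emg$data[ch, seq_len(n_seg * spt)], spt, n_seg)
    template <- rowMeans(seg[, seq_len(n_template_trs), drop = FALSE])
    emg$data[ch, seq_len(n_seg * spt)] <-
      as.vector(seg - template)
  }
  emg
}

#' Waveform length of an EMG segment over a moving window
#'
#' The signal is rectified (absolute value) and, within each window, the
#' absolute sample-to-sample differences are summed:
#' `WL = sum |x_k - x_(k-1)|` — a combined indicator of amplitude and
#' frequency. Windows of `window_ms` advance by `window_ms - overlap_ms`
#' (240 ms window, 24 ms overlap, hence 216 ms step by default); a partial
#' trailing window is discarded.
#'
#' @param x numeric vector, one channel's samples within a segment
#' @param sampling_hz sampling rate
#' @param window_ms window length in ms
#' @param overlap_ms overlap between successive windows in ms
#' @return numeric vector of per-window WL values (all >= 0)
#' @export
waveform_length <- function(x, sampling_hz, window_ms = 240,
                            overlap_ms = 24) {
  w <- as.integer(round(window_ms / 1000 * sampling_hz))
  step <- w - as.integer(round(overlap_ms / 1000 * sampling_hz))
  if (step < 1L) stop("overlap must be shorter than the window")
  if (w > length(x)) stop("window longer than the segment")
  xr <- abs(x)
  starts <- seq(1L, length(x) - w + 1L, by = step)
  vapply(starts, function(s) sum(abs(diff(xr[s:(s + w - 1L)]))), numeric(1))
}

#' Karhunen-Loeve transform (principal-component projection)
#'
#' Mean-centred projection onto the eigenvectors of the feature covariance,
#' ordered by decreasing eigenvalue, with an orthonormal basis. Either a
#' fixed number of components or enough to explain `var_explained` of the
#' total variance is retained.
#'
#' @param features trial x feature matrix (>= 2 trials)
#' @param n_components number of components to keep; `NULL` selects by
#'   `var_explained`
#' @param var_explained fraction of variance to retain when `n_components`
#'   is `NULL` (default 0.95)
#' @return list with `scores` (trial x k), `basis` (feature x k,
#'   orthonormal), `center`, `eigenvalues` (all, decreasing)
#' @export
klt <- function(features, n_components = NULL, var_explained = 0.95) {
  stopifnot(nrow(features) >= 2L)
  if (!is.null(n_components) && n_components > ncol(features))
    stop("n_components exceeds the feature dimension")
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- if (!is.null(n_components)) as.integer(n_components)
       else max(1L, which(cumsum(ev) / sum(ev) >= var_explained)[1L])
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       basis = pc$rotation[, seq_len(k), drop = FALSE],
       center = pc$center, eigenvalues = ev)
}

# ---- feed-forward ANN (tanh hidden layer, sigmoid outputs) ----

.ann_unpack <- function(theta, d, h) {
  n1 <- h * (d + 1L)
  list(W1 = matrix(theta[seq_len(n1)], h, d + 1L),
       W2 = matrix(theta[-seq_len(n1)], 2L, h + 1L))
}

.ann_forward <- function(W1, W2, X) {
  Z1 <- tanh(W1 %*% rbind(t(X), 1))            # h x n
  O <- 1 / (1 + exp(-(W2 %*% rbind(Z1, 1))))   # 2 x n
  list(Z1 = Z1, O = O)
}

# cross-entropy loss and analytic gradient over the packed parameters
.ann_obj <- function(theta, X, T2, d, h) {
  p <- .ann_unpack(theta, d, h)
  f <- .ann_forward(p$W1, p$W2, X)
  O <- pmin(pmax(f$O, 1e-12), 1 - 1e-12)
  -sum(T2 * log(O) + (1 - T2) * log(1 - O)) / ncol(T2)
}

.ann_grad <- function(theta, X, T2, d, h) {
  p <- .ann_unpack(theta, d, h)
  f <- .ann_forward(p$W1, p$W2, X)
  n <- ncol(T2)
  dO <- (f$O - T2) / n                          # 2 x n
  gW2 <- dO %*% t(rbind(f$Z1, 1))
  dZ1 <- (t(p$W2[, seq_len(h), drop = FALSE]) %*% dO) * (1 - f$Z1^2)
  gW1 <- dZ1 %*% t(rbind(t(X), 1))
  c(as.vector(gW1), as.vector(gW2))
}

#' Train a feed-forward neural-network classifier
#'
#' One hidden layer with a tan-sigmoid (tanh) transfer function and two
#' log-sigmoid output units, one per movement class, each reporting a
#' probability in (0, 1); the predicted class is the output with the higher
#' probability. Training minimizes cross-entropy by quasi-Newton batch
#' updates in epochs, with early stopping on a held-out validation split
#' (20%) to improve generalization. Deterministic given `seed`.
#'
#' @param features trial x feature matrix
#' @param labels vector in {-1, +1} (+1 is class 1)
#' @param hidden_units hidden-layer size (default 10)
#' @param seed integer seed (weight init and validation split)
#' @param max_epochs optimizer iteration budget
#' @param patience consecutive validation-loss increases tolerated before
#'   stopping
#' @return an `ann_classifier`
#' @export
train_ann <- function(features, labels, hidden_units = 10L, seed = 1L,
                      max_epochs = 200L, patience = 2L) {
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("training requires samples from both classes")
  X <- as.matrix(features)
  d <- ncol(X); h <- as.integer(hidden_units)
  T2 <- rbind(as.numeric(labels == 1), as.numeric(labels == -1))
  n <- nrow(X)
  init <- local_seed(seed, {
    theta <- stats::rnorm(h * (d + 1L) + 2L * (h + 1L), sd = 0.5)
    val <- sample(n, size = max(1L, floor(0.2 * n)))
    list(theta = theta, val = val)
  })
  val <- init$val; trn <- setdiff(seq_len(n), val)
  theta <- init$theta
  chunk <- 20L
  best <- list(theta = theta, loss = Inf)
  worse <- 0L
  for (ep in seq_len(ceiling(max_epochs / chunk))) {
    fit <- stats::optim(theta, .ann_obj, .ann_grad, method = "BFGS",
                        X = X[trn, , drop = FALSE],
                        T2 = T2[, trn, drop = FALSE], d = d, h = h,
                        control = list(maxit = chunk))
    theta <- fit$par
    vloss <- .ann_obj(theta, X[val, , drop = FALSE],
                      T2[, val, drop = FALSE], d, h)
    if (vloss < best$loss) {
      best <- list(theta = theta, loss = vloss); worse <- 0L
    } else {
      worse <- worse + 1L
      if (worse >= patience) break
    }
    if (fit$convergence == 0) break
  }
  p <- .ann_unpack(best$theta, d, h)
  structure(list(W1 = p$W1, W2 = p$W2, hidden_units = h,
                 input_dim = d, seed = seed),
            class = "ann_classifier")
}

#' Class probabilities and predictions from a trained ANN
#'
#' @param object an `ann_classifier`
#' @param newdata trial x feature matrix
#' @param ... unused
#' @return list with `prob` (trial x 2 matrix, columns class +1 / -1) and
#'   `labels` (+1 / -1, highest probability wins)
#' @export
predict.ann_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$input_dim)
    stop("feature dimension does not match the network")
  O <- .ann_forward(object$W1, object$W2, X)$O
  # keep reported probabilities strictly inside (0, 1) even when the
  # sigmoid saturates in double precision
  O <- pmin(pmax(O, 1e-12), 1 - 1e-12)
  list(prob = t(O), labels = ifelse(O[1, ] >= O[2, ], 1, -1))
}

# stratified fold ids for a +/-1 label vector
.stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  local_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# segment trials of an EMG recording into per-TR feature vectors;
# returns per contrast a list(features, labels)
.emg_trial_features <- function(emg, schedule, window_ms, overlap_ms) {
  spt <- as.integer(round(emg$sampling_hz * emg$tr_seconds))
  occ <- schedule_to_labels(schedule, delay_trs = 0L)
  n_seg <- ncol(emg$data) %/% spt
  if (n_seg < n_trs(schedule))
    stop("EMG recording does not cover the schedule")
  seg_features <- function(t) {
    cols <- ((t - 1L) * spt + 1L):(t * spt)
    unlist(lapply(seq_len(nrow(emg$data)), function(ch)
      waveform_length(emg$data[ch, cols], emg$sampling_hz,
                      window_ms, overlap_ms)))
  }
  out <- list()
  for (tp in c("intention", paste0("imageryT", 1:3))) {
    cond <- if (tp == "intention") "intention" else "imagery"
    btr <- if (tp == "intention") 1L else as.integer(sub("imageryT", "", tp))
    trs <- which(occ$condition == cond & occ$block_tr == btr &
                   occ$laterality %in% c("left", "right"))
    if (length(trs) == 0L) next
    feats <- do.call(rbind, lapply(trs, seg_features))
    out[[tp]] <- list(features = feats,
                      labels = ifelse(occ$laterality[trs] == "left", 1, -1))
  }
  out
}

#' EMG decoding of trial laterality
#'
#' The full EMG control chain: gradient-artifact template subtraction,
#' per-TR trial segmentation (intention = 1 TR; imagery = 3 per-TR
#' segments), waveform-length features per channel and window,
#' Karhunen-Loeve transform, and a feed-forward ANN evaluated with 10-fold
#' cross-validation, per timepoint.
#'
#' @param emg an `emg_recording` aligned with `schedule`
#' @param schedule the `event_schedule` of the session
#' @param seed integer seed (folds and network initialization)
#' @param timepoints subset of `c("intention", "imageryT1", "imageryT2",
#'   "imageryT3")`
#' @param window_ms,overlap_ms waveform-length window parameters
#' @param hidden_units ANN hidden-layer size
#' @return named list of `cv_result`, one per timepoint
#' @export
emg_decode <- function(emg, schedule, seed = 1L,
                       timepoints = c("intention", "imageryT1",
                                      "imageryT2", "imageryT3"),
                       window_ms = 240, overlap_ms = 24,
                       hidden_units = 10L) {
  emg <- gradient_artifact_correct(emg)
  all_feats <- .emg_trial_features(emg, schedule, window_ms, overlap_ms)
  out <- list()
  for (tp in intersect(timepoints, names(all_feats))) {
    fl <- all_feats[[tp]]
    kl <- klt(fl$features)
    folds <- .stratified_folds(fl$labels, 10L, seed)
    acc <- vapply(1:10, function(f) {
      test <- folds == f
      net <- train_ann(kl$scores[!test, , drop = FALSE],
                       fl$labels[!test],
                       hidden_units = hidden_units,
                       seed = seed + 31L * f)
      pred <- predict(net, kl$scores[test, , drop = FALSE])$labels
      100 * mean(pred == fl$labels[test])
    }, numeric(1))
    out[[tp]] <- new_cv_result(acc, "kfold10",
                               contrast = paste0("left-vs-right@", tp),
                               roi = "EMG")
  }
  out
}

# direct LDA prediction; degenerate training sets (a variable constant
# within groups, e.g. each class collapsed to one point) fall back to the
# nearest-class-mean rule, which is the LDA limit for vanishing
# within-class covariance
.lda_predict <- function(xtr, ytr, xte) {
  pred <- tryCatch({
    fit <- MASS::lda(xtr, grouping = factor(ytr, levels = c(1, -1)))
    as.numeric(as.character(stats::predict(fit, xte)$class))
  }, error = function(e) NULL)
  if (!is.null(pred)) return(pred)
  mu1 <- colMeans(xtr[ytr == 1, , drop = FALSE])
  mu2 <- colMeans(xtr[ytr == -1, , drop = FALSE])
  d1 <- rowSums(sweep(xte, 2L, mu1)^2)
  d2 <- rowSums(sweep(xte, 2L, mu2)^2)
  ifelse(d1 <= d2, 1, -1)
}

# per-TR mean gaze position with blink and outlier removal
.gaze_tr_features <- function(gaze) {
  spt <- as.integer(round(gaze$sampling_hz * gaze$tr_seconds))
  xy <- gaze$data
  valid <- gaze$valid
  for (ax in 1:2) {
    med <- stats::median(xy[valid, ax])
    madv <- stats::mad(xy[valid, ax])
    if (madv > 0)
      valid <- valid & abs(xy[, ax] - med) <= 3 * madv
  }
  t(vapply(seq_len(gaze$n_trs), function(t) {
    rows <- ((t - 1L) * spt + 1L):(t * spt)
    v <- rows[valid[rows]]
    if (length(v) == 0L) return(c(NA_real_, NA_real_))
    colMeans(xy[v, , drop = FALSE])
  }, numeric(2)))
}

#' Gaze decoding of trial laterality by per-TR discriminant analysis
#'
#' After blink and outlier removal (invalid samples plus points beyond
#' median +/- 3 MAD per axis), each TR is summarized by its mean pupil
#' position (x, y). For each timepoint a direct linear discriminant
#' analysis — all variables entered together — is evaluated with 10-fold
#' cross-validation, giving a mean and standard error per TR. Trials whose
#' TR has no valid sample are dropped with a warning.
#'
#' @param gaze a `gaze_recording` covering the schedule
#' @param schedule the `event_schedule` of the session
#' @param seed integer seed for fold assignment
#' @param timepoints subset of `c("intention", "imageryT1", "imageryT2",
#'   "imageryT3")`
#' @return named list of `cv_result`, one per timepoint
#' @export
eye_decode <- function(gaze, schedule, seed = 1L,
                       timepoints = c("intention", "imageryT1",
                                      "imageryT2", "imageryT3")) {
  feats <- .gaze_tr_features(gaze)
  occ <- schedule_to_labels(schedule, delay_trs = 0L)
  out <- list()
  for (tp in timepoints) {
    cond <- if (tp == "intention") "intention" else "imagery"
    btr <- if (tp == "intention") 1L else as.integer(sub("imageryT", "", tp))
    trs <- which(occ$condition == cond & occ$block_tr == btr &
                   occ$laterality %in% c("left", "right"))
    if (length(trs) == 0L) next
    x <- feats[trs, , drop = FALSE]
    y <- ifelse(occ$laterality[trs] == "left", 1, -1)
    bad <- !stats::complete.cases(x)
    if (any(bad)) {
      warning(sum(bad), " trial(s) dropped at ", tp,
              ": no valid gaze samples in the TR")
      x <- x[!bad, , drop = FALSE]; y <- y[!bad]
    }
    folds <- .stratified_folds(y, 10L, seed)
    acc <- vapply(1:10, function(f) {
      test <- folds == f
      pred <- .lda_predict(x[!test, , drop = FALSE], y[!test],
                           x[test, , drop = FALSE])
      100 * mean(pred == y[test])
    }, numeric(1))
    out[[tp]] <- new_cv_result(acc, "kfold10",
                               contrast = paste0("left-vs-right@", tp),
                               roi = "gaze")
  }
  out
}
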