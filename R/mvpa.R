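#' Linear SVM decoding of ROI activity patterns
#'
#' Trial features are built from z-normalized BOLD using the delayed per-TR
#' labels, a soft-margin linear SVM is trained at a fixed large
#' regularization constant (C = 1e5, approximating a hard margin on z-scored
#' features), and accuracy is estimated by stratified cross-validation.
#'
#' @name mvpa_decoding
NULL

.CONTRASTS <- c("fixation-vs-intention", "intention-vs-imagery",
                "left-vs-right@intention", "left-vs-right@imageryT1",
                "left-vs-right@imageryT2", "left-vs-right@imageryT3")

new_labeled_samples <- function(features, labels, trial_id = NULL,
                                session = NULL, contrast = NULL) {
  stopifnot(nrow(features) == length(labels), all(labels %in% c(-1, 1)))
  structure(list(features = features, labels = labels,
                 trial_id = trial_id, session = session,
                 contrast = contrast),
            class = "labeled_samples")
}

#' @export
print.labeled_samples <- function(x, ...) {
  cat("<labeled_samples>", nrow(x$features), "samples x",
      ncol(x$features), "features;",
      sum(x$labels == 1), "(+1) /", sum(x$labels == -1), "(-1)",
      if (!is.null(x$contrast)) paste0("[", x$contrast, "]"), "\n")
  invisible(x)
}

# mean of the delayed TRs of one block; rows = usable TR indices
.block_rows <- function(labels, condition, trial) {
  which(labels$usable & !is.na(labels$condition) &
          labels$condition == condition & labels$trial_id == trial)
}

#' Build trial features for a decoding contrast
#'
#' For the block-level condition contrasts (fixation vs. intention,
#' intention vs. imagery) each block contributes one sample: the mean over
#' its delayed TRs. For the per-timepoint laterality contrasts each trial
#' contributes the single delayed TR of the named timepoint (intention TR,
#' or imagery T1/T2/T3). Design labels: +1 for the first condition named in
#' the contrast, -1 for the second (left = +1 for laterality contrasts).
#'
#' @param data TR x voxel matrix of (normalized) values
#' @param labels a `tr_labels` object from [schedule_to_labels()]
#' @param contrast one of `"fixation-vs-intention"`,
#'   `"intention-vs-imagery"`, `"left-vs-right@intention"`,
#'   `"left-vs-right@imageryT1"` / `"...T2"` / `"...T3"`
#' @param session optional session tag stored per sample
#' @return a `labeled_samples` object
#' @export
extract_condition_features <- function(data, labels, contrast,
                                       session = NULL) {
  contrast <- match.arg(contrast, .CONTRASTS)
  stopifnot(nrow(data) == nrow(labels))
  ok <- labels$usable & !is.na(labels$condition)
  if (startsWith(contrast, "left-vs-right")) {
    at <- sub("left-vs-right@", "", contrast)
    cond <- if (at == "intention") "intention" else "imagery"
    btr <- if (at == "intention") 1L
           else as.integer(sub("imageryT", "", at))
    sel <- ok & labels$condition == cond & labels$block_tr == btr &
      labels$laterality %in% c("left", "right")
    if (!any(sel)) stop("no eligible trials for contrast ", contrast)
    feats <- data[sel, , drop = FALSE]
    y <- ifelse(labels$laterality[sel] == "left", 1, -1)
    trials <- labels$trial_id[sel]
  } else {
    pair <- strsplit(contrast, "-vs-")[[1L]]
    rows_list <- list(); y <- numeric(); trials <- integer()
    for (ci in 1:2) {
      cnd <- pair[ci]
      tr_ids <- unique(labels$trial_id[ok & labels$condition == cnd])
      for (tid in tr_ids) {
        r <- .block_rows(labels, cnd, tid)
        rows_list[[length(rows_list) + 1L]] <-
          colMeans(data[r, , drop = FALSE])
        y <- c(y, if (ci == 1L) 1 else -1)
        trials <- c(trials, tid)
      }
    }
    if (length(y) == 0L) stop("no eligible trials for contrast ", contrast)
    feats <- do.call(rbind, rows_list)
  }
  sess <- if (is.null(session)) NULL else rep(session, length(y))
  new_labeled_samples(feats, y, trial_id = trials, session = sess,
                      contrast = contrast)
}

#' Pool labeled samples across sessions
#' @param ... `labeled_samples` objects (or a single list of them)
#' @return one pooled `labeled_samples`
#' @export
pool_samples <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1L]], "labeled_samples"))
    parts <- parts[[1L]]
  new_labeled_samples(
    do.call(rbind, lapply(parts, `[[`, "features")),
    unlist(lapply(parts, `[[`, "labels")),
    trial_id = unlist(lapply(parts, `[[`, "trial_id")),
    session = unlist(lapply(parts, `[[`, "session")),
    contrast = parts[[1L]]$contrast)
}

#' Train a soft-margin linear SVM
#'
#' Minimizes `0.5*||w||^2 + C * sum(hinge)` on the given samples (libsvm
#' backend). The fixed default `C = 1e5` removes dependence of accuracy on
#' the regularization constant; on z-scored features it approximates the
#' hard-margin solution.
#'
#' @param samples a `labeled_samples` object (both classes present)
#' @param C positive regularization constant
#' @return a `linear_svm`: list with weight vector `w`, bias `w0`, `C`
#' @export
train_linear_svm <- function(samples, C = 1e5) {
  y <- samples$labels
  if (length(unique(y)) < 2L)
    stop("training requires samples from both classes")
  x <- samples$features
  fit <- e1071::svm(x, factor(y, levels = c(1, -1)), kernel = "linear",
                    cost = C, scale = FALSE)
  w <- unname(drop(t(fit$coefs) %*% fit$SV))
  w0 <- -fit$rho
  # libsvm orients the decision value to whichever class appears first in
  # the training data; the column name ("1/-1" or "-1/1") records it
  dv <- attr(stats::predict(fit, x[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  positive_class <- strsplit(colnames(dv), "/", fixed = TRUE)[[1L]][1L]
  if (positive_class == "-1") { w <- -w; w0 <- -w0 }
  structure(list(w = w, w0 = w0, C = C), class = "linear_svm")
}

#' SVM decision values (continuous output, sign not taken)
#' @param model a `linear_svm`
#' @param features sample x voxel matrix (or single vector)
#' @return numeric vector `w'x + w0`
#' @export
decision_values <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != length(model$w))
    stop("feature dimension does not match the model")
  drop(features %*% model$w + model$w0)
}

#' Predicted class labels (+1 / -1); ties at 0 classify as +1
#' @param model a `linear_svm`
#' @param features sample x voxel matrix
#' @return numeric vector of +1 / -1
#' @export
predict_labels <- function(model, features) {
  ifelse(decision_values(model, features) >= 0, 1, -1)
}

# deterministic stratified fold assignment; groups by session when the
# session tags partition evenly into the folds (avoids leakage)
.make_folds <- function(samples, k, seed) {
  n <- length(samples$labels)
  sess <- samples$session
  if (!is.null(sess) && length(unique(sess)) == k)
    return(as.integer(factor(sess)))
  folds <- integer(n)
  local_seed(seed, {
    for (cls in c(1, -1)) {
      idx <- sample(which(samples$labels == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

new_cv_result <- function(fold_acc, scheme, contrast = NULL, roi = NULL) {
  m <- mean(fold_acc)
  sem <- if (length(fold_acc) > 1L)
    stats::sd(fold_acc) / sqrt(length(fold_acc)) else 0
  structure(list(fold_accuracies = fold_acc, mean = m, sem = sem,
                 scheme = scheme, contrast = contrast, roi = roi),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s%s: %.1f%% (SEM %.1f) over %d folds [%s]\n",
              if (is.null(x$roi)) "" else paste0(x$roi, " "),
              if (is.null(x$contrast)) "" else x$contrast,
              x$mean, x$sem, length(x$fold_accuracies), x$scheme))
  invisible(x)
}

#' Cross-validated linear-SVM decoding accuracy
#'
#' Folds are stratified by class (and grouped by session when the session
#' tags partition exactly into the folds). Accuracy is the percentage of
#' held-out samples whose decision-value sign matches the design label.
#'
#' @param samples a `labeled_samples` object
#' @param scheme `"kfold4"`, `"kfold10"` or `"loo"` (leave-one-out)
#' @param seed integer seed for fold assignment
#' @param C SVM regularization constant
#' @return a `cv_result`: per-fold accuracies (%), `mean`, `sem`
#' @export
cross_validate <- function(samples, scheme = c("kfold4", "loo", "kfold10"),
                           seed = 1L, C = 1e5) {
  scheme <- match.arg(scheme)
  n <- length(samples$labels)
  k <- switch(scheme, kfold4 = 4L, kfold10 = 10L, loo = n)
  per_class <- min(table(samples$labels))
  if (scheme != "loo" && k > per_class)
    stop("fold count exceeds available samples per class")
  folds <- if (scheme == "loo") seq_len(n)
           else .make_folds(samples, k, seed)
  acc <- vapply(seq_len(k), function(f) {
    test <- folds == f
    train <- new_labeled_samples(
      samples$features[!test, , drop = FALSE], samples$labels[!test])
    model <- train_linear_svm(train, C = C)
    pred <- predict_labels(model, samples$features[test, , drop = FALSE])
    100 * mean(pred == samples$labels[test])
  }, numeric(1))
  new_cv_result(acc, scheme, contrast = samples$contrast)
}

#' Decode every contrast in every ROI for a cohort of participants
#'
#' Runs the standard pipeline per participant: spatial smoothing, ROI
#' masking, z-normalization, feature extraction with the hemodynamic delay,
#' and stratified 4-fold cross-validation; accuracies are then averaged
#' across participants. This is the workhorse behind the summary tables.
#'
#' @param config a [simulation_config()]
#' @param contrasts character vector of contrast names (default: all six)
#' @param rois character vector of parcel names (default: all eight)
#' @param smoothing_fwhm_mm preprocessing smoothing FWHM (default 8 mm; 0
#'   disables)
#' @param scheme cross-validation scheme
#' @param seed seed for fold assignment (defaults to the config seed)
#' @return a data.frame with one row per (roi, contrast, participant) plus
#'   class `cohort_decoding`; see [summarize_accuracy()]
#' @export
decode_cohort <- function(config, contrasts = .CONTRASTS,
                          rois = names(config_roi_masks(config)),
                          smoothing_fwhm_mm = 8, scheme = "kfold4",
                          seed = config$seed) {
  masks <- config_roi_masks(config)[rois]
  rows <- list()
  for (p in seq_len(config$n_participants)) {
    sessions <- simulate_participant(config, p)
    # preprocess once per session: smooth, then per-ROI mask + z-normalize
    roi_samples <- list()
    for (bold in sessions) {
      if (smoothing_fwhm_mm > 0) bold <- smooth_bold(bold, smoothing_fwhm_mm)
      labels <- schedule_to_labels(bold$schedule, config$delay_trs)
      for (rn in rois) {
        z <- z_normalize(apply_mask(bold$data, masks[[rn]]))
        for (ct in contrasts) {
          s <- extract_condition_features(z, labels, ct,
                                          session = bold$session)
          key <- paste(rn, ct, sep = "|")
          roi_samples[[key]] <- c(roi_samples[[key]], list(s))
        }
      }
    }
    for (key in names(roi_samples)) {
      pooled <- pool_samples(roi_samples[[key]])
      parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
      cv <- cross_validate(pooled, scheme = scheme,
                           seed = seed + 13L * p)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, roi = parts[1L], contrast = parts[2L],
        mean_acc = cv$mean, sem = cv$sem,
        n_folds = length(cv$fold_accuracies),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_decoding", "data.frame")
  out
}

#' Summarize cohort decoding as an accuracy table
#'
#' Averages per-participant cross-validated accuracies into one mean and
#' standard error of the mean per (ROI, contrast) cell, the layout of the
#' published accuracy tables. The SEM unit of replication is participants x
#' folds pooled.
#'
#' @param cohort output of [decode_cohort()]
#' @return data.frame with columns `roi`, `contrast`, `mean_acc`, `sem`,
#'   `n_participants`
#' @export
summarize_accuracy <- function(cohort) {
  agg <- stats::aggregate(mean_acc ~ roi + contrast, data = cohort,
                          FUN = mean)
  sem <- stats::aggregate(mean_acc ~ roi + contrast, data = cohort,
                          FUN = function(v)
                            if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                            else 0)
  n <- stats::aggregate(mean_acc ~ roi + contrast, data = cohort,
                        FUN = length)
  out <- agg
  names(out)[3L] <- "mean_acc"
  out$sem <- sem$mean_acc
  out$n_participants <- n$mean_acc
  out[order(out$contrast, -out$mean_acc), ]
}
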