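# Independent oracles used across the suite. Each re-derives a quantity by
# the most direct route available (brute force, enumeration, closed form)
# and never calls the code path it checks.

# direct-space 3D Gaussian convolution by triple loop, mirror boundary
oracle_conv3d <- function(vol, fwhm_mm, voxel_size_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  d <- dim(vol)
  kern1d <- function(s) {
    if (s <= 0) return(1)
    r <- max(1L, ceiling(4 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k / sum(k)
  }
  kx <- kern1d(sigma[1]); ky <- kern1d(sigma[2]); kz <- kern1d(sigma[3])
  rx <- (length(kx) - 1L) / 2L; ry <- (length(ky) - 1L) / 2L
  rz <- (length(kz) - 1L) / 2L
  mirror <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 2L - i
      if (i > n) i <- 2L * n - i
    }
    i
  }
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (a in seq_along(kx)) for (b in seq_along(ky)) for (cc in seq_along(kz)) {
      ii <- mirror(i + a - rx - 1L, d[1])
      jj <- mirror(j + b - ry - 1L, d[2])
      kk <- mirror(k + cc - rz - 1L, d[3])
      acc <- acc + kx[a] * ky[b] * kz[cc] * vol[ii, jj, kk]
    }
    out[i, j, k] <- acc
  }
  out
}

# mutual information as the relative-entropy double sum, in bits
oracle_mi_doublesum <- function(joint) {
  px <- rowSums(joint); py <- colSums(joint)
  acc <- 0
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
    p <- joint[i, j]
    if (p > 0) acc <- acc + p * log2(p / (px[i] * py[j]))
  }
  acc
}

# soft-margin linear SVM by the dual quadratic program (kernlab::ipop)
oracle_svm_qp <- function(x, y, C = 1e5) {
  n <- nrow(x)
  Q <- (y %o% y) * tcrossprod(x) + diag(1e-10, n)
  sol <- kernlab::ipop(c = rep(-1, n), H = Q, A = t(y), b = 0, r = 0,
                       l = rep(0, n), u = rep(C, n), maxiter = 300)
  a <- kernlab::primal(sol)
  w <- drop(t(a * y) %*% x)
  sv <- which(a > 1e-6 * max(a) & a < C * (1 - 1e-6))
  w0 <- if (length(sv)) mean(y[sv] - x[sv, , drop = FALSE] %*% w) else NA_real_
  list(w = w, w0 = w0, alpha = a)
}

# sliding-window start positions under the documented step rule
oracle_window_starts <- function(n_samples, window, step) {
  starts <- integer(0)
  s <- 1L
  while (s + window - 1L <= n_samples) {
    starts <- c(starts, s)
    s <- s + step
  }
  starts
}

# waveform length by direct summation on the rectified trace
oracle_wl <- function(x, window, step) {
  xr <- abs(x)
  vapply(oracle_window_starts(length(x), window, step), function(s) {
    seg <- xr[s:(s + window - 1L)]
    sum(abs(seg[-1] - seg[-length(seg)]))
  }, numeric(1))
}

# per-TR block occupancy by direct enumeration (no vectorized tricks)
oracle_occupancy <- function(blocks) {
  total <- sum(blocks$duration_trs)
  cond <- character(total); lat <- character(total); trial <- integer(total)
  for (b in seq_len(nrow(blocks))) {
    for (t in seq_len(blocks$duration_trs[b])) {
      idx <- blocks$onset_tr[b] + t
      cond[idx] <- blocks$condition[b]
      lat[idx] <- blocks$laterality[b]
      trial[idx] <- blocks$trial_id[b]
    }
  }
  data.frame(condition = cond, laterality = lat, trial_id = trial,
             stringsAsFactors = FALSE)
}

# small signal-bearing configuration for fast pipeline tests
tiny_config <- function(n_participants = 1L, seed = 42L, noise_sd = 1.0,
                        amplitude_scale = 1.0, n_runs_per_hand = 10L) {
  simulation_config(n_participants = n_participants,
                    n_runs_per_hand = n_runs_per_hand,
                    roi_specs = default_roi_specs(amplitude_scale),
                    noise_sd = noise_sd, seed = seed)
}

# two-class Gaussian blobs, linearly separable when delta is large
make_blobs <- function(n_per_class, p, delta, seed) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p, delta), n_per_class),
             matrix(rnorm(n_per_class * p, -delta), n_per_class))
  list(x = x, y = rep(c(1, -1), each = n_per_class))
}
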