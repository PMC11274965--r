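#' Voxelwise z-normalization of a BOLD time series
#'
#' Each voxel's time series is centred and scaled to unit standard deviation
#' over the time axis of one participant's session. The standard deviation
#' uses the population convention (divide by N) throughout this package.
#' Voxels with zero temporal variance are set to all-zeros and flagged, so
#' downstream classifiers ignore them.
#'
#' @param data TR x voxel numeric matrix (or a `bold_dataset`, whose data
#'   slot is normalized in place)
#' @return for a matrix: a matrix of z-values with attribute
#'   `constant_voxels` (logical per voxel); for a `bold_dataset`: the dataset
#'   with normalized data
#' @export
z_normalize <- function(data) {
  if (inherits(data, "bold_dataset")) {
    data$data <- z_normalize(data$data)
    return(data)
  }
  if (!is.matrix(data)) data <- as.matrix(data)
  if (nrow(data) < 2L) stop("z_normalize needs at least 2 TRs")
  mu <- colMeans(data)
  sd_pop <- sqrt(colMeans(sweep(data, 2L, mu)^2))
  constant <- sd_pop == 0
  scl <- ifelse(constant, 1, sd_pop)
  z <- sweep(sweep(data, 2L, mu), 2L, scl, "/")
  z[, constant] <- 0
  structure(z, constant_voxels = constant)
}

.fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# 1D Gaussian convolution matrix with mirror (reflect) padding,
# sigma in voxel units; rows sum to 1 so the volume mean is preserved.
.smooth_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  radius <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- k / sum(k)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq(-radius, radius)) {
      idx <- i + j
      # mirror boundary: reflect about the edges (no repeated edge sample)
      while (idx < 1L || idx > n) {
        if (idx < 1L) idx <- 2L - idx
        if (idx > n) idx <- 2L * n - idx
      }
      S[i, idx] <- S[i, idx] + k[j + radius + 1L]
    }
  }
  S
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' Convolves with an axis-separable Gaussian kernel whose full width at half
#' maximum is given in millimetres per axis; the kernel standard deviation
#' per axis is `fwhm / (2*sqrt(2*log(2))) / voxel_size` in voxel units.
#' Boundaries use mirror padding, which preserves the local mean near edges.
#'
#' @param volume 3D numeric array
#' @param fwhm_mm FWHM in mm, scalar or length-3
#' @param voxel_size_mm voxel edge lengths in mm, scalar or length-3
#' @return smoothed 3D array of the same shape
#' @export
gaussian_smooth <- function(volume, fwhm_mm, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(length(dim(volume)) == 3L)
  if (any(fwhm_mm < 0)) stop("fwhm_mm must be non-negative")
  fwhm <- rep_len(fwhm_mm, 3L)
  vox <- rep_len(voxel_size_mm, 3L)
  sigma <- .fwhm_to_sigma(fwhm) / vox
  d <- dim(volume)
  out <- volume
  # axis 1
  if (sigma[1] > 0) {
    S <- .smooth_matrix(d[1], sigma[1])
    out <- array(S %*% matrix(out, d[1]), d)
  }
  # axis 2: permute to front
  if (sigma[2] > 0) {
    S <- .smooth_matrix(d[2], sigma[2])
    out <- aperm(array(S %*% matrix(aperm(out, c(2, 1, 3)), d[2]),
                       d[c(2, 1, 3)]), c(2, 1, 3))
  }
  # axis 3
  if (sigma[3] > 0) {
    S <- .smooth_matrix(d[3], sigma[3])
    out <- aperm(array(S %*% matrix(aperm(out, c(3, 1, 2)), d[3]),
                       d[c(3, 1, 2)]), c(2, 3, 1))
  }
  out
}

#' Smooth every volume of a 4D BOLD dataset
#'
#' @param bold a `bold_dataset`
#' @param fwhm_mm FWHM in mm (scalar or per-axis)
#' @return the dataset with each TR volume smoothed
#' @export
smooth_bold <- function(bold, fwhm_mm) {
  grid <- bold$grid
  vox <- bold$voxel_size_mm
  for (t in seq_len(nrow(bold$data))) {
    vol <- array(bold$data[t, ], grid)
    bold$data[t, ] <- as.vector(gaussian_smooth(vol, fwhm_mm, vox))
  }
  bold
}

#' Extract in-mask voxels from a TR x voxel matrix
#'
#' Voxel order within the mask is row-major over (x, y, z) — i.e. the order
#' of `which(mask)` on an array stored in R's column-major layout, which is
#' the fixed, documented convention used everywhere in this package.
#'
#' @param data TR x voxel matrix whose columns enumerate the full grid
#' @param mask a `roi_mask` or logical 3D array with `prod(dim)` equal to
#'   `ncol(data)`
#' @return TR x n_masked matrix with attribute `voxel_index` (grid indices)
#' @export
apply_mask <- function(data, mask) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!is.logical(m)) stop("mask must be logical")
  if (prod(dim(m)) != ncol(data))
    stop("mask shape does not match the voxel grid")
  idx <- which(m)
  if (length(idx) == 0L) stop("mask selects no voxels (empty ROI)")
  out <- data[, idx, drop = FALSE]
  attr(out, "voxel_index") <- idx
  out
}

#' Place masked values back onto the full grid
#'
#' Inverse of [apply_mask()] for a single per-voxel vector: out-of-mask
#' voxels are filled with `fill`.
#'
#' @param values numeric vector, one value per in-mask voxel
#' @param mask a `roi_mask` or logical 3D array
#' @param fill value for voxels outside the mask (default 0)
#' @return 3D array of `dim(mask)`
#' @export
unmask <- function(values, mask, fill = 0) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  idx <- which(m)
  if (length(idx) != length(values))
    stop("length(values) does not match the mask voxel count")
  out <- array(fill, dim(m))
  out[idx] <- values
  out
}
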