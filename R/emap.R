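#' Effect mapping: normalized-mutual-information weighting of SVM weights
#'
#' A trained linear SVM assigns every voxel a weight, but a large weight
#' alone does not mean the voxel carries information about the classifier
#' output. Effect mapping combines both factors: for each voxel k the effect
#' value is `E_k = w_k * NMI(x_k; y)`, where `y = w'x + w0` is the
#' continuous SVM output (sign not taken) over the samples and NMI is the
#' mutual information between the voxel's activation and y, normalized by
#' the sum of the two marginal entropies so it lies in [0, 0.5]. Effect
#' values are made comparable across folds and participants by the signed
#' log rescaling `nE_k = sgn(E_k) * log(1 + |E_k| / std(E))`. Positive and
#' negative effect values correspond to the +1 and -1 design labels:
#' swapping the two conditions' labels negates every effect value.
#'
#' Probabilities are estimated with equal-width histograms over the observed
#' range of each variable (16 bins per variable by default); entropies are
#' reported in bits, though NMI and hence E_k are invariant to the logarithm
#' base.
#'
#' @name effect_mapping
NULL

#' Joint histogram probability estimate for two scalar variables
#'
#' Equal-width bins span each variable's observed range; counts are
#' normalized to probabilities. A constant variable occupies a single bin
#' (entropy 0).
#'
#' @param x,y numeric vectors of equal length (>= 2 samples)
#' @param n_bins number of bins per variable (>= 2)
#' @return a `joint_histogram`: list with `joint` (n_bins x n_bins
#'   probability matrix), `px`, `py` (marginals), `x_breaks`, `y_breaks`
#' @export
joint_histogram <- function(x, y, n_bins = 16L) {
  stopifnot(length(x) == length(y), length(x) >= 2L, n_bins >= 2L)
  bin <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(rep(1L, length(v)))
    b <- pmin(n_bins, 1L + floor((v - r[1]) / (r[2] - r[1]) * n_bins))
    as.integer(b)
  }
  bx <- bin(x); by <- bin(y)
  joint <- matrix(0, n_bins, n_bins)
  for (i in seq_along(bx))
    joint[bx[i], by[i]] <- joint[bx[i], by[i]] + 1
  joint <- joint / length(x)
  breaks <- function(v) if (min(v) == max(v)) c(min(v), max(v))
                        else seq(min(v), max(v), length.out = n_bins + 1L)
  structure(list(joint = joint, px = rowSums(joint), py = colSums(joint),
                 x_breaks = breaks(x), y_breaks = breaks(y)),
            class = "joint_histogram")
}

#' Shannon entropy of a probability vector, in bits
#'
#' `-sum(p * log2(p))` with the convention `0 * log 0 = 0`.
#'
#' @param p probability vector (or matrix, for the joint entropy); must be
#'   non-negative and sum to 1 within tolerance
#' @return entropy in bits
#' @export
entropy <- function(p) {
  p <- as.vector(p)
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1")
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Mutual information from a joint histogram, in bits
#'
#' Computed as `H(X) + H(Y) - H(X,Y)`; equal (up to floating point) to the
#' relative-entropy double sum `sum p(x,y) log(p(x,y)/(p(x)p(y)))`.
#'
#' @param h a `joint_histogram`
#' @return mutual information in bits (>= 0 up to floating point)
#' @export
mutual_information <- function(h) {
  entropy(h$px) + entropy(h$py) - entropy(h$joint)
}

#' Normalized mutual information
#'
#' `NMI = I(X;Y) / (H(X) + H(Y))`, dimensionless and invariant to the
#' logarithm base; bounded in [0, 0.5] since `I <= min(H(X), H(Y))`. When
#' both variables are constant (`H(X) + H(Y) = 0`) the value is 0 by
#' convention: constant variables carry no information.
#'
#' @param h a `joint_histogram`
#' @return normalized mutual information in [0, 0.5]
#' @export
normalized_mi <- function(h) {
  denom <- entropy(h$px) + entropy(h$py)
  if (denom == 0) return(0)
  mutual_information(h) / denom
}

#' Per-voxel effect values from a trained linear SVM
#'
#' For each voxel k: `E_k = w_k * NMI(x_k; y)` where y is the vector of
#' continuous decision values over the samples. The sign of E_k is the sign
#' of w_k, tying each voxel to the +1 or -1 design label.
#'
#' @param model a `linear_svm`
#' @param samples the `labeled_samples` the map is computed over (typically
#'   the training samples of one fold)
#' @param n_bins histogram bins per variable
#' @return an `effect_map`: list with `E`, `nE` (per-voxel), `n_voxels`,
#'   and provenance (`contrast`)
#' @export
effect_values <- function(model, samples, n_bins = 16L) {
  x <- samples$features
  if (ncol(x) != length(model$w))
    stop("feature dimension does not match the model")
  y <- decision_values(model, x)
  nmi <- vapply(seq_len(ncol(x)), function(k) {
    if (model$w[k] == 0) return(0)  # E_k = 0 regardless; skip the histogram
    normalized_mi(joint_histogram(x[, k], y, n_bins))
  }, numeric(1))
  E <- model$w * nmi
  structure(list(E = E, nE = normalize_effect_map(E),
                 n_voxels = length(E), contrast = samples$contrast),
            class = "effect_map")
}

#' Signed-log normalization of an effect map
#'
#' `nE_k = sgn(E_k) * log(1 + |E_k| / std(E))`, with std over all E_k
#' (population convention). The rescaling makes maps from different folds
#' and participants comparable while preserving signs and the ranking of
#' magnitudes. An all-zero map returns all zeros.
#'
#' @param E numeric vector of effect values (length >= 2)
#' @return numeric vector nE of the same length
#' @export
normalize_effect_map <- function(E) {
  stopifnot(length(E) >= 2L)
  s <- sqrt(mean((E - mean(E))^2))
  if (s == 0) return(rep(0, length(E)))
  sign(E) * log(1 + abs(E) / s)
}

#' Average effect maps across folds and participants
#'
#' Voxelwise mean of the normalized maps (40 maps in the standard design:
#' 4 folds x 10 participants), followed by spatial Gaussian smoothing of
#' the averaged map (5 mm FWHM default) for ease of interpretation. When a
#' `mask` is supplied the maps are placed on the 3D grid before smoothing.
#'
#' @param maps list of `effect_map` objects on identical voxel sets
#' @param fwhm_mm smoothing FWHM in mm (0 disables)
#' @param mask optional `roi_mask` giving the grid placement of the voxels
#' @param voxel_size_mm voxel size for smoothing (required if `fwhm_mm > 0`)
#' @return an `effect_map` whose `nE` is the group map (and `E` the mean of
#'   E); if `mask` is given, also `volume`: the smoothed 3D nE array
#' @export
group_average_emaps <- function(maps, fwhm_mm = 5, mask = NULL,
                                voxel_size_mm = c(1, 1, 1)) {
  M <- unique(vapply(maps, function(m) m$n_voxels, numeric(1)))
  if (length(M) != 1L) stop("effect maps are on different voxel sets")
  nE <- rowMeans(vapply(maps, `[[`, numeric(M), "nE"))
  E <- rowMeans(vapply(maps, `[[`, numeric(M), "E"))
  vol <- NULL
  if (!is.null(mask)) {
    vol <- unmask(nE, mask)
    if (fwhm_mm > 0) vol <- gaussian_smooth(vol, fwhm_mm, voxel_size_mm)
  }
  structure(list(E = E, nE = nE, n_voxels = M,
                 contrast = maps[[1L]]$contrast, n_maps = length(maps),
                 volume = vol),
            class = "effect_map")
}

#' Select the most informative voxels of an effect map
#'
#' Ranks voxels by `|nE_k|` descending (deterministic tie-break by voxel
#' index) and keeps the top fraction — the display rule used for effect-map
#' figures (top 20%).
#'
#' @param map an `effect_map` (or numeric nE vector)
#' @param fraction fraction of voxels to keep, in (0, 1]
#' @return logical vector selecting exactly `ceiling(fraction * M)` voxels
#' @export
top_fraction <- function(map, fraction = 0.20) {
  nE <- if (inherits(map, "effect_map")) map$nE else map
  if (length(nE) == 0L) stop("empty effect map")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n_keep <- ceiling(fraction * length(nE))
  ord <- order(-abs(nE), seq_along(nE))
  sel <- logical(length(nE))
  sel[ord[seq_len(n_keep)]] <- TRUE
  sel
}

#' Write a group effect map as NIfTI with a JSON provenance sidecar
#'
#' @param map an `effect_map` with a `volume` (see [group_average_emaps()])
#' @param path output `.nii` path
#' @param voxel_size_mm voxel size recorded in the header
#' @param extra named list merged into the sidecar (bins, fwhm, ...)
#' @return `path`, invisibly
#' @export
write_emap_nifti <- function(map, path, voxel_size_mm = c(1, 1, 1),
                             extra = list()) {
  if (is.null(map$volume)) stop("map has no volume; supply a mask when averaging")
  img <- RNifti::asNifti(map$volume)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  meta <- c(list(contrast = map$contrast, n_maps = map$n_maps,
                 n_voxels = map$n_voxels), extra)
  jsonlite::write_json(meta, sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
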