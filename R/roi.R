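#' ROI masks composed from labelled parcel volumes
#'
#' ROIs are built from an integer-labelled atlas volume by taking the union
#' of a set of labels (e.g. several Brodmann areas for one functional
#' region), optionally followed by subtraction of another mask — the rule
#' used to carve the premotor cortex out of BA6 by removing the
#' supplementary motor area. The package ships no third-party atlas: any
#' integer-labelled NIfTI plus a label mapping works, and the synthetic grid
#' provides its own parcels.
#'
#' @name roi_atlas
NULL

new_roi_mask <- function(name, mask, composition = integer(),
                         empty = !any(mask)) {
  structure(list(name = name, mask = mask, composition = composition,
                 empty = empty),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask>", x$name, "-", sum(x$mask), "voxels",
      if (x$empty) "(EMPTY)" else "", "\n")
  invisible(x)
}

#' Compose an ROI from atlas labels
#'
#' @param label_volume integer 3D array of parcel labels
#' @param labels integer vector of labels to include (union)
#' @param name ROI name
#' @return a `roi_mask`; if no voxel carries any requested label the mask is
#'   returned with its `empty` flag set and a warning
#' @export
compose_roi <- function(label_volume, labels, name) {
  if (length(labels) == 0L) stop("labels must be non-empty")
  mask <- array(label_volume %in% labels, dim(label_volume))
  if (!any(mask))
    warning("ROI '", name, "': no voxel carries any requested label")
  new_roi_mask(name, mask, composition = as.integer(labels))
}

#' Subtract one mask from another
#'
#' Returns `a AND NOT b`, the construction used for PMC = BA6 minus SMA.
#'
#' @param a,b `roi_mask` objects on the same grid
#' @param name name of the result
#' @return a `roi_mask`
#' @export
subtract_mask <- function(a, b, name = paste0(a$name, "-", b$name)) {
  if (!identical(dim(a$mask), dim(b$mask)))
    stop("masks are on different grids")
  new_roi_mask(name, a$mask & !b$mask, composition = a$composition)
}

#' Build a named list of ROI masks from a mapping
#'
#' The mapping format mirrors a JSON file
#' `{roi_name: {labels: [..], subtract: [roi_name, ..]}}`: each ROI is the
#' union of its labels, minus any previously defined ROIs named in
#' `subtract`.
#'
#' @param label_volume integer 3D array of parcel labels
#' @param mapping named list; each element has `labels` and optionally
#'   `subtract`
#' @return named list of `roi_mask`
#' @export
roi_set_from_mapping <- function(label_volume, mapping) {
  rois <- list()
  for (nm in names(mapping)) {
    spec <- mapping[[nm]]
    roi <- compose_roi(label_volume, unlist(spec$labels), nm)
    for (sub in spec$subtract) {
      if (is.null(rois[[sub]]))
        stop("ROI '", nm, "' subtracts undefined ROI '", sub, "'")
      roi <- subtract_mask(roi, rois[[sub]], name = nm)
    }
    rois[[nm]] <- roi
  }
  rois
}

#' Read an ROI mapping from a JSON file
#' @param path path to the JSON mapping file
#' @return named list suitable for [roi_set_from_mapping()]
#' @export
read_roi_mapping <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
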