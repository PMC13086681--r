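#' CT volume container
#'
#' A 3D scalar grid of Hounsfield units (HU) with anisotropic voxel spacing.
#' This is the raw imaging substrate consumed by the mask builders, the
#' baseline calcium segmenter and the biomarker extractors.
#'
#' @param values 3D numeric array of HU values.
#' @param spacing Numeric triple, mm per voxel along each axis; all > 0.
#' @param origin Numeric triple, world coordinate (mm) of voxel (1,1,1).
#'   Voxel indices are 1-based in R; world coordinates follow the NIfTI
#'   affine on I/O.
#'
#' @return An object of class `ct_volume` with fields `values`, `spacing`,
#'   `origin`.
#' @examples
#' ct <- ct_volume(array(-1000, dim = c(8, 8, 8)), spacing = c(1, 1, 1))
#' dim(ct$values)
#' @export
ct_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3)
    stopf("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("`spacing` must be 3 strictly positive mm values")
  if (any(dim(values) < 1)) stopf("grid must be nonempty")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Named segmentation masks on a shared CT grid
#'
#' Bundles the anatomical masks used throughout the pipeline: `aorta`, heart
#' chambers (`la`, `lv`, `ra`, `rv`), `myocardium`, `pa` (pulmonary
#' arteries), `lungs`, `vertebral_bodies` (integer-labeled, one unique label
#' per vertebra) and `l3_muscles`. All masks must share the reference grid
#' shape; binary masks are stored as logical arrays.
#'
#' @param masks Named list of 3D arrays (logical, or integer for
#'   `vertebral_bodies`), all with identical dimensions.
#' @param spacing Numeric triple, mm per voxel.
#' @param vertebra_labels Optional named integer vector mapping vertebra
#'   names (e.g. `"L3"`) to labels in `vertebral_bodies`.
#' @param provenance Optional named character vector, one note per mask.
#'
#' @return An object of class `seg_set`.
#' @export
seg_set <- function(masks, spacing, vertebra_labels = NULL,
                    provenance = NULL) {
  if (!is.list(masks) || is.null(names(masks)) || any(names(masks) == ""))
    stopf("`masks` must be a fully named list")
  dims <- lapply(masks, dim)
  if (any(vapply(dims, length, 1L) != 3))
    stopf("all masks must be 3D arrays")
  ref <- dims[[1]]
  bad <- names(masks)[!vapply(dims, function(d) all(d == ref), TRUE)]
  if (length(bad))
    stopf("masks with mismatched grid shape: %s", paste(bad, collapse = ", "))
  for (nm in names(masks)) {
    if (nm != "vertebral_bodies") masks[[nm]] <- as_mask(masks[[nm]])
  }
  if (!is.null(vertebra_labels)) {
    if (anyDuplicated(vertebra_labels))
      stopf("vertebra labels must be unique integers")
  }
  structure(list(masks = masks, spacing = as.numeric(spacing),
                 vertebra_labels = vertebra_labels,
                 provenance = provenance),
            class = "seg_set")
}

#' @export
print.seg_set <- function(x, ...) {
  cat(sprintf("<seg_set> %d masks on %s grid: %s\n", length(x$masks),
              paste(dim(x$masks[[1]]), collapse = "x"),
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

check_same_grid <- function(a, b, what = "mask") {
  if (!all(dim(a) == dim(b)))
    stopf("%s shape (%s) does not match reference grid (%s)", what,
          paste(dim(b), collapse = "x"), paste(dim(a), collapse = "x"))
  invisible(TRUE)
}
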