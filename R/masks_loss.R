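# Calcium-segmentation scaffolding: the location masks that restrict the
# loss to the peri-aortic region, the masked binary cross-entropy itself,
# HU windowing / cropping / patch sampling, and the adaptive-threshold
# baseline segmenter used to produce reference calcium annotations.

#' Bundle of location masks for the masked loss
#'
#' @param ao Dilated-aorta inclusion mask (logical 3D array).
#' @param spie Spine exclusion mask: 1 where the loss applies, 0 inside the
#'   dilated vertebral bodies.
#' @param vae Valve exclusion mask: 1 outside the aortic/mitral valve
#'   neighborhoods, 0 inside.
#' @param spacing Numeric triple, mm.
#' @return An object of class `loss_masks`.
#' @export
loss_masks <- function(ao, spie, vae, spacing) {
  check_same_grid(ao, spie, "spie")
  check_same_grid(ao, vae, "vae")
  structure(list(ao = as_mask(ao), spie = as_mask(spie), vae = as_mask(vae),
                 spacing = as.numeric(spacing)),
            class = "loss_masks")
}

# per-axis structuring-element radius in voxels for a physical margin of
# `k` mm: round(k / sp) on each axis
kernel_radii <- function(k, spacing) round(k / spacing)

#' Dilated-aorta inclusion mask
#'
#' Dilates the aorta segmentation with a ball-shaped structuring element of
#' per-axis voxel radius `round(margin_mm / spacing)`, i.e. an
#' approximately `margin_mm`-mm physical margin regardless of voxel
#' anisotropy. The default 2 mm margin admits wall calcifications that
#' protrude slightly beyond the segmented lumen.
#'
#' @param aorta Logical 3D array, nonempty.
#' @param spacing Numeric triple, mm.
#' @param margin_mm Physical dilation margin (default 2).
#' @return Logical array containing the input mask.
#' @export
build_aorta_mask <- function(aorta, spacing, margin_mm = 2) {
  aorta <- as_mask(aorta)
  if (!any(aorta)) stopf("aorta mask is empty: nothing to include")
  radii <- kernel_radii(margin_mm, spacing)
  dilate_with_offsets(aorta, ball_offsets(radii))
}

#' Spine exclusion mask
#'
#' Returns 1 wherever the loss applies and 0 inside the vertebral bodies
#' dilated by a ball of per-axis radius `round(margin_mm / spacing)`
#' (default 1 mm margin), so cortical bone and its immediate rim never
#' contribute calcium candidates. An empty spine yields an all-ones mask.
#'
#' @param vertebral_bodies 3D array; any nonzero voxel counts as vertebra.
#' @param spacing Numeric triple, mm.
#' @param margin_mm Physical margin (default 1).
#' @return Logical array (TRUE = loss applies).
#' @export
build_spine_exclusion <- function(vertebral_bodies, spacing, margin_mm = 1) {
  vb <- as_mask(vertebral_bodies)
  if (!any(vb)) return(array(TRUE, dim = dim(vb)))
  dil <- dilate_with_offsets(vb, ball_offsets(kernel_radii(margin_mm, spacing)))
  !dil
}

#' Valve exclusion mask
#'
#' Computes Euclidean distance maps (mm) from the left ventricle, left
#' atrium and aorta segmentations. The aortic-valve zone is the set of
#' voxels within `tau_mm` of both the LV and the aorta; the mitral-valve
#' zone within `tau_mm` of both the LV and the LA. The returned mask is 1
#' outside the union of both zones. Dense valvular calcium in these zones
#' is anatomically distinct from aortic wall calcium and must not drive
#' the loss.
#'
#' @param segs A [seg_set()] containing `lv`, `la` and `aorta` masks.
#' @param tau_mm Distance threshold in mm (default 5).
#' @return Logical array (TRUE = loss applies).
#' @export
build_valve_exclusion <- function(segs, tau_mm = 5) {
  stopifnot(inherits(segs, "seg_set"))
  for (nm in c("lv", "la", "aorta"))
    if (is.null(segs$masks[[nm]]))
      stopf("required mask '%s' is missing from the segmentation set", nm)
  sp <- segs$spacing
  tau2 <- tau_mm^2
  d_lv <- edt_sq(segs$masks$lv, sp)
  d_la <- edt_sq(segs$masks$la, sp)
  d_ao <- edt_sq(segs$masks$aorta, sp)
  aortic_zone <- d_lv <= tau2 & d_ao <= tau2
  mitral_zone <- d_lv <= tau2 & d_la <= tau2
  !(aortic_zone | mitral_zone)
}

#' Build the full loss-mask bundle
#'
#' Convenience wrapper producing the dilated-aorta inclusion mask, the
#' spine exclusion and the valve exclusion from one segmentation set.
#'
#' @inheritParams build_valve_exclusion
#' @param aorta_margin_mm,spine_margin_mm Physical margins (mm) for the
#'   aorta dilation and spine exclusion.
#' @return A [loss_masks()] bundle.
#' @export
build_loss_masks <- function(segs, tau_mm = 5, aorta_margin_mm = 2,
                             spine_margin_mm = 1) {
  stopifnot(inherits(segs, "seg_set"))
  if (is.null(segs$masks$aorta)) stopf("required mask 'aorta' is missing")
  sp <- segs$spacing
  ao <- build_aorta_mask(segs$masks$aorta, sp, aorta_margin_mm)
  spie <- if (!is.null(segs$masks$vertebral_bodies))
    build_spine_exclusion(segs$masks$vertebral_bodies, sp, spine_margin_mm)
  else array(TRUE, dim = dim(ao))
  vae <- if (!is.null(segs$masks$lv) && !is.null(segs$masks$la))
    build_valve_exclusion(segs, tau_mm)
  else array(TRUE, dim = dim(ao))
  loss_masks(ao, spie, vae, sp)
}

#' Masked binary cross-entropy
#'
#' Mean over all voxels of the per-voxel binary cross-entropy multiplied by
#' the product of the location masks, so that voxels outside the dilated
#' aorta, inside the spine margin, or inside a valve zone contribute
#' exactly zero. Predictions are clipped to `[eps, 1 - eps]` before the
#' logarithms. Returned as a positive quantity suitable for minimization.
#'
#' With `mask_whole = FALSE` the mask product multiplies only the negative
#' (background) term, an alternative reading of the loss in which masked
#' voxels still incur the foreground term.
#'
#' @param pred Numeric array of predicted probabilities.
#' @param gt Binary ground-truth array.
#' @param masks A [loss_masks()] bundle (or `NULL` for plain BCE).
#' @param eps Clipping constant (default 1e-7).
#' @param mask_whole Multiply the whole per-voxel term (default) or only
#'   the background term.
#' @return Scalar loss.
#' @export
masked_bce <- function(pred, gt, masks = NULL, eps = 1e-7,
                       mask_whole = TRUE) {
  check_same_grid(pred, gt, "ground truth")
  p <- pmin(pmax(pred, eps), 1 - eps)
  y <- as.numeric(gt)
  pos <- y * log(p)
  neg <- (1 - y) * log(1 - p)
  if (is.null(masks)) return(-mean(pos + neg))
  check_same_grid(pred, masks$ao, "loss mask")
  m <- as.numeric(masks$ao) * as.numeric(masks$spie) * as.numeric(masks$vae)
  if (mask_whole) -mean((pos + neg) * m) else -mean(pos + neg * m)
}

#' Window, normalize and crop a CT volume around the aorta
#'
#' Crops to the aorta bounding box padded by the inclusion-mask dilation
#' margin, clips HU to the window (default `[-200, 1000]`, which spans soft
#' tissue to dense calcium) and maps it affinely to `[-1, 1]`. Resolution
#' is unchanged.
#'
#' @param ct A [ct_volume()].
#' @param aorta Logical array on the same grid; must be nonempty.
#' @param window HU window (length 2).
#' @param margin_mm Crop padding in mm (default 2, matching the aorta
#'   dilation margin).
#' @return A list with `ct` (the cropped, normalized [ct_volume]) and
#'   `crop` (a list of index ranges per axis into the original grid).
#' @export
preprocess_ct <- function(ct, aorta, window = c(-200, 1000), margin_mm = 2) {
  stopifnot(inherits(ct, "ct_volume"))
  aorta <- as_mask(aorta)
  check_same_grid(ct$values, aorta, "aorta")
  if (!any(aorta)) stopf("aorta mask is empty: cannot crop")
  idx <- which(aorta, arr.ind = TRUE)
  pad <- kernel_radii(margin_mm, ct$spacing)
  dm <- dim(ct$values)
  rng <- lapply(1:3, function(a)
    seq.int(max(1L, min(idx[, a]) - pad[a]), min(dm[a], max(idx[, a]) + pad[a])))
  v <- ct$values[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  v <- pmin(pmax(v, window[1]), window[2])
  v <- 2 * (v - window[1]) / (window[2] - window[1]) - 1
  list(ct = ct_volume(array(v, dim = vapply(rng, length, 1L)), ct$spacing),
       crop = rng)
}

#' Sample random training patches
#'
#' Draws `count` patches of `size` voxels at offsets uniform over the valid
#' placements, reproducibly under `seed`. A patch dimension larger than the
#' grid is clamped to the grid (with a warning), so small volumes yield the
#' single full-extent patch. Additional arrays in `aligned` (ground truths,
#' masks) are cropped identically.
#'
#' @param volume A [ct_volume()] or a 3D array.
#' @param count Number of patches (default 5).
#' @param size Patch dimensions in voxels (default `c(100, 100, 100)`).
#' @param seed Integer seed.
#' @param aligned Named list of arrays on the same grid to crop alongside.
#' @return List of patches; each has `offset` (1-based corner), `values`,
#'   and one cropped array per `aligned` entry.
#' @export
sample_patches <- function(volume, count = 5, size = c(100, 100, 100),
                           seed = 1L, aligned = list()) {
  v <- if (inherits(volume, "ct_volume")) volume$values else volume
  dm <- dim(v)
  size <- as.integer(size)
  if (any(size > dm)) {
    warnf("patch size (%s) clamped to grid (%s)",
          paste(size, collapse = "x"), paste(dm, collapse = "x"))
    size <- pmin(size, dm)
  }
  nvalid <- dm - size + 1L
  with_seed(seed, {
    lapply(seq_len(count), function(i) {
      off <- vapply(1:3, function(a) sample.int(nvalid[a], 1L), 1L)
      rng <- lapply(1:3, function(a) seq.int(off[a], off[a] + size[a] - 1L))
      out <- list(offset = off,
                  values = v[rng[[1]], rng[[2]], rng[[3]], drop = FALSE])
      for (nm in names(aligned))
        out[[nm]] <- aligned[[nm]][rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
      out
    })
  })
}

#' Adaptive-threshold baseline calcium segmenter
#'
#' Reference (non-learned) thoracic aortic calcium segmentation: candidate
#' seeds are voxels at or above `threshold_hu` (default 130 HU, the
#' conventional calcium cut-off) inside the dilated aorta and allowed by
#' the spine and valve exclusions; each seed's connected component of
#' at-or-above-threshold voxels (26-connectivity by default) is then grown
#' to cover the entire calcification. An empty result is legitimate.
#'
#' @param ct A [ct_volume()].
#' @param masks A [loss_masks()] bundle on the same grid.
#' @param threshold_hu Seeding and growth threshold (default 130).
#' @param connectivity 26 (default) or 6.
#' @return A list of class `calcium_segmentation` with `mask` (logical
#'   array) and `volume_ml`.
#' @export
threshold_calcium <- function(ct, masks, threshold_hu = 130,
                              connectivity = 26) {
  stopifnot(inherits(ct, "ct_volume"), inherits(masks, "loss_masks"))
  check_same_grid(ct$values, masks$ao, "loss mask")
  candidate <- ct$values >= threshold_hu
  seeds <- candidate & masks$ao & masks$spie & masks$vae
  out <- array(FALSE, dim = dim(candidate))
  if (any(seeds)) {
    labels <- label_components(candidate, connectivity)
    keep <- unique(labels[seeds])
    out <- array(labels %in% keep, dim = dim(candidate))
  }
  structure(list(mask = out,
                 volume_ml = sum(out) * voxel_volume_ml(ct$spacing),
                 threshold_hu = threshold_hu, connectivity = connectivity),
            class = "calcium_segmentation")
}

#' @export
print.calcium_segmentation <- function(x, ...) {
  cat(sprintf("<calcium_segmentation> %d voxels, %.3f mL (threshold %g HU)\n",
              sum(x$mask), x$volume_ml, x$threshold_hu))
  invisible(x)
}
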