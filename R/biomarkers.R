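# Extraction of CT imaging biomarkers from segmentation masks: structure
# volumes, emphysema quantification, maximal vessel radii, L3 muscle area,
# body-surface-area indexing, and segmentation agreement metrics.

#' Volume of a binary mask
#'
#' @param mask Logical 3D array.
#' @param spacing Numeric triple, mm.
#' @return Volume in mL: voxel count times voxel volume.
#' @export
mask_volume <- function(mask, spacing) {
  sum(as_mask(mask)) * voxel_volume_ml(spacing)
}

#' Locate the L3 vertebra
#'
#' Axial slice index of the centroid of the L3 vertebral body in a labeled
#' spine segmentation.
#'
#' @param x A [seg_set()] with a `vertebral_bodies` mask and vertebra
#'   labels, or a labeled 3D integer array.
#' @param label Integer label of L3 (required when `x` is a bare array).
#' @return 1-based axial slice index (rounded centroid).
#' @export
locate_l3 <- function(x, label = NULL) {
  if (inherits(x, "seg_set")) {
    vb <- x$masks$vertebral_bodies
    if (is.null(vb)) stopf("segmentation set has no 'vertebral_bodies' mask")
    if (is.null(label)) {
      if (is.null(x$vertebra_labels) || !("L3" %in% names(x$vertebra_labels)))
        stopf("no vertebra labeled 'L3' in the segmentation set")
      label <- x$vertebra_labels[["L3"]]
    }
  } else vb <- x
  if (is.null(label)) stopf("`label` is required for a bare labeled array")
  idx <- which(vb == label, arr.ind = TRUE)
  if (nrow(idx) == 0) stopf("no voxel carries the L3 label (%s)", label)
  as.integer(round(mean(idx[, 3])))
}

#' Muscle cross-sectional area at a given axial slice
#'
#' In-plane area of the abdominal-belt muscle mask at one slice, the
#' standard CT sarcopenia measurement at the L3 level.
#'
#' @param l3_muscles Logical 3D array.
#' @param slice 1-based axial index.
#' @param spacing Numeric triple, mm.
#' @param floor_cm2 Plausibility floor; smaller nonzero values trigger a
#'   segmentation-failure warning (default 10).
#' @return Area in cm^2.
#' @export
muscle_area_at_l3 <- function(l3_muscles, slice, spacing, floor_cm2 = 10) {
  m <- as_mask(l3_muscles)
  if (slice < 1 || slice > dim(m)[3])
    stopf("slice %d outside grid (1..%d)", slice, dim(m)[3])
  area <- sum(m[, , slice]) * spacing[1] * spacing[2] / 100
  if (area == 0)
    warnf("empty muscle mask at slice %d: possible segmentation failure", slice)
  else if (area < floor_cm2)
    warnf("muscle area %.2f cm^2 below plausibility floor %.1f cm^2", area,
          floor_cm2)
  area
}

#' Lung and emphysema quantification
#'
#' Lung volume, emphysema volume and emphysema ratio, with emphysema
#' defined as lung voxels strictly below the attenuation threshold
#' (default -950 HU, the conventional low-attenuation-area cut-off; the
#' ideal value under contrast injection is debated, hence configurable).
#'
#' @param ct A [ct_volume()].
#' @param lungs Logical array on the same grid; must be nonempty.
#' @param threshold_hu Emphysema threshold (default -950).
#' @return List with `lung_volume_ml`, `emphysema_volume_ml`,
#'   `emphysema_ratio_pct`.
#' @export
emphysema_metrics <- function(ct, lungs, threshold_hu = -950) {
  stopifnot(inherits(ct, "ct_volume"))
  lungs <- as_mask(lungs)
  check_same_grid(ct$values, lungs, "lungs")
  n <- sum(lungs)
  if (n == 0) stopf("lung mask is empty: emphysema ratio undefined")
  ne <- sum(ct$values[lungs] < threshold_hu)
  vv <- voxel_volume_ml(ct$spacing)
  list(lung_volume_ml = n * vv, emphysema_volume_ml = ne * vv,
       emphysema_ratio_pct = 100 * ne / n)
}

# elementwise max over the 26-neighborhood (face/edge/corner shifts)
neighborhood_max <- function(d) {
  dm <- dim(d)
  out <- array(-Inf, dim = dm)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- seq.int(max(1, 1 + dx), min(dm[1], dm[1] + dx))
    sy <- seq.int(max(1, 1 + dy), min(dm[2], dm[2] + dy))
    sz <- seq.int(max(1, 1 + dz), min(dm[3], dm[3] + dz))
    tx <- sx - dx; ty <- sy - dy; tz <- sz - dz
    out[tx, ty, tz] <- pmax(out[tx, ty, tz], d[sx, sy, sz])
  }
  out
}

#' Maximal inscribed radius of a vessel
#'
#' Skeletonizes a vessel mask on the ridge of its Euclidean distance
#' transform (voxels whose boundary distance is a 26-neighborhood local
#' maximum — a medial-axis approximation) and returns the largest boundary
#' distance attained on the skeleton, in cm. If the mask is disconnected,
#' the largest 26-connected component is used with a warning.
#'
#' @param vessel Logical 3D array, nonempty.
#' @param spacing Numeric triple, mm.
#' @param floor_cm Plausibility floor; a smaller result warns of likely
#'   segmentation failure (default 0.2).
#' @return Radius in cm.
#' @export
vessel_max_radius <- function(vessel, spacing, floor_cm = 0.2) {
  vessel <- as_mask(vessel)
  if (!any(vessel)) stopf("vessel mask is empty")
  labels <- label_components(vessel, 26)
  k <- max(labels)
  if (k > 1) {
    warnf("vessel mask has %d components: using the largest", k)
    counts <- tabulate(labels[labels > 0], nbins = k)
    vessel <- labels == which.max(counts)
  }
  d <- sqrt(edt_sq(!vessel, spacing))   # mm to nearest background voxel
  skel <- vessel & d >= neighborhood_max(d)
  r <- max(d[skel]) / 10
  if (r < floor_cm)
    warnf("max radius %.3f cm below plausibility floor %.2f cm", r, floor_cm)
  r
}

#' Body surface area
#'
#' Boyd's formula (default): `0.0003207 * height_cm^0.3 *
#' weight_g^(0.7285 - 0.0188 * log10(weight_g))` with weight in grams.
#' Du Bois and Mosteller variants are available for sensitivity checks.
#'
#' @param height_cm,weight_kg Strictly positive; warnings outside
#'   physiologic bounds (height 50-250 cm, weight 20-300 kg).
#' @param method `"boyd"` (default), `"dubois"` or `"mosteller"`.
#' @return BSA in m^2.
#' @examples
#' boyd_bsa(170, 70)
#' @export
boyd_bsa <- function(height_cm, weight_kg,
                     method = c("boyd", "dubois", "mosteller")) {
  method <- match.arg(method)
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stopf("height and weight must be strictly positive")
  if (any(height_cm < 50 | height_cm > 250))
    warnf("height %.0f cm outside physiologic bounds [50, 250]", height_cm)
  if (any(weight_kg < 20 | weight_kg > 300))
    warnf("weight %.0f kg outside physiologic bounds [20, 300]", weight_kg)
  switch(method,
         boyd = {
           wg <- 1000 * weight_kg
           0.0003207 * height_cm^0.3 * wg^(0.7285 - 0.0188 * log10(wg))
         },
         dubois = 0.007184 * height_cm^0.725 * weight_kg^0.425,
         mosteller = sqrt(height_cm * weight_kg / 3600))
}

# biomarker fields that receive a BSA-indexed twin (the emphysema ratio,
# a dimensionless percentage, is never indexed)
bsa_indexable_fields <- function() {
  c("lung_volume_ml", "emphysema_volume_ml", "la_volume_ml", "lv_volume_ml",
    "myo_volume_ml", "ra_volume_ml", "rv_volume_ml", "ao_max_radius_cm",
    "pa_max_radius_cm", "l3_muscle_area_cm2")
}

#' Index biomarkers to body surface area
#'
#' Adds a `bsai_*` column for every indexable biomarker present, computed
#' as raw value / BSA. The emphysema ratio is never indexed.
#'
#' @param record One-row `data.frame` (or named list) of biomarkers.
#' @param bsa_m2 BSA in m^2, e.g. from [boyd_bsa()].
#' @return The record as a one-row `data.frame` with `bsa_m2` and the
#'   `bsai_*` columns appended.
#' @export
bsa_index <- function(record, bsa_m2) {
  rec <- as.data.frame(record)
  if (bsa_m2 <= 0) stopf("BSA must be strictly positive")
  rec$bsa_m2 <- bsa_m2
  for (f in intersect(bsa_indexable_fields(), names(rec))) {
    short <- sub("_(ml|cm2|cm)$", "", f)
    rec[[paste0("bsai_", short)]] <- rec[[f]] / bsa_m2
  }
  rec
}

#' Extract all imaging biomarkers from a CT volume and segmentation set
#'
#' Runs every extraction operator applicable to the masks present: lung and
#' emphysema metrics, chamber/myocardium volumes, aortic and pulmonary
#' maximal radii, L3 muscle area, and thoracic aortic calcium volume (from
#' a `calcium` mask in `segs` or a supplied [threshold_calcium()] result).
#' When height and weight are given, the record is BSA-indexed.
#'
#' @param ct A [ct_volume()].
#' @param segs A [seg_set()] on the same grid.
#' @param height_cm,weight_kg Optional body measurements for BSA indexing.
#' @param calcium Optional `calcium_segmentation` overriding `segs$masks$calcium`.
#' @param emphysema_hu Emphysema threshold (default -950).
#' @return One-row `data.frame` of biomarkers; extraction parameters are
#'   attached as the `"provenance"` attribute.
#' @export
extract_biomarkers <- function(ct, segs, height_cm = NULL, weight_kg = NULL,
                               calcium = NULL, emphysema_hu = -950) {
  stopifnot(inherits(ct, "ct_volume"), inherits(segs, "seg_set"))
  check_same_grid(ct$values, segs$masks[[1]], "segmentation")
  sp <- ct$spacing
  rec <- list()
  prov <- list(emphysema_hu = emphysema_hu, spacing_mm = sp)
  m <- segs$masks
  if (!is.null(m$lungs))
    rec <- c(rec, emphysema_metrics(ct, m$lungs, emphysema_hu))
  for (nm in c("la", "lv", "ra", "rv")) {
    if (!is.null(m[[nm]]))
      rec[[paste0(nm, "_volume_ml")]] <- mask_volume(m[[nm]], sp)
  }
  if (!is.null(m$myocardium))
    rec$myo_volume_ml <- mask_volume(m$myocardium, sp)
  if (!is.null(m$aorta))
    rec$ao_max_radius_cm <- vessel_max_radius(m$aorta, sp)
  if (!is.null(m$pa))
    rec$pa_max_radius_cm <- vessel_max_radius(m$pa, sp)
  if (!is.null(m$l3_muscles)) {
    slice <- locate_l3(segs)
    rec$l3_muscle_area_cm2 <- muscle_area_at_l3(m$l3_muscles, slice, sp)
    prov$l3_slice <- slice
  }
  if (!is.null(calcium)) {
    rec$tac_volume_ml <- calcium$volume_ml
    prov$tac_method <- "threshold_calcium"
  } else if (!is.null(m$calcium)) {
    rec$tac_volume_ml <- mask_volume(m$calcium, sp)
    prov$tac_method <- "mask"
  }
  out <- as.data.frame(rec)
  if (!is.null(height_cm) && !is.null(weight_kg)) {
    out <- bsa_index(out, boyd_bsa(height_cm, weight_kg))
    prov$bsa_method <- "boyd"
  }
  attr(out, "provenance") <- prov
  out
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks are defined to agree
#' perfectly (1.0).
#'
#' @param a,b Binary arrays of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_same_grid(a, b, "second mask")
  a <- as_mask(a); b <- as_mask(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1.0)
  2 * sum(a & b) / denom
}

#' Paired volume agreement (Bland-Altman summary)
#'
#' Mean bias, SD of paired differences, 95% limits of agreement
#' (bias +/- 1.96 SD) and the least-squares slope/intercept of predicted
#' versus reference volumes.
#'
#' @param pred_volumes,gt_volumes Numeric vectors of equal length >= 2.
#' @return List with `bias`, `sd`, `loa` (length 2), `slope`, `intercept`, `n`.
#' @export
volume_agreement <- function(pred_volumes, gt_volumes) {
  if (length(pred_volumes) != length(gt_volumes))
    stopf("prediction and reference vectors differ in length")
  if (length(pred_volumes) < 2) stopf("need at least 2 paired volumes")
  d <- pred_volumes - gt_volumes
  fit <- lm(pred_volumes ~ gt_volumes)
  list(bias = mean(d), sd = sd(d),
       loa = mean(d) + c(-1.96, 1.96) * sd(d),
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(d))
}
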