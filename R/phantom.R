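# CT phantom generation: axis-aligned geometric descriptors rasterized onto a
# voxel grid with known ground truth, so segmentation and biomarker code can
# be tested without patient data.

#' Specify a CT phantom
#'
#' Describes a synthetic CT volume by geometric primitives: a tubular aorta
#' with calcium lesions on its wall, ellipsoidal heart chambers, an
#' ellipsoidal lung field with low-attenuation (emphysema) pockets, a stack
#' of labeled vertebral bodies, and an annular abdominal-muscle cross
#' section at the L3 level. All coordinates and sizes are in mm; voxel
#' centers sit at `(i - 0.5) * spacing`.
#'
#' Rasterization order (later stamps overwrite earlier HU values):
#' background, lungs, spine, muscle, chambers, aorta, calcium. Each
#' structure's mask is its own rasterized footprint, emitted before noise.
#'
#' @param grid_shape Integer triple, voxels per axis.
#' @param spacing Numeric triple, mm per voxel (> 0; anisotropy allowed).
#' @param aorta List: `centerline` (n x 3 matrix of mm points, or `NULL` for
#'   none), `radius_mm`, `hu`.
#' @param calcium_lesions List of lesions, each `list(center, radius_mm, hu)`
#'   with `hu` in `[300, 1000]`.
#' @param chambers Named list of ellipsoids `list(center, semiaxes_mm, hu)`;
#'   allowed names: `la`, `lv`, `ra`, `rv`, `myocardium`, `pa`.
#' @param lungs List: `center`, `semiaxes_mm`, `hu` (parenchyma), and
#'   `pockets` — a list of `list(center, radius_mm, hu)` with `hu < -950`.
#' @param spine List of vertebrae `list(name, center, semiaxes_mm, hu)`;
#'   names such as `"L3"` become labels of the `vertebral_bodies` mask.
#' @param l3_muscle List: `center_xy`, `z_mm`, `thickness_mm`, `r_inner_mm`,
#'   `r_outer_mm`, `hu` — an annulus emulating the abdominal muscle belt.
#' @param background_hu Scalar HU for unoccupied voxels (soft tissue ~ 40).
#' @param noise_sd Gaussian HU noise standard deviation added to the image
#'   (masks and truth are computed before noise).
#' @param seed Integer seed for the noise.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [default_phantom_spec()]
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96), spacing = c(1, 1, 1),
                         aorta = NULL, calcium_lesions = list(),
                         chambers = list(), lungs = NULL, spine = list(),
                         l3_muscle = NULL, background_hu = 40,
                         noise_sd = 0, seed = 1L) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stopf("spacing must be strictly positive")
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 1)) stopf("grid_shape must be positive")
  extent <- grid_shape * spacing

  check_inside <- function(lo, hi, what) {
    if (any(lo < 0) || any(hi > extent))
      stopf("descriptor '%s' extends outside the grid (extent %s mm)",
            what, paste(format(extent), collapse = " x "))
  }
  if (!is.null(aorta) && !is.null(aorta$centerline)) {
    cl <- rbind(aorta$centerline)
    check_inside(apply(cl, 2, min) - c(aorta$radius_mm, aorta$radius_mm, 0),
                 apply(cl, 2, max) + c(aorta$radius_mm, aorta$radius_mm, 0),
                 "aorta")
  }
  for (i in seq_along(calcium_lesions)) {
    le <- calcium_lesions[[i]]
    if (le$hu < 300 || le$hu > 1000)
      stopf("calcium lesion %d HU %.0f outside [300, 1000]", i, le$hu)
    check_inside(le$center - le$radius_mm, le$center + le$radius_mm,
                 sprintf("calcium_lesion[%d]", i))
  }
  if (length(chambers)) {
    bad <- setdiff(names(chambers), c("la", "lv", "ra", "rv", "myocardium", "pa"))
    if (length(bad)) stopf("unknown chamber name(s): %s", paste(bad, collapse = ", "))
    for (nm in names(chambers)) {
      ch <- chambers[[nm]]
      check_inside(ch$center - ch$semiaxes_mm, ch$center + ch$semiaxes_mm, nm)
    }
  }
  if (!is.null(lungs)) {
    check_inside(lungs$center - lungs$semiaxes_mm,
                 lungs$center + lungs$semiaxes_mm, "lungs")
    for (p in lungs$pockets %||% list())
      if (p$hu >= -950) stopf("emphysema pocket HU must be < -950")
  }
  for (v in spine)
    check_inside(v$center - v$semiaxes_mm, v$center + v$semiaxes_mm,
                 paste0("vertebra ", v$name))
  if (!is.null(l3_muscle)) {
    m <- l3_muscle
    check_inside(c(m$center_xy - m$r_outer_mm, m$z_mm - m$thickness_mm / 2),
                 c(m$center_xy + m$r_outer_mm, m$z_mm + m$thickness_mm / 2),
                 "l3_muscle")
  }
  structure(list(grid_shape = grid_shape, spacing = spacing, aorta = aorta,
                 calcium_lesions = calcium_lesions, chambers = chambers,
                 lungs = lungs, spine = spine, l3_muscle = l3_muscle,
                 background_hu = background_hu, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# voxel-center coordinate arrays (mm)
coord_arrays <- function(grid_shape, spacing) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  ux <- (seq_len(nx) - 0.5) * spacing[1]
  uy <- (seq_len(ny) - 0.5) * spacing[2]
  uz <- (seq_len(nz) - 0.5) * spacing[3]
  list(x = array(ux, dim = grid_shape),
       y = array(rep(uy, each = nx), dim = grid_shape),
       z = array(rep(uz, each = nx * ny), dim = grid_shape))
}

raster_ellipsoid <- function(co, center, semiaxes) {
  ((co$x - center[1]) / semiaxes[1])^2 +
    ((co$y - center[2]) / semiaxes[2])^2 +
    ((co$z - center[3]) / semiaxes[3])^2 <= 1
}

raster_sphere <- function(co, center, radius) {
  raster_ellipsoid(co, center, rep(radius, 3))
}

# tube of given radius around a polyline (distance to nearest segment)
raster_tube <- function(co, centerline, radius) {
  cl <- rbind(centerline)
  d2 <- array(Inf, dim = dim(co$x))
  for (s in seq_len(max(1, nrow(cl) - 1))) {
    a <- cl[s, ]
    b <- if (nrow(cl) > 1) cl[s + 1, ] else cl[s, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2s <- (co$x - a[1])^2 + (co$y - a[2])^2 + (co$z - a[3])^2
    } else {
      t <- ((co$x - a[1]) * ab[1] + (co$y - a[2]) * ab[2] +
              (co$z - a[3]) * ab[3]) / len2
      t <- pmin(pmax(t, 0), 1)
      d2s <- (co$x - (a[1] + t * ab[1]))^2 + (co$y - (a[2] + t * ab[2]))^2 +
        (co$z - (a[3] + t * ab[3]))^2
    }
    d2 <- pmin(d2, d2s)
  }
  d2 <= radius^2
}

raster_annulus <- function(co, center_xy, z_mm, thickness_mm,
                           r_inner, r_outer) {
  r2 <- (co$x - center_xy[1])^2 + (co$y - center_xy[2])^2
  r2 >= r_inner^2 & r2 <= r_outer^2 & abs(co$z - z_mm) <= thickness_mm / 2
}

#' Rasterize a phantom specification
#'
#' Stamps the descriptors of a [phantom_spec()] onto the voxel grid in the
#' documented order, adds Gaussian HU noise, and returns the noisy CT, the
#' noise-free segmentation masks, and ground-truth biomarker values. Volumes
#' and areas in `truth` are derived from the rasterized masks (voxel count
#' times voxel volume), so extraction tests are independent of rasterization
#' error; vessel radii are the analytic descriptor radii (the maximal
#' inscribed sphere is not recoverable from a mask without the algorithm
#' under test).
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `ct` ([ct_volume]), `segs` ([seg_set]) and
#'   `truth` (named list of ground-truth biomarker values using the same
#'   names and units as [extract_biomarkers()]).
#' @examples
#' ph <- generate_phantom(default_phantom_spec(seed = 1))
#' ph$truth$tac_volume_ml
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  co <- coord_arrays(spec$grid_shape, spec$spacing)
  hu <- array(spec$background_hu, dim = spec$grid_shape)
  masks <- list()
  vv <- voxel_volume_ml(spec$spacing)

  # lungs
  emphysema_vox <- 0L
  if (!is.null(spec$lungs)) {
    lung_mask <- raster_ellipsoid(co, spec$lungs$center, spec$lungs$semiaxes_mm)
    hu[lung_mask] <- spec$lungs$hu
    for (p in spec$lungs$pockets %||% list()) {
      pm <- raster_sphere(co, p$center, p$radius_mm) & lung_mask
      hu[pm] <- p$hu
    }
    masks$lungs <- lung_mask
  }
  # spine
  if (length(spec$spine)) {
    vb <- array(0L, dim = spec$grid_shape)
    labels <- integer(0)
    for (i in seq_along(spec$spine)) {
      v <- spec$spine[[i]]
      vm <- raster_ellipsoid(co, v$center, v$semiaxes_mm)
      hu[vm] <- v$hu
      vb[vm] <- i
      labels[v$name] <- i
    }
    masks$vertebral_bodies <- vb
    vertebra_labels <- labels
  } else vertebra_labels <- NULL
  # L3 muscle annulus
  if (!is.null(spec$l3_muscle)) {
    m <- spec$l3_muscle
    mm <- raster_annulus(co, m$center_xy, m$z_mm, m$thickness_mm,
                         m$r_inner_mm, m$r_outer_mm)
    hu[mm] <- m$hu
    masks$l3_muscles <- mm
  }
  # chambers (myocardium first so the blood pools overwrite its interior)
  ordered <- intersect(c("myocardium", "la", "lv", "ra", "rv", "pa"),
                       names(spec$chambers))
  for (nm in ordered) {
    ch <- spec$chambers[[nm]]
    cm <- raster_ellipsoid(co, ch$center, ch$semiaxes_mm)
    hu[cm] <- ch$hu
    masks[[nm]] <- cm
  }
  # aorta and calcium
  if (!is.null(spec$aorta)) {
    am <- raster_tube(co, spec$aorta$centerline, spec$aorta$radius_mm)
    hu[am] <- spec$aorta$hu
    masks$aorta <- am
  }
  calcium <- array(FALSE, dim = spec$grid_shape)
  for (le in spec$calcium_lesions) {
    lm <- raster_sphere(co, le$center, le$radius_mm)
    hu[lm] <- le$hu
    calcium <- calcium | lm
  }
  masks$calcium <- calcium

  # ground truth from the noise-free rasterization
  truth <- list(tac_volume_ml = sum(calcium) * vv)
  if (!is.null(spec$lungs)) {
    nlung <- sum(masks$lungs)
    nemph <- sum(hu[masks$lungs] < -950)
    truth$lung_volume_ml <- nlung * vv
    truth$emphysema_volume_ml <- nemph * vv
    truth$emphysema_ratio_pct <- 100 * nemph / nlung
  }
  for (nm in ordered) {
    key <- if (nm == "myocardium") "myo_volume_ml" else paste0(nm, "_volume_ml")
    truth[[key]] <- sum(masks[[nm]]) * vv
  }
  if (!is.null(spec$aorta))
    truth$ao_max_radius_cm <- spec$aorta$radius_mm / 10
  if ("pa" %in% ordered)
    truth$pa_max_radius_cm <- min(spec$chambers$pa$semiaxes_mm) / 10
  if (!is.null(spec$l3_muscle) && length(spec$spine)) {
    l3 <- which(masks$vertebral_bodies == vertebra_labels[["L3"]],
                arr.ind = TRUE)
    slice <- round(mean(l3[, 3]))
    truth$l3_muscle_area_cm2 <-
      sum(masks$l3_muscles[, , slice]) * spec$spacing[1] * spec$spacing[2] / 100
  }

  if (spec$noise_sd > 0) {
    hu <- hu + with_seed(spec$seed,
                         array(rnorm(length(hu), 0, spec$noise_sd),
                               dim = dim(hu)))
  }

  list(ct = ct_volume(hu, spec$spacing),
       segs = seg_set(masks, spec$spacing, vertebra_labels = vertebra_labels,
                      provenance = setNames(rep("phantom raster", length(masks)),
                                            names(masks))),
       truth = truth)
}

#' A complete thoracic phantom specification
#'
#' Ready-made phantom with all supported structures: a straight descending
#' aorta (40 HU lumen, as in a non-contrast acquisition) with two wall
#' calcium lesions, six cardiac structures, a lung field with two emphysema
#' pockets, vertebral bodies L1-L5 and an L3-level muscle annulus. With
#' `jitter = TRUE`, lesion/pocket/chamber sizes and positions are perturbed
#' deterministically by `seed` (within bounds keeping every descriptor
#' inside the grid) so that repeated phantoms exercise different geometry.
#'
#' @param seed Integer; drives noise and, if enabled, geometric jitter.
#' @param noise_sd HU noise standard deviation (default 0).
#' @param jitter Logical; randomize sizes/positions slightly per seed.
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(seed = 1L, noise_sd = 0, jitter = FALSE) {
  j <- function(lo, hi) (lo + hi) / 2  # deterministic default
  if (jitter) {
    rng <- with_seed(seed + 10000L, runif(24))
    k <- 0
    j <- function(lo, hi) {
      k <<- k + 1
      lo + (hi - lo) * rng[k]
    }
  }
  phantom_spec(
    grid_shape = c(96, 96, 96), spacing = c(1, 1, 1),
    aorta = list(centerline = rbind(c(30, 40, 0), c(30, 40, 96)),
                 radius_mm = j(10, 14), hu = 40),
    calcium_lesions = list(
      list(center = c(40 + j(-1, 1), 40, 28 + j(0, 4)),
           radius_mm = j(3, 4.5), hu = 700),
      list(center = c(21, 40 + j(-1, 1), 58 + j(0, 4)),
           radius_mm = j(2.5, 3.5), hu = 500)),
    chambers = list(
      myocardium = list(center = c(58, 50, 45), semiaxes_mm = rep(j(9.5, 10.5), 3), hu = 60),
      lv = list(center = c(58, 50, 45), semiaxes_mm = rep(j(7, 8), 3), hu = 110),
      la = list(center = c(58, 30, 55), semiaxes_mm = rep(j(6, 7), 3), hu = 110),
      ra = list(center = c(45, 28, 55), semiaxes_mm = rep(j(6, 7), 3), hu = 100),
      rv = list(center = c(45, 45, 33), semiaxes_mm = rep(j(7, 8), 3), hu = 100),
      pa = list(center = c(48, 62, 65), semiaxes_mm = c(j(6.5, 7.5), 6, 9), hu = 100)),
    lungs = list(center = c(82, 48, 48), semiaxes_mm = c(12, 30, 40), hu = -850,
                 pockets = list(
                   list(center = c(82, 40, 40), radius_mm = j(5, 6.5), hu = -980),
                   list(center = c(80, 58, 66), radius_mm = j(4, 5.5), hu = -980))),
    spine = list(
      list(name = "L1", center = c(15, 70, 75), semiaxes_mm = c(7, 7, 6), hu = 400),
      list(name = "L2", center = c(15, 70, 60), semiaxes_mm = c(7, 7, 6), hu = 400),
      list(name = "L3", center = c(15, 70, 45), semiaxes_mm = c(7, 7, 6), hu = 400),
      list(name = "L4", center = c(15, 70, 30), semiaxes_mm = c(7, 7, 6), hu = 400),
      list(name = "L5", center = c(15, 70, 15), semiaxes_mm = c(7, 7, 6), hu = 400)),
    l3_muscle = list(center_xy = c(40, 40), z_mm = 45, thickness_mm = 4,
                     r_inner_mm = j(25, 27), r_outer_mm = j(33, 35), hu = 50),
    background_hu = 40, noise_sd = noise_sd, seed = seed)
}
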