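test_that("mask volume is voxel count times voxel volume", {
  m <- array(FALSE, dim = c(10, 10, 10)); m[1:10, 1:10, 1:10][1:1000] <- TRUE
  expect_identical(mask_volume(m, c(1, 1, 1)), 1)
  expect_identical(mask_volume(array(FALSE, dim = c(5, 5, 5)), c(1, 1, 1)), 0)
  set.seed(3)
  r <- array(runif(8^3) < 0.4, dim = c(8, 8, 8))
  sp <- c(0.7, 0.7, 1.25)
  manual <- 0
  for (i in seq_along(r)) if (r[i]) manual <- manual + prod(sp) / 1000
  expect_equal(mask_volume(r, sp), manual, tolerance = 1e-12)
})

test_that("L3 localization returns the axial centroid", {
  vb <- array(0L, dim = c(10, 10, 60))
  vb[4:6, 4:6, 38:42] <- 3L           # symmetric span -> slice 40
  expect_identical(locate_l3(vb, label = 3L), 40L)
  vb2 <- array(0L, dim = c(10, 10, 60))
  vb2[4, 4, c(10, 11, 12, 20)] <- 5L  # asymmetric: mean(10,11,12,20) = 13.25
  expect_identical(locate_l3(vb2, label = 5L),
                   as.integer(round(mean(c(10, 11, 12, 20)))))
  expect_error(locate_l3(vb, label = 9L), "L3")
  # default phantom: L3 body spans slices 40..51, centroid 45.5 -> 46
  ph <- generate_phantom(default_phantom_spec(seed = 2))
  expect_identical(locate_l3(ph$segs), 46L)
})

test_that("muscle area converts in-plane counts and flags failures", {
  m <- array(FALSE, dim = c(20, 20, 5))
  m[1:10, 1:10, 3] <- TRUE            # 100 voxels at 1x1 mm -> 1 cm^2
  expect_warning(a <- muscle_area_at_l3(m, 3, c(1, 1, 1)), "floor")
  expect_identical(a, 1)
  expect_warning(z <- muscle_area_at_l3(m, 1, c(1, 1, 1)), "empty")
  expect_identical(z, 0)
  expect_error(muscle_area_at_l3(m, 9, c(1, 1, 1)), "outside")
  # anisotropic in-plane spacing
  expect_warning(a2 <- muscle_area_at_l3(m, 3, c(0.5, 2, 1)), "floor")
  expect_identical(a2, 100 * 0.5 * 2 / 100)
})

test_that("emphysema metrics count sub-threshold lung voxels", {
  hu <- array(-850, dim = c(6, 6, 6))
  lungs <- array(TRUE, dim = c(6, 6, 6))
  ct <- ct_volume(hu, c(1, 1, 1))
  expect_identical(emphysema_metrics(ct, lungs)$emphysema_ratio_pct, 0)
  hu2 <- hu; hu2[1:3, , ] <- -960
  r <- emphysema_metrics(ct_volume(hu2, c(1, 1, 1)), lungs)
  expect_identical(r$emphysema_ratio_pct, 50)
  expect_identical(r$lung_volume_ml, 216 / 1000)
  expect_identical(r$emphysema_volume_ml, 108 / 1000)
  # threshold is strict and configurable
  hu3 <- hu; hu3[1, 1, 1] <- -950
  expect_identical(emphysema_metrics(ct_volume(hu3, c(1, 1, 1)),
                                     lungs)$emphysema_ratio_pct, 0)
  expect_gt(emphysema_metrics(ct_volume(hu3, c(1, 1, 1)), lungs,
                              threshold_hu = -949)$emphysema_ratio_pct, 0)
  expect_error(emphysema_metrics(ct, array(FALSE, dim = c(6, 6, 6))),
               "empty")
})

test_that("vessel max radius matches analytic cylinders and cones", {
  co <- expand.grid(x = 1:64, y = 1:64, z = 1:40)
  # cylinder radius 15 mm along z
  cyl <- array((co$x - 32)^2 + (co$y - 32)^2 <= 15^2, dim = c(64, 64, 40))
  r <- vessel_max_radius(cyl, c(1, 1, 1))
  expect_lt(abs(r - 1.5), sqrt(3) / 10)
  # cone from radius 5 to 20 mm: max inscribed sphere at the wide end
  rad <- 5 + (co$z - 1) / 39 * 15
  cone <- array((co$x - 32)^2 + (co$y - 32)^2 <= rad^2, dim = c(64, 64, 40))
  rc <- vessel_max_radius(cone, c(1, 1, 1))
  expect_lt(abs(rc - 2.0), sqrt(3) / 10)
  # degenerate single voxel
  single <- array(FALSE, dim = c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_warning(rs <- vessel_max_radius(single, c(1, 1, 1)), "floor")
  expect_lte(rs, 0.1)
  expect_error(vessel_max_radius(array(FALSE, dim = c(4, 4, 4)), c(1, 1, 1)),
               "empty")
})

test_that("vessel max radius is invariant to 90-degree grid rotations", {
  ph <- generate_phantom(default_phantom_spec(seed = 6))
  ao <- ph$segs$masks$aorta
  r0 <- vessel_max_radius(ao, c(1, 1, 1))
  rot <- aperm(ao, c(3, 1, 2))
  expect_equal(vessel_max_radius(rot, c(1, 1, 1)), r0, tolerance = 1e-12)
})

test_that("disconnected vessels fall back to the largest component", {
  m <- array(FALSE, dim = c(30, 10, 10))
  m[2:9, 3:8, 3:8] <- TRUE       # large block
  m[25, 5, 5] <- TRUE            # stray voxel
  expect_warning(r <- vessel_max_radius(m, c(1, 1, 1)), "components")
  expect_gt(r, 0.2)
})

test_that("Boyd BSA matches direct arithmetic and behaves monotonically", {
  wg <- 70000
  manual <- 0.0003207 * 170^0.3 * wg^(0.7285 - 0.0188 * log10(wg))
  expect_equal(boyd_bsa(170, 70), manual, tolerance = 1e-12)
  expect_gt(boyd_bsa(180, 70), boyd_bsa(170, 70))
  expect_gt(boyd_bsa(170, 80), boyd_bsa(170, 70))
  ratio <- boyd_bsa(170, 140) / boyd_bsa(170, 70)
  expect_gt(ratio, 1); expect_lt(ratio, 2)
  expect_error(boyd_bsa(-170, 70), "positive")
  expect_warning(boyd_bsa(170, 400), "bounds")
  # alternates stay within a few percent of Boyd on physiologic inputs
  expect_lt(abs(boyd_bsa(170, 70, "dubois") - boyd_bsa(170, 70)) /
              boyd_bsa(170, 70), 0.05)
  expect_lt(abs(boyd_bsa(170, 70, "mosteller") - boyd_bsa(170, 70)) /
              boyd_bsa(170, 70), 0.05)
})

test_that("BSA indexing divides raw values and skips the emphysema ratio", {
  rec <- data.frame(rv_volume_ml = 148.04, emphysema_ratio_pct = 5,
                    l3_muscle_area_cm2 = 120)
  out <- bsa_index(rec, 2.0)
  expect_identical(out$bsai_rv_volume, 74.02)
  expect_identical(out$bsai_l3_muscle_area, 60)
  expect_false("bsai_emphysema_ratio_pct" %in% names(out))
  expect_false("bsai_emphysema_ratio" %in% names(out))
  # BSA 1 leaves values unchanged; indexing round-trips
  id <- bsa_index(rec, 1.0)
  expect_identical(id$bsai_rv_volume, rec$rv_volume_ml)
  expect_equal(out$bsai_rv_volume * 2.0, rec$rv_volume_ml, tolerance = 1e-12)
  expect_error(bsa_index(rec, 0), "positive")
})

test_that("Dice handles identity, disjointness and partial overlap", {
  a <- array(FALSE, dim = c(10, 10, 2)); a[1:10, 1:10, 1] <- TRUE
  expect_identical(dice(a, a), 1)
  b <- array(FALSE, dim = c(10, 10, 2)); b[1:10, 1:10, 2] <- TRUE
  expect_identical(dice(a, b), 0)
  # |a| = |b| = 100, overlap 60 -> 0.6
  c1 <- array(FALSE, dim = c(200, 1, 1)); c1[1:100, 1, 1] <- TRUE
  c2 <- array(FALSE, dim = c(200, 1, 1)); c2[41:140, 1, 1] <- TRUE
  expect_identical(dice(c1, c2), 0.6)
  expect_identical(dice(a & FALSE, b & FALSE), 1)
  expect_error(dice(a, array(FALSE, dim = c(3, 3, 3))), "shape")
})

test_that("volume agreement recovers bias and slope", {
  gt <- c(1, 2, 4, 8, 12)
  same <- volume_agreement(gt, gt)
  expect_equal(same$bias, 0, tolerance = 1e-12)
  expect_equal(same$slope, 1, tolerance = 1e-12)
  expect_equal(same$intercept, 0, tolerance = 1e-12)
  off <- volume_agreement(gt + 2, gt)
  expect_equal(off$bias, 2, tolerance = 1e-12)
  expect_equal(off$slope, 1, tolerance = 1e-12)
  sc <- volume_agreement(1.1 * gt, gt)
  expect_equal(sc$slope, 1.1, tolerance = 1e-12)
  expect_error(volume_agreement(1:3, 1:4), "length")
})

test_that("extraction is invariant to background padding", {
  ph <- generate_phantom(tiny_phantom_spec())
  rec <- extract_biomarkers(ph$ct, ph$segs)
  pad <- function(a, fill) {
    out <- array(fill, dim = dim(a) + c(4, 4, 4))
    out[3:(dim(a)[1] + 2), 3:(dim(a)[2] + 2), 3:(dim(a)[3] + 2)] <- a
    out
  }
  ct2 <- ct_volume(pad(ph$ct$values, 40), ph$ct$spacing)
  segs2 <- seg_set(lapply(ph$segs$masks, pad, fill = FALSE),
                   ph$segs$spacing)
  rec2 <- extract_biomarkers(ct2, segs2)
  expect_equal(rec2, rec, tolerance = 1e-12, ignore_attr = TRUE)
})
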