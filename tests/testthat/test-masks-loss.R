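test_that("aorta dilation matches the brute-force oracle and the 2/sp rule", {
  # single voxel at 1 mm spacing: radius-2 ball (33 voxels)
  m <- array(FALSE, dim = c(9, 9, 9)); m[5, 5, 5] <- TRUE
  d1 <- build_aorta_mask(m, c(1, 1, 1))
  expect_identical(d1, brute_dilate(m, c(2, 2, 2)))
  expect_identical(sum(d1), 33L)
  # 2 mm spacing: 2/sp = 1 voxel radius (6-neighborhood ball + center)
  d2 <- build_aorta_mask(m, c(2, 2, 2))
  expect_identical(d2, brute_dilate(m, c(1, 1, 1)))
  expect_identical(sum(d2), 7L)
  # random small masks, anisotropic spacing
  set.seed(42)
  for (sp in list(c(1, 1, 1), c(0.8, 0.8, 2))) {
    mm <- array(runif(16^3) < 0.02, dim = c(16, 16, 16))
    mm[8, 8, 8] <- TRUE
    expect_identical(build_aorta_mask(mm, sp),
                     brute_dilate(mm, round(2 / sp)))
  }
  expect_error(build_aorta_mask(array(FALSE, dim = c(4, 4, 4)), c(1, 1, 1)),
               "empty")
})

test_that("dilation is extensive and its radius scales inversely with spacing", {
  set.seed(7)
  m <- array(runif(20^3) < 0.01, dim = c(20, 20, 20))
  m[10, 10, 10] <- TRUE
  out <- build_aorta_mask(m, c(1, 1, 1))
  expect_identical(out & m, m)
  # doubling spacing halves the voxel radius: physical margin preserved
  single <- array(FALSE, dim = c(11, 11, 11)); single[6, 6, 6] <- TRUE
  r1 <- max(abs(which(build_aorta_mask(single, c(1, 1, 1)), arr.ind = TRUE) - 6))
  r2 <- max(abs(which(build_aorta_mask(single, c(2, 2, 2)), arr.ind = TRUE) - 6))
  expect_equal(c(r1, r2), c(2, 1))
})

test_that("spine exclusion inverts and dilates the vertebral bodies", {
  empty <- array(0L, dim = c(8, 8, 8))
  expect_identical(build_spine_exclusion(empty, c(1, 1, 1)),
                   array(TRUE, dim = c(8, 8, 8)))
  vb <- array(0L, dim = c(9, 9, 9)); vb[5, 5, 5] <- 1L
  ex <- build_spine_exclusion(vb, c(1, 1, 1))
  expect_identical(ex, !brute_dilate(vb == 1, c(1, 1, 1)))
  expect_false(ex[5, 5, 5])      # vertebra voxel always excluded
  expect_false(ex[4, 5, 5])      # 1 mm rim excluded
  expect_true(ex[3, 5, 5])
})

test_that("valve exclusion follows the pairwise distance rule", {
  dm <- c(20, 8, 8)
  lv <- array(FALSE, dim = dm); lv[1:10, , ] <- TRUE
  ao <- array(FALSE, dim = dm); ao[11:20, , ] <- TRUE
  la <- array(FALSE, dim = dm); la[1, 1, 1] <- TRUE
  segs <- seg_set(list(lv = lv, la = la, aorta = ao), c(1, 1, 1))
  vae <- build_valve_exclusion(segs, tau_mm = 3)
  # abutting half-spaces: excluded slab of thickness 6 at the interface
  expect_true(all(!vae[8:13, , ]))
  expect_true(all(vae[5:7, 5:8, 5:8]))   # away from the mitral corner
  expect_true(all(vae[14:20, , ]))
  expect_false(vae[1, 1, 1])             # mitral zone around the LA voxel

  # far-apart structures: no aortic exclusion zone
  ao2 <- array(FALSE, dim = dm); ao2[20, 8, 8] <- TRUE
  lv2 <- array(FALSE, dim = dm); lv2[1, 1, 1] <- TRUE
  segs2 <- seg_set(list(lv = lv2, la = la, aorta = ao2), c(1, 1, 1))
  vae2 <- build_valve_exclusion(segs2, tau_mm = 2)
  expect_true(all(vae2[10:20, , ]))

  # tau = 0 only excludes voxels inside both structures simultaneously
  vae0 <- build_valve_exclusion(segs, tau_mm = 0)
  expect_identical(!vae0, (lv & ao) | (lv & la))

  expect_error(build_valve_exclusion(seg_set(list(lv = lv, aorta = ao),
                                             c(1, 1, 1))), "la")
})

test_that("masked BCE reduces to plain BCE under unit masks and to zero under a zero mask", {
  set.seed(11)
  dm <- c(6, 5, 4)
  pred <- array(runif(prod(dm), 0.01, 0.99), dim = dm)
  gt <- array(runif(prod(dm)) < 0.3, dim = dm)
  ones <- array(TRUE, dim = dm)
  lm1 <- loss_masks(ones, ones, ones, c(1, 1, 1))
  plain <- -mean(gt * log(pred) + (1 - gt) * log(1 - pred))
  expect_lt(abs(masked_bce(pred, gt, lm1) - plain), 1e-10)
  expect_equal(masked_bce(pred, gt, NULL), plain, tolerance = 1e-12)

  lm0 <- loss_masks(array(FALSE, dim = dm), ones, ones, c(1, 1, 1))
  expect_identical(masked_bce(pred, gt, lm0), 0)

  # perfect prediction: loss bounded by the clipping epsilon
  perfect <- array(as.numeric(gt), dim = dm)
  expect_lt(masked_bce(perfect, gt, lm1, eps = 1e-7), 1e-6)
  expect_lt(masked_bce(perfect, gt, lm1, eps = 1e-12),
            masked_bce(perfect, gt, lm1, eps = 1e-7))

  # alternative parenthesization only masks the background term
  lmz <- loss_masks(array(FALSE, dim = dm), ones, ones, c(1, 1, 1))
  alt <- masked_bce(pred, gt, lmz, mask_whole = FALSE)
  expect_equal(alt, -mean(gt * log(pred)), tolerance = 1e-12)
  expect_error(masked_bce(pred, gt[, , 1:2], lm1), "shape")
})

test_that("preprocessing windows, normalizes and crops around the aorta", {
  dm <- c(12, 12, 12)
  hu <- array(-1000, dim = dm)
  hu[6, 6, 6] <- -200; hu[7, 6, 6] <- 1000; hu[6, 7, 6] <- 400
  ao <- array(FALSE, dim = dm); ao[5:8, 5:8, 5:8] <- TRUE
  pp <- preprocess_ct(ct_volume(hu, c(1, 1, 1)), ao)
  v <- pp$ct$values
  # crop contains every aorta voxel plus the 2-voxel margin
  expect_identical(pp$crop[[1]], 3:10)
  expect_identical(dim(v), c(8L, 8L, 8L))
  expect_identical(v[4, 4, 4], -1)    # -200 HU -> -1
  expect_identical(v[5, 4, 4], 1)     # 1000 HU -> +1
  expect_identical(v[4, 5, 4], 0)     # 400 HU -> 0 (window midpoint)
  expect_identical(v[1, 1, 1], -1)    # -1000 HU clipped to -1
  expect_error(preprocess_ct(ct_volume(hu, c(1, 1, 1)),
                             array(FALSE, dim = dm)), "empty")
})

test_that("patch sampling is deterministic, clamped, and uniform", {
  v <- array(rnorm(20 * 8 * 8), dim = c(20, 8, 8))
  # grid equal to patch size: the single full-volume patch, repeated
  p <- sample_patches(v, count = 3, size = c(20, 8, 8), seed = 1)
  expect_identical(length(p), 3L)
  for (q in p) expect_identical(q$offset, c(1L, 1L, 1L))
  # determinism
  a <- sample_patches(v, count = 5, size = c(11, 4, 4), seed = 9)
  b <- sample_patches(v, count = 5, size = c(11, 4, 4), seed = 9)
  expect_identical(a, b)
  # clamping warns
  expect_warning(sample_patches(v, count = 1, size = c(30, 8, 8), seed = 1),
                 "clamped")
  # aligned arrays are cropped identically
  gt <- array(seq_along(v), dim = dim(v))
  w <- sample_patches(v, count = 2, size = c(5, 5, 5), seed = 2,
                      aligned = list(gt = gt))[[1]]
  off <- w$offset
  expect_identical(w$gt, gt[off[1] + 0:4, off[2] + 0:4, off[3] + 0:4])
  # offsets uniform over the valid range (chi-square at alpha = 0.01)
  draws <- sample_patches(array(0, dim = c(40, 4, 4)), count = 2000,
                          size = c(31, 4, 4), seed = 33)
  xs <- vapply(draws, function(d) d$offset[1], 1L)
  expect_gt(chisq.test(tabulate(xs, nbins = 10))$p.value, 0.01)
})

test_that("threshold segmentation recovers planted lesions and honors exclusions", {
  ph <- generate_phantom(tiny_phantom_spec(lesion_hu = 700, lumen_hu = 40))
  lm <- build_loss_masks(ph$segs)
  seg <- threshold_calcium(ph$ct, lm)
  expect_identical(seg$mask, ph$segs$masks$calcium)
  expect_identical(seg$volume_ml, sum(ph$segs$masks$calcium) / 1000)

  # calcium-free phantom: empty mask, 0 mL
  spec0 <- phantom_spec(grid_shape = c(40, 40, 32),
                        aorta = list(centerline = rbind(c(20, 20, 0),
                                                        c(20, 20, 32)),
                                     radius_mm = 8, hu = 40))
  ph0 <- generate_phantom(spec0)
  seg0 <- threshold_calcium(ph0$ct, build_loss_masks(ph0$segs))
  expect_identical(sum(seg0$mask), 0L)
  expect_identical(seg0$volume_ml, 0)

  # lesion fully inside the spine exclusion zone yields nothing
  dm <- c(40, 40, 32)
  spie <- array(TRUE, dim = dm); spie[20:32, 14:26, 10:22] <- FALSE
  lm2 <- loss_masks(lm$ao, spie, array(TRUE, dim = dm), c(1, 1, 1))
  seg2 <- threshold_calcium(ph$ct, lm2)
  expect_identical(sum(seg2$mask), 0L)
})

test_that("recovered volume is monotone in lesion HU and threshold", {
  vols_hu <- vapply(c(300, 500, 900), function(hu) {
    ph <- generate_phantom(tiny_phantom_spec(lesion_hu = hu, noise_sd = 15,
                                             seed = 2))
    threshold_calcium(ph$ct, build_loss_masks(ph$segs))$volume_ml
  }, 0)
  expect_true(all(diff(vols_hu) >= 0))
  ph <- generate_phantom(tiny_phantom_spec(lesion_hu = 500, noise_sd = 15,
                                           seed = 2))
  lm <- build_loss_masks(ph$segs)
  vols_thr <- vapply(c(110, 130, 200, 450),
                     function(thr) threshold_calcium(ph$ct, lm,
                                                     threshold_hu = thr)$volume_ml,
                     0)
  expect_true(all(diff(vols_thr) <= 0))
})
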