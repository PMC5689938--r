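test_that("digitized ball approaches the sphere limits", {
  m <- ball_mask(10)
  s <- shape_features(m)
  expect_equal(s$volume_mm3, sum(m$values))
  true_area <- 4 * pi * 10^2
  expect_lt(abs(s$surface_area_mm2 / true_area - 1), 0.05)
  expect_gt(s$sphericity, 0.95)
  expect_lte(s$sphericity, 1.02)           # estimator noise band
  expect_equal(s$spherical_disproportionality, 1 / s$sphericity)
  expect_gte(s$convexity, 0.95)            # convex-shape limit
  expect_lt(s$eccentricity, 0.1)
})

test_that("2:1:1 ellipsoid recovers the axis ratio within 10%", {
  g <- expand.grid(i = 1:49, j = 1:25, k = 1:25)
  ell <- array(((g$i - 25) / 20)^2 + ((g$j - 13) / 10)^2 +
                 ((g$k - 13) / 10)^2 <= 1, c(49, 25, 25))
  m <- roi_mask(ell, c(1, 1, 1))
  ax <- principal_axis_lengths(m)
  expect_lt(abs(ax[1] / ax[3] - 2), 0.2)
  s <- shape_features(m)
  expect_gte(s$convexity, 0.95)
  # analytic eccentricity sqrt(1 - (b/a)^2) = sqrt(3)/2
  expect_equal(s$eccentricity, sqrt(3) / 2, tolerance = 0.05)
})

test_that("voxel-face area is exact on a box and biased high on a ball", {
  box <- array(0, c(14, 12, 10))
  box[3:12, 3:10, 3:8] <- 1        # 10 x 8 x 6 box
  m <- roi_mask(box, c(1, 1, 1))
  expect_equal(voxel_face_area(m$values, m$spacing_mm),
               2 * (10 * 8 + 10 * 6 + 8 * 6))
  ball <- ball_mask(8)
  a_face <- shape_features(ball, method = "voxel-face")$surface_area_mm2
  a_mesh <- shape_features(ball)$surface_area_mm2
  expect_gt(a_face, a_mesh)        # staircase overestimate
})

test_that("shape features are invariant to axis permutation and to Ng", {
  set.seed(61)
  g <- expand.grid(i = 1:19, j = 1:15, k = 1:13)
  blob <- array(((g$i - 10) / 7)^2 + ((g$j - 8) / 5)^2 +
                  ((g$k - 7) / 4)^2 <= 1, c(19, 15, 13))
  m <- roi_mask(blob, c(1, 1, 1))
  s <- shape_features(m)
  mp <- roi_mask(aperm(blob, c(3, 1, 2)), c(1, 1, 1))
  sp_ <- shape_features(mp)
  for (nm in c("volume_mm3", "sphericity", "convexity",
               "surface_to_volume_ratio")) {
    expect_equal(sp_[[nm]], s[[nm]], tolerance = 1e-6, label = nm)
  }
  # Ng invariance through the full extraction path
  vals <- array(runif(prod(dim(blob)), 1, 10), dim(blob))
  v <- suv_volume(vals, c(1, 1, 1))
  shape_cols <- feature_catalogue("shape")
  f32 <- extract_all_features(v, m, Ng = 32)[shape_cols]
  f128 <- extract_all_features(v, m, Ng = 128)[shape_cols]
  expect_identical(f32, f128)
})

test_that("degenerate masks stay finite", {
  # single-slice (planar) mask: eccentricity floored by the voxel moment
  plane <- array(0, c(6, 6, 3))
  plane[2:5, 2:5, 2] <- 1
  s <- shape_features(roi_mask(plane, c(1, 1, 1)))
  expect_true(is.finite(s$eccentricity) && s$eccentricity <= 1)
  # single voxel
  one <- array(0, c(3, 3, 3)); one[2, 2, 2] <- 1
  s1 <- shape_features(roi_mask(one, c(1, 1, 1)))
  expect_true(all(vapply(s1, is.finite, logical(1))))
  expect_equal(s1$volume_mm3, 1)
})
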