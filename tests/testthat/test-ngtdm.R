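test_that("constant ROI has zero deviations and sentinel coarseness", {
  v <- tiny_volume(array(4, c(5, 5, 1)))
  m <- full_mask_like(v)
  d <- suppressWarnings(discretize_roi(v, m, Ng = 8))
  nm <- build_ngtdm(d)
  expect_true(all(nm$s_i == 0))
  expect_equal(nm$n_valid, 25L)
  f <- ngtdm_features(nm)
  expect_equal(unname(f["ngtdm_coarseness"]), 1e12)  # 1/eps sentinel
  expect_equal(unname(f["ngtdm_contrast"]), 0)
  expect_equal(unname(f["ngtdm_busyness"]), 0)
})

test_that("single bright center voxel matches the hand-computed window", {
  # 7x7 single-slice ROI, center voxel hot: with the full 7x7 window every
  # voxel's neighborhood covers the whole slice minus itself
  vals <- array(0, c(7, 7, 1))
  vals[4, 4, 1] <- 10
  v <- suv_volume(vals, c(1, 1, 1))
  m <- full_mask_like(v)
  d <- discretize_roi(v, m, Ng = 2)
  nm <- build_ngtdm(d)
  # center (level 2): its window is the whole slice, 48 neighbors all
  # level 1 -> s_2 = |2 - 1|
  expect_equal(nm$s_i[2], 1)
  # background voxel at (x, y): clipped window spans w[x] * w[y] cells with
  # w = (4,5,6,7,6,5,4); the window always contains the hot center, so the
  # neighbor mean is 1 + 1/(w[x]w[y] - 1) and the deviation 1/(w[x]w[y] - 1)
  w <- c(4, 5, 6, 7, 6, 5, 4)
  s1 <- sum(outer(w, w, function(a, b) 1 / (a * b - 1))) - 1 / 48
  expect_equal(nm$s_i[1], s1, tolerance = 1e-12)
  expect_equal(nm$n_i, c(48L, 1L))
})

test_that("irregular masks use in-mask neighbors only (oracle check)", {
  set.seed(51)
  for (rep in 1:8) {
    d <- random_discretized_roi(c(sample(4:7, 1), sample(4:7, 1),
                                  sample(2:3, 1)), Ng = sample(3:6, 1),
                                mask_prob = 0.6)
    nm <- build_ngtdm(d)
    o <- oracle_ngtdm(d)
    expect_equal(nm$n_i, o$n_i)
    expect_equal(nm$s_i, o$s_i, tolerance = 1e-10)
    expect_equal(nm$n_valid, o$n_valid)
    expect_equal(sum(nm$n_i), nm$n_valid)
  }
})

test_that("the 3D window option widens the neighborhood", {
  d <- random_discretized_roi(c(5, 5, 3), Ng = 4)
  nm2d <- build_ngtdm(d, window_halfwidth = c(3L, 3L, 0L))
  nm3d <- build_ngtdm(d, window_halfwidth = c(3L, 3L, 1L))
  o3 <- oracle_ngtdm(d, hw = c(3L, 3L, 1L))
  expect_equal(nm3d$s_i, o3$s_i, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(nm2d$s_i, nm3d$s_i)))
})

test_that("ngtdm errors when nothing can be scored", {
  v <- tiny_volume(5)
  m <- full_mask_like(v)
  d <- suppressWarnings(discretize_roi(v, m, Ng = 2))
  expect_error(build_ngtdm(d), "no voxel")
})
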