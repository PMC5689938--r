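test_that("direction set has the 13 canonical offsets", {
  ds <- direction_set_3d()
  expect_equal(nrow(ds), 13L)
  expect_true(all(abs(ds) <= 1L))
  expect_true(all(rowSums(abs(ds)) > 0L))
  keys <- apply(ds, 1, paste, collapse = ",")
  negkeys <- apply(-ds, 1, paste, collapse = ",")
  expect_length(intersect(keys, negkeys), 0L)
  expect_error(check_directions(rbind(c(1, 0, 0), c(-1, 0, 0))), "negation")
})

test_that("constant ROI gives the analytic GLCM limits", {
  v <- tiny_volume(array(2, c(3, 3, 2)))
  m <- full_mask_like(v)
  d <- suppressWarnings(discretize_roi(v, m, Ng = 8))
  g <- build_glcm(d)
  expect_equal(unclass(g)[1, 1], 1)
  f <- glcm_features(g)
  expect_equal(unname(f["glcm_idm"]), 1)   # maximum when all values equal
  expect_equal(unname(f["glcm_id"]), 1)
  expect_equal(unname(f["glcm_entropy"]), 0)
  expect_equal(unname(f["glcm_joint_average"]), 1)
})

test_that("a two-voxel two-level ROI gives the symmetric 0.5 pair", {
  v <- tiny_volume(c(0, 10))
  m <- full_mask_like(v)
  d <- discretize_roi(v, m, Ng = 2)
  g <- unclass(build_glcm(d))
  expect_equal(g[1, 2], 0.5)
  expect_equal(g[2, 1], 0.5)
  expect_equal(g[1, 1] + g[2, 2], 0)
})

test_that("checkerboard slab with a single in-plane offset matches the hand-built matrix", {
  vals <- array(0, c(4, 4, 1))
  vals[] <- outer(1:4, 1:4, function(i, j) (i + j) %% 2) * 10
  v <- suv_volume(vals, c(1, 1, 1))
  m <- full_mask_like(v)
  d <- discretize_roi(v, m, Ng = 2)
  g <- build_glcm(d, directions = matrix(c(1L, 0L, 0L), 1))
  # 24 ordered horizontal pairs, all between different levels
  expect_equal(unclass(g), matrix(c(0, 0.5, 0.5, 0), 2),
               ignore_attr = TRUE)
  f <- glcm_features(g)
  expect_equal(unname(f["glcm_contrast"]), 1)
  expect_equal(unname(f["glcm_entropy"]), 1)      # two equal outcomes
  expect_equal(unname(f["glcm_idm"]), 0.5)
  expect_equal(unname(f["glcm_correlation"]), -1)
})

test_that("GLCM matches the brute-force oracle on random ROIs", {
  set.seed(21)
  for (rep in 1:12) {
    d <- random_discretized_roi(c(sample(3:6, 1), sample(3:6, 1),
                                  sample(2:4, 1)), Ng = sample(3:8, 1))
    g <- build_glcm(d)
    expect_equal(unclass(g), oracle_glcm(d), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # structural invariants
    expect_equal(sum(unclass(g)), 1)
    expect_equal(unclass(g), t(unclass(g)), ignore_attr = TRUE)
  }
})

test_that("degenerate and invalid GLCM inputs error", {
  v <- tiny_volume(5)
  m <- full_mask_like(v)
  d <- suppressWarnings(discretize_roi(v, m, Ng = 4))
  expect_error(build_glcm(d), "undefined")
  expect_error(glcm_features(matrix(c(2, 0, 0, 0), 2)), "not normalized")
})
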