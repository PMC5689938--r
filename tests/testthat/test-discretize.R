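test_that("bin size follows the fixed-bin-count rule", {
  v <- tiny_volume(c(0, 10, 5, 2))
  m <- full_mask_like(v)
  d <- discretize_roi(v, m, Ng = 32)
  expect_equal(d$bin_size, 0.3125)
  expect_equal(d$suv_min, 0)
  expect_equal(d$suv_max, 10)
})

test_that("floor rule and top-edge inclusion give the expected levels", {
  v <- tiny_volume(c(1, 2, 3, 4))
  m <- full_mask_like(v)
  d <- discretize_roi(v, m, Ng = 2)
  expect_equal(d$bin_size, 1.5)
  expect_equal(as.integer(d$levels), c(1L, 1L, 2L, 2L))
})

test_that("constant ROI degenerates to all level 1 with a warning", {
  v <- tiny_volume(rep(3.5, 6))
  m <- full_mask_like(v)
  expect_warning(d <- discretize_roi(v, m, Ng = 64), "constant ROI")
  expect_true(all(d$levels[d$mask] == 1L))
  expect_equal(d$bin_size, 0)
})

test_that("invalid inputs error", {
  v <- tiny_volume(c(1, 2))
  m <- full_mask_like(v)
  expect_error(discretize_roi(v, m, Ng = 1), "Ng")
  expect_error(discretize_roi(v, roi_mask(array(0, c(2, 1, 1)), c(1, 1, 1)),
                              Ng = 4), "empty ROI")
  m32 <- roi_mask(array(1, c(3, 1, 1)), c(1, 1, 1))
  expect_error(discretize_roi(v, m32, Ng = 4), "geometry mismatch")
})

test_that("discretization properties hold on random ROIs", {
  set.seed(11)
  for (rep in 1:20) {
    dims <- c(sample(3:6, 1), sample(3:6, 1), sample(2:4, 1))
    vals <- array(runif(prod(dims), 0, 20), dims)
    msk <- array(runif(prod(dims)) < 0.8, dims)
    if (sum(msk) < 2) msk[1:2] <- TRUE
    Ng <- sample(c(4L, 8L, 32L), 1)
    v <- suv_volume(vals, c(1, 1, 1))
    m <- roi_mask(msk, c(1, 1, 1))
    d <- suppressWarnings(discretize_roi(v, m, Ng))
    lv <- d$levels[d$mask]
    sv <- vals[msk]
    # range and histogram conservation
    expect_true(all(lv >= 1L & lv <= Ng))
    expect_equal(sum(level_histogram(d)), sum(msk))
    # monotonicity in SUV
    ord <- order(sv)
    expect_true(all(diff(lv[ord]) >= 0L))
    # shift invariance (range-relative binning); offset chosen exactly
    # representable so fp subtraction is exact
    d2 <- suppressWarnings(discretize_roi(
      suv_volume(vals + 64, c(1, 1, 1)), m, Ng))
    expect_identical(d2$levels, d$levels)
  }
})
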