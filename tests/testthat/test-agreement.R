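test_that("Dice identities and worked overlap", {
  a <- roi_mask(array(c(1, 1, 1, 1, 0, 0, 0, 0), c(8, 1, 1)), c(1, 1, 1))
  b <- roi_mask(array(c(0, 0, 1, 1, 1, 1, 0, 0), c(8, 1, 1)), c(1, 1, 1))
  disj <- roi_mask(array(c(0, 0, 0, 0, 1, 1, 1, 1), c(8, 1, 1)), c(1, 1, 1))
  empty <- roi_mask(array(0, c(8, 1, 1)), c(1, 1, 1))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, disj), 0)
  expect_equal(dice(a, b), 0.5)            # |A|=|B|=4, overlap 2
  expect_error(dice(empty, empty), "undefined")
})

test_that("paired differences reproduce the worked examples", {
  # identical variants
  ft <- toy_feature_table(list(MTV1 = c(2, 3, 4), GBSV = c(2, 3, 4)))
  r <- paired_differences(ft, c("MTV1", "GBSV"), "SM")
  expect_equal(r$d_mean_abs, 0)
  expect_equal(r$sd, 0)
  expect_equal(r$url, 0)
  expect_equal(r$lrl, 0)

  # single case f_m = 3, f_n = 1 -> d = 100%
  ft2 <- toy_feature_table(list(MTV1 = 3, GBSV = 1))
  r2 <- paired_differences(ft2, c("MTV1", "GBSV"), "SM")
  expect_equal(r2$d[[1]], 100)

  # d = {-2, 0, 2}: mean 0, SD 2, URL 3.92, LRL -3.92; choose fn so that
  # (fm - fn) / ((fm + fn)/2) * 100 equals the wanted d exactly
  fm <- c(98, 100, 102)
  dwant <- c(-2, 0, 2)
  fn <- fm * (200 - dwant) / (200 + dwant)
  ft3 <- toy_feature_table(list(MTV1 = fm, GBSV = fn))
  r3 <- paired_differences(ft3, c("MTV1", "GBSV"), "SM")
  expect_equal(r3$d[[1]], dwant, tolerance = 1e-10)
  expect_equal(r3$sd, 2, tolerance = 1e-10)
  expect_equal(r3$url, 3.92, tolerance = 1e-8)
  expect_equal(r3$lrl, -3.92, tolerance = 1e-8)
  expect_equal(r3$url - r3$lrl, 2 * 1.96 * r3$sd, tolerance = 1e-10)
})

test_that("zero-denominator cases are excluded per feature with a log", {
  ft <- toy_feature_table(list(MTV1 = c(1, -2, 5), GBSV = c(1, 2, 5)))
  expect_message(r <- paired_differences(ft, c("MTV1", "GBSV"), "SM"),
                 "excluded")
  expect_equal(r$n_cases, 2L)
  expect_equal(r$n_excluded, 1L)
})

test_that("pair order antisymmetry", {
  set.seed(91)
  ft <- toy_feature_table(list(MTV1 = runif(8, 1, 5), GBSV = runif(8, 1, 5)))
  fw <- paired_differences(ft, c("MTV1", "GBSV"), "SM")
  bw <- paired_differences(ft, c("GBSV", "MTV1"), "SM")
  expect_equal(bw$d[[1]], -fw$d[[1]])
  expect_equal(bw$d_mean_abs, fw$d_mean_abs)
  expect_equal(bw$sd, fw$sd)
  expect_equal(bw$url, -fw$lrl)
  expect_equal(bw$lrl, -fw$url)
})

test_that("reproducibility classification follows the printed bands", {
  mk <- function(dma, sd, lrl, url) {
    data.frame(d_mean_abs = dma, sd = sd, lrl = lrl, url = url)
  }
  expect_equal(as.character(classify_reproducibility(
    mk(5, 10, -20, 25))$class), "High")
  expect_equal(as.character(classify_reproducibility(
    mk(5, 10, -44, 20))$class), "Intermediate")
  expect_equal(as.character(classify_reproducibility(
    mk(5, 10, -20, 48))$class), "Low")
  expect_equal(as.character(classify_reproducibility(
    mk(5, 10, -55, 20))$class), "NR")
  # inclusive edges
  expect_equal(as.character(classify_reproducibility(
    mk(5, 10, -30, 30))$class), "High")
  expect_equal(as.character(classify_reproducibility(
    mk(5, 10, -45, 0))$class), "Intermediate")
  expect_equal(as.character(classify_reproducibility(
    mk(5, 10, -50, 0))$class), "Low")
  # near-zero limits are graded High
  expect_equal(as.character(classify_reproducibility(
    mk(0.1, 0.1, -0.5, 0.5))$class), "High")
  # the |d|/SD gate overrides good limits
  expect_equal(as.character(classify_reproducibility(
    mk(26, 10, -20, 20))$class), "NR")
  expect_equal(as.character(classify_reproducibility(
    mk(5, 36, -20, 20))$class), "NR")
})

test_that("classification is monotone in SD", {
  set.seed(92)
  for (rep in 1:30) {
    dma <- runif(1, 0, 30)
    dm <- runif(1, -1, 1) * dma
    sds <- sort(runif(2, 0, 45))
    cls <- vapply(sds, function(s) {
      as.character(classify_reproducibility(
        data.frame(d_mean_abs = dma, sd = s,
                   lrl = dm - 1.96 * s, url = dm + 1.96 * s))$class)
    }, character(1))
    rank <- c(High = 1, Intermediate = 2, Low = 3, NR = 4)
    expect_lte(rank[cls[1]], rank[cls[2]])
  }
})

test_that("ICC(A,1) matches the frozen reference values", {
  y <- icc_fixture_matrix()
  r <- icc_a1(y)
  expect_equal(r$icc, 0.7607599029, tolerance = 1e-9)
  expect_equal(r$ci_lb, 0.3187560060, tolerance = 1e-8)
  expect_equal(r$ci_ub, 0.9273310812, tolerance = 1e-8)
  expect_equal(r$precision, precision_from_ci(r$ci_lb, r$ci_ub))
})

test_that("ICC degenerate cases behave as documented", {
  # identical raters, varying cases -> ICC 1 with collapsed CI
  y <- matrix(rep(c(1, 5, 9, 2, 7), 3), ncol = 3)
  r <- icc_a1(y)
  expect_equal(r$icc, 1)
  expect_equal(r$precision, 0)
  # zero between-case variance -> NA sentinel with warning
  y0 <- matrix(3, 5, 3)
  expect_warning(r0 <- icc_a1(y0), "zero between-case variance")
  expect_true(is.na(r0$icc))
  expect_error(icc_a1(matrix(1, 2, 2)), ">= 3 cases")
})

test_that("icc_with_precision works per feature on a table", {
  y <- icc_fixture_matrix()
  ft <- toy_feature_table(list(MTV1 = y[, 1], MTV2 = y[, 2],
                               GBSV = y[, 3]))
  out <- icc_with_precision(ft, "SM")
  expect_equal(out$icc, 0.7607599029, tolerance = 1e-9)
  expect_equal(out$n_cases, 12L)
  expect_equal(out$n_levels, 3L)
  # level subsetting drops a rater
  out2 <- icc_with_precision(ft, "SM", levels = c("MTV1", "MTV2"))
  expect_equal(out2$n_levels, 2L)
})

test_that("precision formula reproduces the worked CI examples", {
  expect_equal(precision_from_ci(0.84, 0.94), 5)
  expect_equal(precision_from_ci(0.93, 0.98), 2.5)
  # order-insensitive (tables sometimes print upper bound first)
  expect_equal(precision_from_ci(0.98, 0.93), 2.5)
})

test_that("inter-item correlation hits the exact limits", {
  set.seed(93)
  base <- runif(10, 1, 5)
  ft <- toy_feature_table(list(`64` = base, `128` = base,
                               `256` = -base, `32` = rep(2, 10)),
                          parameter = "GL")
  out <- inter_item_correlation(ft, reference_gl = 64)
  expect_equal(out$iic[out$gray_level == 128], 1)
  expect_equal(out$iic[out$gray_level == 256], -1)
  expect_true(is.na(out$iic[out$gray_level == 32]))
  expect_true(out$constant[out$gray_level == 32])
})

test_that("Bland-Altman limits cover ~95% of normal differences", {
  set.seed(94)
  cover <- replicate(20, {
    d <- rnorm(400, mean = 2, sd = 5)
    fm <- 100 + d / 2
    fn <- 100 - d / 2
    # convert to the percentage-difference scale used by the pipeline
    ft <- toy_feature_table(list(MTV1 = fm, GBSV = fn))
    r <- paired_differences(ft, c("MTV1", "GBSV"), "SM")
    mean(r$d[[1]] >= r$lrl & r$d[[1]] <= r$url)
  })
  expect_lt(abs(mean(cover) * 100 - 95), 3)
})
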