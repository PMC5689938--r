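# Phantom tests use a reduced grid (40 x 40 x 28, tumor radius 16 mm) so
# the full property suites stay inside the test-time budget; the generator
# code path is identical to the full-size default.
small_spec <- function(seed = 1L, ...) {
  phantom_spec(grid_shape = c(40L, 40L, 28L), tumor_radius_mm = 16,
               seed = seed, ...)
}

test_that("noiseless tumor is exactly flat and deterministic", {
  spec <- small_spec(heterogeneity_amp = 0)
  v <- generate_tumor_volume(spec)
  m <- attr(v, "true_mask")
  expect_true(all(v$values[m$values == 1L] == spec$suv_tumor_mean))
  expect_true(all(v$values[m$values == 0L] == spec$suv_background))
  v2 <- generate_tumor_volume(spec)
  expect_identical(v$values, v2$values)
})

test_that("heterogeneous tumor is deterministic and calibrated", {
  spec <- small_spec(seed = 7)
  v1 <- generate_tumor_volume(spec)
  v2 <- generate_tumor_volume(spec)
  expect_identical(v1$values, v2$values)
  v3 <- generate_tumor_volume(small_spec(seed = 8))
  expect_false(identical(v1$values, v3$values))
  tum <- v1$values[attr(v1, "true_mask")$values == 1L]
  expect_equal(mean(tum), spec$suv_tumor_mean, tolerance = 0.02)
  expect_equal(sd(tum), spec$heterogeneity_amp, tolerance = 0.05)
  expect_true(all(v1$values >= 0))
})

test_that("tumor voxel count matches the analytic ellipsoid volume", {
  spec <- phantom_spec(tumor_radius_mm = 20, seed = 1)
  v <- generate_tumor_volume(spec)
  n <- sum(attr(v, "true_mask")$values)
  expected <- (4 / 3) * pi * 20^3 / prod(spec$voxel_spacing_mm)
  expect_lt(abs(n / expected - 1), 0.20)
})

test_that("oversized tumors error with the violated dimension", {
  expect_error(generate_tumor_volume(
    phantom_spec(grid_shape = c(16L, 64L, 48L), tumor_radius_mm = 60)),
    "axis 1")
})

test_that("zero perturbation reproduces the true mask exactly", {
  spec <- small_spec(seed = 2)
  v <- generate_tumor_volume(spec)
  tm <- attr(v, "true_mask")
  ms <- make_mask_variants(v, tm, perturbation_mm = c(MTV1 = 0, MTV2 = 0,
                                                      GBSV = 0), seed = 5)
  for (m in ms) {
    expect_identical(m$values, tm$values)
    expect_equal(dice(m, tm), 1)
  }
})

test_that("modest jitter changes the mask but respects the Dice floor", {
  spec <- small_spec(seed = 3)
  v <- generate_tumor_volume(spec)
  tm <- attr(v, "true_mask")
  ms <- make_mask_variants(v, tm, seed = 11)
  diffs <- vapply(ms, function(m) sum(m$values != tm$values), numeric(1))
  expect_true(all(diffs > 0))
  for (m in ms) expect_gte(dice(m, tm), 0.75)
})

test_that("mask variants pass the Dice floor across many seeded cases", {
  # invariant checked on 100 seeds (reduced grid for runtime)
  spec0 <- small_spec()
  worst <- 1
  for (s in 1:100) {
    spec <- small_spec(seed = s)
    v <- generate_tumor_volume(spec)
    tm <- attr(v, "true_mask")
    ms <- suppressMessages(make_mask_variants(v, tm, seed = s + 1000))
    labs <- names(ms)
    for (a in 1:2) for (b in (a + 1):3) {
      worst <- min(worst, dice(ms[[a]], ms[[b]]))
    }
    for (m in ms) worst <- min(worst, dice(m, tm))
  }
  expect_gte(worst, 0.75)
})

test_that("recon variants honor the identity reference and noise ladder", {
  spec <- small_spec(seed = 4)
  v <- generate_tumor_volume(spec)
  rv <- make_recon_variants(v, seed = 9)
  expect_named(rv, c("OSEM", "FOREIR", "FOREFBP", "3DRP"))
  expect_identical(rv$OSEM$values, v$values)     # identity-like reference
  divergence <- vapply(rv, function(x) mean(abs(x$values - v$values)),
                       numeric(1))
  expect_equal(unname(divergence["OSEM"]), 0)
  # monotone in the profile ladder, 3DRP most divergent
  expect_lt(divergence["FOREIR"], divergence["FOREFBP"])
  expect_lt(divergence["FOREFBP"], divergence["3DRP"])

  # degenerate profiles: four identical volumes
  flat <- lapply(c(OSEM = 1, FOREIR = 1, FOREFBP = 1, `3DRP` = 1),
                 function(i) list(fwhm_mm = 0, noise_sd = 0))
  rv0 <- make_recon_variants(v, flat, seed = 9)
  for (x in rv0) expect_identical(x$values, v$values)

  expect_error(make_recon_variants(v, flat[1:3]), "four")
  expect_error(make_recon_variants(
    v, stats::setNames(flat, c("A", "B", "C", "D"))), "OSEM")
})

test_that("case bundles are pure functions of (spec, seed)", {
  spec <- small_spec(seed = 6)
  b1 <- suppressMessages(generate_case_bundle(spec))
  b2 <- suppressMessages(generate_case_bundle(spec))
  expect_identical(b1$base_volume$values, b2$base_volume$values)
  for (lab in names(b1$mask_variants)) {
    expect_identical(b1$mask_variants[[lab]]$values,
                     b2$mask_variants[[lab]]$values)
  }
  for (lab in names(b1$recon_variants)) {
    expect_identical(b1$recon_variants[[lab]]$values,
                     b2$recon_variants[[lab]]$values)
  }
})

test_that("phantom cohorts serialize with a manifest", {
  out <- withr::local_tempdir()
  man <- write_phantom_cohort(out, n_cases = 2,
                              spec_template = small_spec())
  expect_length(man$cases, 2L)
  files <- list.files(out)
  expect_true("manifest.json" %in% files)
  expect_equal(sum(grepl("_vol_", files)), 8L)   # 4 recon x 2 cases
  expect_equal(sum(grepl("_mask_", files)), 6L)  # 3 masks x 2 cases
  v <- read_volume(file.path(out, man$cases$case001$volume_OSEM))
  expect_equal(dim(v$values), c(40L, 40L, 28L))
})
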