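test_that("NIfTI volumes round-trip voxelwise (nii and nii.gz)", {
  set.seed(81)
  vals <- array(runif(4 * 5 * 3, 0, 12), c(4, 5, 3))
  v <- suv_volume(vals, c(5.49, 5.49, 3.30), origin = c(-10, 4, 2.5))
  for (ext in c("vol.nii", "vol.nii.gz")) {
    path <- file.path(withr::local_tempdir(), ext)
    write_volume(v, path)
    r <- read_volume(path)
    expect_equal(r$values, v$values, tolerance = 1e-6)  # float32 storage
    expect_equal(r$spacing_mm, v$spacing_mm, tolerance = 1e-6)
    expect_equal(r$origin, v$origin, tolerance = 1e-5)
  }
})

test_that("NRRD volumes round-trip exactly (double storage)", {
  set.seed(82)
  vals <- array(runif(3 * 4 * 2, 0, 12), c(3, 4, 2))
  v <- suv_volume(vals, c(2, 2, 3))
  path <- file.path(withr::local_tempdir(), "vol.nrrd")
  write_volume(v, path)
  r <- read_volume(path)
  expect_identical(r$values, v$values)
  expect_equal(r$spacing_mm, v$spacing_mm)
})

test_that("masks coerce nonzero values to 1 and round-trip", {
  mv <- array(c(0, 2, 0, 5, 1, 0), c(6, 1, 1))
  m <- roi_mask(mv, c(1, 1, 1), label = "MTV1")
  expect_equal(as.integer(m$values), c(0L, 1L, 0L, 1L, 1L, 0L))
  for (ext in c("m.nii.gz", "m.nrrd")) {
    path <- file.path(withr::local_tempdir(), ext)
    write_mask(m, path)
    r <- read_mask(path, label = "MTV1")
    expect_equal(r$values, m$values)
  }
})

test_that("geometry and validity errors are descriptive", {
  v <- suv_volume(array(1, c(4, 4, 4)), c(1, 1, 1))
  tmp <- withr::local_tempdir()
  mpath <- file.path(tmp, "small.nii")
  write_mask(roi_mask(array(1, c(2, 2, 2)), c(1, 1, 1)), mpath)
  expect_error(read_mask(mpath, volume = v), "geometry mismatch")
  expect_error(read_volume(file.path(tmp, "nope.nii")), "not found")
  expect_error(suv_volume(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)),
               "non-finite")
  expect_error(suv_volume(matrix(1, 2, 2), c(1, 1, 1)), "3D")
  # a 4D NIfTI is rejected
  p4 <- file.path(tmp, "v4.nii")
  write_nifti_raw(array(1, c(2, 2, 2)), c(1, 1, 1), c(0, 0, 0), p4)
  # forge dim[0] = 4 with an extra axis of length 2
  con <- file(p4, "r+b")
  seek(con, 40, rw = "write")
  writeBin(c(4L, 2L, 2L, 2L, 2L), con, size = 2L, endian = "little")
  close(con)
  expect_error(read_volume(p4), "not a 3D")
})

test_that("feature tables round-trip and enforce the schema", {
  ft <- feature_table(
    case_id = rep(c("c1", "c2", "c3"), each = 2),
    segmentation = "MTV1", gray_level = 64L, recon = "OSEM",
    feature = rep(c("glcm_idm", "glrlm_sre"), 3),
    value = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  path <- file.path(withr::local_tempdir(), "feat.csv")
  write_feature_table(ft, path)
  rt <- read_feature_table(path)
  expect_equal(as.data.frame(rt), as.data.frame(ft))

  # duplicate variant rows rejected
  dup <- rbind(as.data.frame(ft), as.data.frame(ft)[1, ])
  expect_error(validate_feature_table(dup), "duplicate")
  # missing feature named in the error
  expect_error(
    validate_feature_table(as.data.frame(ft),
                           features = c("glcm_idm", "glrlm_sre",
                                        "glszm_zp")),
    "glszm_zp")
  # missing column named
  expect_error(validate_feature_table(ft[, -6]), "value")

  # empty table: valid file with header only
  empty <- ft[0, ]
  write_feature_table(empty, path)
  expect_equal(nrow(read_feature_table(path)), 0L)
})
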