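test_that("DICOM time strings parse to seconds since midnight", {
  expect_identical(parse_dicom_time("000000"), 0)
  expect_equal(parse_dicom_time("130512.5"), 13 * 3600 + 5 * 60 + 12.5)
  expect_equal(parse_dicom_time("235959.999999"), 86399.999999)
  expect_error(parse_dicom_time("236000"), "invalid")
  expect_error(parse_dicom_time("1305"), "malformed")
  expect_error(parse_dicom_time("12:05:00"), "malformed")
})

test_that("a phantom PET series round-trips through DICOM", {
  spec <- one_organ_spec(rescale_slope = 0.25)
  ph <- generate_phantom(spec)
  d <- withr::local_tempdir()
  write_dicom_series(ph$pet_raw, d, spec$suv_params)
  rt <- read_pet_series(d)
  # stored 16-bit integers: lossless up to rounding of the raw value
  expect_lt(max(abs(rt$volume$values - ph$pet_raw$values)), 0.5 + 1e-12)
  expect_grid_equal(rt$volume$grid, ph$pet_raw$grid, tol = 1e-4)
  p <- rt$params
  ref <- spec$suv_params
  expect_equal(p$patient_weight, ref$patient_weight)
  expect_equal(p$total_dose, ref$total_dose)
  expect_equal(p$radiopharmaceutical_start_time,
               ref$radiopharmaceutical_start_time)
  expect_equal(p$series_time, ref$series_time)
  expect_equal(p$half_life, ref$half_life)
  expect_equal(p$rescale_slope, ref$rescale_slope)
  # SUV after the round trip agrees with the in-memory conversion
  suv_rt <- convert_to_suv(rt$volume, p)
  suv_mem <- convert_to_suv(ph$pet_raw, ref)
  expect_lt(max(abs(suv_rt$values - suv_mem$values)),
            0.5 * ref$rescale_slope * 70000 / ref$total_dose + 1e-9)
})

test_that("slice order on disk does not affect the assembled volume", {
  spec <- one_organ_spec()
  ph <- generate_phantom(spec)
  d1 <- withr::local_tempdir()
  write_dicom_series(ph$pet_raw, d1, spec$suv_params)
  # shuffle by renaming so lexicographic order differs from slice order
  d2 <- withr::local_tempdir()
  files <- list.files(d1, full.names = TRUE)
  set.seed(4)
  for (i in seq_along(files)) {
    file.copy(files[i], file.path(d2, sprintf("x_%03d.dcm",
                                              sample(1000, 1) * 10 + i)))
  }
  a <- read_pet_series(d1)
  b <- read_pet_series(d2)
  expect_identical(a$volume$values, b$volume$values)
  expect_grid_equal(a$volume$grid, b$volume$grid)
})

test_that("missing SUV attributes are reported by name", {
  spec <- one_organ_spec()
  ph <- generate_phantom(spec)
  d <- withr::local_tempdir()
  params_nw <- spec$suv_params
  write_dicom_series(ph$pet_raw, d, params_nw)
  # strip the weight tag by rewriting without params, keeping times
  d2 <- withr::local_tempdir()
  g <- ph$pet_raw$grid
  for (k in seq_len(g$dims[3])) {
    meta <- list(modality = "PT", rows = g$dims[2], cols = g$dims[1],
                 pixel_spacing = c(g$spacing[2], g$spacing[1]),
                 slice_thickness = g$spacing[3],
                 image_position = as.numeric(voxel_to_patient(g, c(0, 0, k - 1))),
                 image_orientation = c(g$orientation[, 1], g$orientation[, 2]),
                 series_uid = "1.2.3.4", series_root = "9", instance = k,
                 series_time = "100000", start_time = "090000",
                 total_dose = 3.7e8, rescale_slope = 0.5)
    petquant:::write_dicom_slice(file.path(d2, sprintf("s%03d.dcm", k)),
                                 ph$pet_raw$values[, , k], meta)
  }
  expect_error(read_pet_series(d2), "patient_weight absent")
})

test_that("mixed series in one directory are rejected", {
  spec <- one_organ_spec()
  ph <- generate_phantom(spec)
  d <- withr::local_tempdir()
  write_dicom_series(ph$pet_raw, d, spec$suv_params)
  ct <- generate_phantom(spec)$ct
  ct$values[] <- pmax(ct$values, 0)  # 16-bit unsigned storage
  d_ct <- withr::local_tempdir()
  write_dicom_series(ct, d_ct)
  file.copy(list.files(d_ct, full.names = TRUE),
            file.path(d, paste0("ct_", list.files(d_ct))))
  expect_error(read_pet_series(d), "mixed series")
})

test_that("volumes and label masks round-trip through NIfTI", {
  spec <- tumor_spec()
  ph <- generate_phantom(spec)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_nifti(ph$ct, f)
  rt <- read_volume_nifti(f, "CT")
  expect_identical(rt$values, ph$ct$values)
  expect_grid_equal(rt$grid, ph$ct$grid, tol = 1e-4)

  # non-overlapping organ masks round-trip exactly through one label
  # volume; the tumor overlaps its host breast, so it is written last
  # and wins those voxels
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask_nifti(ph$masks_ct, fm)
  masks <- read_mask(fm)
  expect_length(masks, length(ph$masks_ct))
  expect_identical(masks$label_3$voxels, ph$masks_ct$liver$voxels)
  expect_identical(masks$label_6$voxels, ph$masks_ct$tumor$voxels)
  expect_identical(masks$label_1$voxels,
                   ph$masks_ct$breast_right$voxels &
                     !ph$masks_ct$tumor$voxels)
})

test_that("non-integer label volumes are rejected", {
  g <- volume_grid(c(4, 4, 4), c(1, 1, 1))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_nifti(scalar_volume(array(0.5, c(4, 4, 4)), g, "CT"), f)
  expect_error(read_mask(f), "integer")
  # an all-zero label volume yields an empty mask list
  f0 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_nifti(scalar_volume(array(0, c(4, 4, 4)), g, "CT"), f0)
  expect_length(read_mask(f0), 0)
})
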