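test_that("mask centroid matches geometric expectations", {
  g <- volume_grid(c(9, 9, 9), c(2, 2, 2))
  one <- array(FALSE, c(9, 9, 9)); one[3, 4, 5] <- TRUE
  expect_equal(mask_centroid(binary_mask(one, g)),
               as.numeric(voxel_to_patient(g, c(2, 3, 4))),
               ignore_attr = TRUE)
  cube <- array(FALSE, c(9, 9, 9)); cube[3:5, 3:5, 3:5] <- TRUE
  expect_equal(mask_centroid(binary_mask(cube, g)),
               as.numeric(voxel_to_patient(g, c(3, 3, 3))),
               ignore_attr = TRUE)
  # ellipsoid phantom: centroid within one voxel of the true center
  spec <- one_organ_spec()
  ph <- generate_phantom(spec)
  cen <- mask_centroid(ph$masks_pet$liver)
  expect_lt(max(abs(cen - spec$organs[[1]]$center)), max(spec$pet_grid$spacing))
  expect_error(mask_centroid(binary_mask(array(FALSE, c(9, 9, 9)), g)),
               "empty")
})

test_that("sphere VOI voxel membership matches brute-force enumeration", {
  g <- volume_grid(c(31, 31, 31), c(1, 1, 1))
  ctr <- c(15, 15, 15)
  m <- sphere_voi_mask(g, spherical_voi(ctr, 12))
  # oracle: loop over all voxel centers
  count <- 0L
  for (k in 0:30) for (j in 0:30) for (i in 0:30) {
    if (sum((c(i, j, k) - ctr)^2) <= 144) count <- count + 1L
  }
  expect_identical(sum(m$voxels), count)
  # volume within 3% of (4/3) pi 1.2^3 = 7.238 mL
  expect_lt(abs(mask_volume_ml(m) - 4 / 3 * pi * 1.2^3) / (4 / 3 * pi * 1.2^3),
            0.03)
})

test_that("a sub-voxel sphere on a voxel center captures that voxel", {
  g <- volume_grid(c(5, 5, 5), c(2, 2, 2))
  m <- sphere_voi_mask(g, spherical_voi(c(4, 4, 4), 0.9))
  expect_identical(sum(m$voxels), 1L)
  expect_true(m$voxels[3, 3, 3])
  expect_error(sphere_voi_mask(g, spherical_voi(c(50, 50, 50), 5)),
               "outside")
})

test_that("roi statistics agree with an exhaustive member-voxel scan", {
  spec <- one_organ_spec(noise_sd = 20, seed = 3)
  ph <- generate_phantom(spec)
  suv <- convert_to_suv(ph$pet_raw, spec$suv_params)
  st <- roi_statistics(suv, ph$masks_pet$liver)
  # brute-force loop oracle
  best <- -Inf; total <- 0; n <- 0L; best_idx <- NULL
  d <- dim(suv$values)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (ph$masks_pet$liver$voxels[i, j, k]) {
      v <- suv$values[i, j, k]
      total <- total + v; n <- n + 1L
      if (v > best) { best <- v; best_idx <- c(i, j, k) }
    }
  }
  expect_equal(st$suv_max, best)
  expect_equal(st$suv_mean, total / n)
  expect_identical(st$max_voxel, as.integer(best_idx))
  expect_identical(st$voxel_count, n)
  expect_equal(st$volume_ml, n * voxel_volume_ml(spec$pet_grid))
  expect_gte(st$suv_max, st$suv_mean)
})

test_that("uniform regions have equal max and mean", {
  spec <- one_organ_spec(target_suv = 2)
  ph <- generate_phantom(spec)
  suv <- convert_to_suv(ph$pet_raw, spec$suv_params)
  st <- roi_statistics(suv, ph$masks_pet$liver)
  expect_equal(st$suv_max, 2, tolerance = 1e-9)
  expect_equal(st$suv_mean, 2, tolerance = 1e-9)
})

test_that("hot tumors pull the max and split contour vs VOI means", {
  spec <- tumor_spec(tumor_suv = 8)
  ph <- generate_phantom(spec)
  suv <- convert_to_suv(ph$pet_raw, spec$suv_params)
  st <- roi_statistics(suv, ph$masks_pet$breast_right)
  expect_equal(st$suv_max, 8, tolerance = 1e-9)
  expect_true(ph$masks_pet$tumor$voxels[st$max_voxel[1], st$max_voxel[2],
                                        st$max_voxel[3]])
  # single-VOI mean at the centroid differs from the whole-organ mean
  rep <- organ_suv_report(suv, ph$masks_pet["breast_right"])
  expect_gt(abs(rep$suv_mean_voi - rep$suv_mean_contour), 0)
})

test_that("grid mismatch between SUV and mask is an error", {
  spec <- tumor_spec()
  ph <- generate_phantom(spec)
  suv <- convert_to_suv(ph$pet_raw, spec$suv_params)
  expect_error(roi_statistics(suv, ph$masks_ct$liver), "grids")
})
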