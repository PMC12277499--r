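test_that("uniform organs delineate to the whole organ at any fraction", {
  spec <- one_organ_spec(target_suv = 2)
  ph <- generate_phantom(spec)
  suv <- convert_to_suv(ph$pet_raw, spec$suv_params)
  for (f in c(0.4, 0.5, 0.9)) {
    les <- delineate_by_fraction(suv, ph$masks_pet$liver, f)
    expect_identical(les$mask$voxels, ph$masks_pet$liver$voxels)
    expect_equal(les$reference_suv_max, 2, tolerance = 1e-9)
  }
})

test_that("fractional thresholds nest: the 50% lesion is inside the 40%", {
  for (seed in 1:5) {
    spec <- tumor_spec(tumor_suv = 4 + seed, noise_sd = 10, seed = seed)
    ph <- generate_phantom(spec)
    suv <- convert_to_suv(ph$pet_raw, spec$suv_params)
    l40 <- delineate_by_fraction(suv, ph$masks_pet$breast_right, 0.4)
    l50 <- delineate_by_fraction(suv, ph$masks_pet$breast_right, 0.5)
    expect_true(all(l50$mask$voxels <= l40$mask$voxels))
    expect_lte(l50$volume_ml, l40$volume_ml)
  }
})

test_that("the maximum voxel always belongs to the lesion (inclusive cut)", {
  spec <- tumor_spec(noise_sd = 15, seed = 2)
  ph <- generate_phantom(spec)
  suv <- convert_to_suv(ph$pet_raw, spec$suv_params)
  les <- delineate_by_fraction(suv, ph$masks_pet$breast_right, 0.999)
  st <- roi_statistics(suv, ph$masks_pet$breast_right)
  expect_true(les$mask$voxels[st$max_voxel[1], st$max_voxel[2],
                              st$max_voxel[3]])
  expect_gte(les$voxel_count, 1L)
})

test_that("TLG agrees between the voxel sum and mean-times-volume routes", {
  # closed form: uniform lesion
  spec <- one_organ_spec(target_suv = 3)
  ph <- generate_phantom(spec)
  suv <- convert_to_suv(ph$pet_raw, spec$suv_params)
  les <- delineate_by_fraction(suv, ph$masks_pet$liver, 0.5)
  vv <- voxel_volume_ml(spec$pet_grid)
  expect_equal(total_lesion_glycolysis(les), 3 * les$voxel_count * vv)
  # noisy lesion: two-route identity to rounding
  specn <- tumor_spec(noise_sd = 20, seed = 9)
  phn <- generate_phantom(specn)
  suvn <- convert_to_suv(phn$pet_raw, specn$suv_params)
  lesn <- delineate_by_fraction(suvn, phn$masks_pet$breast_right, 0.4)
  by_sum <- sum(suvn$values[lesn$mask$voxels]) * voxel_volume_ml(specn$pet_grid)
  expect_equal(total_lesion_glycolysis(lesn), by_sum)
  expect_equal(lesn$tlg, lesn$suv_mean * lesn$volume_ml)
})

test_that("single-voxel lesion has TLG = SUV times voxel volume", {
  g <- volume_grid(c(4, 4, 4), c(10, 10, 10))  # 1 mL voxels
  vals <- array(0.1, c(4, 4, 4)); vals[2, 2, 2] <- 2
  suv <- scalar_volume(vals, g, "SUV")
  organ <- binary_mask(array(TRUE, c(4, 4, 4)), g)
  les <- delineate_by_fraction(suv, organ, 0.5)
  expect_identical(les$voxel_count, 1L)
  expect_equal(total_lesion_glycolysis(les), 2)
})

test_that("a lesion threshold above every voxel warns and returns zero", {
  g <- volume_grid(c(3, 3, 3), c(5, 5, 5))
  suv <- scalar_volume(array(1, c(3, 3, 3)), g, "SUV")
  organ <- binary_mask(array(TRUE, c(3, 3, 3)), g)
  les <- delineate_by_fraction(suv, organ, 0.5)
  les$voxel_count <- 0L  # simulate an emptied lesion
  expect_warning(expect_identical(total_lesion_glycolysis(les), 0), "empty")
})

test_that("non-positive organ uptake cannot be thresholded", {
  g <- volume_grid(c(3, 3, 3), c(5, 5, 5))
  suv <- scalar_volume(array(0, c(3, 3, 3)), g, "SUV")
  organ <- binary_mask(array(TRUE, c(3, 3, 3)), g)
  expect_error(delineate_by_fraction(suv, organ, 0.5), "not positive")
  expect_error(delineate_by_fraction(suv, organ, 1.2), "fraction")
})

test_that("largest-component filtering keeps one connected lesion", {
  g <- volume_grid(c(10, 4, 4), c(3, 3, 3))
  vals <- array(0, c(10, 4, 4))
  vals[1:3, 2, 2] <- 5      # 3-voxel component
  vals[8:9, 2, 2] <- c(5, 6)  # 2-voxel component holding the max
  suv <- scalar_volume(vals, g, "SUV")
  organ <- binary_mask(array(TRUE, c(10, 4, 4)), g)
  all_vox <- delineate_by_fraction(suv, organ, 0.5)
  expect_identical(all_vox$voxel_count, 5L)
  largest <- delineate_by_fraction(suv, organ, 0.5, largest_component = TRUE)
  expect_identical(largest$voxel_count, 3L)
  expect_true(all(which(largest$mask$voxels) %in% which(vals == 5)[1:3]))
})

test_that("cumulative SUV histograms are monotone and anchored at 1", {
  spec <- tumor_spec(noise_sd = 10, seed = 6)
  ph <- generate_phantom(spec)
  suv <- convert_to_suv(ph$pet_raw, spec$suv_params)
  for (mode in c("percent_of_max", "absolute")) {
    h <- cumulative_suv_histogram(suv, ph$masks_pet$breast_right, mode)
    expect_equal(h$fraction[1], 1)  # all SUVs >= 0
    expect_true(all(diff(h$fraction) <= 1e-12))
    expect_true(all(h$fraction >= 0 & h$fraction <= 1))
    expect_equal(nrow(h), 101)
  }
})

test_that("uniform uptake gives a flat histogram up to its maximum", {
  spec <- one_organ_spec(target_suv = 2)
  ph <- generate_phantom(spec)
  suv <- convert_to_suv(ph$pet_raw, spec$suv_params)
  h <- cumulative_suv_histogram(suv, ph$masks_pet$liver, "absolute")
  expect_true(all(h$fraction == 1))
})

test_that("tumor histograms retain volume where healthy ones shed it", {
  # noise is the same in stored units everywhere, so relative to its own
  # SUVmax the hot tumor keeps nearly all volume up to high percent
  # thresholds (convex downward) while the low-uptake healthy breast
  # sheds volume well before 100% (convex upward)
  spec <- tumor_spec(tumor_suv = 8, noise_sd = 300, seed = 12)
  ph <- generate_phantom(spec)
  suv <- convert_to_suv(ph$pet_raw, spec$suv_params)
  h_tum <- cumulative_suv_histogram(suv, ph$masks_pet$tumor)
  h_healthy <- cumulative_suv_histogram(suv, ph$masks_pet$breast_left)
  band <- h_tum$threshold >= 50 & h_tum$threshold <= 95
  expect_true(all(h_tum$fraction[band] >= h_healthy$fraction[band]))
  high <- h_tum$threshold >= 85 & h_tum$threshold <= 95
  expect_gt(mean(h_tum$fraction[high]) - mean(h_healthy$fraction[high]), 0.2)
})
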