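test_that("resampling to the identical grid is the identity", {
  spec <- one_organ_spec()
  ph <- generate_phantom(spec)
  out <- resample(ph$pet_raw, ph$pet_raw$grid)
  expect_identical(out$values, ph$pet_raw$values)
})

test_that("a constant volume stays constant in the interior", {
  g1 <- volume_grid(c(20, 20, 20), c(2, 2, 2))
  g2 <- volume_grid(c(12, 12, 12), c(3, 3, 3), origin = c(1, 1, 1))
  vol <- scalar_volume(array(7, g1$dims), g1, "PET")
  out <- resample(vol, g2, "trilinear")
  # all of g2's centers lie inside g1's extent here
  expect_equal(unique(as.vector(out$values)), 7)
})

test_that("mask transfer CT to PET grid preserves volume to a voxel shell", {
  spec <- tumor_spec()
  ph <- generate_phantom(spec)
  m_ct <- ph$masks_ct$liver
  m_pet <- resample(m_ct, spec$pet_grid)
  # oracle: direct rasterization on the PET grid
  ref <- ph$masks_pet$liver
  v_ref <- mask_volume_ml(ref)
  # shell volume: boundary voxel count of the reference times voxel volume
  expect_lt(abs(mask_volume_ml(m_pet) - v_ref) / v_ref, 0.15)
  expect_gt(dice(m_pet, ref), 0.9)
})

test_that("dice matches its closed-form cases and is symmetric", {
  g <- volume_grid(c(6, 6, 6), c(1, 1, 1))
  cube <- function(x0) {
    v <- array(FALSE, c(6, 6, 6)); v[x0:(x0 + 1), 1:2, 1:2] <- TRUE
    binary_mask(v, g)
  }
  a <- cube(1)
  expect_identical(dice(a, a), 1)
  disjoint <- cube(4)
  expect_identical(dice(a, disjoint), 0)
  # 8-voxel cubes overlapping in 4 voxels: 2*4/16
  b <- cube(2)
  expect_equal(dice(a, b), 0.5)
  expect_identical(dice(a, b), dice(b, a))
  empty <- binary_mask(array(FALSE, c(6, 6, 6)), g)
  expect_identical(dice(empty, empty), 1)
  g2 <- volume_grid(c(6, 6, 6), c(2, 2, 2))
  expect_error(dice(a, binary_mask(array(TRUE, c(6, 6, 6)), g2)),
               "different grids")
})

test_that("registering a volume to itself stays at the identity", {
  ph <- generate_phantom(one_organ_spec())
  reg <- register_rigid(ph$ct, ph$ct,
                        register_config(max_iterations = 60))
  expect_lt(sqrt(sum(reg$transform$translation^2)), 0.1)
  ang <- acos(pmin(1, (sum(diag(reg$transform$rotation)) - 1) / 2))
  expect_lt(ang * 180 / pi, 0.1)
})

test_that("known translations are recovered within half a PET voxel", {
  spec <- tumor_spec()
  ph <- generate_phantom(spec)
  fixed <- ph$ct
  for (shift in list(c(6, -4, 3), c(9, 2, -8))) {
    # pulling fixed through (p -> p + shift) moves the image content by
    # -shift; registration must recover the inverse pull-back, -shift
    moving <- resample(fixed, fixed$grid,
                       transform = rigid_transform(diag(3), shift))
    reg <- register_rigid(fixed, moving, register_config(rotations = FALSE))
    err <- sqrt(sum((reg$transform$translation + shift)^2))
    expect_lt(err, 1.5)  # half of the 3 mm PET voxel
    expect_true(reg$converged)
  }
})

test_that("registration of pure noise reports itself honestly", {
  g <- volume_grid(c(12, 12, 12), c(3, 3, 3))
  set.seed(5)
  a <- scalar_volume(array(rnorm(12^3), g$dims), g, "CT")
  b <- scalar_volume(array(rnorm(12^3), g$dims), g, "CT")
  reg <- register_rigid(a, b, register_config(max_iterations = 40,
                                              rotations = FALSE))
  # either fails to converge or stays near the identity with a weak match
  near_identity <- sqrt(sum(reg$transform$translation^2)) < 6
  expect_true(!reg$converged || near_identity)
  expect_error(register_rigid(a, scalar_volume(array(1, g$dims), g, "CT")),
               "non-constant")
})
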